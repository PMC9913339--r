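test_that("wiener paths have the exact increment law", {
  tg <- seq(0, 1, by = 0.1)
  expect_identical(wiener_path(tg, 0, seed = 1), numeric(length(tg)))
  expect_identical(wiener_path(tg, 0.2, seed = 11),
                   wiener_path(tg, 0.2, seed = 11))
  expect_false(identical(wiener_path(tg, 0.2, seed = 11),
                         wiener_path(tg, 0.2, seed = 12)))
  expect_error(wiener_path(c(0, 0.2, 0.1), 0.1), "increasing")
  # ensemble variance at t = 1 equals rho^2 within 5%
  rho <- 0.3
  w1 <- vapply(1:10000, function(i)
    wiener_path(tg, rho, seed = i)[length(tg)], numeric(1))
  expect_lt(abs(var(w1) - rho^2) / rho^2, 0.05)
})

test_that("noised-parameter ensemble variance follows rho^2 t", {
  # chi-squared bounds at the 1% level, N = 1000
  n <- 1000
  rho <- 0.1
  tg <- seq(0, 10, by = 0.1)
  W <- vapply(1:n, function(i) wiener_path(tg, rho, seed = 2000 + i),
              numeric(length(tg)))
  for (tt in c(1, 5, 10)) {
    i <- which(tg == tt)
    v <- mean(W[i, ]^2)  # known zero mean
    stat <- n * v / (rho^2 * tt)
    expect_gt(stat, qchisq(0.005, n))
    expect_lt(stat, qchisq(0.995, n))
  }
})

test_that("zero noise reproduces the deterministic trajectory", {
  for (nm in c("fig1a", "fig1b")) {
    sc <- get_scenario(nm)
    ns <- noise_spec("lambda", rho = 0)
    st <- simulate_stochastic(sc$model, ns, sc$init, t_end = 10, seed = 1,
                              dt = 0.001)
    det <- simulate_csm(sc$model, sc$init, t_end = 10)
    # compare on the exactly shared grid points (0.02 = 20 x 0.001)
    i_st <- seq(1, length(st$times), by = 20L)
    expect_lt(max(abs(st$times[i_st] - det$times)), 1e-9)
    for (v in c("S", "D", "a", "m"))
      expect_lt(max(abs(st$states[[v]][i_st] - det$states[[v]])), 1e-6,
                label = nm)
  }
})

test_that("stochastic integration agrees with the frozen-path oracle", {
  # the noise is state-independent, so conditioning on the sampled path
  # turns the SDE into a non-autonomous ODE that an adaptive deterministic
  # solver can integrate independently
  sc <- get_scenario("fig1b")
  ns <- noise_spec("d", rho = 0.10)
  dt <- 0.005
  for (seed in 1:10) {
    st <- simulate_stochastic(sc$model, ns, sc$init, t_end = 10,
                              seed = seed, dt = dt)
    path_fun <- approxfun(st$param_path$time, st$param_path$value,
                          method = "constant", rule = 2)
    params_at <- function(t) update_params(sc$model,
                                           d = max(path_fun(t), 1e-12))
    det <- simulate_csm(sc$model, sc$init, t_end = 10,
                        params_at = params_at)
    expect_state_close(final_state(st)[c("S", "D", "m")],
                       final_state(det)[c("S", "D", "m")], 1e-3)
  }
})

test_that("noise on the death rate spreads D more than S", {
  sc <- get_scenario("fig2d")
  b <- simulate_bundle(sc$model, sc$noise, sc$init, t_end = 10, n = 20,
                       base_seed = 5)
  w <- bundle_width(b, t = 10)
  expect_gt(w$sigma_D, 2 * w$sigma_S)
})

test_that("bundles are deterministic under the seed ladder and flag excursions", {
  sc <- get_scenario("fig1b")
  ns <- noise_spec("lambda", rho = 0.10)
  b1 <- simulate_bundle(sc$model, ns, sc$init, t_end = 2, n = 5,
                        base_seed = 3, dt = 0.01)
  b2 <- simulate_bundle(sc$model, ns, sc$init, t_end = 2, n = 5,
                        base_seed = 3, dt = 0.01)
  expect_identical(b1$S, b2$S)
  expect_identical(b1$param_paths, b2$param_paths)
  # zero-noise bundle: all trajectories identical, width zero
  b0 <- simulate_bundle(sc$model, noise_spec("lambda", rho = 0), sc$init,
                        t_end = 2, n = 5, base_seed = 1, dt = 0.01)
  expect_identical(b0$S[, 1], b0$S[, 5])
  w <- bundle_width(b0, 2)
  expect_identical(w$sigma_S, 0)
  expect_identical(w$sigma_D, 0)
  # violent noise on d eventually drives it negative -> flagged
  nsbig <- suppressWarnings(noise_spec("d", rho = 0.5))
  bb <- simulate_bundle(params_for("fig1b"), nsbig, sc$init, t_end = 50,
                        n = 5, base_seed = 2, dt = 0.05)
  expect_true(any(vapply(bb$flags, function(f)
    "nonphysical_parameter" %in% f, logical(1))))
})

test_that("the closed-form Gaussian MLE matches an independent fitter", {
  set.seed(99)
  x <- rnorm(400, mean = 0.3, sd = 0.02)
  fit <- csmsim:::gaussian_mle(x)
  ref <- MASS::fitdistr(x, "normal")
  expect_equal(fit[["mu"]], unname(ref$estimate["mean"]), tolerance = 1e-6)
  expect_equal(fit[["sigma"]], unname(ref$estimate["sd"]),
               tolerance = 1e-6)
  # consistency at N = 1000: recovered sigma within 3 standard errors
  x <- rnorm(1000, 0.3, 0.02)
  se <- 0.02 / sqrt(2 * 1000)
  expect_lt(abs(csmsim:::gaussian_mle(x)[["sigma"]] - 0.02), 3 * se)
})

test_that("the fitted width of the noised parameter follows rho sqrt(t)", {
  rho <- 0.02  # absolute, on a unit-rate parameter
  tg <- seq(0, 4, by = 0.5)
  W <- vapply(1:1000, function(i) wiener_path(tg, rho, seed = 400 + i),
              numeric(length(tg)))
  for (tt in c(1, 4)) {
    sig <- csmsim:::gaussian_mle(W[which(tg == tt), ])[["sigma"]]
    expect_lt(abs(sig - rho * sqrt(tt)) / (rho * sqrt(tt)), 0.10)
  }
})

test_that("width growth linearity check separates lines from exponentials", {
  tg <- seq(0.2, 10, by = 0.2)
  lin <- structure(data.frame(t = tg, sigma_D = 0.003 * tg),
                   class = c("csm_width_series", "data.frame"))
  # exact linear data trips lm's perfect-fit warning; that is the point
  chk <- suppressWarnings(width_growth_check(lin, t_max = 10))
  expect_equal(chk$slope, 0.003, tolerance = 1e-10)
  expect_gt(chk$r_squared, 0.999)
  expect_true(chk$linear)
  expo <- structure(data.frame(t = tg, sigma_D = 1e-4 * exp(tg)),
                    class = c("csm_width_series", "data.frame"))
  chk <- width_growth_check(expo, t_max = 10)
  expect_false(chk$linear)
  expect_gt(length(chk$breakout_times), 0)
})

test_that("width fitting needs at least two usable trajectories", {
  sc <- get_scenario("fig1b")
  ns <- noise_spec("lambda", rho = 0.10)
  b <- simulate_bundle(sc$model, ns, sc$init, t_end = 1, n = 2,
                       base_seed = 1, dt = 0.01)
  b$flags[[1]] <- "nonphysical_parameter"
  expect_error(bundle_width(b, 1), "fewer than 2")
})
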