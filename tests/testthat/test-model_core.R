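test_that("parameter and state constructors enforce their invariants", {
  expect_s3_class(csm_params(), "csm_params")
  expect_error(csm_params(d = -0.1), "strictly positive")
  expect_error(csm_params(S0 = 1.2), "S0")
  expect_warning(csm_params(sq = 0.6), "sq")
  expect_warning(csm_params(sl = 0.7), "sl")
  expect_error(csm_state(0.7, 0.5, 0, 0), "exceeds 1")
  expect_error(csm_state(-0.1, 0, 0, 0), "non-negative")
  expect_error(csm_state(0.1, 0.1, -1, 0), "non-negative")
  p <- csm_params()
  expect_equal(update_params(p, d = 0.4)$d, 0.4)
  expect_error(update_params(p, nosuch = 1), "unknown parameter")
})

test_that("division probability matches hand-evaluated values and is monotone", {
  p <- csm_params(eta = 5, psi = 1)
  expect_identical(division_probability(0, 0, p), 0)
  expect_equal(division_probability(0, 1, p), 5 / 6, tolerance = 1e-12)
  expect_equal(division_probability(1, 1, p), 5 / 12, tolerance = 1e-12)
  a <- seq(0, 20, length.out = 50)
  expect_true(all(diff(division_probability(0.3, a, p)) > 0))
  D <- seq(0, 1, length.out = 50)
  expect_true(all(diff(division_probability(D, 2, p)) < 0))
  expect_true(all(division_probability(D, 1e6, p) < 1))
  expect_error(division_probability(-1, 0.5, p), "non-negative")
})

test_that("plasticity rate is a sharp switch around m0", {
  p <- csm_params(q0 = 1)
  expect_equal(plasticity_rate(p$m0, p), 0.5)
  expect_lt(abs(plasticity_rate(p$m0 + 10 * p$sq, p) - 1), 1e-8)
  expect_lt(plasticity_rate(0, p), 1e-20)
  m <- seq(0, 2, length.out = 100)
  q <- plasticity_rate(m, p)
  expect_true(all(q >= 0 & q <= p$q0))
  expect_error(plasticity_rate(-0.1, p), "non-negative")
})

test_that("saturation factor caps confluence", {
  p <- csm_params()
  expect_identical(saturation_factor(0.6, 0.4, p), 0)
  expect_equal(saturation_factor(0, 0, p), tanh(10), tolerance = 1e-15)
  expect_equal(saturation_factor(0.5, 0.4, p), tanh(1), tolerance = 1e-15)
  expect_error(saturation_factor(0.7, 0.5, p), "physical region")
})

test_that("the vector field vanishes at F1 and respects mass balance", {
  p <- params_for("fig1b")
  f1 <- csm_field(csm_state(0, 0, 0, p$gamma / p$alpha_m), p)
  expect_identical(unname(f1), c(0, 0, 0, 0))
  # closed-form F2 is a near-root of the full field
  f2 <- fixed_point_f2(p, classify = FALSE)
  expect_lt(max(abs(csm_field(f2$location, p))), 1e-6)
  # with no stem cells, D decays at exactly rate d and plasticity feeds S
  st <- csm_state(0, 0.3, 0, 0.2)
  f <- csm_field(st, p)
  q <- plasticity_rate(0.2, p)
  expect_equal(f[["D"]], -(p$d + q) * 0.3, tolerance = 1e-15)
  expect_equal(f[["S"]], q * 0.3, tolerance = 1e-15)
  expect_lt(abs(f[["S"]]), 1e-10)  # q(0.2) is numerically zero
  # mass balance: dS + dD == Upsilon*lambda*S - d*D at machine precision
  set.seed(42)
  for (i in 1:50) {
    S <- runif(1, 0, 0.6); D <- runif(1, 0, 1 - S)
    st <- csm_state(S, D, runif(1, 0, 5), runif(1, 0, 2))
    f <- csm_field(st, p)
    net <- saturation_factor(S, D, p) * p$lambda * S - p$d * D
    expect_lt(abs(f[["S"]] + f[["D"]] - net), 1e-12)
  }
})

test_that("a trajectory started at F1 stays there", {
  p <- params_for("fig1b")
  f1 <- fixed_point_f1(p, classify = FALSE)
  tr <- simulate_csm(p, csm_state(0, 0, 0, f1$location[["m"]]), t_end = 20)
  dev <- max(abs(as.matrix(tr$states) -
                   matrix(f1$location, nrow(tr$states), 4, byrow = TRUE)))
  expect_lt(dev, 1e-8)
})

test_that("the fig1b regime relaxes onto F2 within 1% by t = 20", {
  sc <- get_scenario("fig1b")
  tr <- simulate_csm(sc$model, sc$init, t_end = 20)
  f2 <- fixed_point_f2(sc$model, classify = FALSE)
  fs <- final_state(tr)
  for (v in c("S", "D", "m"))
    expect_lt(abs(fs[[v]] - f2$location[[v]]) / f2$location[[v]], 0.01)
  expect_lt(fs[["a"]], 1e-6)
})

test_that("trajectories stay in the physical domain across scenarios", {
  for (nm in c("fig1a", "fig1b", "fig2c", "fig5d")) {
    sc <- get_scenario(nm)
    tr <- simulate_csm(sc$model, sc$init, sc$t_end)
    expect_true(all(tr$states$S >= -1e-9), label = nm)
    expect_true(all(tr$states$D >= -1e-9), label = nm)
    expect_true(all(tr$states$S + tr$states$D <= 1 + 1e-9), label = nm)
    expect_true(all(tr$states$a >= 0 & tr$states$m >= 0), label = nm)
    expect_false(has_event(tr, "bound_violation"), label = nm)
  }
})

test_that("tightening solver tolerances does not move the solution", {
  for (nm in c("fig1a", "fig1b", "fig2c")) {
    sc <- get_scenario(nm)
    lo <- simulate_csm(sc$model, sc$init, sc$t_end,
                       opts = solver_opts(rtol = 1e-6, atol = 1e-8))
    hi <- simulate_csm(sc$model, sc$init, sc$t_end,
                       opts = solver_opts(rtol = 1e-9, atol = 1e-11))
    expect_state_close(final_state(lo), final_state(hi), 1e-4)
  }
})

test_that("the untreated high-activator regime overshoots then regresses", {
  sc <- get_scenario("fig5d")
  tr <- simulate_csm(sc$model, sc$init, sc$t_end)
  tot <- tr$states$S + tr$states$D
  expect_gt(max(tot), tot[length(tot)])
  expect_gt(tr$times[which.max(tot)], 1)  # the peak is a real excursion
  expect_false(has_event(tr, "divergence"))
})

test_that("divergence and extinction events are detected", {
  # runaway: high activator with no treatment pressure off D
  sc <- get_scenario("fig6a")
  tr <- simulate_csm(sc$model, sc$init, sc$t_end)
  expect_true(has_event(tr, "divergence"))
  expect_lt(tr$times[length(tr$times)], sc$t_end)  # halted early
  expect_gte(max(tr$states$a), 1e6 * (1 - 1e-6))
  # extinction: a tiny colony under a supercritical death rate
  p <- params_for("fig1a")
  tr2 <- simulate_csm(p, csm_state(0, 1e-4, 0, 1), t_end = 40)
  expect_true(has_event(tr2, "extinction"))
})
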