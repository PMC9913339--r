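test_that("dose-to-peak inversion matches its closed form", {
  z <- dose_rate_for_peak(1.0, 10, 0.08)
  expect_equal(z, 18.15966220916094, tolerance = 1e-12)  # frozen evaluation
  # saturated-uptake limit: zeta -> chi_max * alpha_d
  expect_equal(dose_rate_for_peak(2, 10, 50), 20, tolerance = 1e-9)
  expect_error(dose_rate_for_peak(1, 10, 0), "tau")
  # definitional round trip: the schedule built from chi_max peaks there
  sch <- table4_schedule()
  expect_equal(drug_level(sch$tau, sch), 1.0, tolerance = 1e-9)
})

test_that("drug level follows the piecewise-exponential solution", {
  sch <- table4_schedule()
  t <- seq(0, sch$tau, length.out = 20)
  expect_equal(drug_level(t, sch),
               sch$zeta * (1 - exp(-sch$alpha_d * t)) / sch$alpha_d,
               tolerance = 1e-12)
  # peak over one period is chi_max, attained at tau
  tt <- seq(0, sch$T, by = 1e-4)
  chi <- drug_level(tt, sch)
  expect_equal(max(chi), 1.0, tolerance = 1e-6)
  expect_equal(tt[which.max(chi)], sch$tau, tolerance = 2e-4)
  # negligible accumulation: chi(T) = chi(tau) e^{-alpha_d (T - tau)}
  expect_equal(drug_level(sch$T, sch),
               drug_level(sch$tau, sch) * exp(-sch$alpha_d *
                                                (sch$T - sch$tau)),
               tolerance = 1e-12)
  expect_lt(drug_level(sch$T, sch), 2e-4)
})

test_that("analytic kinetics agree with direct ODE integration", {
  pk_ode <- function(sch, t_end) {
    rhs <- function(t, y, parms) {
      u <- t - sch$t_start
      infusing <- u >= 0 & (u - floor(u / sch$T) * sch$T) < sch$tau
      list((if (infusing) sch$zeta else 0) - sch$alpha_d * y)
    }
    # restart on every phase boundary to respect the discontinuity
    bounds <- sort(unique(c(
      0, sch$t_start + rep(0:ceiling(t_end / sch$T), each = 2) * sch$T +
        c(0, sch$tau), t_end)))
    bounds <- bounds[bounds >= 0 & bounds <= t_end]
    y <- 0; out_t <- 0; out_chi <- 0
    for (i in seq_len(length(bounds) - 1)) {
      times <- seq(bounds[i], bounds[i + 1], length.out = 25)
      sol <- deSolve::ode(c(chi = y), times, rhs, NULL, method = "lsoda",
                          rtol = 1e-11, atol = 1e-13)
      y <- unname(sol[nrow(sol), "chi"])
      out_t <- c(out_t, times[-1]); out_chi <- c(out_chi, sol[-1, "chi"])
    }
    list(t = out_t, chi = out_chi)
  }
  sch <- table4_schedule()
  num <- pk_ode(sch, 10 * sch$T)
  expect_lt(max(abs(drug_level(num$t, sch) - num$chi)), 1e-8)
  # ten random valid schedules
  set.seed(1234)
  for (i in 1:10) {
    Tp <- runif(1, 0.5, 3)
    tau <- runif(1, 0.02, 0.2) * Tp
    sch <- suppressWarnings(
      drug_schedule(chi_max = runif(1, 0.5, 3),
                    alpha_d = runif(1, 5, 30), T = Tp, tau = tau,
                    t_start = sample(c(0, 0.5), 1)))
    num <- pk_ode(sch, 10 * sch$T)
    expect_lt(max(abs(drug_level(num$t, sch) - num$chi)), 1e-8)
  }
})

test_that("start-of-period levels converge geometrically", {
  sch <- suppressWarnings(drug_schedule(chi_max = 1, alpha_d = 4, T = 1,
                                        tau = 0.3))
  # stop before the increments underflow double precision
  n <- 0:6
  chi_n <- drug_level(n * sch$T + 1e-12, sch)
  expect_true(all(diff(chi_n) >= -1e-12))
  ratios <- diff(chi_n)[-1] / diff(chi_n)[-length(diff(chi_n))]
  expect_equal(ratios, rep(exp(-sch$alpha_d * sch$T), length(ratios)),
               tolerance = 1e-6)
})

test_that("the action function has the prescribed midpoint and plateaus", {
  act <- table4_action()
  expect_equal(drug_action(act$chi0, act), act$omega0 / 2)
  expect_equal(drug_action(1e6, act), act$omega0, tolerance = 1e-12)
  expect_equal(drug_action(0, act), 3.353501304664781e-4,
               tolerance = 1e-12)  # frozen evaluation at chi = 0
  chi <- seq(0, 1, length.out = 200)
  expect_true(all(diff(drug_action(chi, act)) > 0))
  expect_error(drug_action(-0.1, act), "non-negative")
})

test_that("therapy couplings rewrite the right parameter", {
  base <- params_for("fig5ac")
  sch <- table4_schedule()
  act <- table4_action()
  cyt <- therapy_spec("cytotoxic", sch, act)
  # before dosing starts the leakage is Omega(0)
  sch2 <- drug_schedule(chi_max = 1, alpha_d = 10, T = 1, tau = 0.08,
                        t_start = 5)
  eff0 <- effective_params(1, base, therapy_spec("cytotoxic", sch2, act))
  expect_lt(eff0$params$d - base$d, act$omega0 * 3.4e-4)
  # at the pulse peak d rises by nearly the full action magnitude
  effp <- effective_params(sch$tau, base, cyt)
  expect_equal(effp$params$d, base$d + act$omega0, tolerance = 1e-3)
  # clamped cytostatic never goes negative
  strong <- action_params(omega0 = 5, chi0 = 0.2, s_chi = 0.05)
  cst <- therapy_spec("cytostatic", sch, strong)
  lam <- vapply(seq(0, 1, by = 0.01), function(t)
    effective_params(t, base, cst)$params$lambda, numeric(1))
  expect_true(all(lam >= 0))
  expect_identical(min(lam), 0)
  # combined therapy returns a plasticity offset and raises d
  comb <- therapy_spec("differentiation_plus_cytotoxic", sch, act,
                       action_cyto = act)
  effc <- effective_params(sch$tau, base, comb)
  expect_equal(effc$q_offset, drug_action(1, act), tolerance = 1e-9)
  expect_gt(effc$params$d, base$d + 0.9)
  # wiring validation
  expect_error(therapy_spec("differentiation_plus_cytotoxic", sch, act),
               "action_cyto")
  expect_error(therapy_spec("cytotoxic", sch, act, action_cyto = act),
               "only meaningful")
})

test_that("a vanishing action magnitude reproduces the untreated run", {
  sc <- get_scenario("fig5a")
  null_act <- action_params(omega0 = 1e-10, chi0 = 0.2, s_chi = 0.05)
  th <- therapy_spec("cytotoxic", table4_schedule(), null_act)
  treated <- simulate_with_therapy(sc$model, th, sc$init, t_end = 10)
  untreated <- simulate_csm(sc$model, sc$init, t_end = 10)
  for (v in c("S", "D", "a", "m")) {
    u <- traj_at(untreated, v, treated$times)
    expect_lt(max(abs(treated$states[[v]] - u)), 1e-6)
  }
})

test_that("cytotoxic dosing drives the colony toward extinction", {
  sc <- get_scenario("fig5a")
  res <- run_scenario(sc)
  tu <- final_state(res$untreated)
  tt <- final_state(res$treated)
  f2 <- fixed_point_f2(sc$model, classify = FALSE)
  # untreated settles near F2; treated is far below and still falling
  expect_lt(abs(tu[["S"]] + tu[["D"]] -
                  (f2$location[["S"]] + f2$location[["D"]])), 0.02)
  expect_lt(tt[["S"]] + tt[["D"]], 0.25 * (tu[["S"]] + tu[["D"]]))
  tot <- res$treated$states$S + res$treated$states$D
  n <- length(tot)
  expect_lt(tot[n], tot[n - 100])  # decreasing tail
})
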