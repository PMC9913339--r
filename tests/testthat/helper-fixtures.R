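# Shared parameter fixtures: built from the scenario table so tests and
# fixtures cannot drift apart.
params_for <- function(row) {
  tab <- scenario_param_rows()
  r <- tab[tab$row == row, ]
  csm_params(alpha_a = r$alpha_a, alpha_m = r$alpha_m, beta = r$beta,
             gamma = r$gamma, eta = r$eta, psi = r$psi, d = r$d, q0 = r$q0)
}

# Reference drug machinery (shared kinetic/action constants).
table4_schedule <- function() drug_schedule(chi_max = 1.0, alpha_d = 10,
                                            T = 1.0, tau = 0.08)
table4_action <- function() action_params(omega0 = 1.0, chi0 = 0.2,
                                          s_chi = 0.05)

# Interpolate a trajectory variable onto arbitrary times.
traj_at <- function(tr, v, t) {
  stats::approx(tr$times, tr$states[[v]], xout = t)$y
}

expect_state_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
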