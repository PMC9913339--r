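# Run code with a locally-scoped RNG state so package functions never
# disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' White-noise specification for a model parameter
#'
#' Declares which rate constant evolves as a Wiener process
#' \eqn{dX_t = \rho\, dW_t} on top of the otherwise deterministic system.
#' The primary targets are the cell-level rates (`lambda`, `d`, `q0`); the
#' activator-level constants (`eta`, `psi`, `alpha_a`, `alpha_m`) are also
#' accepted. With `amplitude_mode = "relative"` (default) `rho` is a
#' fraction of the parameter's base value; realistic studies use 5--20%
#' and a warning is issued outside that range. `rho = 0` is the
#' deterministic limit.
#'
#' @param target name of the noised parameter.
#' @param rho noise amplitude (fraction if relative, parameter units if
#'   absolute); >= 0.
#' @param amplitude_mode `"relative"` or `"absolute"`.
#' @param seed optional default RNG seed, overridable per simulation call.
#' @return A list of class `csm_noise_spec`.
#' @examples
#' noise_spec("d", rho = 0.10)
#' @export
noise_spec <- function(target = c("lambda", "d", "q0", "eta", "psi",
                                  "alpha_a", "alpha_m"),
                       rho, amplitude_mode = c("relative", "absolute"),
                       seed = NULL) {
  target <- match.arg(target)
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(is.numeric(rho), length(rho) == 1L, rho >= 0)
  if (amplitude_mode == "relative" && rho > 0 &&
      (rho < 0.05 || rho > 0.20))
    warning("relative noise amplitude ", rho, " is outside the realistic ",
            "5%-20% range", call. = FALSE)
  structure(list(target = target, rho = rho,
                 amplitude_mode = amplitude_mode, seed = seed),
            class = "csm_noise_spec")
}

#' Sample a Wiener path on a time grid
#'
#' Draws one realization of \eqn{W(t)} with `W(0) = 0` and independent
#' Gaussian increments: over a step \eqn{\Delta t} the increment is
#' \eqn{N(0, \rho^2\Delta t)}. Sampling at the grid points is exact (no
#' discretization error in the path itself).
#'
#' @param t_grid strictly increasing time grid starting anywhere.
#' @param rho diffusion amplitude (>= 0).
#' @param seed RNG seed; the same seed reproduces the path bitwise.
#' @return Numeric vector of `W` values along `t_grid`, first element 0.
#' @export
wiener_path <- function(t_grid, rho, seed = NULL) {
  if (any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  stopifnot(rho >= 0)
  n <- length(t_grid)
  if (rho == 0) return(numeric(n))
  with_local_seed(seed, {
    inc <- stats::rnorm(n - 1, mean = 0, sd = rho * sqrt(diff(t_grid)))
    c(0, cumsum(inc))
  })
}

# Lean field evaluation for the fixed-step stochastic stepper (no class
# checks; tolerates transient nonphysical parameter values by design).
field_raw <- function(S, D, a, m, p) {
  S <- max(S, 0); D <- max(D, 0); a <- max(a, 0); m <- max(m, 0)
  pp <- p$eta * a / ((1 + p$eta * a) * (1 + p$psi * D))
  q  <- p$q0 / 2 * (1 + tanh((m - p$m0) / p$sq))
  up <- tanh(max(1 - S - D, 0) / p$sl)
  mitosis <- up * p$lambda * S
  c((2 * pp - 1) * mitosis + q * D,
    2 * (1 - pp) * mitosis - (p$d + q) * D,
    a * (p$beta * S * a / (1 + a) - p$alpha_a),
    p$gamma * exp(-S / p$S0) - p$alpha_m * m)
}

#' Simulate one stochastic trajectory
#'
#' Joint evolution of the state and one Wiener-noised parameter. The
#' parameter path is sampled exactly on the step grid ([wiener_path()]
#' added to the base value); the state is advanced with a classical
#' fixed-step fourth-order Runge-Kutta step holding the parameter at its
#' value at the start of the step (Ito convention). Since the noise is
#' independent of the state, this is equivalent to solving the frozen-path
#' non-autonomous ODE, which is also how it is cross-checked in the test
#' suite. A trajectory whose noised parameter leaves \eqn{(0, \infty)} is
#' flagged `nonphysical_parameter` (and, under `policy = "clamp"`, the
#' parameter is clamped at 0 instead; `policy = "resample"` redraws the
#' whole path, up to 20 attempts). A trajectory whose activator crosses
#' `a_ceiling` is flagged `divergence` and truncated (NA beyond).
#'
#' @param p base [csm_params()].
#' @param noise a [noise_spec()].
#' @param init initial [csm_state()].
#' @param t_end final time (day).
#' @param seed RNG seed (falls back to `noise$seed`).
#' @param dt fixed integration step (day).
#' @param policy handling of nonphysical parameter excursions:
#'   `"flag"` (default: keep simulating, record the flag), `"clamp"`, or
#'   `"resample"`.
#' @param a_ceiling divergence threshold on the activator.
#' @return A `csm_trajectory` with extra elements `param_path` (data.frame
#'   `time`, `value`) and `flags` (character vector).
#' @export
simulate_stochastic <- function(p, noise, init, t_end, seed = NULL,
                                dt = 0.005, policy = c("flag", "clamp",
                                                       "resample"),
                                a_ceiling = 1e6) {
  stopifnot(inherits(p, "csm_params"), inherits(noise, "csm_noise_spec"),
            t_end > 0, dt > 0)
  policy <- match.arg(policy)
  if (is.null(seed)) seed <- noise$seed
  base <- p[[noise$target]]
  rho_abs <- if (noise$amplitude_mode == "relative") noise$rho * base
             else noise$rho
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  flags <- character(0)
  path <- base + wiener_path(times, rho_abs, seed)
  if (policy == "resample" && !is.null(seed)) {
    tries <- 0
    while (any(path <= 0) && tries < 20) {
      tries <- tries + 1
      path <- base + wiener_path(times, rho_abs, seed + 1000003L * tries)
    }
    if (any(path <= 0)) flags <- c(flags, "nonphysical_parameter")
  } else if (any(path <= 0)) {
    flags <- c(flags, "nonphysical_parameter")
    if (policy == "clamp") path <- pmax(path, 0)
  }
  nt <- length(times)
  Y <- matrix(NA_real_, nt, 4, dimnames = list(NULL, c("S", "D", "a", "m")))
  y <- c(unname(init[["S"]]), unname(init[["D"]]),
         unname(init[["a"]]), unname(init[["m"]]))
  validate_state(c(S = y[1], D = y[2], a = y[3], m = y[4]))
  Y[1, ] <- y
  pw <- unclass(p)
  diverged_at <- NA_real_
  for (i in seq_len(nt - 1)) {
    pw[[noise$target]] <- path[i]
    h <- times[i + 1] - times[i]
    k1 <- field_raw(y[1], y[2], y[3], y[4], pw)
    y2 <- y + h / 2 * k1
    k2 <- field_raw(y2[1], y2[2], y2[3], y2[4], pw)
    y3 <- y + h / 2 * k2
    k3 <- field_raw(y3[1], y3[2], y3[3], y3[4], pw)
    y4 <- y + h * k3
    k4 <- field_raw(y4[1], y4[2], y4[3], y4[4], pw)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[y < 0 & y > -1e-9] <- 0
    if (!all(is.finite(y)) || y[3] > a_ceiling) {
      diverged_at <- times[i + 1]
      flags <- c(flags, "divergence")
      break
    }
    Y[i + 1, ] <- y
  }
  states <- as.data.frame(Y)
  events <- data.frame(time = numeric(0), kind = character(0))
  if (!is.na(diverged_at))
    events <- rbind(events, data.frame(time = diverged_at,
                                       kind = "divergence"))
  tr <- new_trajectory(times = times, states = states, events = events,
                       params = p,
                       metadata = list(noise = noise, seed = seed, dt = dt,
                                       policy = policy))
  tr$param_path <- data.frame(time = times, value = path)
  tr$flags <- flags
  tr
}

#' Simulate a bundle of stochastic trajectories
#'
#' Runs `n` independent stochastic trajectories on a common time grid,
#' seeding trajectory `i` with `base_seed + i - 1`. The shared grid is what
#' makes ensemble statistics ([bundle_widths()]) well defined.
#'
#' @inheritParams simulate_stochastic
#' @param n number of trajectories (>= 2); ensembles of 20--100 are the
#'   typical working range.
#' @param base_seed first seed of the seed ladder.
#' @return A `csm_bundle`: list with `times`, per-variable matrices (`S`,
#'   `D`, `a`, `m`; time x trajectory), `param_paths` matrix, `flags` (list
#'   per trajectory), `noise`, `n`, and the base parameters.
#' @export
simulate_bundle <- function(p, noise, init, t_end, n, base_seed,
                            dt = 0.005, policy = "flag", a_ceiling = 1e6) {
  stopifnot(n >= 2)
  runs <- lapply(seq_len(n), function(i)
    simulate_stochastic(p, noise, init, t_end, seed = base_seed + i - 1L,
                        dt = dt, policy = policy, a_ceiling = a_ceiling))
  times <- runs[[1]]$times
  grab <- function(v) vapply(runs, function(r) r$states[[v]],
                             numeric(length(times)))
  structure(list(times = times,
                 S = grab("S"), D = grab("D"), a = grab("a"), m = grab("m"),
                 param_paths = vapply(runs, function(r) r$param_path$value,
                                      numeric(length(times))),
                 flags = lapply(runs, `[[`, "flags"),
                 noise = noise, n = n, params = p,
                 base_seed = base_seed, dt = dt),
            class = "csm_bundle")
}

#' @export
print.csm_bundle <- function(x, ...) {
  nf <- sum(vapply(x$flags, length, integer(1)) > 0)
  cat("csm_bundle: ", x$n, " trajectories, noise on '", x$noise$target,
      "' (rho = ", x$noise$rho, " ", x$noise$amplitude_mode, "), t in [0, ",
      max(x$times), "] d; ", nf, " flagged\n", sep = "")
  invisible(x)
}

#' Pointwise mean trajectory of a bundle
#'
#' Arithmetic mean over the unflagged trajectories at each grid time.
#'
#' @param b a `csm_bundle`.
#' @param include_flagged include flagged trajectories (default FALSE).
#' @return data.frame with columns `t`, `S`, `D`, `a`, `m`.
#' @export
bundle_mean <- function(b, include_flagged = FALSE) {
  stopifnot(inherits(b, "csm_bundle"))
  keep <- usable_runs(b, include_flagged)
  data.frame(t = b$times,
             S = rowMeans(b$S[, keep, drop = FALSE]),
             D = rowMeans(b$D[, keep, drop = FALSE]),
             a = rowMeans(b$a[, keep, drop = FALSE]),
             m = rowMeans(b$m[, keep, drop = FALSE]))
}

usable_runs <- function(b, include_flagged) {
  keep <- if (include_flagged) rep(TRUE, b$n)
          else vapply(b$flags, length, integer(1)) == 0
  if (sum(keep) < 2)
    stop("fewer than 2 usable trajectories in the bundle", call. = FALSE)
  which(keep)
}

# Closed-form unbinned Gaussian maximum-likelihood fit: the MLE of the mean
# is the sample mean and the MLE of sigma is the biased (1/N) root mean
# squared deviation.
gaussian_mle <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(c(mu = NA_real_, sigma = NA_real_))
  mu <- mean(x)
  c(mu = mu, sigma = sqrt(mean((x - mu)^2)))
}

#' Bundle width at one time
#'
#' Unbinned Gaussian maximum-likelihood fit of the cross-trajectory
#' distribution of each requested variable at time `t`: the fitted mean is
#' the sample mean and the fitted standard deviation is the biased (1/N)
#' RMS deviation — the closed-form MLE. The activator `a` is omitted by
#' default because in the fixed-point regimes where widths are studied it
#' is a numerical zero.
#'
#' @param b a `csm_bundle`.
#' @param t time (matched to the nearest grid point).
#' @param vars variables to fit (default `S`, `D`, `m`).
#' @param include_flagged include flagged trajectories (default FALSE).
#' @return One-row data.frame with `t` and `mu_<var>`, `sigma_<var>`
#'   columns.
#' @export
bundle_width <- function(b, t, vars = c("S", "D", "m"),
                         include_flagged = FALSE) {
  stopifnot(inherits(b, "csm_bundle"))
  i <- which.min(abs(b$times - t))
  keep <- usable_runs(b, include_flagged)
  out <- data.frame(t = b$times[i])
  for (v in vars) {
    fit <- gaussian_mle(b[[v]][i, keep])
    out[[paste0("mu_", v)]] <- fit[["mu"]]
    out[[paste0("sigma_", v)]] <- fit[["sigma"]]
  }
  out
}

#' Bundle width series over the whole grid
#'
#' [bundle_width()] applied at every grid time.
#'
#' @inheritParams bundle_width
#' @param thin keep every `thin`-th grid point (default 10, since the
#'   integration grid is much finer than needed for width curves).
#' @return data.frame of class `csm_width_series`.
#' @export
bundle_widths <- function(b, vars = c("S", "D", "m"), thin = 10L,
                          include_flagged = FALSE) {
  stopifnot(inherits(b, "csm_bundle"))
  idx <- unique(c(seq(1L, length(b$times), by = thin), length(b$times)))
  keep <- usable_runs(b, include_flagged)
  out <- data.frame(t = b$times[idx])
  for (v in vars) {
    fits <- apply(b[[v]][idx, keep, drop = FALSE], 1, gaussian_mle)
    out[[paste0("mu_", v)]] <- fits["mu", ]
    out[[paste0("sigma_", v)]] <- fits["sigma", ]
  }
  structure(out, class = c("csm_width_series", "data.frame"))
}

#' Linearity check of bundle-width growth
#'
#' Within a window comparable to the system's relaxation time the bundle
#' width grows linearly; beyond it, nonlinear (super-linear) accretion can
#' set in. This fits `sigma(t) = b0 + b1 t` by least squares on
#' `0 < t <= t_max`, reports slope and R-squared, and flags super-linear
#' breakout: the fit is anchored on the first half of the window and times
#' in the second half where the observed width exceeds the anchored
#' prediction by more than `rel_tol` (relatively) plus three RMSE are
#' flagged.
#'
#' @param ws a `csm_width_series` from [bundle_widths()].
#' @param t_max end of the fit window (day).
#' @param var which variable's width to check (default `"D"`).
#' @param rel_tol relative excess over the anchored linear prediction that
#'   counts as breakout (default 0.25).
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `breakout_times` (numeric, possibly empty), and `linear` (TRUE when
#'   no breakout was flagged).
#' @export
width_growth_check <- function(ws, t_max, var = "D", rel_tol = 0.25) {
  col <- paste0("sigma_", var)
  stopifnot(col %in% names(ws))
  d <- data.frame(t = ws$t, sigma = ws[[col]])
  d <- d[d$t > 0 & d$t <= t_max & is.finite(d$sigma), ]
  if (nrow(d) < 4)
    stop("not enough width points in (0, t_max]", call. = FALSE)
  fit <- stats::lm(sigma ~ t, data = d)
  r2 <- summary(fit)$r.squared
  half <- d[d$t <= t_max / 2, ]
  rest <- d[d$t > t_max / 2, ]
  breakout <- numeric(0)
  if (nrow(half) >= 3 && nrow(rest) >= 1) {
    anchor <- stats::lm(sigma ~ t, data = half)
    pred <- stats::predict(anchor, newdata = rest)
    rmse <- sqrt(mean(stats::residuals(anchor)^2))
    excess <- rest$sigma > pred * (1 + rel_tol) + 3 * rmse
    breakout <- rest$t[excess]
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, breakout_times = breakout,
       linear = length(breakout) == 0)
}
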