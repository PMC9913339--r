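#' Symmetric stem-division probability p(D, a)
#'
#' Probability that a stem cell division produces two stem cells, as a
#' function of the stem-division activator `a` (promoting) and the
#' differentiated-cell density `D` (inhibiting):
#' \deqn{p(D, a) = \frac{\eta a}{(1 + \eta a)(1 + \psi D)}.}
#' For `p ~ 0` stem cells divide symmetrically into two differentiated
#' cells; as `a` saturates, `p -> 1/(1 + \psi D)` and divisions favour the
#' stem-stem channel.
#'
#' @param D differentiated cell density (>= 0). Vectorized.
#' @param a stem-division activator density (>= 0). Vectorized.
#' @param p a [csm_params()] object (only `eta` and `psi` are used).
#' @return Probability value(s) in `[0, 1)`; increasing in `a`, decreasing
#'   in `D`.
#' @examples
#' pars <- csm_params(eta = 5, psi = 1)
#' division_probability(D = 0, a = 1, pars)  # 5/6
#' @export
division_probability <- function(D, a, p) {
  stopifnot(inherits(p, "csm_params"))
  if (any(D < 0) || any(a < 0))
    stop("division_probability: D and a must be non-negative", call. = FALSE)
  p$eta * a / ((1 + p$eta * a) * (1 + p$psi * D))
}

#' De-differentiation (plasticity) rate q(m)
#'
#' Rate at which differentiated cells revert to the stem state, switched on
#' by the plasticity activator `m` through a smoothed step:
#' \deqn{q(m) = \frac{q_0}{2}\left[1 + \tanh\frac{m - m_0}{s_q}\right].}
#' Because `sq` is small, q is approximately `q0` for `m > m0` and vanishes
#' otherwise.
#'
#' @param m plasticity activator density (>= 0). Vectorized.
#' @param p a [csm_params()] object (`q0`, `m0`, `sq` are used).
#' @return Rate value(s) in `[0, q0]` (1/day).
#' @examples
#' pars <- csm_params(q0 = 1)
#' plasticity_rate(pars$m0, pars)  # exactly q0/2
#' @export
plasticity_rate <- function(m, p) {
  stopifnot(inherits(p, "csm_params"))
  if (any(m < 0))
    stop("plasticity_rate: m must be non-negative", call. = FALSE)
  p$q0 / 2 * (1 + tanh((m - p$m0) / p$sq))
}

#' Mitosis saturation factor
#'
#' Smooth cut-off suppressing stem mitosis as the total cell density
#' approaches confluence:
#' \deqn{\Upsilon = \tanh\frac{1 - S - D}{s_l}.}
#' For `S + D` away from 1 the factor is indistinguishable from 1; it drops
#' to 0 as `S + D -> 1`, which confines trajectories to the physical simplex.
#'
#' @param S stem cell density. Vectorized.
#' @param D differentiated cell density. Vectorized.
#' @param p a [csm_params()] object (`sl` is used).
#' @return Value(s) in `[0, 1]`; exactly 0 iff `S + D = 1`.
#' @examples
#' pars <- csm_params()
#' saturation_factor(0.5, 0.4, pars)  # tanh(1)
#' @export
saturation_factor <- function(S, D, p) {
  stopifnot(inherits(p, "csm_params"))
  tot <- S + D
  if (any(tot > 1 + 1e-9))
    stop("saturation_factor: S + D exceeds 1 (outside physical region)",
         call. = FALSE)
  tanh(pmax(1 - tot, 0) / p$sl)
}

#' Right-hand side of the cancer stem cell system
#'
#' Time derivatives of the four dynamical variables:
#' \deqn{\dot S = (2p(D,a) - 1)\,\Upsilon\lambda S + q(m) D}
#' \deqn{\dot D = 2(1 - p(D,a))\,\Upsilon\lambda S - (d + q(m)) D}
#' \deqn{\dot a = a\left(\frac{\beta S a}{1 + a} - \alpha_a\right)}
#' \deqn{\dot m = \gamma e^{-S/S_0} - \alpha_m m}
#' Stem divisions add one net cell per division, so
#' \eqn{\dot S + \dot D = \Upsilon\lambda S - d D} holds identically
#' (differentiated-cell death is the only loss channel). The activator `a`
#' is produced autocatalytically, linearly in `S`, with partial saturation
#' through the factor `a/(1+a)`; for sustained `\beta S > \alpha_a` it grows
#' without bound, which is the engine of the runaway-proliferation regime.
#'
#' @param state a [csm_state()] or named numeric vector with `S`, `D`, `a`,
#'   `m`.
#' @param p a [csm_params()] object.
#' @return Named numeric vector `(S, D, a, m)` of time derivatives (1/day).
#' @examples
#' pars <- csm_params()
#' csm_field(csm_state(0, 0, 0, pars$gamma / pars$alpha_m), pars)  # fixed point
#' @export
csm_field <- function(state, p) {
  stopifnot(inherits(p, "csm_params"))
  x <- clip_state(c(S = unname(state[["S"]]), D = unname(state[["D"]]),
                    a = unname(state[["a"]]), m = unname(state[["m"]])))
  S <- x[["S"]]; D <- x[["D"]]; a <- x[["a"]]; m <- x[["m"]]
  pp <- division_probability(D, a, p)
  q  <- plasticity_rate(m, p)
  up <- saturation_factor(S, D, p)
  mitosis <- up * p$lambda * S
  c(S = (2 * pp - 1) * mitosis + q * D,
    D = 2 * (1 - pp) * mitosis - (p$d + q) * D,
    a = a * (p$beta * S * a / (1 + a) - p$alpha_a),
    m = p$gamma * exp(-S / p$S0) - p$alpha_m * m)
}

# deSolve-facing wrapper; parms = list(p = csm_params, params_at = NULL or
# function(t) returning a csm_params for time-dependent therapy runs.
csm_rhs <- function(t, y, parms) {
  p <- if (is.null(parms$params_at)) parms$p else parms$params_at(t)
  list(unname(csm_field(y, p)))
}

#' Solver options for deterministic simulation
#'
#' @param method deSolve integration method. The default `"lsodar"` is an
#'   adaptive multistep method with built-in root finding, used to terminate
#'   cleanly on activator divergence. Any deSolve method name is accepted
#'   (e.g. `"ode45"`), but only the lsodar/radau family supports the
#'   divergence root.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param dt_out output grid spacing (day).
#' @param a_ceiling activator level treated as numerical divergence; the run
#'   halts there with a `divergence` event.
#' @param extinction_floor total density `S + D` below which an `extinction`
#'   event is recorded (non-terminal).
#' @return A list of class `csm_solver_opts`.
#' @export
solver_opts <- function(method = "lsodar", rtol = 1e-8, atol = 1e-10,
                        dt_out = 0.02, a_ceiling = 1e6,
                        extinction_floor = 1e-6) {
  stopifnot(rtol > 0, atol > 0, dt_out > 0, a_ceiling > 0,
            extinction_floor >= 0)
  structure(list(method = method, rtol = rtol, atol = atol, dt_out = dt_out,
                 a_ceiling = a_ceiling, extinction_floor = extinction_floor),
            class = "csm_solver_opts")
}

#' Simulate the deterministic cancer stem cell system
#'
#' Integrates the model from `init` over `[0, t_end]` on a fixed output
#' grid. Integration halts early with a `divergence` event when the
#' activator `a` crosses `opts$a_ceiling` (runaway proliferation); an
#' `extinction` event is recorded at the first time `S + D` falls below
#' `opts$extinction_floor`.
#'
#' @param p a [csm_params()] object.
#' @param init a [csm_state()] initial state.
#' @param t_end final time (day, > 0).
#' @param opts a [solver_opts()] list.
#' @param params_at optional `function(t) -> csm_params` overriding `p` at
#'   each instant (used internally by the therapy layer).
#' @return A `csm_trajectory`: list with elements `times`, `states` (a
#'   data.frame with columns `S`, `D`, `a`, `m`), `events` (data.frame with
#'   `time`, `kind`), `params`, and `metadata`.
#' @examples
#' pars <- csm_params(d = 0.2, q0 = 1, eta = 5, beta = 2)
#' tr <- simulate_csm(pars, csm_state(0.01, 0.1, 0.5, 0.1), t_end = 20)
#' tail(as.data.frame(tr))
#' @export
simulate_csm <- function(p, init, t_end, opts = solver_opts(),
                         params_at = NULL) {
  stopifnot(inherits(p, "csm_params"), t_end > 0)
  y0 <- clip_state(c(S = unname(init[["S"]]), D = unname(init[["D"]]),
                     a = unname(init[["a"]]), m = unname(init[["m"]])))
  times <- seq(0, t_end, by = opts$dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  parms <- list(p = p, params_at = params_at)
  use_root <- opts$method %in% c("lsodar", "radau")
  args <- list(y = y0, times = times, func = csm_rhs, parms = parms,
               method = opts$method, rtol = opts$rtol, atol = opts$atol)
  if (use_root)
    args$rootfunc <- function(t, y, parms) y[["a"]] - opts$a_ceiling
  out <- tryCatch(
    suppressWarnings(do.call(deSolve::ode, args)),
    error = function(e) {
      stop("ODE solver failure at requested span [0, ", t_end, "]: ",
           conditionMessage(e), call. = FALSE)
    })
  out <- as.data.frame(out)
  names(out) <- c("time", "S", "D", "a", "m")
  events <- data.frame(time = numeric(0), kind = character(0))
  t_last <- out$time[nrow(out)]
  if (t_last < t_end - 1e-12) {
    a_last <- out$a[nrow(out)]
    if (is.finite(a_last) && a_last >= opts$a_ceiling * (1 - 1e-6)) {
      events <- rbind(events,
                      data.frame(time = t_last, kind = "divergence"))
    } else {
      stop("ODE solver stopped prematurely at t = ", t_last,
           " (last state: S=", signif(out$S[nrow(out)], 6),
           ", D=", signif(out$D[nrow(out)], 6),
           ", a=", signif(a_last, 6),
           ", m=", signif(out$m[nrow(out)], 6), ")", call. = FALSE)
    }
  }
  tot <- out$S + out$D
  idx <- which(tot < opts$extinction_floor)
  if (length(idx))
    events <- rbind(events,
                    data.frame(time = out$time[idx[1]], kind = "extinction"))
  bad <- which(out$S < -1e-9 | out$D < -1e-9 | tot > 1 + 1e-9)
  if (length(bad))
    events <- rbind(events,
                    data.frame(time = out$time[bad[1]],
                               kind = "bound_violation"))
  new_trajectory(times = out$time,
                 states = out[c("S", "D", "a", "m")],
                 events = events, params = p,
                 metadata = list(solver = opts, t_end = t_end,
                                 time_dependent = !is.null(params_at)))
}

new_trajectory <- function(times, states, events, params, metadata) {
  stopifnot(all(diff(times) > 0), nrow(states) == length(times))
  structure(list(times = times, states = states, events = events,
                 params = params, metadata = metadata),
            class = "csm_trajectory")
}

#' @export
print.csm_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("csm_trajectory: ", n, " points on t = [",
      format(x$times[1]), ", ", format(x$times[n]), "] d\n", sep = "")
  last <- x$states[n, ]
  cat(sprintf("  final state: S=%.6g D=%.6g a=%.6g m=%.6g\n",
              last$S, last$D, last$a, last$m))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("    %-14s at t = %.4g\n",
                  x$events$kind[i], x$events$time[i]))
  } else cat("  events: none\n")
  invisible(x)
}

#' @export
as.data.frame.csm_trajectory <- function(x, ...) {
  cbind(data.frame(t = x$times), x$states)
}

#' Final state of a trajectory
#'
#' @param tr a `csm_trajectory`.
#' @return Named numeric vector `(S, D, a, m)` at the last computed time.
#' @export
final_state <- function(tr) {
  stopifnot(inherits(tr, "csm_trajectory"))
  unlist(tr$states[nrow(tr$states), ])
}

#' Did a trajectory record a given event?
#'
#' @param tr a `csm_trajectory`.
#' @param kind one of `"divergence"`, `"extinction"`, `"bound_violation"`.
#' @return Logical scalar.
#' @export
has_event <- function(tr, kind) {
  stopifnot(inherits(tr, "csm_trajectory"))
  kind %in% tr$events$kind
}
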