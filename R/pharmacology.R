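#' Administration rate for a target peak drug level
#'
#' In the one-compartment kinetic model with first-order clearance, dosing
#' at constant rate \eqn{\zeta} for a duration \eqn{\tau} starting from a
#' drug-free organism yields \eqn{\chi(\tau) = \zeta(1 - e^{-\alpha_d\tau})
#' / \alpha_d}. Inverting gives the rate that attains a prescribed peak:
#' \deqn{\zeta(\chi_{max}) = \frac{\chi_{max}\,\alpha_d}{1 -
#'   e^{-\alpha_d\tau}}.}
#'
#' @param chi_max desired peak drug level (dimensionless).
#' @param alpha_d clearance rate (1/day).
#' @param tau administration duration (day, > 0).
#' @return Administration rate `zeta` (drug amount per day).
#' @examples
#' dose_rate_for_peak(1.0, 10, 0.08)  # ~18.16
#' @export
dose_rate_for_peak <- function(chi_max, alpha_d, tau) {
  stopifnot(chi_max > 0, alpha_d > 0)
  if (tau <= 0)
    stop("tau must be strictly positive (zeta diverges as tau -> 0)",
         call. = FALSE)
  chi_max * alpha_d / (1 - exp(-alpha_d * tau))
}

#' Periodic drug administration schedule
#'
#' Describes repeated administration: in each period of length `T` the drug
#' is infused at rate `zeta` for a duration `tau`, then cleared at rate
#' `alpha_d` for the rest of the period. Exactly one of `zeta` and
#' `chi_max` must be given; a peak target is converted to a rate with
#' [dose_rate_for_peak()]. A warning is issued when the rest period is not
#' long compared to the drug decay time `1/alpha_d`, since the model is
#' meant for schedules without inter-dose accumulation.
#'
#' @param zeta administration rate (amount/day); alternative to `chi_max`.
#' @param chi_max target peak level; alternative to `zeta`.
#' @param alpha_d clearance rate (1/day).
#' @param T administration period (day).
#' @param tau administration duration per period (day), `0 < tau < T`.
#' @param t_start time at which dosing begins (day, default 0).
#' @return A list of class `csm_drug_schedule`.
#' @examples
#' sch <- drug_schedule(chi_max = 1, alpha_d = 10, T = 1, tau = 0.08)
#' sch$zeta
#' @export
drug_schedule <- function(zeta = NULL, chi_max = NULL, alpha_d, T = 1,
                          tau = 0.08, t_start = 0) {
  if (is.null(zeta) == is.null(chi_max))
    stop("give exactly one of 'zeta' and 'chi_max'", call. = FALSE)
  stopifnot(alpha_d > 0, T > 0, tau > 0, tau < T, t_start >= 0)
  if ((T - tau) * alpha_d < 3)
    warning("rest period T - tau is not large compared to 1/alpha_d; the ",
            "drug will accumulate across periods", call. = FALSE)
  if (is.null(zeta)) zeta <- dose_rate_for_peak(chi_max, alpha_d, tau)
  structure(list(zeta = zeta, alpha_d = alpha_d, T = T, tau = tau,
                 t_start = t_start),
            class = "csm_drug_schedule")
}

#' Drug level under periodic administration
#'
#' Piecewise-exponential analytic solution of the one-compartment kinetics
#' \deqn{\dot\chi = \zeta - \alpha_d\chi \; (\text{infusion}),\qquad
#'   \dot\chi = -\alpha_d\chi \; (\text{rest}),}
#' with `chi = 0` before `t_start` and continuity across every phase
#' boundary. The start-of-period level obeys the linear recursion
#' \eqn{\chi_{n+1}(0) = A + e^{-\alpha_d T}\chi_n(0)} whose closed form is
#' used directly, so evaluation is O(1) per time point.
#'
#' @param t time(s) (day); vectorized.
#' @param schedule a [drug_schedule()].
#' @return Drug level(s) `chi` (dimensionless, >= 0).
#' @examples
#' sch <- drug_schedule(chi_max = 1, alpha_d = 10, T = 1, tau = 0.08)
#' drug_level(sch$tau, sch)  # the peak: 1.0
#' @export
drug_level <- function(t, schedule) {
  stopifnot(inherits(schedule, "csm_drug_schedule"))
  zeta <- schedule$zeta; ad <- schedule$alpha_d
  Tp <- schedule$T; tau <- schedule$tau
  u <- t - schedule$t_start
  n <- pmax(floor(u / Tp), 0)
  phase <- u - n * Tp
  sat <- zeta / ad
  # start-of-period level: chi_n = A (1 - B^n) / (1 - B), B = exp(-alpha_d T)
  B <- exp(-ad * Tp)
  A <- sat * (1 - exp(-ad * tau)) * exp(-ad * (Tp - tau))
  chi_n <- A * (1 - B^n) / (1 - B)
  rise <- sat + (chi_n - sat) * exp(-ad * phase)
  peak <- sat + (chi_n - sat) * exp(-ad * tau)
  fall <- peak * exp(-ad * (phase - tau))
  out <- ifelse(phase < tau, rise, fall)
  out[u < 0] <- 0
  out
}

#' Drug action parameters
#'
#' The three constants of the pharmacodynamic action function: magnitude
#' `omega0` (in units of the targeted rate parameter), midpoint `chi0` (the
#' drug level at which the action reaches half its magnitude) and width
#' `s_chi` of the linear response regime.
#'
#' @param omega0 action magnitude (> 0, units of the targeted parameter).
#' @param chi0 action midpoint (> 0, dimensionless drug level).
#' @param s_chi action width (> 0, dimensionless).
#' @return A list of class `csm_action_params`.
#' @export
action_params <- function(omega0 = 1.0, chi0 = 0.2, s_chi = 0.05) {
  stopifnot(omega0 > 0, chi0 > 0, s_chi > 0)
  structure(list(omega0 = omega0, chi0 = chi0, s_chi = s_chi),
            class = "csm_action_params")
}

#' Pharmacodynamic action function
#'
#' Sigmoidal dose-response mapping the instantaneous drug level to an
#' effect on a model rate:
#' \deqn{\Omega(\chi) = \frac{\Omega_0}{2}\left[\tanh\frac{\chi -
#'   \chi_0}{s_\chi} + 1\right],}
#' an approximate step with plateaus at 0 (negligible drug) and
#' \eqn{\Omega_0} (saturating drug), linear around \eqn{\chi_0}.
#'
#' @param chi drug level(s), >= 0; vectorized.
#' @param action an [action_params()] object.
#' @return Action value(s) in `(0, omega0)`, monotone in `chi`.
#' @examples
#' drug_action(0.2, action_params(omega0 = 1, chi0 = 0.2))  # omega0/2
#' @export
drug_action <- function(chi, action) {
  stopifnot(inherits(action, "csm_action_params"))
  if (any(chi < 0))
    stop("drug_action: chi must be non-negative", call. = FALSE)
  action$omega0 / 2 * (tanh((chi - action$chi0) / action$s_chi) + 1)
}

#' Therapy specification
#'
#' Wires a dosing schedule and action function(s) onto the model:
#' \describe{
#'   \item{cytotoxic}{kills differentiated cells: `d(t) = d + Omega(chi)`.}
#'   \item{cytostatic}{slows stem mitosis: `lambda(t) = lambda -
#'     Omega(chi)`, clamped at 0 by default.}
#'   \item{anti_plasticity}{suppresses de-differentiation: `q0(t) = q0 -
#'     Omega(chi)`, clamped at 0 by default.}
#'   \item{differentiation_plus_cytotoxic}{forces stem differentiation by
#'     shifting the plasticity term to `q(m) - Omega_diff(chi)` (not
#'     clamped: the negative excursion acts as an induced stem death rate)
#'     while simultaneously raising `d(t) = d + Omega_cyto(chi)`.}
#' }
#'
#' @param type therapy type, one of the four above.
#' @param schedule a [drug_schedule()].
#' @param action an [action_params()]; for the combined type, the
#'   differentiation action `Omega_diff`.
#' @param action_cyto second [action_params()] (`Omega_cyto`), required by
#'   and only by `differentiation_plus_cytotoxic`.
#' @param clamp_at_zero clamp subtractive targets (`lambda`, `q0`) at zero
#'   (default TRUE); turn off to study the literal unclamped model.
#' @return A list of class `csm_therapy`.
#' @export
therapy_spec <- function(type = c("cytotoxic", "cytostatic",
                                  "anti_plasticity",
                                  "differentiation_plus_cytotoxic"),
                         schedule, action, action_cyto = NULL,
                         clamp_at_zero = TRUE) {
  type <- match.arg(type)
  stopifnot(inherits(schedule, "csm_drug_schedule"),
            inherits(action, "csm_action_params"))
  if (type == "differentiation_plus_cytotoxic") {
    if (is.null(action_cyto))
      stop("the combined therapy needs both 'action' (differentiation) and ",
           "'action_cyto'", call. = FALSE)
    stopifnot(inherits(action_cyto, "csm_action_params"))
  } else if (!is.null(action_cyto)) {
    stop("'action_cyto' is only meaningful for the combined therapy",
         call. = FALSE)
  }
  structure(list(type = type, schedule = schedule, action = action,
                 action_cyto = action_cyto, clamp_at_zero = clamp_at_zero),
            class = "csm_therapy")
}

#' Instantaneous effective parameters under therapy
#'
#' Evaluates the drug level at time `t` and applies the therapy's coupling
#' rule to the base parameters. For the combined therapy the additive shift
#' of the plasticity term (which is a modification of the vector field, not
#' of a constant) is returned in `q_offset`.
#'
#' @param t time (day).
#' @param base a [csm_params()] object.
#' @param therapy a [therapy_spec()].
#' @return List with `params` (a `csm_params`, possibly clamped at zero on
#'   the targeted rate), `q_offset` (value subtracted from `q(m)`; 0 except
#'   for the combined therapy) and `chi` (the drug level used).
#' @export
effective_params <- function(t, base, therapy) {
  stopifnot(inherits(base, "csm_params"), inherits(therapy, "csm_therapy"))
  chi <- drug_level(t, therapy$schedule)
  om <- drug_action(chi, therapy$action)
  p <- unclass(base)
  q_offset <- 0
  if (therapy$type == "cytotoxic") {
    p$d <- p$d + om
  } else if (therapy$type == "cytostatic") {
    p$lambda <- p$lambda - om
    if (therapy$clamp_at_zero) p$lambda <- max(p$lambda, 0)
  } else if (therapy$type == "anti_plasticity") {
    p$q0 <- p$q0 - om
    if (therapy$clamp_at_zero) p$q0 <- max(p$q0, 0)
  } else {  # differentiation_plus_cytotoxic
    q_offset <- om
    p$d <- p$d + drug_action(chi, therapy$action_cyto)
  }
  list(params = structure(p, class = "csm_params"), q_offset = q_offset,
       chi = chi)
}

# Field under therapy: like csm_field but with time-dependent parameters
# and the additive plasticity shift of the combined therapy.
therapy_field <- function(t, state, base, therapy) {
  eff <- effective_params(t, base, therapy)
  p <- eff$params
  x <- pmax(c(S = unname(state[[1]]), D = unname(state[[2]]),
              a = unname(state[[3]]), m = unname(state[[4]])), 0)
  S <- x[["S"]]; D <- x[["D"]]; a <- x[["a"]]; m <- x[["m"]]
  pp <- p$eta * a / ((1 + p$eta * a) * (1 + p$psi * D))
  q  <- p$q0 / 2 * (1 + tanh((m - p$m0) / p$sq)) - eff$q_offset
  up <- tanh(max(1 - S - D, 0) / p$sl)
  # lambda may be zero under a clamped cytostatic pulse; that simply stops
  # mitosis for the duration
  mitosis <- up * p$lambda * S
  c(S = (2 * pp - 1) * mitosis + q * D,
    D = 2 * (1 - pp) * mitosis - (p$d + q) * D,
    a = a * (p$beta * S * a / (1 + a) - p$alpha_a),
    m = p$gamma * exp(-S / p$S0) - p$alpha_m * m)
}

#' Simulate the model under a drug therapy
#'
#' Integrates the system with the therapy's time-dependent parameter
#' coupling. Because the administration switch makes the right-hand side
#' discontinuous at every phase boundary `t_start + nT` and
#' `t_start + nT + tau`, the integrator is restarted on each boundary so no
#' step straddles a discontinuity. Events (activator divergence,
#' extinction) are detected as in [simulate_csm()].
#'
#' @param p base [csm_params()].
#' @param therapy a [therapy_spec()].
#' @param init initial [csm_state()].
#' @param t_end final time (day).
#' @param opts a [solver_opts()].
#' @return A `csm_trajectory`; `metadata$therapy` carries the spec.
#' @export
simulate_with_therapy <- function(p, therapy, init, t_end,
                                  opts = solver_opts()) {
  stopifnot(inherits(p, "csm_params"), inherits(therapy, "csm_therapy"),
            t_end > 0)
  sch <- therapy$schedule
  nmax <- ceiling((t_end - sch$t_start) / sch$T) + 1
  bounds <- sch$t_start + rep(0:nmax, each = 2) * sch$T + c(0, sch$tau)
  bounds <- sort(unique(c(0, bounds[bounds > 0 & bounds < t_end], t_end)))
  rhs <- function(t, y, parms) list(unname(therapy_field(t, y, p, therapy)))
  y <- pmax(c(S = unname(init[["S"]]), D = unname(init[["D"]]),
              a = unname(init[["a"]]), m = unname(init[["m"]])), 0)
  validate_state(y)
  times_all <- numeric(0)
  states_all <- NULL
  events <- data.frame(time = numeric(0), kind = character(0))
  use_root <- opts$method %in% c("lsodar", "radau")
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    times <- seq(t0, t1, by = opts$dt_out)
    if (times[length(times)] < t1 - 1e-9) times <- c(times, t1)
    else times[length(times)] <- t1
    args <- list(y = y, times = times, func = rhs, parms = NULL,
                 method = opts$method, rtol = opts$rtol, atol = opts$atol)
    if (use_root)
      args$rootfunc <- function(t, y, parms) y[["a"]] - opts$a_ceiling
    out <- tryCatch(suppressWarnings(do.call(deSolve::ode, args)),
                    error = function(e)
                      stop("ODE solver failure in segment [", t0, ", ", t1,
                           "]: ", conditionMessage(e), call. = FALSE))
    out <- as.data.frame(out)
    names(out) <- c("time", "S", "D", "a", "m")
    keep <- if (i == 1) seq_len(nrow(out)) else -1L
    times_all <- c(times_all, out$time[keep])
    states_all <- rbind(states_all, out[keep, c("S", "D", "a", "m")])
    y <- unlist(out[nrow(out), c("S", "D", "a", "m")])
    t_last <- out$time[nrow(out)]
    if (t_last < t1 - 1e-12) {
      if (is.finite(y[["a"]]) && y[["a"]] >= opts$a_ceiling * (1 - 1e-6)) {
        events <- rbind(events,
                        data.frame(time = t_last, kind = "divergence"))
        break
      }
      stop("ODE solver stopped prematurely at t = ", t_last, call. = FALSE)
    }
  }
  tot <- states_all$S + states_all$D
  idx <- which(tot < opts$extinction_floor)
  if (length(idx))
    events <- rbind(events, data.frame(time = times_all[idx[1]],
                                       kind = "extinction"))
  rownames(states_all) <- NULL
  new_trajectory(times = times_all, states = states_all, events = events,
                 params = p,
                 metadata = list(solver = opts, t_end = t_end,
                                 therapy = therapy))
}
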