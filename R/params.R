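#' Model parameters for the cancer stem cell system
#'
#' Constructs and validates the full set of rate and shape constants of the
#' four-variable stem-cell/differentiated-cell model. Defaults are the fixed
#' constants used throughout the published parameter regimes: mitotic rate
#' `lambda = 1` (the inverse mitotic rate is the time unit, so all rates are
#' per day), inhibitor strength `psi = 1`, plasticity-trigger stem density
#' `S0 = 0.038`, plasticity threshold `m0 = 0.5`, and step widths
#' `sq = 0.01`, `sl = 0.1`.
#'
#' @param lambda mitotic rate of cancer stem cells (1/day).
#' @param d death rate of differentiated cells (1/day).
#' @param q0 plasticity amplitude: maximal de-differentiation rate (1/day).
#' @param eta activator gain in the stem-division probability (dimensionless).
#' @param psi inhibitor strength of differentiated cells on symmetric stem
#'   division (dimensionless).
#' @param alpha_a decay rate of the stem-division activator a (1/day).
#' @param alpha_m decay rate of the plasticity activator m (1/day).
#' @param beta production gain of the activator a (1/day).
#' @param gamma production gain of the activator m (1/day).
#' @param S0 stem density scale triggering plasticity-activator production
#'   (dimensionless, in (0, 1)).
#' @param m0 threshold of the plasticity activator at which de-differentiation
#'   switches on (density units of m).
#' @param sq width of the plasticity step function (same units as m). Must be
#'   small for q(m) to act as a switch; a warning is issued above 0.5.
#' @param sl width of the saturation step function (dimensionless). Must be
#'   small for the saturation factor to act near total confluence only; a
#'   warning is issued above 0.5.
#'
#' @return An object of class `csm_params`: a named list of the thirteen
#'   constants.
#' @examples
#' p <- csm_params(d = 0.2, q0 = 1.0, eta = 5.0, beta = 2.0)
#' p$lambda
#' @export
csm_params <- function(lambda = 1.0, d = 1.0, q0 = 1.0, eta = 5.0,
                       psi = 1.0, alpha_a = 1.0, alpha_m = 1.0,
                       beta = 2.0, gamma = 1.0,
                       S0 = 0.038, m0 = 0.5, sq = 0.01, sl = 0.1) {
  p <- list(lambda = lambda, d = d, q0 = q0, eta = eta, psi = psi,
            alpha_a = alpha_a, alpha_m = alpha_m, beta = beta,
            gamma = gamma, S0 = S0, m0 = m0, sq = sq, sl = sl)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ", v, ")",
           call. = FALSE)
  }
  if (S0 >= 1)
    stop("S0 must lie in (0, 1); got ", S0, call. = FALSE)
  if (sq > 0.5)
    warning("sq = ", sq, " is large; the plasticity switch q(m) degrades ",
            "into a soft ramp. Keep sq small.", call. = FALSE)
  if (sl > 0.5)
    warning("sl = ", sl, " is large; the saturation factor loses its ",
            "step character. Keep sl small.", call. = FALSE)
  structure(p, class = "csm_params")
}

#' @export
print.csm_params <- function(x, ...) {
  cat("Cancer stem cell model parameters (rates in 1/day):\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 8), " = ", format(v)),
      sep = "\n")
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p a [csm_params()] object.
#' @param ... named scalar replacements, e.g. `d = 0.4`.
#' @return A new `csm_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "csm_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- unclass(p)
  args[names(repl)] <- repl
  do.call(csm_params, args)
}

#' Model state: the four dynamical variables
#'
#' The state holds the two cell densities and the two activator densities:
#' `S` (cancer stem cells) and `D` (differentiated cells) are fractions of
#' the total cell count, so `S >= 0`, `D >= 0` and `S + D <= 1` (the
#' remainder `1 - S - D` is the inert/quiescent fraction); the activators
#' `a` (stem-division activator) and `m` (plasticity activator) are
#' non-negative number densities.
#'
#' @param S stem cell density (fraction in \[0, 1\]).
#' @param D differentiated cell density (fraction in \[0, 1\]).
#' @param a stem-division activator density (>= 0).
#' @param m plasticity activator density (>= 0).
#' @return A named numeric vector of class `csm_state` with components
#'   `S`, `D`, `a`, `m`.
#' @examples
#' csm_state(S = 0.01, D = 0.1, a = 0.5, m = 0.1)
#' @export
csm_state <- function(S, D, a, m) {
  x <- c(S = as.numeric(S), D = as.numeric(D),
         a = as.numeric(a), m = as.numeric(m))
  validate_state(x)
  structure(x, class = c("csm_state", "numeric"))
}

# Shared invariant checks; `tol` absorbs solver round-off.
validate_state <- function(x, tol = 1e-9) {
  if (any(!is.finite(x)))
    stop("state contains non-finite values", call. = FALSE)
  if (x[["S"]] < -tol || x[["D"]] < -tol)
    stop("cell densities must be non-negative (S = ", x[["S"]],
         ", D = ", x[["D"]], ")", call. = FALSE)
  if (x[["S"]] + x[["D"]] > 1 + tol)
    stop("S + D = ", x[["S"]] + x[["D"]],
         " exceeds 1: state outside the physical simplex", call. = FALSE)
  if (x[["a"]] < -tol || x[["m"]] < -tol)
    stop("activator densities must be non-negative (a = ", x[["a"]],
         ", m = ", x[["m"]], ")", call. = FALSE)
  invisible(x)
}

# Clip tiny negative excursions (within tol) to zero; larger ones raise.
clip_state <- function(x, tol = 1e-9) {
  validate_state(x, tol = tol)
  pmax(x, 0)
}
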