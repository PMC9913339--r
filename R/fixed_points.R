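#' Jacobian of the model's right-hand side
#'
#' Two evaluation modes. `"analytic_upsilon1"` uses hand-derived partial
#' derivatives of the vector field with the saturation factor frozen at
#' \eqn{\Upsilon = 1} — the approximation under which the model's
#' fixed-point eigenvalue analysis is carried out, valid well below
#' confluence. `"finite_difference"` applies central differences to the full
#' field (including \eqn{\Upsilon}) and serves as an independent check; the
#' two agree entrywise to about 1e-4 while `S + D < 0.5`.
#'
#' @param state named numeric vector / [csm_state()] at which to evaluate.
#' @param p a [csm_params()] object.
#' @param mode `"analytic_upsilon1"` (default) or `"finite_difference"`.
#' @return A 4x4 matrix with rows/columns ordered `S`, `D`, `a`, `m`.
#' @export
csm_jacobian <- function(state, p,
                         mode = c("analytic_upsilon1", "finite_difference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "csm_params"))
  S <- unname(state[["S"]]); D <- unname(state[["D"]])
  a <- unname(state[["a"]]); m <- unname(state[["m"]])
  if (mode == "analytic_upsilon1") {
    pp   <- division_probability(D, a, p)
    q    <- plasticity_rate(m, p)
    dpda <- p$eta / ((1 + p$eta * a)^2 * (1 + p$psi * D))
    dpdD <- -pp * p$psi / (1 + p$psi * D)
    dqdm <- p$q0 / (2 * p$sq) / cosh((m - p$m0) / p$sq)^2
    lamS <- p$lambda * S
    J <- matrix(0, 4, 4, dimnames = list(c("S", "D", "a", "m"),
                                         c("S", "D", "a", "m")))
    J["S", "S"] <- (2 * pp - 1) * p$lambda
    J["S", "D"] <- 2 * lamS * dpdD + q
    J["S", "a"] <- 2 * lamS * dpda
    J["S", "m"] <- dqdm * D
    J["D", "S"] <- 2 * (1 - pp) * p$lambda
    J["D", "D"] <- -2 * lamS * dpdD - (p$d + q)
    J["D", "a"] <- -2 * lamS * dpda
    J["D", "m"] <- -dqdm * D
    J["a", "S"] <- p$beta * a^2 / (1 + a)
    J["a", "a"] <- p$beta * S * (a^2 + 2 * a) / (1 + a)^2 - p$alpha_a
    J["m", "S"] <- -(p$gamma / p$S0) * exp(-S / p$S0)
    J["m", "m"] <- -p$alpha_m
    return(J)
  }
  # full-field central differences, falling back to one-sided steps at the
  # non-negativity boundary
  x0 <- c(S = S, D = D, a = a, m = m)
  J <- matrix(0, 4, 4, dimnames = list(names(x0), names(x0)))
  for (j in seq_along(x0)) {
    h <- 1e-6 * max(1, abs(x0[[j]]))
    if (h < 1e-12)
      stop("finite-difference step underflow for component ", names(x0)[j],
           call. = FALSE)
    lo_ok <- x0[[j]] - h >= 0
    xp <- x0; xp[[j]] <- x0[[j]] + h
    fp <- csm_field(xp, p)
    if (lo_ok) {
      xm <- x0; xm[[j]] <- x0[[j]] - h
      J[, j] <- (fp - csm_field(xm, p)) / (2 * h)
    } else {
      J[, j] <- (fp - csm_field(x0, p)) / h
    }
  }
  J
}

new_fixed_point <- function(label, location, exists, conditions,
                            eigenvalues = NULL, stability = NA_character_) {
  structure(list(label = label, location = location, exists = exists,
                 existence_conditions = conditions,
                 eigenvalues = eigenvalues, stability = stability),
            class = "csm_fixed_point")
}

#' @export
print.csm_fixed_point <- function(x, ...) {
  cat("Fixed point ", x$label, if (!x$exists) " (does not exist)", "\n",
      sep = "")
  if (x$exists) {
    loc <- x$location
    cat(sprintf("  location : S=%.6g D=%.6g a=%.6g m=%.6g\n",
                loc[["S"]], loc[["D"]], loc[["a"]], loc[["m"]]))
    if (!is.null(x$eigenvalues))
      cat("  eigenvalues:",
          paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
    cat("  stability:", x$stability, "\n")
  }
  cond <- x$existence_conditions
  cat("  conditions:",
      paste(names(cond), unlist(cond), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

existence_record <- function(p, m2 = NA_real_) {
  list(d_lt_q0 = p$d > 0 && p$d < p$q0,
       m2_lt_gamma_over_alpham = is.finite(m2) && m2 < p$gamma / p$alpha_m,
       d_gt_psi_alpha_over_beta = p$d > p$psi * p$alpha_a / p$beta)
}

#' Extinction fixed point F1
#'
#' The tumor-free state `F1 = (0, 0, 0, gamma/alpha_m)`, which exists for
#' every parameter set: with no cells and no stem-division activator, the
#' plasticity activator equilibrates at its production/decay balance.
#'
#' @param p a [csm_params()] object.
#' @param classify compute eigenvalues and a stability label (default TRUE).
#' @return A `csm_fixed_point` with `label = "F1"` and `exists = TRUE`.
#' @export
fixed_point_f1 <- function(p, classify = TRUE) {
  stopifnot(inherits(p, "csm_params"))
  loc <- c(S = 0, D = 0, a = 0, m = p$gamma / p$alpha_m)
  fp <- new_fixed_point("F1", loc, TRUE, existence_record(p))
  if (classify) fp <- classify_stability(fp, p)
  fp
}

#' Plasticity-sustained fixed point F2
#'
#' The dormant-colony state with vanishing stem-division activator, where
#' mitosis and de-differentiation balance differentiated-cell death.
#' Closed forms (derived with the saturation factor approximated by 1):
#' \deqn{m_2 = m_0 + s_q\,\mathrm{artanh}(2d/q_0 - 1),\quad
#'   S_2 = -S_0\log(\alpha_m m_2/\gamma),\quad D_2 = \lambda S_2 / d.}
#' F2 exists iff `0 < d < q0` (so the artanh argument is in (-1, 1)) and
#' `m2 < gamma/alpha_m` (so `S2 > 0`).
#'
#' @inheritParams fixed_point_f1
#' @return A `csm_fixed_point` with `label = "F2"`; `exists = FALSE` with
#'   the failing conditions reported when the regime does not support it.
#' @export
fixed_point_f2 <- function(p, classify = TRUE) {
  stopifnot(inherits(p, "csm_params"))
  if (!(p$d > 0 && p$d < p$q0))
    return(new_fixed_point("F2", NULL, FALSE, existence_record(p)))
  m2 <- p$m0 + p$sq * atanh(2 * p$d / p$q0 - 1)
  cond <- existence_record(p, m2)
  if (!cond$m2_lt_gamma_over_alpham)
    return(new_fixed_point("F2", NULL, FALSE, cond))
  S2 <- -p$S0 * log(p$alpha_m * m2 / p$gamma)
  D2 <- p$lambda * S2 / p$d
  if (S2 <= 0 || S2 + D2 > 1)
    return(new_fixed_point("F2", NULL, FALSE, cond))
  fp <- new_fixed_point("F2", c(S = S2, D = D2, a = 0, m = m2), TRUE, cond)
  if (classify) fp <- classify_stability(fp, p)
  fp
}

#' Activator-carrying fixed point F3
#'
#' The only fixed point with nonvanishing stem-division activator. It has
#' no closed form; like the rest of the fixed-point analysis it is defined
#' in the \eqn{\Upsilon \approx 1} approximation (the saturation factor is
#' a confluence regularization, not part of the rest-state structure), and
#' it is located by a damped-Newton multi-start root search of that
#' analytic field restricted to `a > 0`, seeded along the activator-balance
#' nullcline \eqn{S = \alpha_a(1+a)/(\beta a)}. The approximate existence
#' condition `d > psi*alpha_a/beta` is reported alongside. When it exists,
#' F3 is a saddle; it often lies at high total density (`S + D` possibly
#' beyond 1, see the `in_simplex` element), consistent with its role as the
#' unstable ridge between regression and runaway proliferation.
#'
#' @inheritParams fixed_point_f1
#' @param n_starts number of seed points along the nullcline.
#' @param tol residual tolerance on `max(abs(field))` at the root.
#' @return A `csm_fixed_point` with `label = "F3"` and an extra logical
#'   element `in_simplex`. If the heuristic predicts existence but no root
#'   is found, a warning is issued and `exists = FALSE`.
#' @export
fixed_point_f3 <- function(p, n_starts = 60, tol = 1e-8, classify = TRUE) {
  stopifnot(inherits(p, "csm_params"))
  cond <- existence_record(p)
  roots <- find_fixed_points(p, n_starts = n_starts, tol = tol,
                             max_total = 3)
  cand <- Filter(function(r) r[["a"]] > 1e-4, roots)
  if (!length(cand)) {
    if (cond$d_gt_psi_alpha_over_beta)
      warning("F3 existence heuristic d > psi*alpha_a/beta holds but no ",
              "a > 0 root was found", call. = FALSE)
    return(new_fixed_point("F3", NULL, FALSE, cond))
  }
  # the model has a single a != 0 rest state; if several distinct roots
  # survive dedup, prefer one inside the simplex, then the smallest a
  in_simplex <- vapply(cand, function(r) r[["S"]] + r[["D"]] <= 1,
                       logical(1))
  if (any(in_simplex)) cand <- cand[in_simplex]
  avals <- vapply(cand, `[[`, numeric(1), "a")
  loc <- cand[[which.min(avals)]]
  fp <- new_fixed_point("F3", loc, TRUE, cond)
  fp$in_simplex <- loc[["S"]] + loc[["D"]] <= 1
  if (classify) fp <- classify_stability(fp, p)
  fp
}

# Vector field in the Upsilon = 1 approximation used throughout the
# fixed-point analysis; defined for any non-negative S, D (no confluence
# cap), which is where F3 may live.
field_u1 <- function(x, p) {
  S <- x[[1]]; D <- x[[2]]; a <- x[[3]]; m <- x[[4]]
  pp <- p$eta * a / ((1 + p$eta * a) * (1 + p$psi * D))
  q  <- p$q0 / 2 * (1 + tanh((m - p$m0) / p$sq))
  mitosis <- p$lambda * S
  c((2 * pp - 1) * mitosis + q * D,
    2 * (1 - pp) * mitosis - (p$d + q) * D,
    a * (p$beta * S * a / (1 + a) - p$alpha_a),
    p$gamma * exp(-S / p$S0) - p$alpha_m * m)
}

#' Stability classification from Jacobian eigenvalues
#'
#' Evaluates the Jacobian at the fixed point's location and labels it from
#' the signs of the eigenvalue real parts: `"stable"` when all are
#' negative, `"saddle"` when signs are mixed (unstable with a stable
#' manifold), `"unstable"` when all are positive. An eigenvalue with
#' `|Re| < 1e-10` makes the point non-hyperbolic and raises an error rather
#' than guessing.
#'
#' @param fp a `csm_fixed_point` that exists.
#' @param p a [csm_params()] object.
#' @param mode Jacobian mode, see [csm_jacobian()]. The default matches the
#'   \eqn{\Upsilon \approx 1} approximation used in the analysis.
#' @return The fixed point with `eigenvalues` and `stability` filled in.
#' @export
classify_stability <- function(fp, p, mode = "analytic_upsilon1") {
  stopifnot(inherits(fp, "csm_fixed_point"))
  if (!fp$exists)
    stop("cannot classify a non-existent fixed point", call. = FALSE)
  J <- csm_jacobian(fp$location, p, mode = mode)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  if (any(abs(re) < 1e-10))
    stop("non-hyperbolic fixed point: eigenvalue real part within 1e-10 of ",
         "zero; linear classification is inconclusive", call. = FALSE)
  fp$eigenvalues <- ev
  fp$stability <- if (all(re < 0)) "stable"
                  else if (all(re > 0)) "unstable"
                  else "saddle"
  fp
}

#' Multi-start root search over the analytic vector field
#'
#' Brute-force locator of every rest state of the \eqn{\Upsilon \approx 1}
#' analytic system: damped Newton iterations (analytic Jacobian) from a
#' deterministic battery of seeds — the known closed-form candidates, a
#' grid over the low-density region, and points along the a-nullcline
#' \eqn{S = \alpha_a(1+a)/(\beta a)}. Roots are constrained to
#' `S, D, a, m >= 0` with `S, D <= max_total` (the rest-state structure of
#' the saturated model may place the activator-carrying root beyond the
#' simplex `S + D <= 1`) and de-duplicated. Restricting the returned set to
#' the simplex recovers exactly `{F1, F2 (if it exists), F3 (when it lies
#' inside)}`.
#'
#' @param p a [csm_params()] object.
#' @param n_starts seeds along the a-nullcline.
#' @param tol acceptance tolerance on `max(abs(field))`.
#' @param max_total upper bound on `S` and `D` for accepted roots.
#' @return A list of named numeric root vectors.
#' @export
find_fixed_points <- function(p, n_starts = 60, tol = 1e-8, max_total = 3) {
  stopifnot(inherits(p, "csm_params"))
  f <- function(x) {
    if (any(x < 0) || x[1] > max_total || x[2] > max_total)
      return(rep(1e6, 4))  # push the search back into the domain
    field_u1(x, p)
  }
  seeds <- list()
  # closed-form candidates
  seeds[[1]] <- c(0, 0, 0, p$gamma / p$alpha_m)
  f2 <- fixed_point_f2(p, classify = FALSE)
  if (f2$exists) seeds[[length(seeds) + 1]] <- unname(f2$location)
  # a-nullcline seeds: S = alpha_a (1+a) / (beta a); D either from the cell
  # balance D = lambda S / d or from the p = 1/2 branch
  a_grid <- exp(seq(log(0.05), log(500), length.out = n_starts))
  for (a0 in a_grid) {
    S0 <- p$alpha_a * (1 + a0) / (p$beta * a0)
    if (S0 <= 0 || S0 > max_total) next
    m0 <- p$gamma * exp(-S0 / p$S0) / p$alpha_m
    seeds[[length(seeds) + 1]] <- c(S0, p$lambda * S0 / p$d, a0, m0)
    Dhalf <- (p$eta * a0 - 1) / (p$psi * (p$eta * a0 + 1))
    if (Dhalf > 0)
      seeds[[length(seeds) + 1]] <- c(S0, Dhalf, a0, m0)
  }
  # coarse low-density grid (a = 0 sheet and a small a > 0 sheet)
  for (S0 in c(0.01, 0.05, 0.2, 0.5)) for (D0 in c(0.01, 0.1, 0.4)) {
    m0 <- p$gamma * exp(-S0 / p$S0) / p$alpha_m
    seeds[[length(seeds) + 1]] <- c(S0, D0, 0, m0)
    seeds[[length(seeds) + 1]] <- c(S0, D0, 0.5, m0)
  }
  roots <- list()
  for (s in seeds) {
    r <- newton_root(s, f, p, tol = tol)
    if (is.null(r)) next
    # snap numerically-zero activator onto the invariant sheet a = 0
    if (abs(r[3]) < 1e-10) {
      r2 <- c(r[1], r[2], 0, r[4])
      if (max(abs(f(r2))) <= tol) r <- r2 else next
    }
    if (any(r < -1e-12) || r[1] > max_total || r[2] > max_total) next
    r <- pmax(r, 0)
    roots[[length(roots) + 1]] <- c(S = r[1], D = r[2], a = r[3], m = r[4])
  }
  dedupe_roots(roots)
}

# Damped Newton with the analytic (Upsilon = 1) Jacobian; returns NULL if
# not converged.
newton_root <- function(x0, f, p, tol, maxit = 200) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    if (any(!is.finite(fx))) return(NULL)
    nf <- max(abs(fx))
    if (nf <= tol) return(x)
    J <- tryCatch(
      csm_jacobian(c(S = max(x[1], 0), D = max(x[2], 0),
                     a = max(x[3], 0), m = max(x[4], 0)), p,
                   mode = "analytic_upsilon1"),
      error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(unname(solve(J, -fx)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    # backtracking line search on the residual norm
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nf) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn
  }
  NULL
}

dedupe_roots <- function(roots, eps = 1e-5) {
  out <- list()
  for (r in roots) {
    dup <- FALSE
    for (o in out)
      if (max(abs(r - o)) < eps) { dup <- TRUE; break }
    if (!dup) out[[length(out) + 1]] <- r
  }
  out
}

#' All fixed points of a parameter set
#'
#' Convenience wrapper returning the F1/F2/F3 analysis in one list.
#'
#' @param p a [csm_params()] object.
#' @return Named list with elements `F1`, `F2`, `F3` (each a
#'   `csm_fixed_point`).
#' @examples
#' fps <- csm_fixed_points(csm_params(d = 0.2, q0 = 1, eta = 5, beta = 2))
#' fps$F2$stability
#' @export
csm_fixed_points <- function(p) {
  list(F1 = fixed_point_f1(p),
       F2 = fixed_point_f2(p),
       F3 = fixed_point_f3(p))
}
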