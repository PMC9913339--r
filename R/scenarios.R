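# The 15 published parameter regimes. Columns: four activator-side
# constants (alpha_a, alpha_m, beta, gamma) and four cell-side constants
# (eta, psi, d, q0); the remaining constants are the package-wide fixed
# defaults (lambda = 1, S0 = 0.038, m0 = 0.5, sq = 0.01, sl = 0.1).
#' Parameter regime table
#'
#' The catalogue of published parameter rows, one per figure regime. The
#' three panels of the dose-escalation study (`fig5a`-`fig5c`) share the
#' row `fig5ac` and differ only in the drug block.
#'
#' @return data.frame with 15 rows and columns `row`, `alpha_a`, `alpha_m`,
#'   `beta`, `gamma`, `eta`, `psi`, `d`, `q0`.
#' @export
scenario_param_rows <- function() {
  rows <- rbind(
    c("fig1a",  0.5, 1.0, 2.0, 1.0, 5.0,  1.0, 1.2,  0.5),
    c("fig1b",  1.0, 1.0, 2.0, 1.0, 5.0,  1.0, 0.2,  1.0),
    c("fig2a",  0.5, 1.0, 2.0, 1.0, 5.0,  1.0, 1.2,  0.5),
    c("fig2b",  1.0, 1.0, 2.0, 1.0, 5.0,  1.0, 0.2,  1.0),
    c("fig2c",  0.4, 0.4, 2.0, 1.0, 2.0,  1.0, 0.4,  1.0),
    c("fig2d",  1.0, 1.0, 2.0, 1.0, 5.0,  1.0, 0.2,  1.0),
    c("fig3a",  1.0, 1.0, 2.0, 1.0, 5.0,  1.0, 0.2,  1.0),
    c("fig5ac", 1.0, 1.0, 2.0, 4.0, 2.0,  1.0, 0.95, 1.0),
    c("fig5d",  1.0, 1.0, 2.0, 1.0, 1.75, 1.0, 0.8,  1.0),
    c("fig6a",  0.7, 1.0, 4.0, 1.0, 4.0,  1.0, 1.2,  1.0),
    c("fig6b",  1.0, 1.0, 3.0, 1.0, 1.0,  1.0, 0.8,  1.0),
    c("fig7a",  1.0, 0.5, 2.0, 3.0, 5.0,  1.0, 0.9,  1.0),
    c("fig7b",  1.0, 1.0, 2.0, 1.0, 5.0,  1.0, 0.2,  1.0),
    c("fig8a",  1.0, 0.5, 2.0, 3.0, 5.0,  1.0, 0.9,  1.0),
    c("fig8b",  0.7, 1.0, 4.0, 1.0, 4.0,  1.0, 1.2,  1.0))
  out <- data.frame(row = rows[, 1], stringsAsFactors = FALSE)
  nums <- c("alpha_a", "alpha_m", "beta", "gamma", "eta", "psi", "d", "q0")
  for (j in seq_along(nums)) out[[nums[j]]] <- as.numeric(rows[, j + 1])
  out
}

# Reference drug constants shared by all therapy scenarios.
default_drug_constants <- function() {
  list(chi_max = 1.0, alpha_d = 10.0, T = 1.0, tau = 0.08,
       omega0 = 1.0, chi0 = 0.2, s_chi = 0.05)
}

scenario_registry <- function() {
  dc <- default_drug_constants()
  # helper closures keep each entry terse
  drug <- function(type, chi_max = dc$chi_max, omega0 = dc$omega0)
    list(type = type, chi_max = chi_max, alpha_d = dc$alpha_d, T = dc$T,
         tau = dc$tau, omega0 = omega0, chi0 = dc$chi0, s_chi = dc$s_chi)
  noise <- function(target, rho = 0.10, n = 20)
    list(target = target, rho = rho, n = n)
  seeded <- c(S = 0.01, D = 0.1, a = 0.5, m = 0.1)  # small seeded tumor
  # activator-primed state: enough early symmetric stem division for a
  # transient overshoot before the activator decays
  over_f1 <- c(S = 0.05, D = 0.02, a = 1, m = 0.1)
  list(
    fig1a = list(row = "fig1a", init = over_f1, t_end = 20,
                 outcome = "overshoot, then convergence on F1 (extinction)"),
    fig1b = list(row = "fig1b", init = seeded, t_end = 20,
                 outcome = "convergence on the plasticity-sustained F2"),
    fig2a = list(row = "fig2a", init = over_f1, t_end = 10,
                 noise = noise("lambda"),
                 outcome = "stochastic bundle around the F1-convergent run"),
    fig2b = list(row = "fig2b", init = seeded, t_end = 10,
                 noise = noise("lambda"),
                 outcome = "stochastic bundle around the F2-convergent run"),
    fig2c = list(row = "fig2c",
                 init = c(S = 0.15, D = 0.3, a = 0.3, m = 0.1), t_end = 15,
                 noise = noise("lambda"),
                 outcome = paste("falling S and D until m crosses m0, then",
                                 "a plasticity bump and damped relaxation",
                                 "onto F2")),
    fig2d = list(row = "fig2d", init = seeded, t_end = 10,
                 noise = noise("d"),
                 outcome = "noise on d: D spreads wider than S"),
    fig3a = list(row = "fig3a", init = "F2", t_end = 10,
                 noise = noise("lambda", n = 100),
                 outcome = "bundle width growth around F2, linear for t<10"),
    fig5a = list(row = "fig5ac", init = seeded, t_end = 20,
                 drug = drug("cytotoxic"),
                 outcome = "cytotoxic therapy breaks the F2 loop; regression"),
    fig5b = list(row = "fig5ac", init = seeded, t_end = 20,
                 drug = drug("cytotoxic", chi_max = 2.0, omega0 = 1.5),
                 outcome = "higher dose: faster regression"),
    fig5c = list(row = "fig5ac", init = seeded, t_end = 20,
                 drug = drug("cytotoxic", chi_max = 3.0, omega0 = 2.0),
                 outcome = "highest dose: fastest regression"),
    fig5d = list(row = "fig5d",
                 init = c(S = 0.1, D = 0.5, a = 20, m = 0.1), t_end = 30,
                 drug = drug("cytotoxic"),
                 outcome = paste("tumor growth paradox: untreated",
                                 "overshoot regresses, treated run",
                                 "diverges")),
    fig6a = list(row = "fig6a",
                 init = c(S = 0.02, D = 0.05, a = 5, m = 0.1), t_end = 20,
                 drug = drug("cytostatic"),
                 outcome = paste("cytostatic rescue: untreated activator",
                                 "diverges, treated tumor regresses")),
    fig6b = list(row = "fig6b",
                 init = c(S = 0.05, D = 0.02, a = 3, m = 0.1), t_end = 25,
                 drug = drug("cytostatic"),
                 outcome = paste("spontaneous regression; cytostatic drug",
                                 "only delays it")),
    fig7a = list(row = "fig7a",
                 init = c(S = 0.05, D = 0.1, a = 0.1, m = 0.6), t_end = 30,
                 drug = drug("anti_plasticity"),
                 outcome = "anti-plasticity drug breaks the F2 loop"),
    fig7b = list(row = "fig7b", init = seeded, t_end = 30,
                 drug = drug("anti_plasticity"),
                 outcome = paste("anti-plasticity action too weak against",
                                 "d << q0; colony persists near F2")),
    fig8a = list(row = "fig8a",
                 init = c(S = 0.05, D = 0.1, a = 0.1, m = 0.6), t_end = 30,
                 drug = drug("differentiation_plus_cytotoxic"),
                 outcome = "combined therapy: regression of the F2 colony"),
    fig8b = list(row = "fig8b",
                 init = c(S = 0.02, D = 0.05, a = 5, m = 0.1), t_end = 20,
                 drug = drug("differentiation_plus_cytotoxic"),
                 outcome = paste("combined therapy rescues an otherwise",
                                 "divergent proliferation")))
}

#' Retrieve a named scenario
#'
#' Builds the fully-populated scenario for one figure regime: validated
#' model parameters from the regime table, the package-default initial
#' state (the published regimes come without initial conditions, so these
#' are package choices, documented in `notes`), simulation horizon, and the
#' optional noise or drug block.
#'
#' @param name scenario name, e.g. `"fig1b"`; see [list_scenarios()].
#' @return A list of class `csm_scenario` with elements `name`, `model`
#'   ([csm_params()]), `init` ([csm_state()]), `t_end`, `noise`
#'   ([noise_spec()] plus `n`, or NULL), `therapy` ([therapy_spec()] or
#'   NULL), `outcome`, `notes`.
#' @examples
#' sc <- get_scenario("fig1b")
#' sc$model$d
#' @export
get_scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'. Available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  entry <- reg[[name]]
  tab <- scenario_param_rows()
  row <- tab[tab$row == entry$row, ]
  model <- csm_params(alpha_a = row$alpha_a, alpha_m = row$alpha_m,
                      beta = row$beta, gamma = row$gamma, eta = row$eta,
                      psi = row$psi, d = row$d, q0 = row$q0)
  init <- entry$init
  if (identical(init, "F2")) {
    f2 <- fixed_point_f2(model, classify = FALSE)
    if (!f2$exists) stop("scenario '", name, "' anchors at F2 but F2 does ",
                         "not exist for its parameters", call. = FALSE)
    init <- f2$location
  }
  init <- csm_state(init[["S"]], init[["D"]], init[["a"]], init[["m"]])
  noise <- NULL
  if (!is.null(entry$noise)) {
    noise <- noise_spec(entry$noise$target, rho = entry$noise$rho)
    noise$n <- entry$noise$n
  }
  therapy <- NULL
  if (!is.null(entry$drug)) {
    d <- entry$drug
    sched <- drug_schedule(chi_max = d$chi_max, alpha_d = d$alpha_d,
                           T = d$T, tau = d$tau)
    act <- action_params(omega0 = d$omega0, chi0 = d$chi0,
                         s_chi = d$s_chi)
    therapy <- if (d$type == "differentiation_plus_cytotoxic")
      therapy_spec(d$type, sched, act, action_cyto = act)
    else therapy_spec(d$type, sched, act)
  }
  structure(list(name = name, model = model, init = init,
                 t_end = entry$t_end, noise = noise, therapy = therapy,
                 outcome = entry$outcome,
                 notes = paste0("model constants from regime row '",
                                entry$row, "'; initial state and t_end are ",
                                "package defaults chosen to exhibit the ",
                                "catalogued outcome")),
            class = "csm_scenario")
}

#' @export
print.csm_scenario <- function(x, ...) {
  cat("Scenario ", x$name, ": ", x$outcome, "\n", sep = "")
  cat(sprintf("  init: S=%.3g D=%.3g a=%.3g m=%.3g;  t_end = %g d\n",
              x$init[["S"]], x$init[["D"]], x$init[["a"]], x$init[["m"]],
              x$t_end))
  if (!is.null(x$noise))
    cat("  noise on '", x$noise$target, "', rho = ", x$noise$rho,
        " (relative), bundle n = ", x$noise$n, "\n", sep = "")
  if (!is.null(x$therapy))
    cat("  therapy:", x$therapy$type, "\n")
  invisible(x)
}

#' Catalogue of available scenarios
#'
#' @return data.frame with one row per scenario: `name`, `row` (parameter
#'   regime), `kind` (deterministic / stochastic / therapy) and `outcome`.
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(
    name = names(reg),
    row = vapply(reg, `[[`, character(1), "row"),
    kind = vapply(reg, function(e)
      if (!is.null(e$drug)) "therapy"
      else if (!is.null(e$noise)) "stochastic"
      else "deterministic", character(1)),
    outcome = vapply(reg, `[[`, character(1), "outcome"),
    row.names = NULL)
}

#' Run a scenario with its packaged defaults
#'
#' Dispatches on the scenario kind: plain deterministic integration,
#' stochastic bundle, or therapy run (returned together with the matching
#' untreated control).
#'
#' @param sc a `csm_scenario` or scenario name.
#' @param seed RNG seed for stochastic scenarios.
#' @param ... forwarded to the underlying simulator.
#' @return A `csm_trajectory`, a `csm_bundle`, or (therapy scenarios) a
#'   list with `treated` and `untreated` trajectories.
#' @export
run_scenario <- function(sc, seed = 1L, ...) {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "csm_scenario"))
  if (!is.null(sc$therapy)) {
    list(treated = simulate_with_therapy(sc$model, sc$therapy, sc$init,
                                         sc$t_end, ...),
         untreated = simulate_csm(sc$model, sc$init, sc$t_end, ...))
  } else if (!is.null(sc$noise)) {
    simulate_bundle(sc$model, sc$noise, sc$init, sc$t_end,
                    n = sc$noise$n, base_seed = seed, ...)
  } else {
    simulate_csm(sc$model, sc$init, sc$t_end, ...)
  }
}
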