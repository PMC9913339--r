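#' Write a trajectory to CSV (with JSON sidecar)
#'
#' Writes columns `t,S,D,a,m` (plus `param` for stochastic trajectories
#' carrying a parameter path) with 15 significant digits so regression
#' diffs are meaningful. Events and metadata go to `<path>.json`.
#'
#' @param tr a `csm_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(tr, path, sidecar = TRUE) {
  stopifnot(inherits(tr, "csm_trajectory"))
  df <- as.data.frame(tr)
  if (!is.null(tr$param_path)) df$param <- tr$param_path$value
  fmt <- vapply(df, function(col) format(col, digits = 15, trim = TRUE,
                                         scientific = FALSE),
                character(nrow(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  if (sidecar) {
    meta <- list(events = tr$events,
                 params = unclass(tr$params),
                 flags = tr$flags,
                 t_end = tr$metadata$t_end)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return data.frame with columns `t`, `S`, `D`, `a`, `m` (and `param`
#'   when present).
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}

#' Export a scenario configuration to YAML
#'
#' The configuration mirrors the constructor field names (`alpha_a`,
#' `alpha_m`, `beta`, `gamma`, `eta`, `psi`, `d`, `q0`, ... and the drug
#' block `chi_max`, `alpha_d`, `T`, `tau`, `omega0`, `chi0`, `s_chi`), so
#' an exported file can be hand-edited and re-imported.
#'
#' @param sc a `csm_scenario` or scenario name.
#' @param path output file; NULL returns the YAML text.
#' @return `path` (or the YAML string), invisibly.
#' @export
export_scenario_yaml <- function(sc, path = NULL) {
  if (is.character(sc)) sc <- get_scenario(sc)
  stopifnot(inherits(sc, "csm_scenario"))
  cfg <- list(name = sc$name,
              model = unclass(sc$model),
              init = as.list(unclass(sc$init)),
              t_end = sc$t_end)
  if (!is.null(sc$noise))
    cfg$noise <- list(target = sc$noise$target, rho = sc$noise$rho,
                      amplitude_mode = sc$noise$amplitude_mode,
                      n = sc$noise$n)
  if (!is.null(sc$therapy)) {
    th <- sc$therapy
    cfg$drug <- list(type = th$type,
                     zeta = th$schedule$zeta,
                     alpha_d = th$schedule$alpha_d, T = th$schedule$T,
                     tau = th$schedule$tau, t_start = th$schedule$t_start,
                     omega0 = th$action$omega0, chi0 = th$action$chi0,
                     s_chi = th$action$s_chi,
                     clamp_at_zero = th$clamp_at_zero)
    if (!is.null(th$action_cyto))
      cfg$drug$cyto <- unclass(th$action_cyto)
  }
  txt <- yaml::as.yaml(cfg, precision = 18)  # 18 digits round-trip doubles
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Import a scenario configuration from YAML
#'
#' Inverse of [export_scenario_yaml()]. Field names are validated; unknown
#' model fields are an error.
#'
#' @param path YAML file (or a YAML string containing a newline).
#' @return A `csm_scenario`.
#' @export
import_scenario_yaml <- function(path) {
  cfg <- yaml::yaml.load(
    if (grepl("\n", path)) path else paste(readLines(path), collapse = "\n"))
  known <- names(formals(csm_params))
  unknown <- setdiff(names(cfg$model), known)
  if (length(unknown))
    stop("unknown model field(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  model <- do.call(csm_params, cfg$model)
  init <- csm_state(cfg$init$S, cfg$init$D, cfg$init$a, cfg$init$m)
  noise <- NULL
  if (!is.null(cfg$noise)) {
    noise <- noise_spec(cfg$noise$target, rho = cfg$noise$rho,
                        amplitude_mode = cfg$noise$amplitude_mode)
    noise$n <- cfg$noise$n
  }
  therapy <- NULL
  if (!is.null(cfg$drug)) {
    d <- cfg$drug
    sched <- drug_schedule(zeta = d$zeta, alpha_d = d$alpha_d, T = d$T,
                           tau = d$tau,
                           t_start = if (is.null(d$t_start)) 0 else d$t_start)
    act <- action_params(omega0 = d$omega0, chi0 = d$chi0,
                         s_chi = d$s_chi)
    act2 <- if (!is.null(d$cyto))
      action_params(d$cyto$omega0, d$cyto$chi0, d$cyto$s_chi) else NULL
    therapy <- therapy_spec(d$type, sched, act, action_cyto = act2,
                            clamp_at_zero = isTRUE(d$clamp_at_zero))
  }
  structure(list(name = cfg$name, model = model, init = init,
                 t_end = cfg$t_end, noise = noise, therapy = therapy,
                 outcome = "imported configuration",
                 notes = "imported from YAML"),
            class = "csm_scenario")
}

#' Export a fixed-point analysis to JSON
#'
#' @param fps result of [csm_fixed_points()].
#' @param path output path; NULL returns the JSON text.
#' @return `path` or the JSON string, invisibly.
#' @export
export_fixed_points_json <- function(fps, path = NULL) {
  enc <- lapply(fps, function(fp) {
    out <- list(label = fp$label, exists = fp$exists,
                existence_conditions = fp$existence_conditions)
    if (fp$exists) {
      out$location <- as.list(fp$location)
      out$eigenvalues_re <- Re(fp$eigenvalues)
      out$eigenvalues_im <- Im(fp$eigenvalues)
      out$stability <- fp$stability
    }
    out
  })
  txt <- jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}
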