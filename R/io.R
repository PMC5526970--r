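#' Read a run configuration file
#'
#' Parses a flat YAML (or JSON, which YAML subsumes) configuration into model
#' objects. Recognised keys: \code{model} ("fixed" or "moi"); \code{params}
#' with \code{gamma}, \code{K_eta} (or \code{eta}), \code{beta},
#' \code{delta}; \code{strategies} (a list of two: numbers for the fixed
#' model, length-3 lists for the MOI model); \code{init} with \code{B0_0},
#' \code{P1_0}, \code{P2_0}; optional \code{rtol}, \code{atol}, \code{t_max},
#' \code{seed}. Missing keys fall back to the package defaults.
#'
#' @param path path to a YAML/JSON configuration file.
#' @return A list with elements \code{model}, \code{params}, \code{init},
#'   \code{strategies} (possibly \code{NULL}), \code{rtol}, \code{atol},
#'   \code{t_max}, \code{seed}.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("model: fixed", "params: {K_eta: 20, beta: 100}",
#'              "strategies: [0.25, 0.29]"), cfg_file)
#' readRunConfig(cfg_file)$params
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$params
  eta <- if (!is.null(p$K_eta)) p$K_eta else if (!is.null(p$eta)) p$eta else 20
  params <- modelParams(gamma = p$gamma %||% 1, K = 1, eta = eta,
                        beta = p$beta %||% 100, delta = p$delta %||% 1)
  ic <- cfg$init
  init <- initialState(B0 = ic$B0_0 %||% 1e-3, P1 = ic$P1_0 %||% 1e-7,
                       P2 = ic$P2_0 %||% 1e-7)
  model <- cfg$model %||% "fixed"
  strategies <- if (is.null(cfg$strategies)) NULL else {
    lapply(cfg$strategies, function(s) {
      if (model == "moi") as_moi_strategy(unlist(s))
      else as_fixed_strategy(unlist(s))
    })
  }
  list(model = model, params = params, init = init, strategies = strategies,
       rtol = cfg$rtol %||% 1e-8, atol = cfg$atol %||% 1e-12,
       t_max = cfg$t_max %||% 1e5, seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory as tidy CSV
#'
#' Writes the time grid and per-compartment densities with a header row
#' (\code{t}, compartment names).
#'
#' @param traj a \code{"phage_trajectory"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(inherits(traj, "phage_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Export a payoff matrix as CSV with a JSON sidecar
#'
#' The CSV carries the strategy grid as header row and first column; the
#' sidecar (\code{<path>.json}) records parameters, the mirroring flag,
#' convergence failures and the saddle location.
#'
#' @param pm a \code{"phage_payoff_matrix"}.
#' @param path output CSV path.
#' @param solution optional \code{"minimax_solution"} to record in the
#'   sidecar (computed from \code{pm} when omitted and the matrix is
#'   complete).
#' @return \code{path}, invisibly.
#' @export
writePayoffMatrix <- function(pm, path, solution = NULL) {
  stopifnot(inherits(pm, "phage_payoff_matrix"))
  df <- data.frame(f1 = pm$f_grid, pm$M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (is.null(solution) && !anyNA(pm$M)) solution <- minimaxSolution(pm)
  meta <- list(params = unclass(pm$params), init = unclass(pm$init),
               mirrored = pm$mirrored,
               n_nonconverged = sum(!pm$converged),
               saddle = if (!is.null(solution))
                 list(f_opt = solution$f_opt, game_value = solution$game_value,
                      unique = solution$unique))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export an evolution trace as CSV with a JSON summary
#'
#' The CSV has one row per game iteration (winner and loser propensities and
#' the payoff); the JSON summary (\code{<path>.json}) records the seed,
#' convergence iteration and final strategy.
#'
#' @param trace a \code{"phage_evolution_trace"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEvolutionTrace <- function(trace, path) {
  stopifnot(inherits(trace, "phage_evolution_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  fin <- attr(trace, "final")
  ca <- attr(trace, "converged_at")
  smry <- list(seed = attr(trace, "seed"),
               converged_at = if (is.na(ca)) NULL else ca,
               final_strategy = fin$f)
  jsonlite::write_json(smry, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export a steady-state result as a JSON record
#'
#' @param ss a \code{"phage_steady_state"}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSteadyState <- function(ss, path) {
  stopifnot(inherits(ss, "phage_steady_state"))
  rec <- list(model = ss$model, L1 = ss$L1, L2 = ss$L2,
              B0_final = ss$B0_final, t_end = ss$t_end,
              converged = ss$converged, state = as.list(ss$state))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export a sweep result as CSV with provenance sidecar
#'
#' @param sweep a \code{"phage_sweep"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "phage_sweep"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  spec <- attr(sweep, "spec")
  meta <- list(parameter = attr(sweep, "parameter"),
               preset = attr(sweep, "preset"),
               base_params = unclass(spec$params),
               base_init = unclass(spec$init),
               provenance = attr(sweep, "provenance"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
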