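#' Parameter ranges for the robustness analysis
#'
#' The two range presets used by the sweep engine: the biologically
#' reasonable range of each parameter, and the much wider range explored in
#' simulations. Initial densities are fractions of the carrying capacity.
#'
#' @return Named list; each element has components \code{biological} and
#'   \code{explored}, each a length-2 numeric range.
#' @examples
#' sweepRanges()$beta
#' @export
sweepRanges <- function() {
  list(
    gamma = list(biological = c(0.5, 10),    explored = c(0.2, 1e3)),
    eta   = list(biological = c(0.45, 100),  explored = c(0.2, 1e3)),
    beta  = list(biological = c(20, 1000),   explored = c(2, 1e4)),
    delta = list(biological = c(0.5, 10),    explored = c(0.1, 1e4)),
    B0_0  = list(biological = c(1e-9, 1),    explored = c(1e-6, 1e-1)),
    P0    = list(biological = c(1e-9, 1e-7), explored = c(1e-9, 1e-3))
  )
}

#' Specify a one-parameter sweep
#'
#' One parameter is varied at a time (log-spaced by default) while all others
#' stay at their base values; this is the design behind the robustness
#' analysis showing that the optimal propensity stays in a narrow band over
#' orders of magnitude of parameter variation.
#'
#' @param parameter one of \code{"gamma", "eta", "beta", "delta", "B0_0",
#'   "P0"} (\code{eta} is the composite K*eta when densities are in units of
#'   K).
#' @param n number of sweep points (log-spaced across the preset range).
#' @param preset \code{"biological"} or \code{"explored"} range
#'   (\code{\link{sweepRanges}}).
#' @param values explicit values overriding the preset grid (must lie within
#'   the preset range).
#' @param params,init base configuration from which each point deviates in
#'   the swept parameter only.
#' @return A \code{"sweep_spec"} list.
#' @examples
#' sweepSpec("beta", n = 5)
#' @export
sweepSpec <- function(parameter = c("gamma", "eta", "beta", "delta",
                                    "B0_0", "P0"),
                      n = 5, preset = c("biological", "explored"),
                      values = NULL, params = modelParams(),
                      init = initialState()) {
  parameter <- match.arg(parameter)
  preset <- match.arg(preset)
  rng <- sweepRanges()[[parameter]][[preset]]
  if (is.null(values)) {
    values <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
    # guard the endpoints against floating-point drift out of the preset range
    values <- pmin(pmax(values, rng[1]), rng[2])
  } else {
    if (any(values < rng[1] | values > rng[2]))
      stop("sweep values outside the '", preset, "' range [",
           rng[1], ", ", rng[2], "] for ", parameter, call. = FALSE)
  }
  structure(list(parameter = parameter, values = sort(values),
                 preset = preset, params = params, init = init),
            class = "sweep_spec")
}

# Apply one swept value to the base configuration.
apply_sweep_value <- function(spec, value) {
  params <- spec$params
  init <- spec$init
  if (spec$parameter %in% c("gamma", "eta", "beta", "delta")) {
    params[[spec$parameter]] <- value
    params <- modelParams(gamma = params$gamma, K = params$K,
                          eta = params$eta, beta = params$beta,
                          delta = params$delta)
  } else if (spec$parameter == "B0_0") {
    init <- initialState(B0 = value, P1 = init$P1, P2 = init$P2)
  } else {
    init <- initialState(B0 = init$B0, P1 = value, P2 = value)
  }
  list(params = params, init = init)
}

#' Run a one-parameter robustness sweep
#'
#' Computes the minimax-optimal propensity at every sweep value, and attaches
#' the crash onset time of the symmetric game played at that optimum together
#' with the closed-form analytic prediction. Points where the minimax fails
#' are marked, and the sweep continues.
#'
#' @param spec a \code{\link{sweepSpec}}.
#' @param resolution minimax grid resolution (see \code{\link{findFopt}}).
#' @param ... passed to \code{\link{findFopt}}.
#' @return A \code{"phage_sweep"} data frame: one row per value with columns
#'   \code{value}, \code{f_opt}, \code{unique}, \code{t_star},
#'   \code{f_formula}, \code{failed}; attributes carry the spec, preset and
#'   provenance (package version, config hash).
#' @examples
#' \donttest{
#' sw <- runSweep(sweepSpec("beta", n = 3), resolution = 0.02)
#' trendReport(sw)
#' }
#' @export
runSweep <- function(spec, resolution = 0.01, ...) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(spec$values, function(v) {
    cfg <- apply_sweep_value(spec, v)
    res <- tryCatch(findFopt(cfg$params, cfg$init, resolution = resolution,
                             ...),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(value = v, f_opt = NA_real_, unique = NA,
                        t_star = NA_real_, f_formula = NA_real_,
                        failed = TRUE))
    # crash time of the symmetric game at the optimum
    traj <- integrateDynamics("fixed", cfg$params,
                              strategies = list(res$f_opt, res$f_opt),
                              init = cfg$init,
                              t_end = 50 / cfg$params$gamma, n_out = 5001)
    ct <- crashTime(traj, cfg$params)
    form <- foptClosedForm(cfg$params, P0 = cfg$init$P1)
    data.frame(value = v, f_opt = res$f_opt, unique = res$unique,
               t_star = ct$t_star, f_formula = form$f_opt_formula,
               failed = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("phage_sweep", "data.frame"),
            spec = spec, parameter = spec$parameter, preset = spec$preset,
            provenance = list(package_version =
                                as.character(utils::packageVersion("phagegame")),
                              config_hash = config_hash(spec)))
}

#' @export
print.phage_sweep <- function(x, ...) {
  cat(sprintf("Sweep of %s over the %s range (%d points):\n",
              attr(x, "parameter"), attr(x, "preset"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Signed trend of the optimum across a sweep
#'
#' Classifies how the optimal propensity moves as the swept parameter
#' increases, by comparing endpoints and interior points: increasing in the
#' infection rate constant, burst size and initial densities; decreasing in
#' the decision rate and bacterial growth rate.
#'
#' @param result a \code{"phage_sweep"} from \code{\link{runSweep}} (at least
#'   3 non-failed points).
#' @param tol changes in f_opt smaller than this are treated as flat.
#' @return A list: \code{parameter}, \code{direction} (one of
#'   \code{"increasing", "decreasing", "flat", "non-monotonic"}),
#'   \code{f_opt_range}.
#' @export
trendReport <- function(result, tol = 0.005) {
  stopifnot(inherits(result, "phage_sweep"))
  ok <- !result$failed & !is.na(result$f_opt)
  if (sum(ok) < 3L)
    stop("need at least 3 successful sweep points for a trend", call. = FALSE)
  f <- result$f_opt[ok]
  d <- diff(f)
  direction <- if (all(abs(d) <= tol)) "flat"
  else if (all(d >= -tol) && (f[length(f)] - f[1]) > tol) "increasing"
  else if (all(d <= tol) && (f[1] - f[length(f)]) > tol) "decreasing"
  else "non-monotonic"
  list(parameter = attr(result, "parameter"), direction = direction,
       f_opt_range = range(f))
}

# Small deterministic polynomial hash of a configuration object, for
# provenance stamps in result files.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
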