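#' Crash-time scaling of the optimal propensity
#'
#' During buildup, uninfected bacteria grow as \eqn{e^{\gamma t}} and free
#' phage abundances grow double-exponentially with a rate set by their lytic
#' propensity. Maximizing the lysogens formed at the crash then makes the
#' optimal lysogeny propensity scale as \eqn{e^{-\gamma t^*}}, where
#' \eqn{t^*} is the crash onset time: the later the crash, the lower the
#' optimal propensity. The returned value is a proportionality (trend
#' predictor), not an absolute propensity.
#'
#' @param gamma bacterial growth rate (per hour).
#' @param t_star crash onset time (hours), e.g. from \code{\link{crashTime}}.
#' @return \code{exp(-gamma * t_star)}, an unnormalized scaling value.
#' @examples
#' foptScaling(1, 5)
#' @export
foptScaling <- function(gamma, t_star) {
  stopifnot(gamma > 0, t_star >= 0)
  exp(-gamma * t_star)
}

#' Closed-form approximation of the optimal lysogeny propensity
#'
#' Combines the buildup and crash arguments into an explicit formula, valid
#' when decisions are fast (large delta) so the crash is practically
#' instantaneous. During buildup the net phage multiplication per adsorption
#' cycle is \eqn{\beta(1-f) - 1}, so
#' \eqn{\ln(P_i(t)/P_i(0)) = (\beta(1-f_i)-1)\,\eta B_0(0)(e^{\gamma t}-1)/\gamma};
#' the crash starts when \eqn{P_{tot}(t^*) = \gamma/\eta}; and the winner is
#' the variant maximizing \eqn{f_i P_i(t^*)}. Eliminating \eqn{t^*} gives
#' \deqn{f_{opt} = \frac{1 - 1/\beta}{1 + \ln[\gamma/(\eta P_{tot}(0))]}.}
#' Neither the carrying capacity, the initial bacterial density nor the
#' decision rate appears, and the parameters that do appear enter only
#' logarithmically (except the burst size, whose effect is negligible once
#' \eqn{\beta > 10}) — which is why the optimum is so robust.
#'
#' By default \code{P0} is the per-variant inoculum and the total is
#' \eqn{P_{tot}(0) = 2 P_0} (the symmetric game); \code{p0_scope = "total"}
#' treats \code{P0} as the total instead.
#'
#' @param params a \code{\link{modelParams}} (uses \code{beta}, \code{gamma},
#'   \code{eta}).
#' @param P0 initial free-phage density.
#' @param p0_scope whether \code{P0} is per variant or the total.
#' @return A \code{"fopt_prediction"} list: \code{f_opt_formula},
#'   \code{valid} (FALSE when the log argument is <= 1, outside the formula's
#'   validity range), \code{t_star_used} (NA; the crash time is eliminated
#'   analytically), and the inputs echoed.
#' @examples
#' foptClosedForm(modelParams(), P0 = 1e-7)  # ~0.074 at the defaults
#' @export
foptClosedForm <- function(params = modelParams(), P0 = 1e-7,
                           p0_scope = c("per-variant", "total")) {
  p0_scope <- match.arg(p0_scope)
  stopifnot(P0 > 0)
  ptot0 <- if (p0_scope == "per-variant") 2 * P0 else P0
  larg <- params$gamma / (params$eta * ptot0)
  valid <- larg > 1
  f <- (1 - 1 / params$beta) / (1 + log(larg))
  structure(list(f_opt_formula = if (valid) f else NA_real_, valid = valid,
                 t_star_used = NA_real_,
                 inputs = list(beta = params$beta, gamma = params$gamma,
                               eta = params$eta, P0 = P0,
                               p0_scope = p0_scope)),
            class = "fopt_prediction")
}

#' @export
print.fopt_prediction <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Analytic optimal propensity: f_opt = %.4f\n",
                x$f_opt_formula))
  else
    cat("Analytic prediction invalid: parameters outside the formula's validity range\n")
  invisible(x)
}

#' Compare the closed-form prediction with simulated minimax optima
#'
#' Evaluates, for every row of a parameter grid, both the simulated
#' minimax-optimal propensity (\code{\link{findFopt}}) and the analytic
#' approximation (\code{\link{foptClosedForm}}), and tabulates their
#' difference. Summary statistics are reported separately for the fast
#' decision regime (\code{delta >= 100}), where the formula is expected to be
#' accurate, and for biologically reasonable decision rates, where the
#' neglected decision time contributes a systematic offset of about 0.03.
#'
#' @param param_grid data frame with columns among \code{gamma, eta, beta,
#'   delta, B0_0, P0}; missing columns take the default values.
#' @param resolution minimax grid resolution passed to \code{\link{findFopt}}.
#' @param ... passed to \code{\link{findFopt}}.
#' @return A data frame with one row per grid point (parameters,
#'   \code{f_opt_sim}, \code{f_opt_formula}, \code{delta_f}, \code{failed}),
#'   with a \code{summary} attribute splitting mean/max |delta_f| by
#'   decision-rate regime.
#' @examples
#' \donttest{
#' grid <- data.frame(delta = c(1, 100))
#' compareFormulaVsSimulation(grid, resolution = 0.01)
#' }
#' @export
compareFormulaVsSimulation <- function(param_grid, resolution = 0.01, ...) {
  defaults <- list(gamma = 1, eta = 20, beta = 100, delta = 1,
                   B0_0 = 1e-3, P0 = 1e-7)
  rows <- lapply(seq_len(nrow(param_grid)), function(r) {
    pv <- defaults
    for (nm in names(param_grid)) pv[[nm]] <- param_grid[[nm]][r]
    params <- modelParams(gamma = pv$gamma, eta = pv$eta, beta = pv$beta,
                          delta = pv$delta)
    init <- initialState(B0 = pv$B0_0, P1 = pv$P0, P2 = pv$P0)
    sim <- tryCatch(findFopt(params, init, resolution = resolution, ...),
                    error = function(e) NULL)
    form <- foptClosedForm(params, P0 = pv$P0)
    data.frame(gamma = pv$gamma, eta = pv$eta, beta = pv$beta,
               delta = pv$delta, B0_0 = pv$B0_0, P0 = pv$P0,
               f_opt_sim = if (is.null(sim)) NA_real_ else sim$f_opt,
               f_opt_formula = form$f_opt_formula,
               delta_f = if (is.null(sim)) NA_real_ else
                 sim$f_opt - form$f_opt_formula,
               failed = is.null(sim) || !form$valid)
  })
  out <- do.call(rbind, rows)
  fast <- out$delta >= 100 & !out$failed
  slow <- out$delta < 100 & !out$failed
  smry <- data.frame(
    regime = c("fast decisions (delta >= 100)", "biological delta"),
    n = c(sum(fast), sum(slow)),
    mean_abs = c(mean(abs(out$delta_f[fast])), mean(abs(out$delta_f[slow]))),
    max_abs = c(if (any(fast)) max(abs(out$delta_f[fast])) else NA_real_,
                if (any(slow)) max(abs(out$delta_f[slow])) else NA_real_))
  attr(out, "summary") <- smry
  out
}
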