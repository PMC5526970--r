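#' Model parameters for the phage-bacteria competition system
#'
#' Bundles the biological rate constants shared by the bacterial host and by
#' both phage variants. Populations are measured in units of the carrying
#' capacity (so \code{K = 1} by default) and time in units of the bacterial
#' division time; the infection rate constant then enters the dynamics only
#' through the product \eqn{K\eta}, which is what \code{eta} holds when
#' \code{K = 1}.
#'
#' @param gamma bacterial growth rate (per hour). Default 1.
#' @param K carrying capacity, the maximal sustainable total bacterial
#'   density. Default 1 (densities expressed as fractions of K).
#' @param eta infection (adsorption) rate constant, per density per hour;
#'   with \code{K = 1} this equals the composite parameter \eqn{K\eta}.
#'   Default 20.
#' @param beta burst size: phage particles released per lysed cell.
#'   Default 100.
#' @param delta decision rate (per hour) at which infected cells commit to
#'   lysis or lysogeny. Default 1.
#'
#' @return An object of class \code{"phage_params"}: a named list of the five
#'   rate constants.
#' @examples
#' modelParams()                    # the default parameter set
#' modelParams(beta = 50, delta = 2)
#' @export
modelParams <- function(gamma = 1, K = 1, eta = 20, beta = 100, delta = 1) {
  for (nm in c("gamma", "K", "eta", "beta", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (beta < 1)
    stop("'beta' must be >= 1 for lysis to produce phage", call. = FALSE)
  structure(list(gamma = gamma, K = K, eta = eta, beta = beta, delta = delta),
            class = "phage_params")
}

#' @export
print.phage_params <- function(x, ...) {
  cat("Phage-bacteria model parameters:\n")
  cat(sprintf("  gamma = %g /h   K = %g   K*eta = %g /h   beta = %g   delta = %g /h\n",
              x$gamma, x$K, x$K * x$eta, x$beta, x$delta))
  invisible(x)
}

#' Fixed lysogeny-propensity strategy
#'
#' A phage variant's genotype in the fixed-propensity model: the fraction
#' \code{f} of infected cells that become lysogens (the rest lyse).
#'
#' @param f lysogeny propensity, in \[0, 1\].
#' @return An object of class \code{"fixed_strategy"}.
#' @examples
#' fixedStrategy(0.1)
#' @export
fixedStrategy <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("'f' must be a single number in [0, 1]", call. = FALSE)
  structure(list(f = f), class = "fixed_strategy")
}

#' @export
print.fixed_strategy <- function(x, ...) {
  cat(sprintf("Fixed lysogeny propensity f = %g\n", x$f))
  invisible(x)
}

#' Multiplicity-of-infection dependent strategy
#'
#' A strategy for the MOI model: separate lysogeny propensities for cells
#' infected once, twice, or three or more times. The "switch" strategy of
#' counting phages is \code{moiStrategy(0, 1, 1)}: lyse on single infection,
#' lysogenize on multiple infection.
#'
#' @param f1 propensity at MOI = 1.
#' @param f2 propensity at MOI = 2.
#' @param f3 propensity at MOI >= 3.
#' @return An object of class \code{"moi_strategy"} holding the vector
#'   \code{f = c(f1, f2, f3)}.
#' @examples
#' moiStrategy(0, 1, 1)       # the switch strategy
#' moiStrategy(0.1, 0.1, 0.1) # flat: equivalent to a fixed propensity
#' @export
moiStrategy <- function(f1, f2, f3) {
  f <- c(f1, f2, f3)
  if (!is.numeric(f) || length(f) != 3L || anyNA(f) || any(f < 0) || any(f > 1))
    stop("propensities must be single numbers in [0, 1]", call. = FALSE)
  structure(list(f = as.numeric(f)), class = "moi_strategy")
}

#' @export
print.moi_strategy <- function(x, ...) {
  cat(sprintf("MOI-dependent strategy: f(1) = %g, f(2) = %g, f(>=3) = %g\n",
              x$f[1], x$f[2], x$f[3]))
  invisible(x)
}

#' Initial state of the competition
#'
#' Densities at time zero, in units of the carrying capacity. All compartments
#' other than uninfected bacteria and free phage start empty. The defaults are
#' a small bacterial inoculum well below carrying capacity invaded by a tiny,
#' equal amount of each phage variant (P_i(0) = 1e-4 * B0(0)).
#'
#' @param B0 initial uninfected bacterial density. Default 1e-3.
#' @param P1,P2 initial free-phage densities of variants 1 and 2.
#'   Default 1e-7 each.
#' @return An object of class \code{"initial_state"}.
#' @examples
#' initialState()
#' initialState(P1 = 1e-3, P2 = 1e-3)  # large phage inoculum
#' @export
initialState <- function(B0 = 1e-3, P1 = 1e-7, P2 = 1e-7) {
  v <- c(B0 = B0, P1 = P1, P2 = P2)
  if (!is.numeric(v) || anyNA(v) || any(v < 0))
    stop("initial densities must be non-negative numbers", call. = FALSE)
  structure(list(B0 = B0, P1 = P1, P2 = P2), class = "initial_state")
}

#' @export
print.initial_state <- function(x, ...) {
  cat(sprintf("Initial state: B0(0) = %g, P1(0) = %g, P2(0) = %g\n",
              x$B0, x$P1, x$P2))
  invisible(x)
}

# Coerce a strategy argument to a fixed or MOI strategy object.
as_fixed_strategy <- function(s) {
  if (inherits(s, "fixed_strategy")) return(s)
  if (is.numeric(s) && length(s) == 1L) return(fixedStrategy(s))
  stop("expected a fixedStrategy() or a single propensity in [0, 1]",
       call. = FALSE)
}

as_moi_strategy <- function(s) {
  if (inherits(s, "moi_strategy")) return(s)
  if (is.numeric(s) && length(s) == 3L)
    return(moiStrategy(s[1], s[2], s[3]))
  if (inherits(s, "fixed_strategy"))
    return(moiStrategy(s$f, s$f, s$f))
  stop("expected a moiStrategy() or a numeric vector of 3 propensities",
       call. = FALSE)
}
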