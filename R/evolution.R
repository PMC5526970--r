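#' Mutate an MOI-dependent strategy
#'
#' Applies the multiplicative mutation used in the iterated game: each
#' propensity is changed by up to 3\%,
#' \eqn{f(m) \to (1 + 0.01 r_m) f(m)} with \eqn{r_m} an integer drawn
#' uniformly from \{-3, ..., 3\}, independently per MOI class; results are
#' clipped to \[0, 1\]. A propensity of exactly 0 is a fixed point of the
#' mutation.
#'
#' Draws come from R's global RNG stream; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param s a \code{\link{moiStrategy}}.
#' @param r optional integer vector of length 3 in \{-3,...,3\} to use
#'   instead of random draws (deterministic mutation, mainly for testing).
#' @return A mutated \code{\link{moiStrategy}}.
#' @examples
#' set.seed(1)
#' mutateStrategy(moiStrategy(0.5, 0.5, 0.5))
#' mutateStrategy(moiStrategy(0.5, 0.5, 0.5), r = c(3, 0, -3))
#' @export
mutateStrategy <- function(s, r = NULL) {
  s <- as_moi_strategy(s)
  if (is.null(r)) r <- sample(-3:3, 3L, replace = TRUE)
  stopifnot(length(r) == 3L, all(r %in% -3:3))
  f <- pmin(1, pmax(0, s$f * (1 + 0.01 * r)))
  moiStrategy(f[1], f[2], f[3])
}

#' Compete two MOI strategies to steady state
#'
#' Integrates the MOI model with the two strategies at equal inocula until
#' steady state and declares the variant with more lysogens the winner. Ties
#' (|payoff| below \code{tie_tol}) go to the incumbent, the first argument: a
#' challenger must strictly win to invade.
#'
#' @param s1,s2 \code{\link{moiStrategy}} objects (or length-3 vectors);
#'   \code{s1} is the incumbent.
#' @param params a \code{\link{modelParams}}.
#' @param init an \code{\link{initialState}}.
#' @param tie_tol payoff magnitude below which the game is a tie.
#' @param ... passed to \code{\link{runToSteadyState}}.
#' @return A list: \code{winner} (1 or 2), \code{payoff} (for player 1),
#'   \code{converged}.
#' @examples
#' competeStrategies(moiStrategy(0, 1, 1), moiStrategy(0.5, 0.5, 0.5),
#'                   modelParams())
#' @export
competeStrategies <- function(s1, s2, params = modelParams(),
                              init = initialState(), tie_tol = 1e-10, ...) {
  s1 <- as_moi_strategy(s1); s2 <- as_moi_strategy(s2)
  ss <- runToSteadyState("moi", params, strategies = list(s1, s2),
                         init = init, ...)
  if (!ss$converged)
    return(list(winner = NA_integer_, payoff = NA_real_, converged = FALSE))
  pay <- payoffScore(ss$L1, ss$L2)
  winner <- if (abs(pay) < tie_tol) 1L else if (pay > 0) 1L else 2L
  list(winner = winner, payoff = pay, converged = TRUE)
}

#' Iterated evolutionary game over MOI strategies
#'
#' Exhaustive payoff matrices are impractical over three-component
#' strategies, so the optimum is found by an iterated game: two random
#' strategies compete to steady state; the winner keeps its strategy and the
#' loser is replaced by a mutated copy of the winner
#' (\code{\link{mutateStrategy}}); repeat until the winning strategy stops
#' changing. At the defaults the winner converges to the switch strategy
#' (lyse at MOI 1, lysogenize at MOI >= 2).
#'
#' Convergence is declared when the winner's strategy vector has varied by
#' less than \code{conv_tol} in max-norm over the last \code{conv_window}
#' iterations. The window must be generous: components near zero move
#' multiplicatively slowly (a 3\% step of a propensity of 0.03 is under
#' 0.001), so short windows mistake a slow escape from zero for stasis. Even
#' with a long window the game occasionally settles on an alternative
#' switch-like strategy with f(1) and f(2) both near zero and f(3) near 1 —
#' a metastable outcome that loses a direct pairwise game against the
#' (0, 1, 1) switch strategy but is invaded only through weakly selected
#' mutations. A competition that fails to reach steady state is logged and
#' the mutation redrawn rather than aborting the run.
#'
#' @param params a \code{\link{modelParams}}.
#' @param init an \code{\link{initialState}}.
#' @param seed integer seed driving both the random initial strategies and
#'   all mutation draws; recorded in the trace. \code{NULL} uses the current
#'   RNG state.
#' @param max_iter iteration cap.
#' @param conv_window,conv_tol convergence rule (see Details).
#' @param ... passed to \code{\link{competeStrategies}}.
#' @return A \code{"phage_evolution_trace"}: data frame with one row per
#'   iteration (winner and loser propensities, payoff, winner index) plus
#'   attributes \code{seed}, \code{converged_at} (\code{NA} if the cap was
#'   hit) and \code{final} (the winning \code{\link{moiStrategy}}).
#' @examples
#' \donttest{
#' tr <- evolveStrategies(modelParams(), seed = 1)
#' attr(tr, "final")
#' }
#' @export
evolveStrategies <- function(params = modelParams(), init = initialState(),
                             seed = NULL, max_iter = 3000,
                             conv_window = 300, conv_tol = 0.005, ...) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- moiStrategy(stats::runif(1), stats::runif(1), stats::runif(1))
  s2 <- moiStrategy(stats::runif(1), stats::runif(1), stats::runif(1))
  win_mat <- matrix(NA_real_, max_iter, 3)
  rec <- vector("list", max_iter)
  converged_at <- NA_integer_
  winner <- s1
  for (k in seq_len(max_iter)) {
    res <- competeStrategies(s1, s2, params, init, ...)
    if (!res$converged) {
      warning("competition did not reach steady state at iteration ", k,
              "; redrawing mutation", call. = FALSE)
      s2 <- mutateStrategy(winner)
      next
    }
    winner <- if (res$winner == 1L) s1 else s2
    loser <- if (res$winner == 1L) s2 else s1
    win_mat[k, ] <- winner$f
    rec[[k]] <- c(iter = k, w = winner$f, l = loser$f,
                  payoff = res$payoff, winner = res$winner)
    if (k >= conv_window + 1L) {
      window <- win_mat[(k - conv_window):k, , drop = FALSE]
      if (!anyNA(window) &&
          max(apply(window, 2, function(col) diff(range(col)))) < conv_tol) {
        converged_at <- k
        break
      }
    }
    s1 <- winner
    s2 <- mutateStrategy(winner)
  }
  rec <- rec[!vapply(rec, is.null, logical(1))]
  df <- as.data.frame(do.call(rbind, rec))
  names(df) <- c("iter", "f1_winner", "f2_winner", "f3_winner",
                 "f1_loser", "f2_loser", "f3_loser", "payoff", "winner")
  structure(df, class = c("phage_evolution_trace", "data.frame"),
            seed = if (is.null(seed)) NA_integer_ else seed,
            converged_at = converged_at,
            final = winner, params = params, init = init)
}

#' @export
print.phage_evolution_trace <- function(x, ...) {
  if (is.null(attr(x, "final"))) {  # subset rows lose the trace attributes
    print(as.data.frame(x))
    return(invisible(x))
  }
  fin <- attr(x, "final")
  ca <- attr(x, "converged_at")
  cat(sprintf("Evolutionary game trace: %d iterations, %s\n", nrow(x),
              if (is.na(ca)) "not converged" else
                sprintf("converged at iteration %d", ca)))
  cat(sprintf("  final winner: f(1) = %.3f, f(2) = %.3f, f(>=3) = %.3f\n",
              fin$f[1], fin$f[2], fin$f[3]))
  invisible(x)
}

#' First-crossing iterations of the winning strategy components
#'
#' Summarises the selection-pressure ordering seen in evolution traces: the
#' iteration at which the winner's f(1) first drops below \code{lo}, and at
#' which f(2) and f(3) first exceed \code{hi}. At the default parameters the
#' typical order is f(1) first, then f(3), then f(2).
#'
#' @param trace a \code{"phage_evolution_trace"}.
#' @param lo,hi thresholds for "near 0" and "near 1".
#' @return Named numeric vector \code{c(f1_low, f3_high, f2_high)} of
#'   iteration indices (\code{NA} if never crossed).
#' @export
convergenceOrder <- function(trace, lo = 0.05, hi = 0.95) {
  stopifnot(inherits(trace, "phage_evolution_trace"))
  first <- function(x) if (any(x)) trace$iter[which(x)[1L]] else NA_real_
  c(f1_low = first(trace$f1_winner < lo),
    f3_high = first(trace$f3_winner > hi),
    f2_high = first(trace$f2_winner > hi))
}
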