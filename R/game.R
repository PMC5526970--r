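#' Steady-state payoff for phage variant 1
#'
#' The score of the zero-sum game: variant 1's share advantage in the final
#' lysogen population, \eqn{(L_1 - L_2)/(L_1 + L_2)}. It is +1 when variant 1
#' completely dominates, -1 when variant 2 does, and 0 for a draw. When no
#' lysogens form at all (both variants fail identically) the game is scored
#' as a draw.
#'
#' @param L1,L2 final lysogen densities of variants 1 and 2 (non-negative).
#' @return A number in \[-1, 1\].
#' @examples
#' payoffScore(0.6, 0.4)  # 0.2
#' payoffScore(1, 0)      # +1
#' @export
payoffScore <- function(L1, L2) {
  if (any(c(L1, L2) < 0)) stop("lysogen densities must be non-negative",
                               call. = FALSE)
  tot <- L1 + L2
  ifelse(tot == 0, 0, (L1 - L2) / tot)
}

#' Payoff matrix over a grid of fixed lysogeny propensities
#'
#' Plays every strategy on the grid against every other: entry (i, j) is the
#' steady-state payoff to player 1 using propensity \code{f_grid[i]} against
#' player 2 using \code{f_grid[j]}, with equal inocula. Because the two
#' variants obey identical equations the game is zero-sum and the matrix
#' antisymmetric, so by default only the upper triangle is simulated and the
#' lower is filled by antisymmetry (the diagonal is exactly 0 by symmetry of
#' the dynamics); \code{both_triangles = TRUE} simulates every off-diagonal
#' entry independently, which is used to validate the antisymmetry.
#'
#' @param params a \code{\link{modelParams}}.
#' @param init an \code{\link{initialState}} (equal \code{P1}, \code{P2}
#'   expected for a symmetric game).
#' @param f_grid ordered vector of propensities in \[0, 1\].
#' @param both_triangles simulate both triangles independently.
#' @param ... passed to \code{\link{runToSteadyState}}.
#' @return A \code{"phage_payoff_matrix"}: list with \code{f_grid}, matrix
#'   \code{M}, logical matrix \code{converged}, and metadata (\code{params},
#'   \code{init}, \code{mirrored}). Non-converged entries are \code{NA}.
#' @examples
#' pm <- buildPayoffMatrix(modelParams(), f_grid = c(0, 0.1, 0.2))
#' pm$M
#' @export
buildPayoffMatrix <- function(params = modelParams(), init = initialState(),
                              f_grid = seq(0, 1, by = 0.01),
                              both_triangles = FALSE, ...) {
  stopifnot(all(f_grid >= 0 & f_grid <= 1), !is.unsorted(f_grid))
  n <- length(f_grid)
  M <- matrix(0, n, n, dimnames = list(f1 = f_grid, f2 = f_grid))
  conv <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    jset <- if (both_triangles) setdiff(seq_len(n), i) else seq_len(n)[-seq_len(i)]
    for (j in jset) {
      ss <- runToSteadyState("fixed", params,
                             strategies = list(f_grid[i], f_grid[j]),
                             init = init, ...)
      conv[i, j] <- ss$converged
      M[i, j] <- if (ss$converged) payoffScore(ss$L1, ss$L2) else NA_real_
      if (!both_triangles) {
        M[j, i] <- -M[i, j]
        conv[j, i] <- conv[i, j]
      }
    }
  }
  structure(list(f_grid = f_grid, M = M, converged = conv,
                 params = params, init = init,
                 mirrored = !both_triangles),
            class = "phage_payoff_matrix")
}

#' @export
print.phage_payoff_matrix <- function(x, ...) {
  cat(sprintf("Payoff matrix on %d x %d propensity grid [%g, %g]%s\n",
              length(x$f_grid), length(x$f_grid), min(x$f_grid),
              max(x$f_grid),
              if (x$mirrored) " (lower triangle filled by antisymmetry)" else ""))
  if (!all(x$converged))
    cat(sprintf("  %d entries did not converge (NA)\n", sum(!x$converged)))
  invisible(x)
}

#' Minimax (saddle-point) solution of a payoff matrix
#'
#' For each strategy player 2 could play (a column), player 1 can secure at
#' most the column maximum; player 2 therefore plays the column minimizing
#' that maximum. In this symmetric zero-sum game the solution, when unique,
#' is a pure saddle point: an entry that is simultaneously the maximum of its
#' column and the minimum of its row. All grid cells satisfying the saddle
#' condition within tolerance are reported.
#'
#' @param pm a \code{"phage_payoff_matrix"}, or a plain numeric matrix (the
#'   grid then defaults to column indices).
#' @param tol absolute tolerance for payoff comparisons.
#' @return A \code{"minimax_solution"} list: \code{f_opt}, \code{game_value},
#'   \code{unique}, \code{saddle_exists}, \code{saddles} (data frame of all
#'   saddle cells), \code{minimax} and \code{maximin} values.
#' @examples
#' m <- matrix(c(0, 1, -1, 0), 2, 2)  # strategy 1 dominates
#' minimaxSolution(m)
#' @export
minimaxSolution <- function(pm, tol = 1e-8) {
  if (is.matrix(pm)) pm <- list(f_grid = seq_len(ncol(pm)), M = pm)
  M <- pm$M
  if (anyNA(M)) stop("payoff matrix has missing (non-converged) entries",
                     call. = FALSE)
  col_max <- apply(M, 2, max)
  row_min <- apply(M, 1, min)
  v_minimax <- min(col_max)
  v_maximin <- max(row_min)
  saddle_exists <- (v_minimax - v_maximin) <= tol
  # saddle cells: column max and row min simultaneously (within tol)
  is_saddle <- which(outer(seq_len(nrow(M)), seq_len(ncol(M)), function(i, j) {
    Mij <- M[cbind(i, j)]
    (Mij >= col_max[j] - tol) & (Mij <= row_min[i] + tol)
  }), arr.ind = TRUE)
  saddles <- data.frame(i = is_saddle[, 1], j = is_saddle[, 2],
                        f1 = pm$f_grid[is_saddle[, 1]],
                        f2 = pm$f_grid[is_saddle[, 2]],
                        payoff = M[is_saddle])
  j_star <- which.min(col_max)
  uniq <- saddle_exists && nrow(saddles) == 1L
  f_opt <- if (nrow(saddles) >= 1L) {
    # midpoint of the tie set of player-2 saddle strategies
    mean(range(saddles$f2))
  } else pm$f_grid[j_star]
  structure(list(f_opt = f_opt, game_value = v_minimax, unique = uniq,
                 saddle_exists = saddle_exists, saddles = saddles,
                 minimax = v_minimax, maximin = v_maximin),
            class = "minimax_solution")
}

#' @export
print.minimax_solution <- function(x, ...) {
  if (!x$saddle_exists) {
    cat(sprintf("No pure-strategy saddle: minimax = %g != maximin = %g\n",
                x$minimax, x$maximin))
  } else {
    cat(sprintf("Minimax solution: f_opt = %g (game value %g, %s)\n",
                x$f_opt, x$game_value,
                if (x$unique) "unique saddle" else
                  sprintf("%d tied saddle cells", nrow(x$saddles))))
  }
  invisible(x)
}

#' Optimal lysogeny propensity by coarse-to-fine minimax
#'
#' Finds the minimax-optimal propensity: builds a payoff matrix on a coarse
#' grid over \[0, 1\], locates the saddle, then rebuilds at the requested
#' resolution on a window around it. When the saddle is unique this equals
#' the minimax of the full fine grid at a fraction of the cost.
#'
#' @param params a \code{\link{modelParams}}.
#' @param init an \code{\link{initialState}}.
#' @param resolution target grid step (>= 0.001).
#' @param coarse_step step of the first-pass grid.
#' @param ... passed to \code{\link{runToSteadyState}}.
#' @return A \code{"fopt_result"} list: \code{f_opt}, \code{unique},
#'   \code{coarse} and \code{fine} minimax solutions, and the fine
#'   \code{"phage_payoff_matrix"}.
#' @examples
#' \donttest{
#' findFopt(modelParams(), resolution = 0.01)$f_opt  # ~0.10 at the defaults
#' }
#' @export
findFopt <- function(params = modelParams(), init = initialState(),
                     resolution = 0.01, coarse_step = 0.05, ...) {
  stopifnot(resolution >= 0.001, coarse_step >= resolution)
  coarse_grid <- seq(0, 1, by = coarse_step)
  pm0 <- buildPayoffMatrix(params, init, coarse_grid, ...)
  mm0 <- minimaxSolution(pm0)
  if (coarse_step == resolution) {
    return(structure(list(f_opt = mm0$f_opt, unique = mm0$unique,
                          coarse = mm0, fine = mm0, payoff_matrix = pm0),
                     class = "fopt_result"))
  }
  lo <- max(0, mm0$f_opt - coarse_step)
  hi <- min(1, mm0$f_opt + coarse_step)
  fine_grid <- seq(lo, hi, by = resolution)
  pm1 <- buildPayoffMatrix(params, init, fine_grid, ...)
  mm1 <- minimaxSolution(pm1)
  structure(list(f_opt = mm1$f_opt, unique = mm1$unique,
                 coarse = mm0, fine = mm1, payoff_matrix = pm1),
            class = "fopt_result")
}

#' @export
print.fopt_result <- function(x, ...) {
  cat(sprintf("Optimal lysogeny propensity f_opt = %g (%s)\n", x$f_opt,
              if (x$unique) "unique saddle" else "tied/degenerate saddle"))
  invisible(x)
}
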