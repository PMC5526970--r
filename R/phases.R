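#' Detect the three dynamical phases of a phage invasion
#'
#' The invasion of a growing bacterial population by a small phage inoculum
#' passes through three phases: \emph{buildup} (bacteria and phage grow,
#' phage faster), the \emph{crash} (phage infect almost all uninfected
#' bacteria within about a generation), and \emph{lysogenic growth} (lysogens
#' regrow to carrying capacity). The buildup ends, and the crash begins, when
#' the uninfected population peaks; the crash ends when uninfected bacteria
#' have become much smaller than the lysogen population.
#'
#' @param traj a \code{"phage_trajectory"} from \code{\link{integrateDynamics}}.
#' @param crash_end_frac the crash is over when
#'   \code{B0 < crash_end_frac * (L1 + L2)}; "much smaller" is quantified as
#'   1\% by default.
#' @return A list with \code{t_buildup_end}, \code{t_crash_end} and
#'   \code{crash_detected}. When no phage-driven collapse occurs (e.g. no
#'   phage present) \code{crash_detected} is \code{FALSE} and the times are
#'   \code{NA}.
#' @examples
#' traj <- integrateDynamics("fixed", modelParams(),
#'                           strategies = list(0.25, 0.29), t_end = 30)
#' detectPhases(traj)
#' @export
detectPhases <- function(traj, crash_end_frac = 0.01) {
  stopifnot(inherits(traj, "phage_trajectory"))
  B0 <- traj$B0
  L <- traj$L1 + traj$L2
  ipk <- which.max(B0)
  no_crash <- list(t_buildup_end = NA_real_, t_crash_end = NA_real_,
                   crash_detected = FALSE)
  # A peak on the boundary means B0 never collapsed within the trajectory.
  if (ipk == 1L || ipk == nrow(traj)) return(no_crash)
  after <- seq(ipk, nrow(traj))
  below <- after[B0[after] < crash_end_frac * L[after]]
  if (length(below) == 0L) return(no_crash)
  list(t_buildup_end = traj$t[ipk], t_crash_end = traj$t[below[1L]],
       crash_detected = TRUE)
}

#' Crash onset time from the phage threshold
#'
#' The crash starts when the total free phage density makes the infection
#' rate of uninfected bacteria equal to their growth rate, i.e. when
#' \eqn{P_{tot}(t^*) = \gamma/\eta}. This locates the first upward crossing
#' of that threshold by linear interpolation on the dense trajectory.
#'
#' @param traj a \code{"phage_trajectory"}.
#' @param params the \code{\link{modelParams}} used for the run; defaults to
#'   the ones stored in the trajectory.
#' @return A list with \code{t_star} (hours) and \code{crossed}
#'   (\code{FALSE}, with \code{t_star = NA}, if the threshold is never
#'   reached).
#' @examples
#' traj <- integrateDynamics("fixed", modelParams(),
#'                           strategies = list(0.1, 0.1), t_end = 30)
#' crashTime(traj)
#' @export
crashTime <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "phage_trajectory"))
  thr <- params$gamma / params$eta
  ptot <- traj$P1 + traj$P2
  above <- which(ptot >= thr)
  if (length(above) == 0L)
    return(list(t_star = NA_real_, crossed = FALSE))
  i <- above[1L]
  if (i == 1L)
    return(list(t_star = traj$t[1L], crossed = TRUE))
  # linear interpolation between the bracketing output points
  t0 <- traj$t[i - 1L]; t1 <- traj$t[i]
  p0 <- ptot[i - 1L]; p1 <- ptot[i]
  list(t_star = t0 + (thr - p0) / (p1 - p0) * (t1 - t0), crossed = TRUE)
}
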