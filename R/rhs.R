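#' Time derivatives of the fixed-propensity competition model
#'
#' Evaluates the right-hand side of the seven-compartment ODE system for two
#' phage variants with fixed lysogeny propensities competing on one host:
#' uninfected bacteria B0, infected bacteria B1/B2, lysogens L1/L2 and free
#' phage P1/P2. Uninfected and infected bacteria and lysogens grow
#' logistically toward the carrying capacity; infection is mass-action in
#' phage and host density; infected cells commit at rate delta, a fraction
#' f_i to lysogeny and the rest to lysis with burst size beta; free phage are
#' lost by adsorption to any bacterium.
#'
#' The signature follows \code{deSolve} conventions so the function can be
#' passed directly to \code{\link[deSolve]{ode}}, but the packaged integrator
#' (\code{\link{integrateDynamics}}) uses an equivalent compiled version; this
#' R implementation is the readable reference and is cross-checked against the
#' compiled one in the test suite.
#'
#' @param t time (unused; the system is autonomous).
#' @param state named numeric vector with components
#'   \code{B0, B1, B2, L1, L2, P1, P2}, all non-negative.
#' @param parms list with elements \code{params} (a
#'   \code{\link{modelParams}}), \code{f1} and \code{f2} (propensities).
#' @return A list whose first element is the vector of derivatives, in the
#'   order of \code{state}.
#' @examples
#' p <- modelParams()
#' y <- c(B0 = 5e-1, B1 = 0, B2 = 0, L1 = 0, L2 = 0, P1 = 0, P2 = 0)
#' phageRhsFixed(0, y, list(params = p, f1 = 0.1, f2 = 0.1))
#' @export
phageRhsFixed <- function(t, state, parms) {
  if (any(state < 0))
    stop("state components must be non-negative", call. = FALSE)
  p <- parms$params
  f1 <- parms$f1; f2 <- parms$f2
  B0 <- state[["B0"]]; B1 <- state[["B1"]]; B2 <- state[["B2"]]
  L1 <- state[["L1"]]; L2 <- state[["L2"]]
  P1 <- state[["P1"]]; P2 <- state[["P2"]]
  Btot <- B0 + B1 + B2 + L1 + L2
  Ptot <- P1 + P2
  g <- p$gamma * (1 - Btot / p$K)
  list(c(
    B0 = g * B0 - p$eta * Ptot * B0,
    B1 = g * B1 + p$eta * P1 * B0 - p$delta * B1,
    B2 = g * B2 + p$eta * P2 * B0 - p$delta * B2,
    L1 = g * L1 + f1 * p$delta * B1,
    L2 = g * L2 + f2 * p$delta * B2,
    P1 = p$beta * (1 - f1) * p$delta * B1 - p$eta * P1 * Btot,
    P2 = p$beta * (1 - f2) * p$delta * B2 - p$eta * P2 * Btot
  ))
}

#' Time derivatives of the MOI-dependent competition model
#'
#' Right-hand side of the eleven-compartment system in which bacteria
#' infected by variant i are tracked by their multiplicity of infection
#' (MOI), truncated at 3: \code{Bi_1, Bi_2, Bi_3}. Re-adsorption of a phage
#' of the same variant moves a cell up one MOI class; the top class receives
#' inflow but has no adsorption outflow (truncation). Decisions occur at rate
#' delta in every MOI class, with class-specific lysogeny propensities
#' \code{f(m)}. Infected compartments carry no logistic growth term. Free
#' phage adsorbing to any bacterium (including top-class cells and lysogens)
#' are lost through the \code{-eta * Pi * Btot} sink.
#'
#' @param t time (unused).
#' @param state named numeric vector with components \code{B0, B1_1, B1_2,
#'   B1_3, B2_1, B2_2, B2_3, L1, L2, P1, P2}, all non-negative.
#' @param parms list with elements \code{params} (a
#'   \code{\link{modelParams}}) and \code{s1}, \code{s2}
#'   (\code{\link{moiStrategy}} objects).
#' @return A list whose first element is the vector of derivatives.
#' @examples
#' p <- modelParams()
#' y <- c(B0 = 0, B1_1 = 0.1, B1_2 = 0, B1_3 = 0,
#'        B2_1 = 0, B2_2 = 0, B2_3 = 0, L1 = 0, L2 = 0, P1 = 0, P2 = 0)
#' phageRhsMoi(0, y, list(params = p, s1 = moiStrategy(0, 1, 1),
#'                        s2 = moiStrategy(0.1, 0.1, 0.1)))
#' @export
phageRhsMoi <- function(t, state, parms) {
  if (any(state < 0))
    stop("state components must be non-negative", call. = FALSE)
  p <- parms$params
  f1 <- parms$s1$f; f2 <- parms$s2$f
  B0 <- state[["B0"]]
  B11 <- state[["B1_1"]]; B12 <- state[["B1_2"]]; B13 <- state[["B1_3"]]
  B21 <- state[["B2_1"]]; B22 <- state[["B2_2"]]; B23 <- state[["B2_3"]]
  L1 <- state[["L1"]]; L2 <- state[["L2"]]
  P1 <- state[["P1"]]; P2 <- state[["P2"]]
  Btot <- B0 + B11 + B12 + B13 + B21 + B22 + B23 + L1 + L2
  Ptot <- P1 + P2
  g <- p$gamma * (1 - Btot / p$K)
  eta <- p$eta; delta <- p$delta
  list(c(
    B0   = g * B0 - eta * Ptot * B0,
    B1_1 = eta * P1 * B0 - eta * P1 * B11 - delta * B11,
    B1_2 = eta * P1 * B11 - eta * P1 * B12 - delta * B12,
    B1_3 = eta * P1 * B12 - delta * B13,
    B2_1 = eta * P2 * B0 - eta * P2 * B21 - delta * B21,
    B2_2 = eta * P2 * B21 - eta * P2 * B22 - delta * B22,
    B2_3 = eta * P2 * B22 - delta * B23,
    L1   = g * L1 + delta * sum(f1 * c(B11, B12, B13)),
    L2   = g * L2 + delta * sum(f2 * c(B21, B22, B23)),
    P1   = p$beta * delta * sum((1 - f1) * c(B11, B12, B13)) - eta * P1 * Btot,
    P2   = p$beta * delta * sum((1 - f2) * c(B21, B22, B23)) - eta * P2 * Btot
  ))
}
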