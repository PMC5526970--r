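state_names_fixed <- c("B0", "B1", "B2", "L1", "L2", "P1", "P2")
state_names_moi   <- c("B0", "B1_1", "B1_2", "B1_3", "B2_1", "B2_2", "B2_3",
                       "L1", "L2", "P1", "P2")

initial_vector <- function(model, init) {
  if (model == "fixed") {
    y <- c(init$B0, 0, 0, 0, 0, init$P1, init$P2)
    names(y) <- state_names_fixed
  } else {
    y <- c(init$B0, rep(0, 6), 0, 0, init$P1, init$P2)
    names(y) <- state_names_moi
  }
  y
}

# Normalise the strategies argument into compiled-parameter vector + R parms.
strategy_parms <- function(model, params, strategies) {
  base <- c(params$gamma, params$K, params$eta, params$beta, params$delta)
  if (model == "fixed") {
    s1 <- as_fixed_strategy(strategies[[1]])
    s2 <- as_fixed_strategy(strategies[[2]])
    list(cparms = c(base, s1$f, s2$f),
         rparms = list(params = params, f1 = s1$f, f2 = s2$f),
         s1 = s1, s2 = s2)
  } else {
    s1 <- as_moi_strategy(strategies[[1]])
    s2 <- as_moi_strategy(strategies[[2]])
    list(cparms = c(base, s1$f, s2$f),
         rparms = list(params = params, s1 = s1, s2 = s2),
         s1 = s1, s2 = s2)
  }
}

#' Integrate the competition dynamics
#'
#' Solves the fixed-propensity or MOI-dependent ODE system with a
#' stiff-capable integrator (\code{deSolve}'s \code{lsoda}) and returns a
#' dense trajectory. The dynamics span densities from ~1e-9 up to the
#' carrying capacity and the crash phase is fast, so tight tolerances are the
#' default (\code{rtol = 1e-8}, \code{atol = 1e-12}). Tiny solver-induced
#' negative densities are clipped to zero in the returned table (the
#' integration itself is not altered).
#'
#' @param model \code{"fixed"} or \code{"moi"}.
#' @param params a \code{\link{modelParams}} object.
#' @param strategies list of two strategies: propensities /
#'   \code{\link{fixedStrategy}} objects for the fixed model,
#'   \code{\link{moiStrategy}} objects (or length-3 vectors) for the MOI
#'   model.
#' @param init a \code{\link{initialState}}.
#' @param t_end integration horizon (hours), > 0.
#' @param n_out number of equally spaced output times (dense output).
#' @param rtol,atol solver tolerances.
#' @param compiled use the compiled C right-hand side (default) or the R one.
#' @param y0 optional full named initial state vector overriding \code{init}
#'   (used internally to continue integrations).
#' @return A \code{"phage_trajectory"}: a data frame with column \code{t} and
#'   one column per compartment, plus attributes \code{model}, \code{params},
#'   \code{strategies}.
#' @examples
#' traj <- integrateDynamics("fixed", modelParams(),
#'                           strategies = list(0.25, 0.29), t_end = 20)
#' head(traj)
#' @export
integrateDynamics <- function(model = c("fixed", "moi"), params = modelParams(),
                              strategies, init = initialState(), t_end = 100,
                              n_out = 2001, rtol = 1e-8, atol = 1e-12,
                              compiled = TRUE, y0 = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "phage_params"), t_end > 0, n_out >= 2)
  sp <- strategy_parms(model, params, strategies)
  y <- if (is.null(y0)) initial_vector(model, init) else y0
  times <- seq(0, t_end, length.out = n_out)
  if (compiled) {
    out <- deSolve::ode(y, times, func = paste0("phg_derivs_", model),
                        parms = sp$cparms, dllname = "phagegame",
                        initfunc = paste0("phg_init_", model),
                        rtol = rtol, atol = atol, method = "lsoda")
  } else {
    func <- if (model == "fixed") phageRhsFixed else phageRhsMoi
    # The R rhs rejects negative states; tolerate solver exploration below 0.
    safe <- function(t, yy, pp) func(t, pmax(yy, 0), pp)
    out <- deSolve::ode(y, times, func = safe, parms = sp$rparms,
                        rtol = rtol, atol = atol, method = "lsoda")
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0)
    stop("ODE solver failed (istate = ", istate,
         "); last time reached t = ", max(out[, 1]),
         ". Consider loosening tolerances or shortening t_end.",
         call. = FALSE)
  df <- as.data.frame(out)
  names(df)[1] <- "t"
  df[-1] <- lapply(df[-1], function(col) pmax(col, 0))
  structure(df, class = c("phage_trajectory", "data.frame"),
            model = model, params = params,
            strategies = list(sp$s1, sp$s2))
}

#' @export
print.phage_trajectory <- function(x, ...) {
  cat(sprintf("Phage competition trajectory (%s model): %d time points, t in [%g, %g]\n",
              attr(x, "model"), nrow(x), min(x$t), max(x$t)))
  cat("Final densities:\n")
  print(unlist(x[nrow(x), -1]))
  invisible(x)
}

# Evaluate the rhs at one state using the R reference implementation.
rhs_at <- function(model, params, strategies, state) {
  sp <- strategy_parms(model, params, strategies)
  func <- if (model == "fixed") phageRhsFixed else phageRhsMoi
  func(0, pmax(state, 0), sp$rparms)[[1]]
}

#' Run the dynamics to steady state
#'
#' Integrates in windows of doubling length until the system is stationary:
#' the maximum absolute time derivative falls below \code{deriv_tol} and the
#' total free-phage density below \code{p_tol}. At convergence the survivors
#' are the lysogens and possibly uninfected bacteria; all free phage and
#' transiently infected compartments have decayed.
#'
#' @inheritParams integrateDynamics
#' @param window0 length (hours) of the first integration window; windows
#'   double thereafter.
#' @param t_max give up (converged = FALSE) beyond this total time.
#' @param deriv_tol stationarity threshold on max |dX/dt|.
#' @param p_tol threshold on total free phage density.
#' @return A \code{"phage_steady_state"} list: \code{L1}, \code{L2},
#'   \code{B0_final}, \code{t_end}, \code{converged}, and the full final
#'   \code{state} (clipped at 0).
#' @examples
#' ss <- runToSteadyState("fixed", modelParams(), strategies = list(0.25, 0.29))
#' ss$converged
#' ss$L1 + ss$L2   # lysogens fill the carrying capacity
#' @export
runToSteadyState <- function(model = c("fixed", "moi"), params = modelParams(),
                             strategies, init = initialState(),
                             window0 = 100, t_max = 1e5,
                             deriv_tol = 1e-10, p_tol = 1e-12,
                             rtol = 1e-8, atol = 1e-12, compiled = TRUE) {
  model <- match.arg(model)
  y <- initial_vector(model, init)
  t_acc <- 0
  w <- window0
  converged <- FALSE
  while (t_acc < t_max) {
    w <- min(w, t_max - t_acc)
    traj <- integrateDynamics(model, params, strategies, init,
                              t_end = w, n_out = 101, rtol = rtol, atol = atol,
                              compiled = compiled, y0 = y)
    y <- unlist(traj[nrow(traj), -1])
    t_acc <- t_acc + w
    dy <- rhs_at(model, params, strategies, y)
    ptot <- y[["P1"]] + y[["P2"]]
    if (max(abs(dy)) < deriv_tol && ptot < p_tol) {
      converged <- TRUE
      break
    }
    w <- 2 * w
  }
  y <- pmax(y, 0)
  structure(list(L1 = y[["L1"]], L2 = y[["L2"]], B0_final = y[["B0"]],
                 t_end = t_acc, converged = converged, state = y,
                 model = model),
            class = "phage_steady_state")
}

#' @export
print.phage_steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s model) at t = %g: %s\n", x$model, x$t_end,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  L1 = %g, L2 = %g, B0 = %g\n", x$L1, x$L2, x$B0_final))
  invisible(x)
}
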