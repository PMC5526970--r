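# Shared fixtures, computed lazily and cached across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

default_params <- function() modelParams()

# Minimax at the default parameter set, 0.01 resolution.
default_fopt <- function() {
  cached("fopt_default", findFopt(modelParams(), resolution = 0.01))
}

# Invasion trajectory at the default parameters (dense output).
invasion_traj <- function() {
  cached("invasion_traj",
         integrateDynamics("fixed", modelParams(),
                           strategies = list(0.25, 0.29),
                           t_end = 60, n_out = 6001))
}

# Evolutionary game traces for five fixed seeds.
evolution_traces <- function() {
  cached("evolution_traces",
         lapply(1:5, function(s) evolveStrategies(seed = s)))
}

# Burst-size sweep over the biological range.
beta_sweep <- function() {
  cached("beta_sweep",
         runSweep(sweepSpec("beta", n = 5, preset = "biological"),
                  resolution = 0.01))
}

# Brute-force saddle enumeration: every cell that is simultaneously a column
# maximum and a row minimum (within tol). Independent of minimaxSolution().
brute_force_saddles <- function(M, tol = 1e-8) {
  out <- NULL
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      if (M[i, j] >= max(M[, j]) - tol && M[i, j] <= min(M[i, ]) + tol)
        out <- rbind(out, c(i = i, j = j))
    }
  }
  out
}

# Random antisymmetric matrix with zero diagonal.
random_antisym <- function(n) {
  A <- matrix(stats::rnorm(n * n), n, n)
  M <- A - t(A)
  diag(M) <- 0
  M
}
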