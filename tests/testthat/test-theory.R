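test_that("crash-time scaling is the exponential of the buildup duration", {
  expect_equal(foptScaling(1, 0), 1)
  expect_equal(foptScaling(1, 10), foptScaling(1, 5)^2)
  expect_equal(foptScaling(2, 3), exp(-6))
})

test_that("closed form depends only on beta, gamma, eta and P(0)", {
  p <- modelParams()
  base <- foptClosedForm(p, 1e-7)$f_opt_formula
  # initial bacterial density and decision rate are absent from the formula
  expect_identical(foptClosedForm(modelParams(delta = 100), 1e-7)$f_opt_formula,
                   base)
  # burst size has little effect once above ~10
  f20 <- foptClosedForm(modelParams(beta = 20), 1e-7)$f_opt_formula
  f1000 <- foptClosedForm(modelParams(beta = 1000), 1e-7)$f_opt_formula
  expect_lt(abs(f1000 - f20), 0.01)
  # extreme parameters outside the validity range are flagged
  bad <- foptClosedForm(modelParams(eta = 20), P0 = 0.5)
  expect_false(bad$valid)
  expect_true(is.na(bad$f_opt_formula))
})

test_that("closed form stays in (0,1) across the biological parameter box", {
  rng <- sweepRanges()
  grid <- expand.grid(gamma = rng$gamma$biological,
                      eta = rng$eta$biological,
                      beta = rng$beta$biological,
                      P0 = rng$P0$biological)
  for (r in seq_len(nrow(grid))) {
    p <- modelParams(gamma = grid$gamma[r], eta = grid$eta[r],
                     beta = grid$beta[r])
    f <- foptClosedForm(p, grid$P0[r])$f_opt_formula
    expect_gt(f, 0)
    expect_lt(f, 1)
  }
})

test_that("the derived formula matches fast-decision simulations away from gamma = 1", {
  # discriminates between readings of the closed form: the derivation gives
  # ln(gamma / (eta * Ptot(0))) inside the denominator
  p <- modelParams(gamma = 2, delta = 100)
  sim <- findFopt(p, resolution = 0.01)
  form <- foptClosedForm(p, 1e-7)
  expect_true(form$valid)
  expect_lt(abs(sim$f_opt - form$f_opt_formula), 0.02)
})

test_that("crash-time scaling rank-orders the simulated optimum across burst sizes", {
  sw <- beta_sweep()
  sc <- foptScaling(1, sw$t_star)
  expect_gt(stats::cor(sw$f_opt, sc, method = "spearman"), 0.9)
})

test_that("formula-simulation comparison splits regimes correctly", {
  tab <- compareFormulaVsSimulation(data.frame(delta = c(1, 100)),
                                    resolution = 0.01)
  expect_false(any(tab$failed))
  smry <- attr(tab, "summary")
  fast <- smry[smry$regime == "fast decisions (delta >= 100)", ]
  slow <- smry[smry$regime == "biological delta", ]
  expect_lt(fast$max_abs, slow$max_abs)
  expect_lt(fast$max_abs, 0.02)
})
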