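test_that("mutation is multiplicative, clipped, and fixes zero", {
  s <- moiStrategy(0, 0.5, 1)
  for (rep in 1:20) {
    m <- mutateStrategy(s)
    expect_equal(m$f[1], 0)          # 0 is a fixed point
    expect_lte(m$f[3], 1)            # clipping at 1
    expect_true(all(m$f >= 0 & m$f <= 1))
  }
  m <- mutateStrategy(moiStrategy(0.5, 0.5, 0.5), r = c(3, 0, -3))
  expect_equal(m$f, c(0.515, 0.5, 0.485))
})

test_that("mutation draws follow the uniform integer law", {
  set.seed(11)
  draws <- replicate(1e4, mutateStrategy(moiStrategy(0.5, 0.5, 0.5))$f)
  expect_true(all(draws >= 0.485 & draws <= 0.515))
  for (comp in 1:3) {
    tab <- table(round(draws[comp, ], 4))
    expect_equal(length(tab), 7L)    # 7 equally likely values
    expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
  }
})

test_that("identical strategies tie and the incumbent is retained", {
  res <- competeStrategies(moiStrategy(0.3, 0.6, 0.9),
                           moiStrategy(0.3, 0.6, 0.9))
  expect_equal(res$winner, 1L)
  expect_lt(abs(res$payoff), 1e-12)
})

test_that("the switch strategy beats every flat fixed-propensity strategy", {
  switch_s <- moiStrategy(0, 1, 1)
  for (f in seq(0, 1, by = 0.05)) {
    res <- competeStrategies(switch_s, moiStrategy(f, f, f))
    expect_equal(res$winner, 1L)
    expect_gt(res$payoff, 0)
  }
})

test_that("evolution traces are deterministic under a fixed seed", {
  t1 <- evolveStrategies(seed = 99, max_iter = 60, conv_window = 20)
  t2 <- evolveStrategies(seed = 99, max_iter = 60, conv_window = 20)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "final")$f, attr(t2, "final")$f)
})

test_that("evolution converges to the switch strategy across seeds", {
  for (tr in evolution_traces()) {
    fin <- attr(tr, "final")
    expect_false(is.na(attr(tr, "converged_at")))
    expect_lte(fin$f[1], 0.05)
    expect_gte(fin$f[2], 0.9)
    expect_gte(fin$f[3], 0.9)
  }
})

test_that("winner bookkeeping is consistent along the trace", {
  for (tr in evolution_traces()[1:2]) {
    w <- as.matrix(tr[, c("f1_winner", "f2_winner", "f3_winner")])
    expect_true(all(w >= 0 & w <= 1))
    # each winner is the previous winner or a <=3% mutant of it
    dw <- abs(w[-1, , drop = FALSE] - w[-nrow(w), , drop = FALSE])
    bound <- 0.03 * w[-nrow(w), , drop = FALSE] + 1e-12
    expect_true(all(dw <= bound))
  }
})

test_that("selection settles f(1) first, then f(3), then f(2) on average", {
  # events = first entry into the 0.1-neighbourhood of the converged values
  # (0, 1, 1); a tighter low threshold would measure the multiplicative
  # mutation kinetics near zero rather than the order of selection pressures
  ord <- t(sapply(evolution_traces(),
                  convergenceOrder, lo = 0.1, hi = 0.9))
  means <- colMeans(ord)
  expect_lt(means[["f1_low"]], means[["f3_high"]])
  expect_lt(means[["f3_high"]], means[["f2_high"]])
})
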