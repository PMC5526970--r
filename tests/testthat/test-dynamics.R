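test_that("fixed-model derivatives match direct substitution", {
  p <- modelParams(gamma = 1, K = 1, eta = 20, beta = 100, delta = 1)
  y0 <- c(B0 = 0, B1 = 0, B2 = 0, L1 = 0, L2 = 0, P1 = 0, P2 = 0)

  # logistic growth of uninfected bacteria alone
  y <- y0; y["B0"] <- 0.5
  d <- phageRhsFixed(0, y, list(params = p, f1 = 0.1, f2 = 0.1))[[1]]
  expect_equal(d[["B0"]], 0.25)
  expect_equal(unname(d[names(d) != "B0"]), rep(0, 6))

  # logistic fixed point at carrying capacity
  y <- y0; y["B0"] <- 1
  d <- phageRhsFixed(0, y, list(params = p, f1 = 0.1, f2 = 0.1))[[1]]
  expect_equal(unname(d), rep(0, 7))

  # infection terms
  y <- y0; y["B0"] <- 0.5; y["P1"] <- 1
  d <- phageRhsFixed(0, y, list(params = p, f1 = 0.1, f2 = 0.1))[[1]]
  expect_equal(d[["B0"]], 0.25 - 10)
  expect_equal(d[["B1"]], 10)
  expect_equal(d[["P1"]], -10)

  expect_error(phageRhsFixed(0, replace(y0, 1, -1),
                             list(params = p, f1 = 0.1, f2 = 0.1)),
               "non-negative")
})

test_that("MOI-model derivatives match direct substitution", {
  p <- modelParams(gamma = 1, K = 1, eta = 20, beta = 100, delta = 1)
  y0 <- c(B0 = 0, B1_1 = 0, B1_2 = 0, B1_3 = 0, B2_1 = 0, B2_2 = 0,
          B2_3 = 0, L1 = 0, L2 = 0, P1 = 0, P2 = 0)
  parms <- list(params = p, s1 = moiStrategy(0, 1, 1),
                s2 = moiStrategy(0.5, 0.5, 0.5))

  # empty system is stationary
  d <- phageRhsMoi(0, y0, parms)[[1]]
  expect_equal(unname(d), rep(0, 11))

  # singly infected cells with fully lytic f(1): burst, no lysogens
  y <- y0; y["B1_1"] <- 0.1
  d <- phageRhsMoi(0, y, parms)[[1]]
  expect_equal(d[["L1"]], 0)
  expect_equal(d[["P1"]], 100 * 0.1)
  expect_equal(d[["B1_1"]], -0.1)

  # doubly infected cells with full lysogeny at MOI 2
  parms2 <- list(params = p, s1 = moiStrategy(0, 1, 1),
                 s2 = parms$s2)
  y <- y0; y["B1_2"] <- 0.1
  d <- phageRhsMoi(0, y, parms2)[[1]]
  expect_equal(d[["L1"]], 0.1)
  expect_equal(d[["P1"]], 0)
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  p <- modelParams()
  trC <- integrateDynamics("fixed", p, list(0.25, 0.29), t_end = 30,
                           n_out = 301)
  trR <- integrateDynamics("fixed", p, list(0.25, 0.29), t_end = 30,
                           n_out = 301, compiled = FALSE)
  expect_lt(max(abs(as.matrix(trC[-1]) - as.matrix(trR[-1]))), 1e-6)

  s <- list(c(0, 1, 1), c(0.1, 0.1, 0.1))
  trC <- integrateDynamics("moi", p, s, t_end = 30, n_out = 301)
  trR <- integrateDynamics("moi", p, s, t_end = 30, n_out = 301,
                           compiled = FALSE)
  expect_lt(max(abs(as.matrix(trC[-1]) - as.matrix(trR[-1]))), 1e-6)
})

test_that("phage-free dynamics follow the logistic closed form", {
  p <- modelParams()
  init <- initialState(B0 = 1e-3, P1 = 0, P2 = 0)
  tr <- integrateDynamics("fixed", p, list(0.1, 0.1), init = init,
                          t_end = 20, n_out = 201)
  expected <- p$K * init$B0 * exp(p$gamma * tr$t) /
    (p$K + init$B0 * (exp(p$gamma * tr$t) - 1))
  expect_equal(tr$B0, expected, tolerance = 1e-6)
  expect_true(all(as.matrix(tr[c("B1", "B2", "L1", "L2", "P1", "P2")]) == 0))
})

test_that("identical strategies and inocula give identical variant trajectories", {
  tr <- integrateDynamics("fixed", modelParams(), list(0.2, 0.2), t_end = 40)
  expect_equal(tr$L1, tr$L2, tolerance = 1e-10)
  expect_equal(tr$P1, tr$P2, tolerance = 1e-10)
})

test_that("swapping variant labels swaps the trajectories", {
  p <- modelParams()
  init_a <- initialState(B0 = 1e-3, P1 = 1e-7, P2 = 3e-7)
  init_b <- initialState(B0 = 1e-3, P1 = 3e-7, P2 = 1e-7)
  ta <- integrateDynamics("fixed", p, list(0.15, 0.3), init_a, t_end = 40)
  tb <- integrateDynamics("fixed", p, list(0.3, 0.15), init_b, t_end = 40)
  expect_equal(ta$L1, tb$L2, tolerance = 1e-9)
  expect_equal(ta$L2, tb$L1, tolerance = 1e-9)
  expect_equal(ta$P1, tb$P2, tolerance = 1e-9)
  expect_equal(ta$B0, tb$B0, tolerance = 1e-9)
})

test_that("densities stay non-negative and bounded by carrying capacity", {
  set.seed(42)
  ranges <- sweepRanges()
  for (rep in 1:5) {
    draw <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
    p <- modelParams(gamma = draw(ranges$gamma$explored),
                     eta = draw(ranges$eta$explored),
                     beta = draw(ranges$beta$explored),
                     delta = draw(ranges$delta$explored))
    init <- initialState(B0 = draw(ranges$B0_0$explored),
                         P1 = draw(ranges$P0$explored),
                         P2 = draw(ranges$P0$explored))
    f <- stats::runif(2)
    tr <- integrateDynamics("fixed", p, list(f[1], f[2]), init,
                            t_end = 30 / p$gamma, n_out = 501)
    m <- as.matrix(tr[-1])
    expect_true(all(m >= 0))  # clipped at solver tolerance on output
    btot <- rowSums(tr[c("B0", "B1", "B2", "L1", "L2")])
    expect_true(all(btot <= p$K * (1 + 1e-6)))
  }
})

test_that("steady state retains only lysogens and possibly uninfected bacteria", {
  p <- modelParams()
  ss <- runToSteadyState("fixed", p, list(0.25, 0.29))
  expect_true(ss$converged)
  expect_equal(ss$L1 + ss$L2 + ss$B0_final, p$K, tolerance = 1e-6)
  expect_lt(ss$state[["P1"]] + ss$state[["P2"]], 1e-12)
  expect_lt(ss$state[["B1"]] + ss$state[["B2"]], 1e-10)

  # a variant that never lysogenizes leaves no lysogens
  ss0 <- runToSteadyState("fixed", p, list(0, 0.1))
  expect_lt(ss0$L1, 1e-12)
  expect_gt(ss0$L2, 0.9)

  # small burst sizes can leave uninfected survivors alongside lysogens
  ssb <- runToSteadyState("fixed", modelParams(beta = 2), list(0.1, 0.1))
  expect_true(ssb$converged)
  expect_gt(ssb$B0_final, 0.01)
  expect_gt(ssb$L1 + ssb$L2, 0.1)
})

test_that("MOI model with a flat strategy approaches the fixed model as delta grows", {
  ratio_gap <- sapply(c(10, 1000), function(d) {
    p <- modelParams(delta = d)
    ssF <- runToSteadyState("fixed", p, list(0.1, 0.2))
    ssM <- runToSteadyState("moi", p,
                            list(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2)))
    abs(ssM$L1 / ssM$L2 - ssF$L1 / ssF$L2) / (ssF$L1 / ssF$L2)
  })
  expect_lt(ratio_gap[2], 1e-3)
  expect_lt(ratio_gap[2], ratio_gap[1])
})

test_that("free phage grow double-exponentially during buildup when decisions are fast", {
  p <- modelParams(delta = 100)
  tr <- integrateDynamics("fixed", p, list(0.1, 0.3), t_end = 10,
                          n_out = 4001)
  ct <- crashTime(tr, p)
  win <- tr$t > 0.5 & tr$t < 0.8 * ct$t_star
  for (i in 1:2) {
    f <- c(0.1, 0.3)[i]
    x <- (1 - f) * (exp(p$gamma * tr$t[win]) - 1)
    y <- log(tr[[paste0("P", i)]][win] / tr[[paste0("P", i)]][1])
    expect_gt(summary(stats::lm(y ~ x))$r.squared, 0.99)
  }
})
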