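test_that("payoff score is the lysogen share difference", {
  expect_equal(payoffScore(0.6, 0.4), 0.2)
  expect_equal(payoffScore(0.37, 0.37), 0)
  expect_equal(payoffScore(0.5, 0), 1)
  expect_equal(payoffScore(0, 0.5), -1)
  expect_equal(payoffScore(0, 0), 0)  # no lysogens at all: a draw
  expect_error(payoffScore(-0.1, 0.5), "non-negative")
})

test_that("minimax recovers a dominant strategy", {
  M <- matrix(c(0, -1, 1, 0), 2, 2)  # row 1 dominates: M[1,2] = 1
  mm <- minimaxSolution(list(f_grid = c(0.1, 0.9), M = M))
  expect_true(mm$saddle_exists)
  expect_equal(mm$f_opt, 0.1)
  expect_equal(mm$game_value, 0)
})

test_that("minimax agrees with brute-force saddle enumeration", {
  set.seed(7)
  for (rep in 1:20) {
    M <- random_antisym(5)
    mm <- minimaxSolution(M)
    bf <- brute_force_saddles(M)
    if (is.null(bf)) {
      expect_false(mm$saddle_exists)
    } else {
      expect_true(mm$saddle_exists)
      expect_equal(as.matrix(mm$saddles[, c("i", "j")]), bf,
                   ignore_attr = TRUE)
    }
  }
})

test_that("payoff matrices are antisymmetric with zero diagonal", {
  grid <- c(0, 0.1, 0.2, 0.3)
  pm <- buildPayoffMatrix(modelParams(), f_grid = grid,
                          both_triangles = TRUE)
  expect_true(all(diag(pm$M) == 0))
  expect_lt(max(abs(pm$M + t(pm$M))), 1e-6)
  # a non-lysogenizing opponent always loses completely
  expect_equal(pm$M["0.1", "0"], 1)
})

test_that("the default game has a unique saddle near 10% lysogeny", {
  res <- default_fopt()
  expect_true(res$unique)
  expect_true(res$fine$saddle_exists)
  expect_lt(abs(res$f_opt - 0.10), 0.011)
  # saddle property: column max and row min at the saddle cell
  M <- res$payoff_matrix$M
  s <- res$fine$saddles[1, ]
  expect_gte(M[s$i, s$j], max(M[, s$j]) - 1e-8)
  expect_lte(M[s$i, s$j], min(M[s$i, ]) + 1e-8)
})

test_that("coarse-to-fine refinement matches the full fine grid", {
  res <- default_fopt()
  pm_full <- buildPayoffMatrix(modelParams(), f_grid = seq(0, 0.4, by = 0.01))
  mm_full <- minimaxSolution(pm_full)
  expect_true(mm_full$unique)
  expect_equal(res$f_opt, mm_full$f_opt)

  # equilibrium property: any deviation from f_opt can be beaten
  j_star <- mm_full$saddles$j[1]
  col_max <- apply(pm_full$M, 2, max)
  expect_true(all(col_max[-j_star] > 0))
})
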