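test_that("equal-width partitions tile the axis with the documented sizes", {
  p20 <- interval_partition(2075, 20)
  expect_equal(p20$sizes, c(rep(104, 15), rep(103, 5)))
  p10 <- interval_partition(2075, 10)
  expect_equal(p10$sizes, c(rep(208, 5), rep(207, 5)))
  p1 <- interval_partition(10, 10)
  expect_equal(p1$sizes, rep(1, 10))
  set.seed(1)
  for (trial in 1:20) {
    nv <- sample(5:500, 1); ni <- sample(seq_len(nv), 1)
    pt <- interval_partition(nv, ni)
    expect_equal(sum(pt$sizes), nv)
    expect_lte(max(pt$sizes) - min(pt$sizes), 1)
    expect_equal(unname(pt$bounds[1, 1]), 1)
    expect_equal(unname(pt$bounds[ni, 2]), nv)
    if (ni > 1)
      expect_true(all(pt$bounds[-1, 1] == pt$bounds[-ni, 2] + 1))
    # extra points sit in the leading intervals
    expect_true(all(diff(pt$sizes) <= 0))
  }
  expect_error(interval_partition(5, 6), "n_intervals")
})

test_that("partition boundaries reproduce the published interval ranges", {
  g <- standard_grid()
  p20 <- interval_partition(2075, 20)
  r12 <- interval_ranges(c(1, 2), p20, g)
  expect_length(r12, 1)                       # adjacent intervals merge
  expect_equal(r12[[1]]$low, 3999.70, tolerance = 0.02)
  expect_equal(r12[[1]]$high, 4798.10, tolerance = 0.02)
  r8 <- interval_ranges(8, p20, g)
  expect_equal(r8[[1]]$low, 6807.60, tolerance = 0.02)
  expect_equal(r8[[1]]$high, 7204.87, tolerance = 0.02)
  p10 <- interval_partition(2075, 10)
  r9 <- interval_ranges(9, p10, g)
  expect_equal(r9[[1]]$low, 10406.17, tolerance = 0.02)
  expect_equal(r9[[1]]$high, 11200.71, tolerance = 0.02)
  expect_identical(interval_ranges(integer(0), p20, g), list())
  r38 <- interval_ranges(c(3, 8), p20, g)
  expect_length(r38, 2)
  expect_lt(r38[[1]]$high, r38[[2]]$low)
})

test_that("siPLS equals exhaustive enumeration and is a global minimum", {
  sp <- small_planted(seed = 11, n = 30, p = 60, n_intervals = 6)
  X <- sp$ds$absorbance; y <- sp$ds$meta$y
  res <- sipls(X, y, n_intervals = 6, combo_sizes = 2, ncomp_max = 4)
  # literal brute force over all 2-interval combinations
  part <- interval_partition(60, 6)
  best <- Inf; best_sel <- NULL
  for (i in 1:5) for (j in (i + 1):6) {
    cols <- c(seq(part$bounds[i, 1], part$bounds[i, 2]),
              seq(part$bounds[j, 1], part$bounds[j, 2]))
    cv <- pls_loocv(X[, cols], y, 4)
    if (cv$rmsecv[cv$ncomp] < best) {
      best <- cv$rmsecv[cv$ncomp]; best_sel <- c(i, j)
    }
  }
  expect_equal(res$selected, best_sel)
  expect_equal(res$rmsecv, best, tolerance = 1e-10)
  expect_true(all(res$rmsecv <= res$candidates$rmsecv + 1e-12))
  expect_equal(nrow(res$candidates), choose(6, 2))
  expect_equal(res$n_selected_vars, 20)
})

test_that("siPLS recovers a planted informative interval", {
  for (seed in 1:5) {
    sp <- small_planted(seed = seed)
    res <- sipls(sp$ds$absorbance, sp$ds$meta$y, n_intervals = 10,
                 combo_sizes = 2, ncomp_max = 4)
    expect_true(sp$band_iv %in% res$selected)
  }
})

test_that("each biPLS elimination step matches the literal loop", {
  sp <- small_planted(seed = 21, n = 30, p = 60, n_intervals = 5)
  X <- sp$ds$absorbance; y <- sp$ds$meta$y
  res <- bipls(X, y, n_intervals = 5, ncomp_max = 4)
  part <- interval_partition(60, 5)
  # recompute the first elimination by hand
  rms <- sapply(1:5, function(k) {
    keep <- setdiff(1:5, k)
    cols <- unlist(lapply(keep, function(m)
      seq(part$bounds[m, 1], part$bounds[m, 2])))
    cv <- pls_loocv(X[, cols], y, 4)
    cv$rmsecv[cv$ncomp]
  })
  expect_equal(res$trajectory$removed[2], which.min(rms))
  expect_equal(res$trajectory$rmsecv[2], min(rms), tolerance = 1e-10)
  # trajectory runs to exhaustion and the reported set is its minimum
  expect_equal(nrow(res$trajectory), 5)
  expect_equal(res$rmsecv, min(res$trajectory$rmsecv), tolerance = 1e-10)
})

test_that("biPLS keeps the informative interval of planted data", {
  for (seed in 1:5) {
    sp <- small_planted(seed = seed, n = 40, p = 100, n_intervals = 5)
    res <- bipls(sp$ds$absorbance, sp$ds$meta$y, n_intervals = 5,
                 ncomp_max = 4)
    expect_true(sp$band_iv %in% res$selected)
  }
})

test_that("an all-zero interval never hurts cross-validation", {
  set.seed(31)
  X <- matrix(rnorm(40 * 30), 40, 30)
  X[, 11:15] <- 0
  y <- rowSums(X[, 1:5]) + rnorm(40, sd = 0.2)
  cv_with <- pls_loocv(X, y, 3)
  cv_without <- pls_loocv(X[, -(11:15)], y, 3)
  expect_equal(cv_with$press, cv_without$press, tolerance = 1e-10)
})
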