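test_that("PCA captures exact low-rank structure and matches eigen", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(8 * 2), 8, 2)))
  scores <- matrix(rnorm(20), 10, 2)
  X <- scores %*% t(basis) + rep(rnorm(8), each = 10)
  pc <- pca_fit(X, 2)
  expect_equal(pc$explained_pct[2], 100, tolerance = 1e-9)
  # reconstruction at full retained rank
  Xhat <- rep(pc$mean, each = 10) + pc$scores %*% t(pc$loadings)
  expect_equal(Xhat, X, tolerance = 1e-9)
  # eigen oracle on the covariance
  set.seed(2)
  Y <- matrix(rnorm(60), 12, 5)
  pc2 <- pca_fit(Y, 3)
  ev <- eigen(stats::cov(Y), symmetric = TRUE)$values
  expect_equal(pc2$sdev^2, ev[1:3], tolerance = 1e-9)
  expect_equal(pc2$explained_pct, 100 * cumsum(ev[1:3]) / sum(ev),
               tolerance = 1e-9)
  expect_equal(crossprod(pc2$loadings), diag(3), tolerance = 1e-9)
  expect_error(pca_fit(Y, 12), "k must be")
})

test_that("Mahalanobis distances match the linear-solve oracle", {
  set.seed(3)
  A <- matrix(rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  mu <- rnorm(3)
  stats <- list(g1 = list(centroid = mu, cov = S))
  x <- rnorm(3)
  d <- mahalanobis_distances(x, stats)
  expect_equal(unname(d[1, 1]), unname(sqrt(stats::mahalanobis(x, mu, S))),
               tolerance = 1e-10)
  expect_equal(unname(mahalanobis_distances(mu, stats)[1, 1]), 0)
  # identity covariance reduces to Euclidean distance
  stats_i <- list(g1 = list(centroid = mu, cov = diag(3)))
  expect_equal(unname(mahalanobis_distances(x, stats_i)[1, 1]),
               sqrt(sum((x - mu)^2)), tolerance = 1e-12)
  expect_error(mahalanobis_distances(c(NA, 1, 2), stats), "non-finite")
})

test_that("well-separated classes classify perfectly; stats are definitional", {
  set.seed(4)
  n <- 15; p <- 40
  base <- matrix(rnorm(n * 2 * p, sd = 0.3), n * 2, p)
  base[1:n, 1:10] <- base[1:n, 1:10] + 5       # class shift
  labels <- rep(c("LY", "NLY"), each = n)
  da <- da_fit(base, labels, k = 3)
  self <- predict(da, base, truth = labels)
  expect_equal(self$pct_correct, 100)
  expect_equal(unname(self$incorrect_by_class), c(0L, 0L))
  # centroids are per-class means of the scores
  scores <- (base - rep(da$mean, each = 2 * n)) %*% da$loadings
  expect_equal(da$class_stats$LY$centroid, colMeans(scores[1:n, ]),
               tolerance = 1e-10)
  expect_error(da_fit(base[c(1:3, 16:30), ], labels[c(1:3, 16:30)], k = 3),
               "at least k")
})

test_that("classification summary arithmetic and tie handling", {
  # 31 of 86 incorrect corresponds to 63.95% correct
  expect_equal(round(100 * (86 - 31) / 86, 2), 63.95)
  set.seed(5)
  stats <- list(A = list(centroid = c(-1, 0), cov = diag(2)),
                B = list(centroid = c(1, 0), cov = diag(2)))
  model <- structure(list(loadings = diag(2), mean = c(0, 0), k = 2,
                          explained_pct = 100, class_stats = stats,
                          classes = c("A", "B"), pooled = FALSE),
                     class = "nir_da")
  pred <- predict(model, rbind(c(0, 3), c(-2, 0)),
                  truth = c("A", "A"))
  expect_equal(pred$table$assigned, c("A", "A"))   # tie -> first label
  expect_true(pred$table$tie[1])
  expect_false(pred$table$tie[2])
  expect_equal(pred$pct_correct, 100)
})

test_that("classification is invariant to affine score transforms", {
  set.seed(6)
  k <- 3
  scores <- matrix(rnorm(60), 20, k)
  stats <- list(
    A = list(centroid = rnorm(k), cov = crossprod(matrix(rnorm(9), 3)) + diag(3) * .2),
    B = list(centroid = rnorm(k), cov = crossprod(matrix(rnorm(9), 3)) + diag(3) * .2))
  M <- matrix(rnorm(9), 3, 3); M <- M + diag(3) * 2   # invertible
  stats_t <- lapply(stats, function(s)
    list(centroid = as.vector(M %*% s$centroid),
         cov = M %*% s$cov %*% t(M)))
  d0 <- mahalanobis_distances(scores, stats)
  d1 <- mahalanobis_distances(scores %*% t(M), stats_t)
  expect_equal(d0, d1, tolerance = 1e-8)
})

test_that("DA accuracy rises with the between-class marker shift", {
  shifts <- c(0.000, 0.004, 0.008, 0.012, 0.016)
  acc <- sapply(shifts, function(sh) {
    mean(sapply(1:5, function(seed) {
      cfg <- sim_config(n_ly = 28, n_nly = 18,
                        marker_mean = c(LY = 0.004 + sh, NLY = 0.004),
                        grid = standard_grid(3999.70, 15.428, 12000),
                        seed = seed)
      sim <- generate_dataset(cfg)
      plan <- split_calibration(sim$dataset, seed = seed)
      cal <- sim$dataset[plan$calibration]
      pred <- sim$dataset[plan$prediction]
      pf <- preprocess_fit("msc", cal$absorbance)
      da <- da_fit(pf$X, cal$meta$class, k = 6)
      predict(da, preprocess_apply(pf, pred$absorbance),
              truth = pred$meta$class)$pct_correct
    }))
  })
  # monotone trend test: accuracy correlates positively with the shift
  expect_gt(stats::cor(shifts, acc, method = "spearman"), 0.8)
  expect_gt(acc[5], acc[1])
})
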