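test_that("a single factor recovers an exact one-direction response", {
  set.seed(1)
  v <- rnorm(12)
  t <- rnorm(9)
  X <- outer(t, v)                       # rank-1 spectra
  y <- as.vector(X %*% (2 * v))
  m <- pls_fit(X, y, 1)
  expect_lt(sqrt(mean(m$residuals^2)), 1e-8)
})

test_that("PLS at full rank reproduces ordinary least squares", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  m <- pls_fit(X, y, 4)
  ols <- stats::lsfit(X, y)
  yhat_ols <- y - ols$residuals
  expect_equal(m$fitted.values, yhat_ols, tolerance = 1e-6)
})

test_that("the NIPALS decomposition matches the literal deflation loop", {
  set.seed(3)
  X <- matrix(rnorm(40), 8, 5)
  y <- rnorm(8)
  for (A in c(1, 2, 4)) {
    ref <- reference_pls1(X, y, A)
    m <- pls_fit(X, y, A)
    expect_equal(m$coefficients, ref$b, tolerance = 1e-8)
    expect_equal(abs(m$weights), abs(ref$W), tolerance = 1e-8)
    expect_equal(m$y_mean, ref$y_mean)
  }
  # successive score vectors are mutually orthogonal
  m <- pls_fit(X, y, 4)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # first weight vector is the centered covariance direction
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w1 <- crossprod(Xc, yc); w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(m$weights[, 1]), abs(as.vector(w1)), tolerance = 1e-10)
})

test_that("prediction is affine and anchored at the training mean", {
  set.seed(4)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  m <- pls_fit(X, y, 3)
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean)
  expect_equal(predict(m, X), m$fitted.values)
  X1 <- matrix(rnorm(18), 3, 6); X2 <- matrix(rnorm(18), 3, 6)
  al <- 0.3
  expect_equal(predict(m, al * X1 + (1 - al) * X2),
               al * predict(m, X1) + (1 - al) * predict(m, X2),
               tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 1, 5)), "variables")
  # shifting y shifts predictions by the same constant
  m2 <- pls_fit(X, y + 100, 3)
  expect_equal(predict(m2, X1), predict(m, X1) + 100, tolerance = 1e-8)
})

test_that("LOOCV PRESS equals the brute-force refit loop", {
  set.seed(5)
  X <- matrix(rnorm(48), 8, 6)
  y <- rnorm(8)
  cv <- pls_loocv(X, y, 3)
  expect_equal(cv$press, brute_force_press(X, y, 3), tolerance = 1e-8)
  expect_equal(cv$rmsecv, sqrt(cv$press / 8))
  # exchangeability: sample order is irrelevant
  per <- sample(8)
  cv2 <- pls_loocv(X[per, ], y[per], 3)
  expect_equal(cv2$press, cv$press, tolerance = 1e-8)
})

test_that("LOOCV of a noiseless one-direction response is exact at 1 LV", {
  set.seed(6)
  v <- rnorm(10)
  X <- outer(rnorm(8), v)
  y <- as.vector(X %*% v)
  cv <- pls_loocv(X, y, 2)
  expect_lt(cv$press[1], 1e-12 * sum(y^2))
})

test_that("factor selection finds the first PRESS minimum", {
  expect_equal(select_factors(c(10, 5, 3, 4, 6)), 3)
  expect_equal(select_factors(c(9, 7, 5, 4)), 4)     # monotone -> A_max
  expect_equal(select_factors(c(8, 8, 7)), 3)        # tie is not a minimum
  expect_equal(select_factors(c(4, 9)), 1)
  expect_error(select_factors(numeric(0)), "empty")
})

test_that("evaluation metrics match their defining formulas", {
  set.seed(7)
  X <- matrix(rnorm(80), 10, 8)
  y <- as.vector(X %*% rnorm(8)) + rnorm(10, sd = 0.3)
  Xp <- matrix(rnorm(48), 6, 8)
  yp <- as.vector(Xp %*% rnorm(8))
  m <- pls_fit(X, y, 3)
  met <- pls_evaluate(m, X, y, Xp, yp)
  yh_c <- predict(m, X); yh_p <- predict(m, Xp)
  expect_equal(met$rmsec, sqrt(sum((y - yh_c)^2) / 10))
  expect_equal(met$rmsep, sqrt(sum((yp - yh_p)^2) / 6))
  expect_equal(met$r_c, sum((y - mean(y)) * (yh_c - mean(yh_c))) /
                 sqrt(sum((y - mean(y))^2) * sum((yh_c - mean(yh_c))^2)))
  expect_equal(met$rpd, sd(yp) / met$rmsep)
  # perfect predictions: R = 1, RMSE = 0, RPD = Inf
  met2 <- pls_evaluate(m, X, yh_c, Xp, yh_p)
  expect_equal(met2$r_c, 1)
  expect_equal(met2$rmsep, 0)
  expect_equal(met2$rpd, Inf)
  expect_warning(pls_evaluate(m, X, y, Xp[1:2, ], yp[1:2]), "unstable")
})

test_that("degenerate fits are rejected with clear errors", {
  X <- matrix(rnorm(30), 6, 5)
  expect_error(pls_fit(X, rep(2, 6), 1), "zero variance")
  expect_error(pls_fit(X, rnorm(6), 6), "ncomp")
  expect_error(pls_fit(X[1:2, ], rnorm(2), 1), "3 samples")
})
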