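# Small in-code fixtures shared across the test files.

# tiny spectral dataset with known values
toy_dataset <- function(n = 3, p = 5, seed = 42) {
  set.seed(seed)
  wn <- 4000 + 10 * seq_len(p)
  meta <- data.frame(sample_id = paste0("S", seq_len(n)),
                     origin = rep(c("A", "B"), length.out = n),
                     class = rep(c("LY", "NLY"), length.out = n),
                     tp = 200 + 10 * seq_len(n),
                     faa = 40 + 2 * seq_len(n),
                     stringsAsFactors = FALSE)
  spectral_dataset(wn, matrix(rnorm(n * p), n, p), meta)
}

# write a toy spectra CSV with a descending wavenumber header
write_descending_csv <- function(path, wn_desc, values, ids) {
  header <- paste(c("sample_id", wn_desc), collapse = ",")
  rows <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], values[i, ]), collapse = ","), "")
  writeLines(c(header, rows), path)
}

# literal step-by-step PLS1 deflation, written independently of the
# package internals: scalar loops, no shared helpers
reference_pls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- matrix(NA, p, A); P <- matrix(NA, p, A); q <- numeric(A)
  for (a in 1:A) {
    w <- numeric(p)
    for (j in 1:p) w[j] <- sum(E[, j] * f)
    w <- w / sqrt(sum(w^2))
    t <- numeric(n)
    for (i in 1:n) t[i] <- sum(E[i, ] * w)
    pv <- numeric(p)
    for (j in 1:p) pv[j] <- sum(E[, j] * t) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    for (i in 1:n) for (j in 1:p) E[i, j] <- E[i, j] - t[i] * pv[j]
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  b <- W %*% solve(t(P) %*% W) %*% q
  list(b = as.vector(b), x_mean = xm, y_mean = ym, W = W, P = P, q = q)
}

# brute-force LOOCV PRESS: refit the exported pls_fit n times per factor
brute_force_press <- function(X, y, A_max) {
  n <- nrow(X)
  press <- numeric(A_max)
  for (a in 1:A_max) {
    for (i in 1:n) {
      m <- pls_fit(X[-i, , drop = FALSE], y[-i], a)
      press[a] <- press[a] + (y[i] - predict(m, X[i, , drop = FALSE]))^2
    }
  }
  press
}

# small planted-signal regression problem on a coarse grid
small_planted <- function(seed, n = 60, p = 200, n_intervals = 10) {
  grid <- seq(4000, by = 10, length.out = p)
  part <- interval_partition(p, n_intervals)
  band_iv <- 4                       # plant the signal in interval 4
  lo <- grid[part$bounds[band_iv, 1]]
  hi <- grid[part$bounds[band_iv, 2]]
  pd <- planted_interval_dataset(c(lo, hi), n = n, seed = seed,
                                 grid = grid)
  list(ds = pd$dataset, band_iv = band_iv, part = part, grid = grid,
       band_cols = pd$band_cols)
}
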