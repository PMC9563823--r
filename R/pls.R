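# Internal NIPALS PLS1 engine. X, y are raw (uncentered); returns the
# centered decomposition. For a single response the NIPALS inner loop
# converges in one step, so the weight of each component is X_deflated' y
# normalized; a convergence guard is unnecessary but components are still
# extracted by explicit deflation.
.nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- X - rep(x_mean, each = n)
  yc <- y - y_mean
  if (sum(yc^2) <= 0) stop("response has zero variance")
  if (ncomp > min(n - 1, p))
    stop("ncomp must be <= min(n - 1, p) = ", min(n - 1, p))
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)                 # covariance direction
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual X orthogonal to residual y: stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      break
    }
    w <- w / nw
    t <- as.vector(Xc %*% w)
    tt <- sum(t^2)
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pvec)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa; Tm[, a] <- t
  }
  list(x_mean = x_mean, y_mean = y_mean, W = W, P = P, q = q,
       scores = Tm, ncomp = ncol(W))
}

# Predictions of the nested 1..ncomp models for new rows: m x ncomp matrix.
.pls_predict_all <- function(fit, Xnew) {
  Xd <- as.matrix(Xnew) - rep(fit$x_mean, each = nrow(as.matrix(Xnew)))
  m <- nrow(Xd)
  A <- fit$ncomp
  out <- matrix(fit$y_mean, m, max(A, 1))
  if (A == 0) return(out)
  acc <- rep(fit$y_mean, m)
  for (a in seq_len(A)) {
    t <- as.vector(Xd %*% fit$W[, a])
    acc <- acc + t * fit$q[a]
    out[, a] <- acc
    Xd <- Xd - tcrossprod(t, fit$P[, a])
  }
  out
}

# Regression vector b with ncomp components: b = W (P'W)^{-1} q.
.pls_coef <- function(fit, ncomp = fit$ncomp) {
  a <- seq_len(ncomp)
  W <- fit$W[, a, drop = FALSE]
  P <- fit$P[, a, drop = FALSE]
  as.vector(W %*% solve(crossprod(P, W), fit$q[a]))
}

#' Fit a PLS1 calibration model
#'
#' Mean-centered NIPALS partial least squares regression of a single
#' response (e.g. total polyphenols) on a spectral matrix. The regression
#' vector is assembled as W (P'W)^-1 q so that predictions are
#' `y_mean + (x - x_mean) %*% b`.
#'
#' @param X numeric matrix of predictors (n samples x p variables), or a
#'   [spectral_dataset()] together with `response`.
#' @param y numeric response vector, or (for a dataset) the name of a
#'   reference column (`"tp"`, `"faa"`, `"tp_faa"`).
#' @param ncomp number of latent variables (factors), `<= min(n - 1, p)`.
#' @return an object of class `nir_pls` with elements `x_mean`, `y_mean`,
#'   `weights` (W), `x_loadings` (P), `y_loadings` (q), `scores`,
#'   `coefficients` (the regression vector b), `ncomp`, `fitted.values`
#'   and `residuals`.
#' @seealso [pls_loocv()], [select_factors()], [pls_evaluate()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 8, 5)
#' y <- X %*% c(1, -1, 0, 0.5, 0) + rnorm(8, sd = 0.01)
#' fit <- pls_fit(X, y, ncomp = 3)
#' fit
#' @export
pls_fit <- function(X, y, ncomp) {
  if (inherits(X, "spectral_dataset")) {
    if (is.character(y)) y <- X$meta[[y]]
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (!all(is.finite(X))) stop("X must be finite")
  core <- .nipals_pls1(X, y, ncomp)
  b <- .pls_coef(core)
  fitted <- core$y_mean +
    as.vector((X - rep(core$x_mean, each = nrow(X))) %*% b)
  structure(list(x_mean = core$x_mean, y_mean = core$y_mean,
                 weights = core$W, x_loadings = core$P,
                 y_loadings = core$q, scores = core$scores,
                 coefficients = b, ncomp = core$ncomp,
                 fitted.values = fitted, residuals = y - fitted, y = y),
            class = "nir_pls")
}

#' @export
print.nir_pls <- function(x, ...) {
  cat("PLS1 calibration model:", x$ncomp, "latent variable(s),",
      length(x$coefficients), "spectral variables,",
      length(x$y), "calibration samples\n")
  cat(sprintf("  RMSEC = %.6g\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
summary.nir_pls <- function(object, ...) {
  rmsec <- sqrt(mean(object$residuals^2))
  r_c <- stats::cor(object$fitted.values, object$y)
  ssy <- sum((object$y - mean(object$y))^2)
  expl <- 1 - cumsum_resid_ss(object) / ssy
  out <- list(ncomp = object$ncomp, rmsec = rmsec, r_c = r_c,
              y_variance_explained = expl)
  class(out) <- "summary.nir_pls"
  out
}

# residual SS of y after each successive component
cumsum_resid_ss <- function(object) {
  yc <- object$y - object$y_mean
  out <- numeric(object$ncomp)
  for (a in seq_len(object$ncomp)) {
    yc <- yc - object$y_loadings[a] * object$scores[, a]
    out[a] <- sum(yc^2)
  }
  out
}

#' @export
print.summary.nir_pls <- function(x, ...) {
  cat("PLS1 model with", x$ncomp, "latent variables\n")
  cat(sprintf("  R_C = %.4f, RMSEC = %.4g\n", x$r_c, x$rmsec))
  cat("  cumulative fraction of response variance captured:\n   ",
      paste(sprintf("%.4f", x$y_variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.nir_pls <- function(object, ...) object$coefficients

#' @export
residuals.nir_pls <- function(object, ...) object$residuals

#' @export
fitted.nir_pls <- function(object, ...) object$fitted.values

#' Predict from a PLS calibration model
#'
#' @param object a `nir_pls` model.
#' @param newdata matrix (or `spectral_dataset`) with the training variable
#'   count; defaults to returning the fitted values.
#' @param ncomp number of latent variables to use (default: all fitted).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.nir_pls <- function(object, newdata = NULL, ncomp = object$ncomp,
                            ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "spectral_dataset")) newdata <- newdata$absorbance
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object$x_mean))
  b <- if (ncomp == object$ncomp) object$coefficients else
    .pls_coef(list(W = object$weights, P = object$x_loadings,
                   q = object$y_loadings, ncomp = object$ncomp), ncomp)
  object$y_mean +
    as.vector((newdata - rep(object$x_mean, each = nrow(newdata))) %*% b)
}

#' @export
plot.nir_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values,
                 xlab = "reference value", ylab = "fitted value",
                 main = sprintf("PLS calibration (%d LVs)", x$ncomp), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validation of a PLS calibration
#'
#' For each number of latent variables a = 1..`ncomp_max`, computes
#' PRESS(a) = sum_i (y_i - yhat_(-i)(a))^2, refitting the model on the
#' remaining n - 1 samples for every left-out sample, and the derived
#' RMSECV(a) = sqrt(PRESS(a) / n).
#'
#' @param X predictor matrix (or `spectral_dataset` with `y` a column name).
#' @param y response vector or reference column name.
#' @param ncomp_max largest factor count examined, `<= min(n - 2, p)`.
#' @return an object of class `pls_cv`: list with `press`, `rmsecv`
#'   (vectors over 1..ncomp_max) and `ncomp` (the PRESS-selected count,
#'   see [select_factors()]).
#' @export
pls_loocv <- function(X, y, ncomp_max = 10) {
  if (inherits(X, "spectral_dataset")) {
    if (is.character(y)) y <- X$meta[[y]]
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples for LOOCV")
  ncomp_max <- min(ncomp_max, n - 2, ncol(X))
  if (ncomp_max < 1) stop("no feasible factor count")
  press <- numeric(ncomp_max)
  for (i in seq_len(n)) {
    fit <- .nipals_pls1(X[-i, , drop = FALSE], y[-i], ncomp_max)
    pred <- .pls_predict_all(fit, X[i, , drop = FALSE])[1, ]
    # early-stopped fits: pad with the last available prediction
    if (fit$ncomp < ncomp_max)
      pred <- c(pred[seq_len(fit$ncomp)],
                rep(pred[max(fit$ncomp, 1)], ncomp_max - fit$ncomp))
    press <- press + (y[i] - pred[seq_len(ncomp_max)])^2
  }
  out <- structure(list(press = press, rmsecv = sqrt(press / n)),
                   class = "pls_cv")
  out$ncomp <- select_factors(out)
  out
}

#' @export
print.pls_cv <- function(x, ...) {
  cat("LOOCV over", length(x$press), "factor counts; selected", x$ncomp,
      "factor(s)\n")
  cat("  RMSECV:", paste(sprintf("%.4g", x$rmsecv), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of PLS factors from a PRESS curve
#'
#' Returns the factor count at the first minimum of PRESS: the smallest a
#' with PRESS(a) < PRESS(a + 1). If PRESS never rises (strict decrease
#' required to continue), the largest examined count is returned; ties in
#' successive PRESS values therefore do not stop the search.
#'
#' @param cv a `pls_cv` object or a numeric PRESS vector.
#' @return integer factor count.
#' @examples
#' select_factors(c(10, 5, 3, 4, 6))  # 3
#' @export
select_factors <- function(cv) {
  press <- if (inherits(cv, "pls_cv")) cv$press else as.numeric(cv)
  if (!length(press)) stop("empty PRESS vector")
  for (a in seq_len(length(press) - 1))
    if (press[a] < press[a + 1]) return(a)
  length(press)
}

#' Calibration / prediction evaluation metrics
#'
#' Computes the standard chemometric figures of merit for one model and
#' response: correlation coefficients R_C and R_P of predicted versus
#' reference values on the calibration and prediction sets, RMSEC, RMSEP
#' (root-mean-square errors, denominator n), RMSECV from the supplied
#' cross-validation, and RPD = sd(prediction-set reference) / RMSEP
#' (n - 1 denominator). An RPD above 2 conventionally marks a usable model.
#'
#' @param model a `nir_pls` model.
#' @param X_cal,y_cal calibration predictors and reference values.
#' @param X_pred,y_pred prediction-set predictors and reference values.
#' @param cv optional `pls_cv` (its RMSECV at the model's factor count is
#'   reported).
#' @return an object of class `pls_metrics`: list with `r_c`, `r_p`,
#'   `rmsec`, `rmsecv`, `rmsep`, `rpd`, `ncomp`.
#' @export
pls_evaluate <- function(model, X_cal, y_cal, X_pred, y_pred, cv = NULL) {
  y_cal <- as.numeric(y_cal); y_pred <- as.numeric(y_pred)
  if (!length(y_cal) || !length(y_pred)) stop("empty evaluation set")
  if (length(y_pred) < 3)
    warning("prediction set smaller than 3: correlation is unstable")
  yhat_c <- predict(model, X_cal)
  yhat_p <- predict(model, X_pred)
  rmsec <- sqrt(mean((y_cal - yhat_c)^2))
  rmsep <- sqrt(mean((y_pred - yhat_p)^2))
  r_c <- stats::cor(yhat_c, y_cal)
  r_p <- stats::cor(yhat_p, y_pred)
  rpd <- stats::sd(y_pred) / rmsep          # Inf when RMSEP == 0
  rmsecv <- if (!is.null(cv)) cv$rmsecv[min(model$ncomp, length(cv$rmsecv))]
            else NA_real_
  structure(list(r_c = r_c, r_p = r_p, rmsec = rmsec, rmsecv = rmsecv,
                 rmsep = rmsep, rpd = rpd, ncomp = model$ncomp),
            class = "pls_metrics")
}

#' @export
print.pls_metrics <- function(x, ...) {
  cat(sprintf(
    "Factors %d | R_C %.4f RMSEC %.4g RMSECV %.4g | R_P %.4f RMSEP %.4g RPD %.3g\n",
    x$ncomp, x$r_c, x$rmsec, x$rmsecv, x$r_p, x$rmsep, x$rpd))
  invisible(x)
}
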