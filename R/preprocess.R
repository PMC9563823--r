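#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, x = a + b * reference,
#' and returns (x - a) / b. Removes the additive and multiplicative
#' particle-size scatter effects of diffuse-reflectance measurements.
#'
#' @param X numeric matrix, samples in rows.
#' @param reference reference spectrum; defaults to the column mean of `X`
#'   (for a calibration set). Pass a stored calibration reference when
#'   correcting a prediction set.
#' @return corrected matrix with attributes `reference`, and per-sample
#'   `intercept`/`slope`; rows whose slope magnitude is below 1e-12 are
#'   passed through unchanged with a warning.
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("msc needs at least 2 spectral points")
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match ncol(X)")
  rc <- reference - mean(reference)
  denom <- sum(rc * rc)
  if (denom <= 0) stop("reference spectrum is constant")
  b <- as.vector(X %*% rc) / denom          # slope of x ~ a + b*ref
  a <- rowMeans(X) - b * mean(reference)
  flat <- abs(b) < 1e-12
  out <- (X - a) / b
  if (any(flat)) {
    warning(sum(flat), " sample(s) flat relative to the reference; ",
            "passed through uncorrected")
    out[flat, ] <- X[flat, , drop = FALSE]
  }
  attr(out, "reference") <- reference
  attr(out, "intercept") <- a
  attr(out, "slope") <- b
  out
}

#' Standard normal variate transform
#'
#' Centers each spectrum to mean 0 and scales it to unit standard deviation
#' (n - 1 denominator), removing path-length and particle scatter effects.
#'
#' @param X numeric matrix, samples in rows.
#' @return the transformed matrix.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- !is.finite(s) | s <= 0
  if (any(bad))
    stop("constant spectrum (zero variance) for sample(s): ",
         paste(if (!is.null(rownames(X))) rownames(X)[bad] else which(bad),
               collapse = ", "))
  (X - mu) / s
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Per-row local polynomial filtering (window `window`, order `polyorder`).
#' Derivative outputs are expressed per cm^-1 by dividing by
#' `spacing^deriv`. Edges use the one-sided full-window polynomial fit, so
#' the number of variables is preserved.
#'
#' @param X numeric matrix, samples in rows.
#' @param window odd window length in points (default 7).
#' @param polyorder polynomial order (default 3), `< window`.
#' @param deriv derivative order 0, 1 or 2.
#' @param spacing grid spacing in cm^-1 (used to scale derivatives).
#' @return filtered matrix of the same dimension.
#' @export
sg_filter <- function(X, window = 7, polyorder = 3, deriv = 0, spacing = 1) {
  X <- as.matrix(X)
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (ncol(X) < window) stop("spectrum shorter than the filter window")
  out <- t(apply(X, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv))
  out / spacing^deriv
}

#' Finite-difference spectral derivative
#'
#' Central differences scaled by the grid spacing (one-sided differences at
#' the two edge points), the standalone "1st/2nd derivative" pretreatment.
#'
#' @param X numeric matrix, samples in rows.
#' @param order 1 or 2.
#' @param spacing grid spacing in cm^-1.
#' @return derivative matrix, same dimension, units absorbance / cm^-1^order.
#' @export
spectral_derivative <- function(X, order = 1, spacing = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 3) stop("need at least 3 spectral points")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  out <- X
  j <- 2:(p - 1)
  if (order == 1) {
    out[, j] <- (X[, j + 1] - X[, j - 1]) / (2 * spacing)
    out[, 1] <- (X[, 2] - X[, 1]) / spacing
    out[, p] <- (X[, p] - X[, p - 1]) / spacing
  } else {
    out[, j] <- (X[, j + 1] - 2 * X[, j] + X[, j - 1]) / spacing^2
    out[, 1] <- out[, 2]
    out[, p] <- out[, p - 1]
  }
  out
}

#' Pretreatment specification
#'
#' An ordered list of pretreatment steps, applied left to right. Step names:
#' `"none"`, `"msc"`, `"snv"`, `"d1"`, `"d2"` and `"sg(window,polyorder)"`
#' (e.g. `"sg(7,3)"`). Statistics that must be learned on the calibration
#' set only (the MSC reference) are fitted by [preprocess_fit()] and reused
#' on prediction data, so no prediction-set information leaks into the
#' pretreatment.
#'
#' @param steps character vector of step names.
#' @return an object of class `preprocess_spec`.
#' @examples
#' preprocess_spec(c("msc", "d1", "sg(7,3)"))
#' @export
preprocess_spec <- function(steps = "none") {
  parsed <- lapply(steps, function(s) {
    s <- gsub(" ", "", s)
    if (s %in% c("none", "msc", "snv", "d1", "d2"))
      return(list(kind = s))
    m <- regmatches(s, regexec("^sg\\((\\d+),(\\d+)\\)$", s))[[1]]
    if (length(m) == 3)
      return(list(kind = "sg", window = as.integer(m[2]),
                  polyorder = as.integer(m[3])))
    stop("unknown pretreatment step: ", s)
  })
  structure(list(steps = parsed, label = paste(steps, collapse = " + ")),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat("Pretreatment:", x$label, "\n"); invisible(x)
}

#' Fit a pretreatment on a calibration set
#'
#' Applies the steps of a [preprocess_spec()] to the calibration matrix and
#' records any calibration-derived statistics (currently the MSC reference
#' spectrum, taken as the calibration mean at that point of the chain).
#'
#' @param spec a `preprocess_spec` (or character vector of steps).
#' @param X calibration absorbance matrix.
#' @param spacing grid spacing in cm^-1.
#' @return a `preprocess_fit` object holding the transformed calibration
#'   matrix (`$X`) and everything needed by [preprocess_apply()].
#' @export
preprocess_fit <- function(spec, X, spacing = 1) {
  if (!inherits(spec, "preprocess_spec")) spec <- preprocess_spec(spec)
  X <- as.matrix(X)
  refs <- vector("list", length(spec$steps))
  for (k in seq_along(spec$steps)) {
    st <- spec$steps[[k]]
    if (st$kind == "msc") {
      refs[[k]] <- colMeans(X)
      X <- msc(X, refs[[k]])
    } else {
      X <- .apply_step(st, X, spacing, NULL)
    }
  }
  structure(list(spec = spec, refs = refs, spacing = spacing, X = X),
            class = "preprocess_fit")
}

.apply_step <- function(st, X, spacing, msc_ref) {
  switch(st$kind,
         none = X,
         msc = msc(X, msc_ref),
         snv = snv(X),
         d1 = spectral_derivative(X, 1, spacing),
         d2 = spectral_derivative(X, 2, spacing),
         sg = sg_filter(X, st$window, st$polyorder, deriv = 0,
                        spacing = spacing))
}

#' Apply a fitted pretreatment to new spectra
#'
#' @param fit a `preprocess_fit` from [preprocess_fit()].
#' @param X absorbance matrix with the calibration variable count.
#' @return the transformed matrix.
#' @export
preprocess_apply <- function(fit, X) {
  X <- as.matrix(X)
  for (k in seq_along(fit$spec$steps))
    X <- .apply_step(fit$spec$steps[[k]], X, fit$spacing, fit$refs[[k]])
  X
}
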