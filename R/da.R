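#' Principal component decomposition of a spectral matrix
#'
#' Mean-centered PCA via singular value decomposition, with the cumulative
#' percentage of variance captured by the leading components.
#'
#' @param X numeric matrix (n samples x p variables).
#' @param k number of components, `<= min(n - 1, p)`.
#' @return list with `loadings` (p x k, orthonormal), `mean` (p-vector),
#'   `scores` (n x k), `sdev` (component standard deviations),
#'   `explained_pct` (cumulative % of total variance over 1..k) and `k`.
#' @export
pca_fit <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > min(n - 1, ncol(X)))
    stop("k must be <= min(n - 1, p) = ", min(n - 1, ncol(X)))
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = n)
  sv <- svd(Xc, nu = 0, nv = k)
  scores <- Xc %*% sv$v
  ev <- sv$d^2 / (n - 1)                    # all eigenvalues
  total <- sum(ev)
  list(loadings = sv$v, mean = mu, scores = scores,
       sdev = sv$d[seq_len(k)] / sqrt(n - 1),
       explained_pct = 100 * cumsum(ev[seq_len(k)]) / total, k = k)
}

#' Fit a Mahalanobis-distance discriminant model
#'
#' Origin-authentication model: spectra are compressed by PCA on the pooled
#' calibration set, then each class (e.g. LY vs NLY tea) is summarised by
#' the centroid and covariance of its scores. Unknowns are assigned to the
#' class with the smallest Mahalanobis distance from the class centroid.
#' Class covariances are regularised by adding `lambda * trace/k` to the
#' diagonal to guarantee invertibility on small classes.
#'
#' @param X calibration spectra (matrix or `spectral_dataset`; for a
#'   dataset, `labels` defaults to its `class` column). Apply any
#'   pretreatment beforehand (see [preprocess_fit()]).
#' @param labels class label per sample (factor or character).
#' @param k number of principal components retained (default 9).
#' @param pooled use a single pooled within-class covariance instead of
#'   per-class covariances.
#' @param lambda regularisation weight (default 1e-6).
#' @return an object of class `nir_da`: PCA (`loadings`, `mean`, `k`,
#'   `explained_pct`) plus `class_stats`, a per-class list of
#'   `centroid`/`cov`.
#' @export
da_fit <- function(X, labels = NULL, k = 9, pooled = FALSE,
                   lambda = 1e-6) {
  if (inherits(X, "spectral_dataset")) {
    if (is.null(labels)) labels <- X$meta$class
    X <- X$absorbance
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per sample required")
  counts <- table(labels)
  if (any(counts < k + 2))
    stop("every class needs at least k + 2 = ", k + 2, " samples; got: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  pca <- pca_fit(X, k)
  classes <- sort(unique(labels))
  scores <- pca$scores
  regularise <- function(S) {
    S <- S + diag(lambda * sum(diag(S)) / k, k)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("class covariance singular after regularisation")
    S
  }
  if (pooled) {
    pooled_cov <- matrix(0, k, k)
    for (cl in classes) {
      sc <- scores[labels == cl, , drop = FALSE]
      pooled_cov <- pooled_cov +
        crossprod(sc - rep(colMeans(sc), each = nrow(sc)))
    }
    pooled_cov <- regularise(pooled_cov / (nrow(X) - length(classes)))
  }
  class_stats <- lapply(classes, function(cl) {
    sc <- scores[labels == cl, , drop = FALSE]
    list(centroid = colMeans(sc),
         cov = if (pooled) pooled_cov else regularise(stats::cov(sc)))
  })
  names(class_stats) <- classes
  structure(list(loadings = pca$loadings, mean = pca$mean, k = k,
                 explained_pct = pca$explained_pct[k],
                 class_stats = class_stats, classes = classes,
                 pooled = pooled, labels = labels),
            class = "nir_da")
}

#' @export
print.nir_da <- function(x, ...) {
  cat("Mahalanobis-distance discriminant model\n")
  cat(sprintf("  %d PCs (%.2f%% of spectral variance), classes: %s (%s covariance)\n",
              x$k, x$explained_pct, paste(x$classes, collapse = ", "),
              if (x$pooled) "pooled" else "per-class"))
  invisible(x)
}

#' Mahalanobis distance of score vectors to each class
#'
#' d_c = sqrt((s - mu_c)' Sigma_c^-1 (s - mu_c)) for each class c.
#'
#' @param scores matrix of score vectors (rows) or a single k-vector.
#' @param class_stats per-class list of `centroid`/`cov` (as in a
#'   `nir_da` model).
#' @return matrix with one row per score vector, one column per class.
#' @export
mahalanobis_distances <- function(scores, class_stats) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (!all(is.finite(scores))) stop("non-finite score vector")
  out <- sapply(class_stats, function(st) {
    d <- scores - rep(st$centroid, each = nrow(scores))
    sqrt(rowSums(d * t(solve(st$cov, t(d)))))
  })
  matrix(out, nrow = nrow(scores),
         dimnames = list(rownames(scores), names(class_stats)))
}

#' Classify spectra with a discriminant model
#'
#' Projects spectra into the model's PCA score space and assigns each to
#' the class with the smallest Mahalanobis distance. Exact distance ties go
#' deterministically to the lexicographically first class label and are
#' flagged.
#'
#' @param object a `nir_da` model.
#' @param newdata spectra matrix or `spectral_dataset` (same pretreatment
#'   and variable count as the calibration set).
#' @param truth optional true labels; enables the misclassification
#'   summary.
#' @param ... ignored.
#' @return an object of class `da_classification`: data.frame `table`
#'   (sample, assigned class, one distance column per class, tie flag),
#'   and when `truth` is given, `incorrect_by_class` (named vector) and
#'   `pct_correct` (percentage over all samples).
#' @export
predict.nir_da <- function(object, newdata, truth = NULL, ...) {
  if (inherits(newdata, "spectral_dataset")) {
    if (is.null(truth)) truth <- newdata$meta$class
    ids <- newdata$meta$sample_id
    newdata <- newdata$absorbance
  } else ids <- rownames(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean))
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object$mean))
  scores <- (newdata - rep(object$mean, each = nrow(newdata))) %*%
    object$loadings
  D <- mahalanobis_distances(scores, object$class_stats)
  assigned <- object$classes[apply(D, 1, which.min)]  # ties -> first label
  tie <- apply(D, 1, function(d) sum(d == min(d)) > 1)
  tab <- data.frame(sample_id = if (is.null(ids)) seq_len(nrow(D)) else ids,
                    assigned = assigned, tie = tie,
                    stringsAsFactors = FALSE)
  for (cl in object$classes) tab[[paste0("dist_", cl)]] <- D[, cl]
  out <- list(table = tab, classes = object$classes)
  if (!is.null(truth)) {
    truth <- as.character(truth)
    out$table$truth <- truth
    inc <- vapply(object$classes,
                  function(cl) sum(truth == cl & assigned != cl), 0L)
    out$incorrect_by_class <- inc
    out$pct_correct <- 100 * (length(truth) - sum(inc)) / length(truth)
  }
  structure(out, class = "da_classification")
}

#' @export
print.da_classification <- function(x, ...) {
  cat("DA classification of", nrow(x$table), "samples\n")
  if (!is.null(x$pct_correct)) {
    cat("  incorrectly classified:",
        paste(sprintf("%s=%d", names(x$incorrect_by_class),
                      x$incorrect_by_class), collapse = ", "), "\n")
    cat(sprintf("  %% correctly classified: %.2f\n", x$pct_correct))
  }
  invisible(x)
}

#' @export
plot.nir_da <- function(x, newdata = NULL, truth = NULL, ...) {
  if (is.null(newdata)) stop("supply spectra to plot")
  pred <- predict(x, newdata, truth = truth)
  d <- pred$table
  dcols <- paste0("dist_", x$classes[1:2])
  graphics::plot(d[[dcols[1]]], d[[dcols[2]]],
                 col = ifelse(d$assigned == x$classes[1], 1, 2),
                 xlab = paste("distance to", x$classes[1]),
                 ylab = paste("distance to", x$classes[2]),
                 main = "Mahalanobis distances to class centroids", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pred)
}
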