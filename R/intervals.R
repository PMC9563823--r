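#' Equal-width partition of the spectral variable axis
#'
#' Splits `n_vars` consecutive variables (ascending wavenumber order) into
#' `n_intervals` contiguous intervals whose sizes differ by at most one
#' point; when the division is not exact, the leading (low-wavenumber)
#' intervals carry the extra point.
#'
#' @param n_vars number of spectral variables.
#' @param n_intervals number of intervals, `1 <= n_intervals <= n_vars`.
#' @return an object of class `interval_partition`: list with `n_vars`,
#'   `n_intervals` and `bounds`, an n_intervals x 2 matrix of 1-based
#'   first/last variable indices.
#' @examples
#' interval_partition(2075, 20)  # 15 intervals of 104, then 5 of 103
#' @export
interval_partition <- function(n_vars, n_intervals) {
  if (n_intervals < 1 || n_intervals > n_vars)
    stop("n_intervals must be between 1 and n_vars")
  base <- n_vars %/% n_intervals
  extra <- n_vars %% n_intervals
  sizes <- rep(base, n_intervals)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  last <- cumsum(sizes)
  first <- c(1, last[-n_intervals] + 1)
  structure(list(n_vars = n_vars, n_intervals = n_intervals,
                 bounds = cbind(first = first, last = last),
                 sizes = sizes),
            class = "interval_partition")
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("Partition of", x$n_vars, "variables into", x$n_intervals,
      "intervals (sizes", paste(unique(x$sizes), collapse = "/"), ")\n")
  invisible(x)
}

# column indices of a set of intervals
.interval_cols <- function(part, idx) {
  unlist(lapply(idx, function(k) seq(part$bounds[k, 1], part$bounds[k, 2])))
}

#' Wavenumber ranges of a selected interval set
#'
#' Merges adjacent selected intervals and reports the min/max wavenumber of
#' each merged block, the form in which interval selections are usually
#' published.
#'
#' @param selected integer vector of 1-based interval indices.
#' @param partition an [interval_partition()].
#' @param wavenumbers ascending grid the partition refers to.
#' @return list of [wavenumber_range()] objects (empty list for an empty
#'   selection).
#' @export
interval_ranges <- function(selected, partition, wavenumbers) {
  if (length(wavenumbers) != partition$n_vars)
    stop("grid length does not match the partition")
  selected <- sort(unique(as.integer(selected)))
  if (!length(selected)) return(list())
  breaks <- c(0, which(diff(selected) > 1), length(selected))
  out <- list()
  for (g in seq_len(length(breaks) - 1)) {
    block <- selected[(breaks[g] + 1):breaks[g + 1]]
    lo <- wavenumbers[partition$bounds[block[1], 1]]
    hi <- wavenumbers[partition$bounds[block[length(block)], 2]]
    out[[g]] <- wavenumber_range(lo, hi)
  }
  out
}

# LOOCV-score a candidate column set: returns rmsecv at the PRESS-selected
# factor count, plus that count.
.score_cols <- function(X, y, cols, ncomp_max) {
  cv <- pls_loocv(X[, cols, drop = FALSE], y, ncomp_max)
  list(rmsecv = cv$rmsecv[cv$ncomp], ncomp = cv$ncomp)
}

.selection_result <- function(method, selected, part, X, y, ncomp_max,
                              wavenumbers, candidates = NULL,
                              trajectory = NULL) {
  cols <- .interval_cols(part, selected)
  sc <- .score_cols(X, y, cols, ncomp_max)
  structure(list(method = method, selected = sort(selected),
                 n_selected_vars = length(cols), rmsecv = sc$rmsecv,
                 ncomp = sc$ncomp, partition = part,
                 wavenumber_ranges = if (is.null(wavenumbers)) NULL
                   else interval_ranges(selected, part, wavenumbers),
                 candidates = candidates, trajectory = trajectory),
            class = "interval_selection")
}

#' @export
print.interval_selection <- function(x, ...) {
  cat(sprintf("%s selection: intervals {%s} of %d, %d variables, %d factors, RMSECV %.4g\n",
              x$method, paste(x$selected, collapse = ","),
              x$partition$n_intervals, x$n_selected_vars, x$ncomp, x$rmsecv))
  if (!is.null(x$wavenumber_ranges) && length(x$wavenumber_ranges)) {
    cat("  ranges:",
        paste(vapply(x$wavenumber_ranges,
                     function(r) sprintf("%.2f-%.2f", r$low, r$high), ""),
              collapse = ", "), "cm^-1\n")
  }
  invisible(x)
}

#' @export
plot.interval_selection <- function(x, ...) {
  if (!is.null(x$trajectory)) {
    graphics::plot(x$trajectory$n_vars, x$trajectory$rmsecv, type = "b",
                   xlab = "retained variables", ylab = "RMSECV",
                   main = "biPLS elimination trajectory", ...)
    graphics::abline(h = x$rmsecv, lty = 2)
  } else if (!is.null(x$candidates)) {
    graphics::plot(seq_len(nrow(x$candidates)), x$candidates$rmsecv,
                   type = "h", xlab = "interval combination",
                   ylab = "RMSECV", main = "siPLS candidate search", ...)
    graphics::points(which.min(x$candidates$rmsecv), x$rmsecv, pch = 19)
  }
  invisible(x)
}

#' Synergy-interval PLS variable selection
#'
#' Divides the spectrum into `n_intervals` equal-width intervals and
#' exhaustively evaluates every combination of `combo_sizes` intervals: the
#' columns of each combination are concatenated, a PLS model is
#' cross-validated by LOOCV with PRESS-based factor selection, and the
#' combination with the lowest RMSECV wins. Ties are broken toward fewer
#' variables, then the lexicographically smallest interval index set.
#'
#' @param X predictor matrix (or `spectral_dataset` with `y` a column name),
#'   columns in ascending wavenumber order.
#' @param y response vector or reference column name.
#' @param n_intervals number of equal-width intervals (10 or 20 typically).
#' @param combo_sizes sizes of interval combinations to enumerate
#'   (subset of 2:4). Default: 2 and 3 intervals for a 20-interval split,
#'   3 and 4 for a 10-interval split.
#' @param ncomp_max largest factor count examined per candidate.
#' @param wavenumbers optional grid for reporting wavenumber ranges.
#' @return an `interval_selection` object; `$candidates` is a data.frame
#'   with one row per evaluated combination (intervals, n_vars, factors,
#'   rmsecv).
#' @export
sipls <- function(X, y, n_intervals = 20, combo_sizes = NULL,
                  ncomp_max = 10, wavenumbers = NULL) {
  if (inherits(X, "spectral_dataset")) {
    if (is.null(wavenumbers)) wavenumbers <- X$wavenumbers
    if (is.character(y)) y <- X$meta[[y]]
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  if (is.null(combo_sizes))
    combo_sizes <- if (n_intervals >= 20) c(2L, 3L) else c(3L, 4L)
  if (!all(combo_sizes %in% 2:4)) stop("combo_sizes must lie in 2:4")
  part <- interval_partition(ncol(X), n_intervals)
  rows <- list()
  best <- NULL
  for (sz in sort(combo_sizes)) {
    combos <- utils::combn(n_intervals, sz)
    for (j in seq_len(ncol(combos))) {
      sel <- combos[, j]
      cols <- .interval_cols(part, sel)
      sc <- .score_cols(X, y, cols, ncomp_max)
      rows[[length(rows) + 1]] <- data.frame(
        intervals = paste(sel, collapse = "+"), n_vars = length(cols),
        factors = sc$ncomp, rmsecv = sc$rmsecv)
      cand <- list(sel = sel, n_vars = length(cols), rmsecv = sc$rmsecv)
      if (is.null(best) || .cand_better(cand, best)) best <- cand
    }
  }
  res <- .selection_result("siPLS", best$sel, part, X, y, ncomp_max,
                           wavenumbers, candidates = do.call(rbind, rows))
  res
}

# deterministic ordering: lower rmsecv, then fewer variables, then
# lexicographically smaller index set
.cand_better <- function(a, b) {
  if (a$rmsecv != b$rmsecv) return(a$rmsecv < b$rmsecv)
  if (a$n_vars != b$n_vars) return(a$n_vars < b$n_vars)
  if (length(a$sel) != length(b$sel)) return(length(a$sel) < length(b$sel))
  d <- which(a$sel != b$sel)
  length(d) > 0 && a$sel[d[1]] < b$sel[d[1]]
}

#' Backward-interval PLS variable selection
#'
#' Starting from all `n_intervals` equal-width intervals, repeatedly
#' removes the interval whose exclusion gives the lowest cross-validated
#' RMSECV (i.e. rejects the least informative interval each round), down to
#' a single interval. The retained set with the lowest RMSECV anywhere
#' along the trajectory (including the full spectrum) is returned.
#'
#' @inheritParams sipls
#' @return an `interval_selection` object; `$trajectory` is a data.frame
#'   with one row per elimination step (removed interval, remaining set,
#'   n_vars, factors, rmsecv).
#' @export
bipls <- function(X, y, n_intervals = 20, ncomp_max = 10,
                  wavenumbers = NULL) {
  if (inherits(X, "spectral_dataset")) {
    if (is.null(wavenumbers)) wavenumbers <- X$wavenumbers
    if (is.character(y)) y <- X$meta[[y]]
    X <- X$absorbance
  }
  X <- as.matrix(X); y <- as.numeric(y)
  if (n_intervals < 2) stop("need at least 2 intervals")
  part <- interval_partition(ncol(X), n_intervals)
  remaining <- seq_len(n_intervals)
  sc0 <- .score_cols(X, y, .interval_cols(part, remaining), ncomp_max)
  traj <- list(data.frame(removed = NA_integer_,
                          remaining = paste(remaining, collapse = "+"),
                          n_vars = part$n_vars, factors = sc0$ncomp,
                          rmsecv = sc0$rmsecv))
  best_set <- remaining; best_rmsecv <- sc0$rmsecv
  while (length(remaining) > 1) {
    step_best <- NULL
    for (k in remaining) {
      keep <- setdiff(remaining, k)
      sc <- .score_cols(X, y, .interval_cols(part, keep), ncomp_max)
      cand <- list(k = k, keep = keep, rmsecv = sc$rmsecv, ncomp = sc$ncomp,
                   n_vars = length(.interval_cols(part, keep)))
      if (is.null(step_best) || cand$rmsecv < step_best$rmsecv ||
          (cand$rmsecv == step_best$rmsecv && cand$k < step_best$k))
        step_best <- cand
    }
    remaining <- step_best$keep
    traj[[length(traj) + 1]] <- data.frame(
      removed = step_best$k, remaining = paste(remaining, collapse = "+"),
      n_vars = step_best$n_vars, factors = step_best$ncomp,
      rmsecv = step_best$rmsecv)
    if (step_best$rmsecv < best_rmsecv) {
      best_rmsecv <- step_best$rmsecv
      best_set <- remaining
    }
  }
  .selection_result("biPLS", best_set, part, X, y, ncomp_max, wavenumbers,
                    trajectory = do.call(rbind, traj))
}
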