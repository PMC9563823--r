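#' Construct a spectral dataset
#'
#' Bundles a wavenumber grid, an absorbance matrix (log 1/R units) and
#' per-sample metadata into a single object. The wavenumber grid is stored in
#' canonical ascending order; descending (FTIR-convention) input is reversed
#' together with the corresponding absorbance columns.
#'
#' @param wavenumbers numeric vector, strictly monotonic grid in cm^-1.
#' @param absorbance numeric matrix, one row per sample, one column per grid
#'   point.
#' @param meta data.frame with one row per sample. Must contain `sample_id`;
#'   recognised columns are `origin`, `class` (e.g. "LY"/"NLY"), `tp`
#'   (total polyphenols, mg GAE/g), `faa` (free amino acids, mg TE/g) and
#'   `tp_faa` (their ratio, computed from `tp`/`faa` when absent).
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavenumbers`, `absorbance` (rownames = sample ids) and `meta`.
#' @export
spectral_dataset <- function(wavenumbers, absorbance, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) != ncol(absorbance))
    stop("length(wavenumbers) must equal ncol(absorbance)")
  dw <- diff(wavenumbers)
  if (length(dw) && !(all(dw > 0) || all(dw < 0)))
    stop("wavenumber grid must be strictly monotonic")
  if (length(dw) && all(dw < 0)) {        # descending input: normalize
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  if (!is.data.frame(meta) || is.null(meta$sample_id))
    stop("meta must be a data.frame with a sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (nrow(meta) != nrow(absorbance))
    stop("metadata row count (", nrow(meta),
         ") does not match absorbance row count (", nrow(absorbance), ")")
  if (anyNA(absorbance)) stop("absorbance matrix contains missing values")
  if (!is.null(meta$tp) && !is.null(meta$faa)) {
    ratio <- meta$tp / meta$faa
    if (is.null(meta$tp_faa)) {
      meta$tp_faa <- ratio
    } else {
      both <- !is.na(meta$tp_faa) & !is.na(ratio)
      bad <- both & abs(meta$tp_faa - ratio) > 1e-9 * pmax(abs(ratio), 1)
      if (any(bad))
        stop("tp_faa inconsistent with tp/faa for sample(s): ",
             paste(meta$sample_id[bad], collapse = ", "))
    }
  }
  rownames(absorbance) <- meta$sample_id
  colnames(absorbance) <- NULL
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("Spectral dataset:", nrow(x$absorbance), "samples x",
      length(x$wavenumbers), "wavenumbers\n")
  cat(sprintf("  grid: %.2f to %.2f cm^-1 (ascending)\n",
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.null(x$meta$class))
    print(table(class = x$meta$class))
  ref <- intersect(c("tp", "faa", "tp_faa"), names(x$meta))
  if (length(ref))
    cat("  reference chemistry:", paste(ref, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / variables of a spectral dataset
#' @param x a `spectral_dataset`.
#' @return `dim` returns c(n_samples, n_wavenumbers).
#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

#' Subset samples of a spectral dataset
#' @param x a `spectral_dataset`.
#' @param i sample index (logical, integer or character ids).
#' @param ... ignored.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$sample_id)
  spectral_dataset(x$wavenumbers, x$absorbance[i, , drop = FALSE],
                   x$meta[i, , drop = FALSE])
}

#' Read spectra and reference chemistry from delimited text
#'
#' The spectra file has a `sample_id` first column and numeric wavenumber
#' column headers (ascending or descending); the reference file has columns
#' `sample_id, origin, class, tp, faa[, tp_faa]`. Rows are joined by id;
#' `tp_faa` is computed as tp/faa when absent.
#'
#' @param spectra_path path to the spectra CSV.
#' @param reference_path path to the reference CSV (optional; `NULL` for
#'   spectra-only datasets).
#' @return a [spectral_dataset()].
#' @export
read_dataset <- function(spectra_path, reference_path = NULL) {
  sp <- utils::read.csv(spectra_path, check.names = FALSE,
                        colClasses = "character")
  if (names(sp)[1] != "sample_id")
    stop("first column of the spectra file must be 'sample_id'")
  wn <- suppressWarnings(as.numeric(names(sp)[-1]))
  if (anyNA(wn)) stop("non-numeric wavenumber header in ", spectra_path)
  vals <- suppressWarnings(vapply(sp[-1], as.numeric, numeric(nrow(sp))))
  vals <- matrix(vals, nrow = nrow(sp))
  if (anyNA(vals)) stop("non-numeric absorbance cells in ", spectra_path)
  ids <- sp$sample_id
  if (is.null(reference_path)) {
    meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  } else {
    meta <- utils::read.csv(reference_path, stringsAsFactors = FALSE)
    if (is.null(meta$sample_id))
      stop("reference file must have a sample_id column")
    meta$sample_id <- as.character(meta$sample_id)
    missing_ids <- setdiff(ids, meta$sample_id)
    if (length(missing_ids))
      stop("sample id(s) missing from reference file: ",
           paste(missing_ids, collapse = ", "))
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    num_cols <- intersect(c("tp", "faa", "tp_faa"), names(meta))
    for (cc in num_cols) {
      if (anyNA(suppressWarnings(as.numeric(meta[[cc]]))) &&
          !anyNA(meta[[cc]]))
        stop("non-numeric values in reference column ", cc)
      meta[[cc]] <- as.numeric(meta[[cc]])
      if (anyNA(meta[[cc]]))
        stop("missing ", cc, " for sample(s): ",
             paste(meta$sample_id[is.na(meta[[cc]])], collapse = ", "))
    }
    rownames(meta) <- NULL
  }
  spectral_dataset(wn, vals, meta)
}

#' Write a spectral dataset to delimited text
#'
#' Emits the CSV dialect read by [read_dataset()]: UTF-8, '.' decimal
#' separator, full-precision numbers so that read -> write -> read
#' round-trips exactly.
#'
#' @param ds a `spectral_dataset`.
#' @param spectra_path output path for the spectra table.
#' @param reference_path optional output path for the reference table.
#' @param descending write columns in descending (FTIR display) order.
#' @return invisibly, `ds`.
#' @export
write_dataset <- function(ds, spectra_path, reference_path = NULL,
                          descending = FALSE) {
  wn <- ds$wavenumbers
  ab <- ds$absorbance
  if (descending) {
    idx <- rev(seq_along(wn))
    wn <- wn[idx]; ab <- ab[, idx, drop = FALSE]
  }
  fmt <- function(v) sprintf("%.17g", v)
  header <- paste(c("sample_id", fmt(wn)), collapse = ",")
  rows <- vapply(seq_len(nrow(ab)), function(i)
    paste(c(ds$meta$sample_id[i], fmt(ab[i, ])), collapse = ","), "")
  writeLines(c(header, rows), spectra_path, useBytes = TRUE)
  if (!is.null(reference_path)) {
    m <- ds$meta
    out <- data.frame(sample_id = m$sample_id, stringsAsFactors = FALSE)
    for (cc in c("origin", "class")) if (!is.null(m[[cc]])) out[[cc]] <- m[[cc]]
    for (cc in c("tp", "faa", "tp_faa"))
      if (!is.null(m[[cc]])) out[[cc]] <- fmt(m[[cc]])
    utils::write.csv(out, reference_path, row.names = FALSE, quote = FALSE)
  }
  invisible(ds)
}

#' Standard FT-NIR wavenumber grid
#'
#' Builds the ascending grid `start, start + spacing, ...` up to the largest
#' point not exceeding `upper_limit`. The default arguments give the
#' 2075-point 12,000-4000 cm^-1 grid of an FT spectrum digitised at
#' 3.857 cm^-1 point spacing (8 cm^-1 instrument resolution).
#'
#' @param start first (lowest) wavenumber, cm^-1.
#' @param spacing grid spacing, cm^-1 (> 0).
#' @param upper_limit largest admissible wavenumber, cm^-1.
#' @return numeric ascending grid.
#' @examples
#' length(standard_grid())  # 2075
#' @export
standard_grid <- function(start = 3999.70, spacing = 3.857,
                          upper_limit = 12000) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (start >= upper_limit) stop("start must be below upper_limit")
  n <- floor((upper_limit - start) / spacing + 1e-9) + 1
  start + spacing * (seq_len(n) - 1)
}

#' Wavenumber range
#'
#' @param low,high range endpoints in cm^-1, `low < high`.
#' @return an object of class `wavenumber_range`.
#' @export
wavenumber_range <- function(low, high) {
  if (!(low < high)) stop("low must be < high")
  structure(list(low = low, high = high), class = "wavenumber_range")
}

#' @export
print.wavenumber_range <- function(x, ...) {
  cat(sprintf("%.2f-%.2f cm^-1\n", x$low, x$high)); invisible(x)
}

.as_range_list <- function(ranges) {
  if (inherits(ranges, "wavenumber_range")) return(list(ranges))
  lapply(ranges, function(r) {
    if (inherits(r, "wavenumber_range")) r
    else if (is.numeric(r) && length(r) == 2) wavenumber_range(r[1], r[2])
    else stop("each range must be a wavenumber_range or numeric length-2")
  })
}

#' Select spectral variables by wavenumber ranges
#'
#' Keeps the columns whose wavenumber lies in any of the given ranges.
#' Membership is endpoint-inclusive with a 0.02 cm^-1 tolerance, because
#' published range boundaries are rounded to two decimals.
#'
#' @param ds a `spectral_dataset`.
#' @param ranges a `wavenumber_range`, a list of them, or a list of
#'   numeric `c(low, high)` pairs.
#' @param tol boundary tolerance in cm^-1.
#' @return a `spectral_dataset` restricted to the selected columns.
#' @export
subset_by_ranges <- function(ds, ranges, tol = 0.02) {
  ranges <- .as_range_list(ranges)
  keep <- rep(FALSE, length(ds$wavenumbers))
  for (r in ranges)
    keep <- keep | (ds$wavenumbers >= r$low - tol &
                    ds$wavenumbers <= r$high + tol)
  if (!any(keep)) stop("no wavenumbers fall inside the requested ranges")
  spectral_dataset(ds$wavenumbers[keep],
                   ds$absorbance[, keep, drop = FALSE], ds$meta)
}
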