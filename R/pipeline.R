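#' Calibration / prediction split plan
#'
#' Splits a dataset into a calibration and a prediction set following the
#' usual NIR calibration rules: (1) the samples carrying the minimum and
#' maximum of each reference quantity (TP, FAA, TP/FAA) are forced into
#' the calibration set, so predictions never extrapolate; (2) every
#' collection origin is represented in both sets where its sample count
#' permits; (3) the calibration fraction is honoured to rounding (nearest
#' integer, ties upward). The random fill is stratified by origin and
#' fully determined by the seed.
#'
#' @param ds a [spectral_dataset()] with reference values and origins.
#' @param fraction calibration fraction (default 0.75).
#' @param seed integer seed for the stratified random fill.
#' @return an object of class `split_plan`: list with `calibration` and
#'   `prediction` (character sample ids) and `assignments` (named vector).
#' @export
split_calibration <- function(ds, fraction = 0.75, seed = 1L) {
  meta <- ds$meta
  n <- nrow(meta)
  n_cal <- floor(n * fraction + 0.5)         # round half up
  forced <- character(0)
  for (cc in intersect(c("tp", "faa", "tp_faa"), names(meta))) {
    v <- meta[[cc]]
    forced <- c(forced, meta$sample_id[which.min(v)],
                meta$sample_id[which.max(v)])
  }
  forced <- unique(forced)
  if (length(forced) > n_cal)
    stop("calibration fraction too small to hold the extreme samples")
  origin <- if (is.null(meta$origin)) rep("all", n) else meta$origin
  singletons <- names(table(origin))[table(origin) == 1]
  if (length(singletons))
    warning("origin(s) with a single sample assigned to calibration: ",
            paste(singletons, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cal <- forced
  # one random calibration and (capacity permitting) one prediction sample
  # per origin, so both sets cover every origin
  for (og in unique(origin)) {
    ids <- meta$sample_id[origin == og]
    if (!any(ids %in% cal) && length(cal) < n_cal)
      cal <- c(cal, sample(ids, 1))
  }
  pred_reserved <- character(0)
  for (og in unique(origin)) {
    ids <- setdiff(meta$sample_id[origin == og], cal)
    if (length(ids) && (n - n_cal) > length(pred_reserved))
      pred_reserved <- c(pred_reserved, sample(ids, 1))
  }
  pool <- setdiff(meta$sample_id, c(cal, pred_reserved))
  need <- n_cal - length(cal)
  if (need > 0) cal <- c(cal, sample(pool, need))
  pred <- setdiff(meta$sample_id, cal)
  assignments <- stats::setNames(
    ifelse(meta$sample_id %in% cal, "calibration", "prediction"),
    meta$sample_id)
  structure(list(calibration = meta$sample_id[meta$sample_id %in% cal],
                 prediction = pred, fraction = fraction, seed = seed,
                 assignments = assignments),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", length(x$calibration), "calibration /",
      length(x$prediction), "prediction samples (fraction",
      x$fraction, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Default experiment grid
#'
#' The pretreatment-by-wavenumber-range grid of the tea study: seven
#' pretreatments (none, MSC, SNV, 1st and 2nd derivative, and
#' MSC/SNV + 1st derivative + SG(7,3) smoothing) crossed with the full
#' 12,000-4000 cm^-1 range, the manually selected 8000-4000 cm^-1 range
#' (range 1) and the three-segment 9700-8600 + 7400-6800 + 5600-4000
#' cm^-1 range (range 2).
#'
#' @return list with `preprocess` (named list of step-name vectors) and
#'   `ranges` (named list of range lists).
#' @export
default_grid <- function() {
  list(preprocess = list(
         none = "none",
         msc = "msc",
         snv = "snv",
         d1 = "d1",
         d2 = "d2",
         msc_d1_sg = c("msc", "d1", "sg(7,3)"),
         snv_d1_sg = c("snv", "d1", "sg(7,3)")),
       ranges = list(
         full = list(c(3999.70, 12000)),
         range1 = list(c(3999.70, 8000)),
         range2 = list(c(3999.70, 5600), c(6800, 7400), c(8600, 9700))))
}

#' Run the authentication / prediction experiment grid
#'
#' Evaluates every combination of pretreatment and wavenumber range on a
#' split dataset: a Mahalanobis-DA classification block (when class labels
#' are present), a PLS block per response, and optionally an interval
#' selection block (full-spectrum PLS vs siPLS vs biPLS). Every
#' pretreatment statistic and every model parameter is learned on the
#' calibration set only.
#'
#' @param ds a [spectral_dataset()].
#' @param plan a [split_calibration()] plan.
#' @param preprocess named list of pretreatment step vectors (default: the
#'   seven pretreatments of [default_grid()]).
#' @param ranges named list of wavenumber range lists.
#' @param responses reference columns to model (default: those present
#'   among tp, faa, tp_faa).
#' @param models character subset of c("DA", "PLS", "siPLS", "biPLS").
#' @param ncomp_max largest PLS factor count examined.
#' @param k_da number of PCs in the DA models.
#' @param n_intervals intervals for siPLS/biPLS (run on the full range and
#'   the `none` pretreatment only).
#' @return list of data.frames: `da` (pretreatment x range classification
#'   summary), `pls` (pretreatment x range x response metrics) and
#'   `selection` (full/siPLS/biPLS rows per response), as present.
#' @export
run_experiments <- function(ds, plan,
                            preprocess = default_grid()$preprocess,
                            ranges = default_grid()$ranges,
                            responses = intersect(c("tp", "faa", "tp_faa"),
                                                  names(ds$meta)),
                            models = c("DA", "PLS"),
                            ncomp_max = 10, k_da = 9, n_intervals = 20) {
  cal <- ds[plan$calibration]
  pred <- ds[plan$prediction]
  da_rows <- list(); pls_rows <- list(); sel_rows <- list()
  for (rg in names(ranges)) {
    cal_r <- subset_by_ranges(cal, ranges[[rg]])
    pred_r <- subset_by_ranges(pred, ranges[[rg]])
    spacing <- stats::median(diff(cal_r$wavenumbers))
    for (pp in names(preprocess)) {
      fit_pp <- tryCatch(
        preprocess_fit(preprocess[[pp]], cal_r$absorbance, spacing),
        error = function(e) e)
      if (inherits(fit_pp, "error")) {
        warning("pretreatment ", pp, " on range ", rg, " failed: ",
                conditionMessage(fit_pp))
        next
      }
      Xc <- fit_pp$X
      Xp <- preprocess_apply(fit_pp, pred_r$absorbance)
      if ("DA" %in% models && !is.null(ds$meta$class)) {
        da <- da_fit(Xc, cal_r$meta$class, k = k_da)
        all_cls <- predict(da, rbind(Xc, Xp),
                           truth = c(cal_r$meta$class, pred_r$meta$class))
        held <- predict(da, Xp, truth = pred_r$meta$class)
        da_rows[[length(da_rows) + 1]] <- data.frame(
          range = rg, pretreatment = pp, factors = k_da,
          pct_variability = da$explained_pct,
          t(da_incorrect(all_cls)),
          pct_correct_all = all_cls$pct_correct,
          pct_correct_heldout = held$pct_correct)
      }
      if ("PLS" %in% models) {
        for (resp in responses) {
          y_c <- cal_r$meta[[resp]]; y_p <- pred_r$meta[[resp]]
          cv <- pls_loocv(Xc, y_c, ncomp_max)
          m <- pls_fit(Xc, y_c, cv$ncomp)
          met <- pls_evaluate(m, Xc, y_c, Xp, y_p, cv)
          pls_rows[[length(pls_rows) + 1]] <- data.frame(
            range = rg, pretreatment = pp, response = resp,
            factors = met$ncomp, r_c = met$r_c, rmsec = met$rmsec,
            rmsecv = met$rmsecv, r_p = met$r_p, rmsep = met$rmsep,
            rpd = met$rpd)
        }
      }
    }
  }
  if (any(c("siPLS", "biPLS") %in% models)) {
    full_cal <- cal; full_pred <- pred
    for (resp in responses) {
      y_c <- full_cal$meta[[resp]]; y_p <- full_pred$meta[[resp]]
      Xc <- full_cal$absorbance; Xp <- full_pred$absorbance
      cv <- pls_loocv(Xc, y_c, ncomp_max)
      m <- pls_fit(Xc, y_c, cv$ncomp)
      met <- pls_evaluate(m, Xc, y_c, Xp, y_p, cv)
      sel_rows[[length(sel_rows) + 1]] <- data.frame(
        method = "Full", response = resp, variables = ncol(Xc),
        factors = met$ncomp, r_c = met$r_c, rmsec = met$rmsec,
        rmsecv = met$rmsecv, r_p = met$r_p, rmsep = met$rmsep,
        rpd = met$rpd)
      sels <- list()
      if ("siPLS" %in% models)
        sels$siPLS <- sipls(Xc, y_c, n_intervals, ncomp_max = ncomp_max,
                            wavenumbers = full_cal$wavenumbers)
      if ("biPLS" %in% models)
        sels$biPLS <- bipls(Xc, y_c, n_intervals, ncomp_max = ncomp_max,
                            wavenumbers = full_cal$wavenumbers)
      for (nm in names(sels)) {
        s <- sels[[nm]]
        cols <- .interval_cols(s$partition, s$selected)
        m2 <- pls_fit(Xc[, cols, drop = FALSE], y_c, s$ncomp)
        met2 <- pls_evaluate(m2, Xc[, cols, drop = FALSE], y_c,
                             Xp[, cols, drop = FALSE], y_p)
        sel_rows[[length(sel_rows) + 1]] <- data.frame(
          method = nm, response = resp, variables = s$n_selected_vars,
          factors = s$ncomp, r_c = met2$r_c, rmsec = met2$rmsec,
          rmsecv = s$rmsecv, r_p = met2$r_p, rmsep = met2$rmsep,
          rpd = met2$rpd)
      }
    }
  }
  out <- list()
  if (length(da_rows)) out$da <- do.call(rbind, da_rows)
  if (length(pls_rows)) out$pls <- do.call(rbind, pls_rows)
  if (length(sel_rows)) out$selection <- do.call(rbind, sel_rows)
  out
}

# per-class incorrect counts as a named integer vector
da_incorrect <- function(cls) {
  v <- cls$incorrect_by_class
  stats::setNames(as.integer(v), paste0("incorrect_", names(v)))
}
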