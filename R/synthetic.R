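#' Pure-component NIR spectra of the tea matrix
#'
#' Gaussian-band models of the four spectral components mixed by the
#' generator: water (O-H combination bands near 5160 and 7000 cm^-1),
#' polyphenols (C-H combination region 4800-4000 cm^-1 and the weak C-H
#' stretch region 8600-8000 cm^-1), free amino acids (N-H bands near 4650
#' and 6700 cm^-1, N-H co-frequency near 5000 cm^-1), the bulk
#' carbohydrate/protein matrix (C-H first overtone near 5780 cm^-1 and
#' broad background), and an origin-marker profile: the region-specific
#' secondary-metabolite signature that lets spectra separate two origins
#' even when their bulk TP/FAA chemistry overlaps. Band positions follow
#' the usual NIR assignments for green tea; widths (Gaussian sigma,
#' 45-250 cm^-1) and heights are synthetic values scaled so mixed spectra
#' span roughly 0.1-1.2 log(1/R).
#'
#' @param grid wavenumber grid (cm^-1) on which to evaluate the spectra.
#' @return matrix with one column per component (`water`, `polyphenol`,
#'   `amino_acid`, `ch_matrix`, `origin_marker`), rows = grid points;
#'   absorbance per unit mass fraction.
#' @export
component_spectra <- function(grid = standard_grid()) {
  bands <- list(
    water      = cbind(center = c(5160, 7000),
                       width  = c(90, 130),
                       height = c(8.0, 4.0)),
    polyphenol = cbind(center = c(4258, 4327, 4440, 8300),
                       width  = c(45, 45, 90, 250),
                       height = c(1.2, 1.2, 1.5, 0.5)),
    amino_acid = cbind(center = c(4650, 5000, 6700),
                       width  = c(70, 100, 130),
                       height = c(3.0, 2.0, 1.6)),
    ch_matrix  = cbind(center = c(4380, 5780, 8450, 5500),
                       width  = c(110, 100, 250, 1500),
                       height = c(0.9, 0.8, 0.3, 0.45)),
    origin_marker = cbind(center = c(5300, 7100, 8900),
                          width  = c(90, 100, 120),
                          height = c(2.5, 1.5, 2.0)))
  out <- sapply(bands, function(B)
    rowSums(sapply(seq_len(nrow(B)), function(i)
      B[i, "height"] * exp(-0.5 * ((grid - B[i, "center"]) / B[i, "width"])^2))))
  rownames(out) <- NULL
  out
}

#' Simulation configuration for synthetic tea spectra
#'
#' Default study conditions: 56 authentic (LY) and 30 non-authentic (NLY)
#' samples on the 2075-point 12,000-4000 cm^-1 grid. LY samples carry more
#' polyphenols and fewer free amino acids than NLY on average, and the two
#' origins differ slightly in bulk matrix composition; concentration
#' magnitudes are synthetic values typical of green tea (TP 200-300
#' mg GAE/g, FAA 30-70 mg TE/g), not measured ones. Scatter follows the
#' usual diffuse-reflectance model: per-sample multiplicative factor
#' b ~ lognormal(0, sigma_b), additive offset a ~ N(0, sigma_a), a random
#' linear baseline tilt, and iid Gaussian absorbance noise.
#'
#' @param n_ly,n_nly samples per class.
#' @param grid wavenumber grid.
#' @param tp_mean,tp_sd named c(LY=, NLY=) TP means/sds, mg GAE/g.
#' @param faa_mean,faa_sd named c(LY=, NLY=) FAA means/sds, mg TE/g.
#' @param matrix_mean,matrix_sd named c(LY=, NLY=) bulk-matrix mass
#'   fractions.
#' @param marker_mean,marker_sd named c(LY=, NLY=) mass fractions of the
#'   origin-marker metabolite profile; the class difference carries the
#'   spectral origin signature that authentication exploits.
#' @param water_mean,water_sd moisture mass fraction (4-7% typical for dry
#'   leaf).
#' @param sigma_b lognormal sdlog of the multiplicative scatter factor.
#' @param sigma_a sd of the additive offset, absorbance units.
#' @param sigma_tilt sd of the baseline tilt amplitude at the grid ends,
#'   absorbance units.
#' @param noise_sd iid absorbance noise sd.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_ly = 56, n_nly = 30, grid = standard_grid(),
                       tp_mean = c(LY = 250, NLY = 225),
                       tp_sd = c(LY = 25, NLY = 25),
                       faa_mean = c(LY = 45, NLY = 55),
                       faa_sd = c(LY = 8, NLY = 8),
                       matrix_mean = c(LY = 0.70, NLY = 0.64),
                       matrix_sd = c(LY = 0.015, NLY = 0.015),
                       marker_mean = c(LY = 0.014, NLY = 0.004),
                       marker_sd = c(LY = 0.002, NLY = 0.002),
                       water_mean = 0.055, water_sd = 0.006,
                       sigma_b = 0.08, sigma_a = 0.02,
                       sigma_tilt = 0.02, noise_sd = 0.004,
                       seed = 1L) {
  stopifnot(n_ly > 0, n_nly > 0, all(tp_mean > 0), all(faa_mean > 0),
            sigma_b >= 0, sigma_a >= 0, sigma_tilt >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic tea NIR dataset with known ground truth
#'
#' Draws per-sample concentrations from the class-conditional
#' distributions of the configuration, forms each clean spectrum as the
#' Beer-Lambert mixture of the [component_spectra()], then applies the
#' scatter model `a + b * (clean + tilt) + noise`. Fully reproducible from
#' the configuration seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [spectral_dataset()] whose reference
#'   table holds the drawn TP/FAA and their ratio) and `truth` (per-sample
#'   scatter parameters `a`, `b`, `tilt`, mass fractions, and the clean
#'   mixture spectra as matrix `clean`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  grid <- config$grid
  comps <- component_spectra(grid)
  n <- config$n_ly + config$n_nly
  cls <- c(rep("LY", config$n_ly), rep("NLY", config$n_nly))
  # several collection origins per class, as in a multi-origin survey
  origin <- c(paste0("LY_origin_", 1 + (seq_len(config$n_ly) - 1) %% 4),
              paste0("NLY_origin_", 1 + (seq_len(config$n_nly) - 1) %% 3))
  tp <- stats::rnorm(n, config$tp_mean[cls], config$tp_sd[cls])
  faa <- stats::rnorm(n, config$faa_mean[cls], config$faa_sd[cls])
  tp <- pmax(tp, 50); faa <- pmax(faa, 10)   # keep chemistry physical
  mat <- pmax(stats::rnorm(n, config$matrix_mean[cls],
                           config$matrix_sd[cls]), 0.3)
  mark <- pmax(stats::rnorm(n, config$marker_mean[cls],
                            config$marker_sd[cls]), 0)
  wat <- pmax(stats::rnorm(n, config$water_mean, config$water_sd), 0.01)
  conc <- cbind(water = wat, polyphenol = tp / 1000,
                amino_acid = faa / 1000, ch_matrix = mat,
                origin_marker = mark)
  clean <- conc %*% t(comps)                 # n x p mixtures
  b <- stats::rlnorm(n, 0, config$sigma_b)
  a <- stats::rnorm(n, 0, config$sigma_a)
  tilt_amp <- stats::rnorm(n, 0, config$sigma_tilt)
  tilt_shape <- (grid - mean(grid)) / (diff(range(grid)) / 2)
  noise <- matrix(stats::rnorm(n * length(grid), 0, config$noise_sd),
                  n, length(grid))
  absorb <- a + b * (clean + outer(tilt_amp, tilt_shape)) + noise
  ids <- sprintf("%s_%03d", cls, seq_len(n))
  meta <- data.frame(sample_id = ids, origin = origin, class = cls,
                     tp = tp, faa = faa, stringsAsFactors = FALSE)
  ds <- spectral_dataset(grid, absorb, meta)
  truth <- data.frame(sample_id = ids, a = a, b = b, tilt = tilt_amp,
                      water = wat, polyphenol = tp / 1000,
                      amino_acid = faa / 1000, ch_matrix = mat,
                      origin_marker = mark, stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth, clean = clean)
}

#' Synthetic dataset with a single informative spectral interval
#'
#' Harness for validating interval selection: the response depends only on
#' the absorbance inside `informative_band`; every other column is
#' independent noise, so a correct interval search must recover the band's
#' interval.
#'
#' @param informative_band a [wavenumber_range()] (or `c(low, high)`)
#'   inside the grid.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @param grid wavenumber grid (default: the standard 2075-point grid).
#' @param y_noise_sd sd of the noise added to the response.
#' @return list with `dataset` (a `spectral_dataset` whose meta carries the
#'   response as column `y`), `band_cols` (the informative column indices)
#'   and `weights` (the true regression weights on those columns).
#' @export
planted_interval_dataset <- function(informative_band, n = 60, seed = 1L,
                                     grid = standard_grid(),
                                     y_noise_sd = 0.1) {
  if (is.numeric(informative_band) && length(informative_band) == 2)
    informative_band <- wavenumber_range(informative_band[1],
                                         informative_band[2])
  if (informative_band$low < min(grid) - 0.02 ||
      informative_band$high > max(grid) + 0.02)
    stop("informative band lies outside the grid")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  p <- length(grid)
  X <- matrix(stats::rnorm(n * p), n, p)
  cols <- which(grid >= informative_band$low - 0.02 &
                grid <= informative_band$high + 0.02)
  if (!length(cols)) stop("informative band contains no grid points")
  w <- rep(1 / sqrt(length(cols)), length(cols))
  y <- as.vector(X[, cols, drop = FALSE] %*% w) +
    stats::rnorm(n, 0, y_noise_sd)
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), y = y,
                     stringsAsFactors = FALSE)
  list(dataset = spectral_dataset(grid, X, meta), band_cols = cols,
       weights = w)
}
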