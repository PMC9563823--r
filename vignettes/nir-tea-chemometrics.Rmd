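---
title: "NIR chemometrics for tea: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIR chemometrics for tea: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirtea)
```

## The problem

Green teas of protected geographical origin command a price premium and
attract imitation. Diffuse-reflectance near-infrared (NIR) spectra of ground
leaf, recorded as log(1/R) over 12,000-4000 cm^-1, carry overtone and
combination bands of the O-H, C-H and N-H groups of water, polyphenols,
free amino acids and the bulk leaf matrix. Two tasks follow from this:

1. **Authentication** — decide whether a sample belongs to the protected
   origin (class LY) or not (NLY), from the spectrum alone.
2. **Taste-indicator prediction** — estimate total polyphenols (TP, mg
   gallic-acid equivalents per g), total free amino acids (FAA, mg theanine
   equivalents per g) and their ratio TP/FAA, the standard chemical proxies
   for astringency, umami and their balance.

The package implements the full modelling chain for both tasks, plus a
ground-truth synthetic spectra generator so that every stage can be
validated without access to proprietary spectra.

## Data model

A `spectral_dataset` couples a strictly monotonic wavenumber grid, an
absorbance matrix and a per-sample reference table (id, origin, class, TP,
FAA, TP/FAA). Internally the grid is always ascending; descending
FTIR-convention files are normalised on input and can be written on output.
The standard grid is `standard_grid()`: 2075 points from 3999.70 cm^-1 in
steps of 3.857 cm^-1 (the digital point spacing of an FT spectrum acquired
at 8 cm^-1 resolution), ending at 11,999.12 cm^-1. The last-point position
is the one place where "12,000-4000 cm^-1" is ambiguous at the point
spacing; we keep the largest grid point below the nominal limit.

Wavenumber-range selection is endpoint-inclusive with a 0.02 cm^-1
tolerance because published boundaries are rounded to two decimals. On the
standard grid the three published interval selections contain exactly 312
(TP), 312 (FAA) and 831 (TP/FAA) variables, which the test suite asserts.

## Pretreatments

Seven pretreatments are compared throughout: none, MSC, SNV, 1st and 2nd
derivative, and MSC or SNV followed by a 1st derivative and Savitzky-Golay
smoothing with window 7 and polynomial order 3.

* **MSC** regresses each spectrum on a reference (x = a + b·ref) and
  returns (x − a)/b. The reference is the *calibration-set mean*, stored by
  `preprocess_fit()` and reused verbatim on prediction spectra — no
  prediction-set statistic ever enters a transform.
* **SNV** centres and scales each row (n − 1 denominator); a constant row
  is an error naming the sample.
* **Derivatives** are central finite differences scaled by the grid
  spacing, so units are absorbance per cm^-1 and results are
  grid-independent; one-sided differences fill the two edge points. The
  instrument software behind the comparison tables does not document its
  derivative flavour; central differences are the neutral choice and are
  stated here once.
* **SG filtering** delegates to `signal::sgolayfilt`; edges are handled by
  the one-sided full-window polynomial fit so the variable count (and hence
  interval indexing) is preserved. Derivative outputs are divided by
  spacing^m in our wrapper because the underlying filter works per index
  step. In a composed chain the printed order is respected: "MSC + 1st +
  SG(7,3)" means difference first, smoothing second.

## PLS with PRESS-based factor selection

`pls_fit()` implements mean-centred NIPALS PLS1. For one response the inner
iteration converges in a single step, so each component's weight vector is
the residual covariance direction X'y normalised, followed by explicit
deflation. The regression vector is b = W(P'W)^-1 q, and predictions are
ŷ = ȳ + (x − x̄)b.

`pls_loocv()` computes PRESS(a) = Σᵢ (yᵢ − ŷ₋ᵢ(a))² by refitting on every
leave-one-out subset; `select_factors()` returns the *first local minimum*:
the smallest a with PRESS(a) < PRESS(a+1), falling back to the largest
examined count when PRESS never rises. Ties between successive PRESS values
do not count as a minimum (strict inequality), which makes the rule
deterministic. The default ceiling is 10 factors.

Figures of merit follow the usual conventions: R_C/R_P are Pearson
correlations of predicted versus reference values; RMSEC/RMSEP use
denominator n (the degrees-of-freedom convention is not universal, so we
state ours once and use it consistently); RMSECV(a) = sqrt(PRESS(a)/n);
RPD = sd(prediction-set reference, n − 1)/RMSEP, with RPD > 2 the
customary threshold for a usable model.

## Interval selection

`interval_partition(p, k)` tiles the ascending variable axis into k
contiguous intervals whose sizes differ by at most one; when p mod k > 0
the *leading* (low-wavenumber) intervals carry the extra point. This
remainder rule is the one consistent, to 0.01 cm^-1, with all six published
interval boundaries on the standard grid, which is why it is fixed rather
than configurable.

* **siPLS** exhaustively scores every combination of 2-3 intervals (for 20
  intervals; 3-4 for 10, matching the published selections' combination
  sizes) by LOOCV RMSECV at the PRESS-selected factor count, and returns
  the global minimum. Ties break toward fewer variables, then the
  lexicographically smallest index set, so results are reproducible.
* **biPLS** starts from all intervals and repeatedly removes the interval
  whose exclusion lowers RMSECV the most, down to one interval; the
  retained set at the global minimum of the whole trajectory (the full
  spectrum included) is returned, since the method's stopping rule is not
  standardised.

Within the search, each candidate chooses its own factor count by the PRESS
rule under a shared ceiling; a fixed count would penalise small candidates.

## Origin authentication

`da_fit()` compresses pooled calibration spectra by mean-centred PCA
(default 9 components, mirroring common practice of keeping a fixed small
score space) and summarises each class by the centroid and covariance of
its scores. Classification assigns the class with the smallest Mahalanobis
distance d_c = sqrt((s − μ_c)' Σ_c^-1 (s − μ_c)). Per-class covariances
(quadratic flavour) are the default because the two origins need not share
a scatter structure; `pooled = TRUE` gives the linear flavour. Covariances
are regularised by adding 1e-6·trace/k to the diagonal, which is invisible
at normal conditioning but guarantees invertibility for small classes.
Exact distance ties go to the lexicographically first class label and are
flagged. Summaries report both all-sample and held-out accuracy, labelled,
because comparison tables in the field often quote the former.

## The synthetic generator

`generate_dataset()` emulates the study conditions: 56 LY and 30 NLY
samples on the standard grid. Each clean spectrum is a Beer-Lambert mixture
of five Gaussian-band component spectra (`component_spectra()`): water
(5160, 7000 cm^-1), polyphenols (4258, 4327, 4440, 8300 cm^-1), free amino
acids (4650, 5000, 6700 cm^-1), the bulk carbohydrate/protein matrix
(4380, 5780, 8450 cm^-1 plus a broad background) and an *origin marker*
(5300, 7100, 8900 cm^-1). Band widths (45-250 cm^-1 sigma) are broad NIR
overtone widths; heights are scaled so mixtures span roughly 0.1-1.2
absorbance. Measured spectra are a + b·(clean + tilt) + noise with
b ~ lognormal(0, 0.08), a ~ N(0, 0.02), a random linear baseline tilt
(sd 0.02 at the grid ends) and iid noise (sd 0.004 absorbance) — the
particle-size, packing and baseline effects that motivate MSC/SNV in
practice.

Concentrations are class-conditional normals chosen once as plausible
green-tea values: TP 250 ± 25 (LY) vs 225 ± 25 (NLY) mg GAE/g, FAA 45 ± 8
vs 55 ± 8 mg TE/g — the authentic class higher in polyphenols and lower in
amino acids, with deliberately overlapping distributions. The origin
marker (mass fraction 0.014 ± 0.002 vs 0.004 ± 0.002) encodes the
region-specific secondary-metabolite profile: in real surveys the two
origins remain spectrally separable even though their TP/FAA chemistry
overlaps, and a concentration-only class shift cannot reproduce that after
scatter normalisation. The spreads were calibrated once so that
taste-indicator prediction is demanding but feasible — TP prediction at
default noise reaches R_P ≈ 0.95-0.97 with RPD ≈ 3-4 at n = 150 — and were
frozen before the validation suite.

What the generator does *not* emulate: instrument line shape,
Kubelka-Munk nonlinearity, wavelength-dependent scatter, moisture-band
temperature shifts, and any nonlinear concentration-absorbance relation.
Passing recovery tests therefore demonstrate that the algorithms are
implemented correctly and behave as theory predicts on data satisfying
their assumptions — they do not certify performance on real tea spectra.

`planted_interval_dataset()` is the sharper tool for the selection
algorithms: the response depends only on columns inside a chosen band and
all other columns are independent noise, so a correct interval search must
recover the band's interval.

## Numerical and design choices

* Degenerate inputs fail loudly: constant rows in SNV, zero-variance
  responses, infeasible factor counts, mismatched variable counts, classes
  too small for the score-space dimension.
* A flat spectrum in MSC (slope below 1e-12) is passed through with a
  warning rather than amplified.
* NIPALS stops early if the residual covariance direction collapses below
  1e-14 (exactly collinear data), returning the components found.
* The calibration/prediction split forces the min/max samples of TP, FAA
  and TP/FAA into calibration, keeps every origin in both sets where
  counts permit, rounds the 75% fraction to the nearest integer (ties
  upward: 86 samples give 65 + 21), and is otherwise a seeded stratified
  draw.
* Problem sizes in the test suite are chosen for tight feedback loops:
  oracle-equivalence checks run on matrices up to ~60 x 200, seed-loop
  properties on a 519-point grid (every fourth point of the standard
  grid) or on 100-200 variable planted problems, and full-scale runs
  (2075 variables, 20 intervals) are exercised by the acceptance script.

## Known limitations

* The "good model" heuristic RMSEP < RMSECV holds here only on average
  (mean ratio ≈ 0.96 on well-specified synthetic data): with a 21-sample
  prediction set the per-split indicator is close to a coin flip, and
  published comparison tables show the same instability on real data. We
  report both numbers and leave the judgement to the analyst.
* siPLS restricted to 2-3 intervals can cross-validate *worse* than the
  full spectrum when the response loads on many bands at once; that is a
  property of the method, not a defect of the search (which is provably
  the global minimum over its candidate set).
* PLS1 only: one response per model. Multi-response PLS2, nonlinear
  kernels and other variable-selection families (moving window, genetic
  algorithms, CARS) are out of scope.
* No instrument-native file formats (JCAMP-DX, SPC, OPUS) and no
  resampling between grids: delimited text on a single grid is the
  exchange format.
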