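---
title: "Blob-texture quantification of muscle ultrasound: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blob-texture quantification of muscle ultrasound: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoblob)
```

## The measurement problem

Fibromyalgia lacks an objective imaging biomarker: diagnosis rests on
patient-reported indices (pain VAS, CSI, FIQ, SF-36, BDI/BAI). B-mode
ultrasound of tender-point muscles such as the upper trapezius shows, to the
eye, a subtly brighter and more heterogeneous echotexture in patients, and
blob analysis turns that impression into numbers. A *blob* is a maximal
spatially connected region of pixels whose grayscale exceeds a reference
threshold; its count and total area quantify how much abnormally hyperechoic
tissue a muscle contains.

The pipeline implemented here is:

1. **Echointensity.** Each frame is an 8-bit grayscale matrix (0 darkest,
   255 brightest) with a manually delineated region of interest (ROI)
   excluding fascia. Echointensity is the arithmetic mean grayscale over the
   ROI.
2. **Reference thresholds.** All ROI pixels of all frames of the *healthy*
   arm are pooled; the 95th and 99th percentiles of that pooled distribution
   (linear interpolation between order statistics, R quantile type 7) define
   the grayscale thresholds. Brightness is thereby always referenced to the
   healthy distribution, not to the image under analysis.
3. **Binarization and labeling.** A pixel maps to 1 iff it lies in the ROI
   and its value is *at or above* the threshold; connected components of the
   1-pixels (8-neighbor adjacency by default) are the blobs.
4. **Metrics.** Per frame and threshold level: blob count, total blob size in
   pixels and mm², and both divided by ROI area in mm². Per subject: the
   arithmetic mean over the three consecutive frames.
5. **Cohort statistics.** Normality-gated two-group tests, correlations with
   the clinical covariates, backward-elimination regressions with VIF and
   Durbin–Watson diagnostics, and a Benjamini–Hochberg FDR adjustment.

## Decisions where the protocol was underspecified

The source protocol leaves several details open; the package fixes them as
follows and exposes each as configuration:

* **Threshold semantics.** "Regions within the 95th and 99th percentiles that
  exceeded the threshold" is ambiguous. The full metric set is computed
  independently at each percentile level; the 95th-level metrics are the
  primary endpoints (their magnitudes match the published counts), and
  `band_map()` exposes the band `t95 <= g < t99` for exploration.
* **Tie handling.** "Below the threshold → 0, above → 1" does not define
  equality; ties at the threshold count as bright (`>=`). With interpolated
  percentile thresholds on integer grayscales, the threshold usually falls on
  an integer, so this choice matters: it inflates the nominal 5% tail by the
  tie mass at the threshold level (measured ~0.2 percentage points at the
  reference preset's compression gain).
* **Connectivity.** 8-connectivity by default (the usual choice for bright
  blob analysis); 4-connectivity by argument. Both are oracle-tested.
* **Percentile definition.** Linear interpolation between order statistics;
  recorded in `threshold_set$definition` and in `thresholds.json`.
* **Pooling.** Thresholds come from the pooled pixel distribution of all
  healthy ROI pixels, not from per-image percentiles.
* **Subject aggregation.** Arithmetic mean over the three frames (median by
  argument). The three frames are consecutive static images of the same
  tissue, so this is a noise average, not a sampling average.
* **No minimum blob size** by default; a pixel floor is available
  (`min_blob_px`).
* **Normality gate.** Shapiro–Wilk at α = 0.05 routes between Student t /
  Pearson and Mann–Whitney / Spearman; constant samples take the rank route
  (the test is undefined there). Gate decisions are returned with each
  result, and every route can be forced.
* **Mann–Whitney.** Two-sided, tie-corrected normal approximation with a 0.5
  continuity correction; full enumeration (midranks, distance-from-mean
  two-siding) replaces it automatically when both groups have n ≤ 8. The
  enumeration returns p = 1 for identical samples. For continuous data the
  approximation agrees with the exact distribution within 0.05 absolute at
  every n ≤ 8 (worst observed 0.037); under adversarial tie structures no
  normal approximation can do so (a = {5,5,5} vs b = {5,5,6} has exact p = 1
  while the approximation gives ~0.5), which is exactly why the exact route
  owns the small-n regime.
* **Fisher's exact test** for sparse tables uses the Freeman–Halton
  convention (sum of table probabilities not exceeding the observed one),
  i.e. `stats::fisher.test`. For the published 2×3 physical-activity table
  the Pearson statistic is 10.02; the published exact p (0.004) could not be
  assigned to a unique convention, so the package reports its own value and
  does not tune toward the printed one.
* **FDR family.** One global family across comparisons, correlations and
  regression terms by default (`per_table` optional). Coding published
  "< 0.001" entries as 0.001 and adjusting the 23 published table p-values as
  a single family reproduces every published adjusted value to 3 decimals —
  that reproduction is an acceptance test, not an assumption. Note that the
  BH step-up is *not* idempotent: re-adjusting an adjusted vector generally
  changes it, which is why no such invariant is asserted.
* **Backward elimination** removes the predictor with the largest p ≥ 0.05
  and refits until all retained p < 0.05; `p_remove = 1` returns the full
  model. Standardized β is b·sd(x)/sd(y); VIF is 1/(1−R²) of each predictor
  on the others; Durbin–Watson is Σ(Δe)²/Σe².

## The synthetic cohort generator

No public data accompany the source study, so the package carries a seeded
generator whose outputs have the statistical structure the analysis assumes.

**Speckle.** Fully developed speckle is simulated as the envelope of a
complex Gaussian scatterer field: real and imaginary parts are i.i.d. normal,
smoothed by a separable Gaussian PSF, variance-renormalized, and combined as
an amplitude. The marginal is exactly Rayleigh at any PSF size, so the PSF
sets the speckle *grain* (spatial correlation) without touching the contrast.
Log compression `g = gain · log(1 + A)` maps amplitude to the 0–255 scale.
One protocol deviation is deliberate: a first design sketch had no PSF by
default, but without spatial correlation the thresholded field shatters into
thousands of 1–2-pixel components (blob counts ~1100 per frame against the
published ~37–42), so the frozen preset uses a fiber-aligned grain of
1.8 × 4.0 px (axial × lateral). `simulate_frame()` itself still defaults to
no PSF, which is also how the percentile-tail acceptance check is sharpest.

**Inclusions.** Hyperechoic fibrous bands are Poisson-placed ellipses,
elongated along the lateral (fiber) axis, 4 × 1 mm mean geometry with
log-normal size jitter and near-lateral orientation, multiplying the
amplitude by a Gaussian profile peaking at gain 2.

**Subjects and covariates.** Each subject carries a log-amplitude random
effect (between-subject SD 0.0343) plus a small per-frame jitter (SD 0.01;
the source reports no frame-to-frame variance, so this is a free choice).
Each FM subject additionally carries a latent severity z ~ N(0,1) that loads
positively on every symptom score (pain/fatigue/sleep VAS, CSI, BDI, BAI,
FIQ, WPI, SSS), negatively on the SF-36 subscales, and cross-links into the
imaging model by multiplying the inclusion rate by `exp(0.4·z)` and shifting
the subject echo effect by `0.030·z`. That cross-link is what makes blob
metrics correlate with CSI and pain — the signal the correlation and
regression stages are tested against. All scores are truncated to their
instrument ranges.

**Calibration.** The preset was tuned once (`tools/tune_preset.R`, frozen
thereafter) against the published group statistics, rescaled to the 256 × 128
frame: healthy mean echointensity 71.95; healthy total-blob-size CV 0.233;
FM/healthy blob-size ratio 1.451; FM CV 0.308. Validation over 40 seeded
cohorts gave healthy blobs 1440 ± 306 px (CV 0.213), FM 2115 ± 614 px
(CV 0.290), ratio 1.469, pooled healthy tail fraction 0.052.

**What the generator cannot reproduce — and hence what a green test does not
establish.** The published statistics are internally inconsistent with any
percentile-tail model:

* an 11-gray-level between-subject echointensity SD would make the 5%-tail
  pixel count vary with CV far above the published 0.23, so the preset's echo
  SD is a few gray levels and the published echo SDs (±11.4) are not
  reproduced;
* the published FM mean echointensity (78.48) cannot coexist with the
  published blob-size ratio 1.45 under a common within-frame texture; the
  preset prioritizes the blob-size distributions (the primary endpoints) and
  realizes FM echo ≈ 75.3;
* the published per-mm² unit labels are inconsistent with the stated image
  sizes (blob sizes of ~2000 are plausible as pixel counts, not mm²); the
  package reports pixel and mm² quantities separately and does not attempt to
  reproduce the published per-mm² magnitudes;
* published blob counts (~37–42) trade off against the frame-noise floor:
  matching them exactly would require a coarser grain whose sampling noise
  exceeds the published blob-size SDs; the preset yields ~80–100 blobs per
  frame.

Green acceptance tests therefore establish that the *pipeline* behaves as
specified on data with the assumed structure (threshold semantics, effect
direction and size, severity cross-link, test calibration) — not that the
generator is a faithful forward model of trapezius ultrasound.

**Regression harness.** `simulate_regression_cohort()` builds subject-level
rows (no images) with a known linear structure,
`blob density = 1000 + 83.706·pain − 3.255·dx_months + ε`, ε ~ N(0, 120),
plus nuisance covariates. The residual SD is chosen so that a ±10% recovery
band at n = 500 is a meaningful test of the estimator (roughly a 2-SE band);
with the source study's own residual noise the stated criterion would be
underpowered by construction.

## Numerical notes

* Thresholds may be fractional (interpolated); binarization compares integer
  pixels with `>=` against them, which is exact.
* The connected-component labeler is a compiled two-pass union-find; labels
  are renumbered 1..N in row-major raster order of each component's first
  pixel, which makes results comparable across implementations, and a
  recursive flood fill serves as its independent oracle in the tests.
* All randomness flows through explicit seeds; a master seed expands into
  per-subject and per-frame substreams (kept below 2³¹), so a cohort is
  reproducible and byte-identical on disk across runs.
* Degenerate inputs fail loudly and early: empty ROIs, non-8-bit images,
  dimension mismatches, duplicate subjects, frame counts ≠ 3, zero-margin
  tables, constant predictors and rank-deficient designs are all contract
  errors with the offending item named.

## Known limitations

* No acquisition physics: no beamforming, attenuation, shadowing or gain
  profile; the fascia is a margin convention, not a segmented structure.
* PNG is the only frame format (the deployment environment has no TIFF/DICOM
  reader); pixel spacing must be supplied via the manifest.
* The statistics battery covers the published plan only — no mixed-effects
  models, no imputation beyond listwise deletion.
* Published raw p-values from the source cohort are reproduced only where
  they are deterministic re-computations (the FDR family); raw test p-values
  depend on the unavailable raw data and on the original software's
  tie-handling dialect.
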