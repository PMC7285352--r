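---
title: "Calibrating loline alkaloids and fungal biomass from NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating loline alkaloids and fungal biomass from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Loline alkaloids — *N*-acetylloline (NAL), *N*-acetylnorloline (NANL) and
*N*-formylloline (NFL) — are insecticidal aminopyrrolizidines produced by
*Epichloë* endophytes living inside cool-season grasses such as meadow
fescue. Breeders screening for insect-resistant, endophyte-infected
material need per-plant concentrations of the individual lolines, their
sum, and ideally the amount of fungal mycelium in the host tissue. The
reference assays (gas chromatography for alkaloids, ELISA for mycelium) are
accurate but slow and expensive. Near-infrared reflectance spectroscopy
(NIRS) of freeze-dried, ground tissue offers a fast surrogate — once a
calibration equation linking spectra to reference values has been built.

`lolichemo` implements that calibration workflow end to end: spectra are
stored as log(1/R) absorbance on a 1100–2000 nm grid at 2 nm steps
(451 points), acquired in triplicate and averaged; candidate equations are
generated by crossing spectral pre-treatments; outliers are screened twice
(spectrally, then chemically); and the winning equation is selected on
cross-validation statistics.

## The pipeline, stage by stage

### Pre-treatment codes

Each pre-treatment is named by a letter and a digit, e.g. `"s2"`. The
letter selects the scatter correction applied per spectrum over the full
grid: `n` none, `s` standard normal variate (SNV: center and scale each
spectrum to mean 0, sample SD 1), `d` detrend (residual of a least-squares
polynomial in wavelength), `m` SNV followed by detrend. The digit selects
the derivative/smoothing numerals (a, b, c, d) = (derivative order, gap in
points, first smoothing segment, second smoothing segment):
0 = (0,0,1,1) (identity), 1 = (1,4,4,1), 2 = (2,4,4,1), 3 = (2,10,10,1),
4 = (2,8,6,1).

Numerical choices made where the field's conventions leave latitude:

* **Order of stages.** Scatter correction is applied to the raw log(1/R)
  spectrum first, then the derivative stage — the convention of the NIR
  processing software lineage these codes come from.
* **Detrend degree.** 2 (quadratic), the standard choice for scatter
  detrending of powdered samples; exposed as `detrend_degree`.
* **Derivative semantics.** The first derivative is the difference of
  points `b` apart assigned to the window midpoint; the second derivative
  is `x[i-b] - 2 x[i] + x[i+b]`. No step-size normalization is applied
  (raw differences), which is irrelevant downstream because PLS is
  invariant to a common scaling of the design matrix.
* **Smoothing.** Boxcar means over `c` (and then `d`) consecutive points;
  `d = 1` means no second smoothing.
* **Edges.** Derivatives and smoothing truncate to the valid window rather
  than padding; the output `wavelength_grid` records the truncation. A
  (2,10,10,1) treatment of a 451-point spectrum therefore yields
  451 − 9 − 20 = 422 points.
* **SD convention.** SNV (and all SDs in the package) use the sample
  (n − 1) denominator.

### Spectral outlier screening (H statistic)

For each candidate PCA-stage treatment, a principal component model is
fitted to the treated calibration spectra. Components are retained up to a
cumulative explained-variance target (default 0.99, capped at
min(n − 1, 30) components; a fixed `k` can be given instead — both entry
points exist because published component counts may come from either
rule). Each sample's **H statistic** is the squared Mahalanobis distance
of its score vector — each score standardized by that component's training
SD — divided by the number of components. Because PCA scores are
uncorrelated, this equals the subspace Mahalanobis distance / k ("global
H"), which makes the conventional cutoff H > 3.0 scale-appropriate; over
the training set H averages exactly (n − 1)/n. Screening is single-pass by
default (one discard step before regression); an iterative refit mode is
available via `iterate = TRUE`.

### Modified partial least squares (MPLS)

The regression core is PLS1 with a between-factor residual
standardization. Per factor: the weight vector is the normalized
covariance of the current spectral residual with the current reference
residual; the score is the residual projected on the weight; spectral
matrix and reference are both deflated by the score projection. The
modification: after each factor, every wavelength column of the spectral
residual — and, by default, the reference residual — is divided by its SD
before the next factor is extracted. The divisors are stored and replayed
at prediction time, so prediction is an exact affine map. Standardizing
the reference residual as well is a genuine open choice in the field's
descriptions of the method; it is on by default and controlled by
`scale_y`. With `scale_residuals = FALSE` the algorithm reduces exactly to
classical NIPALS PLS1, which the test suite verifies against an
independent oracle to 1e−8. Residual columns whose SD collapses to zero
are left unscaled (unit divisor) rather than erroring, since second
derivative treatments can flatten edge columns.

The default number of factors is 10, the conventional setting for this
workflow; cross-validation exists to detect overfitting rather than to
search the factor count per cell.

### Cross-validation, T outliers and statistics

Cross-validation assigns samples to 6 near-equal groups by a seeded random
permutation (the assignment rule is not fixed by convention; a uniform
permutation split is the simplest exchangeable choice) and predicts each
group from a model fitted on the rest. SECV is the root mean square of the
pooled held-out residuals. A sample's **T value** is its held-out residual
divided by SECV; samples with |T| > 2.5 are eliminated and the
cross-validation re-run, at most twice (the second round catches samples
unmasked by the first removal).

`compute_stats()` bundles the selection statistics. With residual
r = reference − predicted:

* RSQ = squared Pearson correlation;
* SEC = sqrt(SSE / (n − factors − 1)) (calibration context only — the
  degrees-of-freedom-corrected "best obtainable" error);
* SEP = RMSE = sqrt(SSE / n); SEPc = sqrt(Σ(r − BIAS)² / (n − 1));
* BIAS = mean(r);
* RPD = SD(reference) / SEP by default. The literature defines RPD against
  SECV, but published tables in this workflow's lineage print SD/SEP;
  both are available via `rpd_on`, and the object records which was used.
* a paired two-sided t-test of reference vs predicted values. Degenerate
  constant differences return p = 1 (identical) or p = 0 (constant nonzero
  shift) by convention.

### The 400-equation grid

`run_grid()` crosses 20 PCA-stage codes with 20 MPLS-stage codes. The two
stages are independent: H-outlier removal uses the PCA-stage treatment
(applied once per PCA code, not re-screened per regression treatment),
while the regression design matrix applies the MPLS-stage treatment to the
raw averaged spectra of the surviving samples. Samples with zero or
missing reference for the target constituent are excluded first. Per-cell
failures are caught and recorded in the candidates table without aborting
the grid; the grid is a deterministic function of (data, seed), with one
shared seed so every cell sees the same grouping philosophy.

Selection is lexicographic — minimize SECV, tie-break by maximal RSQ, then
maximal RPD, then enumeration order — because SECV is the overall accuracy
measure of an equation while RSQ/RPD grade its fit and practical utility;
the rule is recorded in the report. Only the winning cell's models are
kept in the report (re-fitted deterministically after selection); storing
400 fitted models would cost tens of MB for no analytical gain.

## The synthetic population

No public spectral dataset with loline references exists, so the package
ships a generator whose defaults define its reference test population:

* n = 190 samples, triplicate spectra on the 1100–2000 nm grid;
* total lolines log-uniform over 101–5629 mg·kg⁻¹ (log-uniform reproduces
  the wide right-skewed ranges typical of field collections), split into
  NFL/NANL/NAL shares by a Dirichlet draw with mean (0.73, 0.16, 0.11) and
  concentration 100 (sample-to-sample SD of the NFL share ≈ 0.04);
* mycelium log-uniform over 0.22–3.97 mg·g⁻¹, coupled to total lolines by
  a Gaussian copula with ρ = sin(π·τ/2) targeting Kendall τ = 0.48 (the
  copula is the natural way to hit a rank correlation, which monotone
  marginal transforms preserve);
* spectra built as Beer–Lambert mixtures: a smooth quadratic baseline plus
  per-constituent Gaussian overtone bands (idealized but standard for NIR
  band shapes; amplitudes put each constituent at ~0.03–0.06 absorbance
  units at the top of its range, a minor-analyte scale);
* scatter artifacts per sample: multiplicative amplitude (log-normal,
  SD 0.08), additive offset (SD 0.03 AU) and a linear tilt (SD 2e−5
  AU/nm) — the classic artifacts SNV and detrending exist to remove;
* independent instrument noise per replicate (SD 3e−4 AU, consistent with
  heavy scan averaging) and reference values reported with 3% CV
  multiplicative analytical noise.

What the generator does **not** emulate: correlated matrix constituents
(protein, fiber, water bands), non-linear detector response,
wavelength-registration error, and between-batch drift. Passing the
end-to-end tests therefore shows the machinery is correct and that the
workflow recovers known structure under realistic scatter and noise — it
does not certify accuracy levels on real field material, whose errors are
dominated by matrix effects the generator idealizes away. That is also why
the synthetic cross-validated RSQ (≈ 0.99) is higher than what field
calibrations achieve.

`inject_outliers()` plants known anomalies for testing the two screens:
spectral outliers get a 5–10× amplitude factor *and* a spurious narrow
band (so they are anomalous in shape as well as scale, and remain
detectable after SNV); chemical outliers get the reference displaced
upward by 5–8 reference SDs (upward, so the corrupted value stays positive
and is not silently removed by the zero-reference exclusion).

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run the full 400-cell grid on
one default synthetic population (190 samples → ~142 calibration samples
after the 75/25 split), 10-seed screening-power loops at n = 190, and
oracle comparisons on random instances up to n = 40, p = 60. These sizes
were chosen as the smallest that exercise every code path at the
population's documented scale.

## Known limitations

* MPLS is reconstructed from the standard one-sentence description of the
  method (divide residuals by their SDs between factors); proprietary
  implementations may differ in unpublished details such as whether the
  reference residual is scaled (both settings are provided) and in edge
  handling of derivatives.
* The H-screening and the grid share a single variance-target rule;
  per-cell manual component choices are supported only through `k`.
* Cross-validation group assignment is random-uniform; stratified or
  Kennard–Stone style assignments are out of scope.
* The generator's concentration–spectrum link is exactly linear; it cannot
  probe non-linear calibration failure modes.

## A worked example

```{r, eval = FALSE}
library(lolichemo)

d <- generate(default_population_config(seed = 7))
parts <- split_calibration_validation(average_replicates(d$set), 0.75, seed = 7)
report <- run_grid(parts$calibration, "total_lolines", seed = 7)
report
best <- select_best(report)
best$stats
```
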