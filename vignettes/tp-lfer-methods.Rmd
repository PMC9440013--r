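---
title: "Two-parameter LFERs for lipid-water partitioning: models, validation and applicability domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-parameter LFERs for lipid-water partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipolfer)
```

## The scientific problem

Bioaccumulation and baseline toxicity of neutral organic contaminants
are governed largely by how strongly a chemical partitions into an
organism's lipids. Two lipid pools matter and behave differently:
storage lipids (triacylglyceride fat tissue; partition coefficient
logK~lw~) and membrane phospholipids (liposome bilayers; logK~pw~).
Experimental databases for both endpoints are small — a few hundred
chemicals — because the measurements (batch sorption, headspace
sampling, equilibrium dialysis) are slow and delicate. Estimation
approaches exist at two extremes: one-parameter regressions on
logK~ow~ alone, which miss polar interactions, and poly-parameter
Abraham-descriptor models, which need six experimental descriptors
that are tabulated for only a few thousand chemicals.

`lipolfer` implements the middle ground: a two-parameter linear free
energy relationship (tp-LFER)

$$\log K_{\mathrm{lipid},w} = c_0 + c_{ow}\,\log K_{ow} + c_{aw}\,\log K_{aw}$$

in which logK~ow~ carries the nonspecific (dispersion/cavity)
contribution and the dimensionless Henry's law constant
logK~aw~ = log[HLC/(RT)] carries the polar and hydrogen-bonding
contribution. Both inputs are available, measured or reliably
estimated, for four orders of magnitude more chemicals than Abraham
descriptor sets.

### Assumptions

* Chemicals are neutral. Ionizable species (acids, bases, zwitterionic
  drugs) violate the model; membrane partitioning of charged species
  follows different physics, and the validation machinery surfaces
  such chemicals as residual outliers rather than correcting for them.
* No temperature correction is applied. The conversion
  K~aw~ = HLC/(RT) is evaluated at T = 298.15 K with
  R = 8.205 × 10⁻⁵ m³·atm·K⁻¹·mol⁻¹, and calibration data measured
  between 20 and 40 °C are treated as exchangeable — temperature
  variation in that window is small relative to the model's rmse
  (~0.38-0.41 log units).
* Lipid-type differences within an endpoint (fish oil vs olive oil vs
  milk fat for storage lipids; phosphatidylcholine vs mixed liposomes)
  are pooled.

## The coefficient registry

Eight published coefficient sets are built in (`list_models()`): each
endpoint calibrated on three input variants — dataset I
(ASM-estimated logK~ow~/logK~aw~, the largest n), dataset II (purely
experimental inputs) and dataset III (experimental with ASM backfill) —
plus the dataset-I training-split refits used in external validation.
Coefficients are stored at their printed three-decimal precision with
their bootstrap standard errors; no "un-rounding" is attempted.
`get_model()` defaults to dataset I, the recommended choice because of
its calibration size. Two metadata quirks are preserved verbatim and
flagged in the model's `note` field rather than silently corrected:
the phospholipid dataset-II intercept SE is recorded as 0.0109
(almost certainly a typo for 0.109, since every other SE has 2-3
decimals), and the full phospholipid model's rmse circulates both as
0.413 and 0.414.

## Calibration and its statistics

`fit_lfer()` is ordinary least squares (via `stats::lm`) with a
condition-number guard (κ > 10⁸ on the standardized cross-product is
refused as collinear). Two error conventions exist in the field, so
both are exposed: `rmse = sqrt(SSE/n)` (what the calibration reports
print) and `rse = sqrt(SSE/(n−p−1))` (the unbiased residual scale).
At n = 305, p = 2 they differ by under 0.5 %, below printed precision.
R² is 1 − SSE/SST in-sample; for *external* evaluation
(`evaluate_predictions()`, `external_validate()`) R² is the squared
Pearson correlation between predictions and observations, because
1 − SSE/SST can go negative off-calibration and the two conventions
must not be conflated.

Bootstrap standard errors (`bootstrap_se()`) use nonparametric *case*
resampling — rows with replacement at size n — rather than residual
resampling: calibration data are observational, so the predictor
design is itself random and should be resampled with the response.
Degenerate (singular) resamples are redrawn and counted. B = 1000 by
default; B < 100 is refused.

`compare_nested()` quantifies what the volatility descriptor buys:
dropping logK~aw~ from the storage-lipid model raises in-sample rmse
by ~0.02-0.03 log units under the calibrated noise level (the tests
reproduce this by simulation), modest overall but concentrated in
polar, hydrogen-bonding chemicals where logK~aw~ is most informative.

## Validation schemes

* `loo_cv()` — literal n-refit leave-one-out; deterministic. The tests
  verify the held-out residuals against the hat-matrix identity
  e~i~/(1 − h~i~) to 10⁻¹⁰.
* `kfold_cv()` — unstratified k-fold (default k = 10): indices are
  shuffled with the run seed and dealt round-robin, so fold sizes
  differ by at most one and `k = n` reduces *exactly* to LOO. A
  "repeat = 0" convention in some reports is read as a single
  unrepeated run (`repeats = 1` here); `repeats = 3` averages three
  runs at derived seeds (seed, seed+1, seed+2).
* `bootstrap_cv()` — fit on each case resample, score on its
  out-of-bag records. Note a common mislabel: 1 − (1 − 1/n)ⁿ ≈ 0.632
  is the *unique in-bag* fraction; the out-of-bag fraction is its
  complement ≈ 0.368. Both are reported (`inbag_fraction`,
  `oob_fraction`) and each is tested against its analytic limit.
* `split_train_validation()` — uniform unstratified random split
  (the published calibrations used 245/60 and 107/24).

`cv_rmse` is sqrt(PRESS/n) and `cv_r2` is the predictive R²
1 − PRESS/SST, chosen so that internal-validation numbers are directly
comparable to the fit statistics; per-fold rmse/r² are stored too.
Every stochastic scheme is reproducible: identical seed, identical
report.

## Applicability domain

`influence_diagnostics()` reproduces the influence-plot assessment:
hat values (leverage) from the OLS projection diagonal, *externally*
studentized residuals (the leave-one-out variance estimate, the
standard influence-plot choice), and Cook's distance. The flagging
thresholds are the conventional defaults — hat > 3(p+1)/n,
|studentized residual| > 2, Cook's D > 4/n, any one sufficient — and
all three are configurable, since published influence analyses rarely
print their critical values and flag counts are sensitive to them.
`plot()` on the report draws the studentized-residual-vs-hat plot with
circle radius ∝ √(Cook's D), i.e. circle *area* ∝ Cook's D.

For new chemicals, `in_domain()` computes the prospective leverage
x'(X'X)⁻¹x against the stored calibration design; a prediction is
in-domain when that leverage is below the hat threshold. Published
registry models ship without design information (the calibration
tables are not bundled), so domain membership is reported as
`"unknown"` for them unless the user refits on their own data — the
domain is a property of the calibration design, not of the
coefficients.

## The synthetic-data generator

`generate_chemicals()` emulates the statistical structure of the
storage-lipid calibration data so every other module is testable
without any external data download:

* log K~ow~ ~ Normal(3.0, 2.2) truncated to [−2, 10] — the
  hydrophobicity range spanned by the calibration chemicals, from
  short-chain polar solutes up to hexadecane (logK~ow~ ≈ 9.3);
* log K~aw~ = 0.45·logK~ow~ − 3.5 + Normal(0, 2.0) — a loose coupling
  giving the weak-to-moderate predictor correlation seen in the real
  descriptor tables (r ≈ 0.44 here);
* endpoint = truth(logK~ow~, logK~aw~) + Normal(0, 0.375), with the
  published storage-lipid coefficients as the default truth;
* HLC back-filled from logK~aw~ so generated records always satisfy
  the HLC/K~aw~ consistency invariant.

These marginal/joint parameters are configuration, not estimates: they
were chosen once so that the generated data reproduce the two printed
structural targets — endpoint-logK~ow~ correlation ≈ 0.98 and a
two-predictor refit rmse ≈ 0.375 — and the tests confirm both by
Monte Carlo over 30 seeds. What the generator does *not* emulate:
chemical-class clustering (PAHs, organochlorines, alcohols occupy
distinct descriptor niches), heteroscedastic measurement error,
ionizable chemicals, and real outliers with wrong reported values.
Passing the recovery suite therefore demonstrates that the estimation
machinery is correct under the model's own assumptions, not that the
published coefficients are right for any particular chemical family.

`generate_descriptor_matrix()` builds latent-factor matrices of
controlled rank as PCA fixtures: rank-2 with zero noise loads 100 % on
two dimensions; rank-2 with column noise sd 0.5 yields ≈ 75 %
cumulative variance in two dimensions, the regime reported for real
Abraham-descriptor tables, whose six descriptors are substantially
redundant.

## Descriptor dimensionality analysis

`pca_analysis()` performs correlation-matrix PCA by default
(standardized variables), the right choice when mixing Abraham
descriptors, log-partition coefficients and endpoints on different
scales. Variable contributions are squared loadings (summing to 1 per
dimension) and representation quality is cos² from the
sd-scaled coordinates. Loading signs are made deterministic by forcing
the largest-magnitude loading in each dimension positive, so reports
are reproducible across platforms. `classify_correlation()` uses five
contiguous |r| bins — negligible [0, 0.10), weak [0.10, 0.40),
moderate [0.40, 0.70), strong [0.70, 0.90), very strong [0.90, 1] —
with boundary values in the upper bin; rule-of-thumb tables in the
literature sometimes print these bins with typographical gaps, and the
contiguous convention is used deliberately (an r of 0.31 is therefore
labelled "weak" even where prose descriptions might call it
moderate).

## Numerical choices and degenerate inputs

* HLC ≤ 0, |r| > 1, partial Abraham descriptor sets (some but not all
  six), k outside [2, n], B < 100, n_validation outside (0, n), and
  zero-variance columns under standardization are all hard errors
  naming the offending record or column.
* CSV ingest never silently drops a row: unparseable numeric cells and
  invariant violations go to a rejection report. Missing values are
  empty cells on disk; "NA"/"NaN" are accepted on read, never written.
  Numerics are written at 12 significant digits so write→read
  round-trips are lossless at working precision.
* HLC/logK~aw~ mutual consistency is enforced at 10⁻⁶ log units;
  conversion round-trips are exact to 10⁻¹² relative error.
* Seeds: every resampling function takes an explicit integer seed and
  restores the caller's RNG state afterwards.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run entirely on generated
data: 200 replicates of n = 305 for coefficient recovery, B = 1000 for
the bootstrap-SE scale check, 30-60 seed Monte Carlo loops for the
structural and coverage properties, and n = 12-15 toys for the
exact-oracle comparisons (leave-one-out refits, normal equations,
eigendecompositions). These sizes were chosen as the smallest that
make the Monte Carlo error comfortably smaller than the tolerance
being asserted.

## Known limitations

* The published calibration tables are not redistributed, so the
  package cannot itself reproduce the printed full-dataset statistics
  (R² = 0.971/0.953, the 75.7 %/79.1 % PCA variance, r = 0.98); users
  with those tables can load them as CSV and run `fit_lfer()`,
  `pca_analysis()` and `correlogram()` directly.
* Predictions inherit the error of their inputs: with estimated
  logK~ow~/logK~aw~ the effective prediction error grows (reported as
  ~0.52 rmse with screening-level estimated inputs, vs ~0.38-0.41 with
  calibration-quality inputs).
* Not in scope: estimating descriptors from structure, one-parameter
  published constants (fit your own via `fit_lfer(..., predictors =
  "log_kow")`), poly-parameter Abraham fits, temperature corrections,
  and ionizable-species handling.
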