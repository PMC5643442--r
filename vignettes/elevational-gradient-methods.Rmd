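---
title: "Methods: mid-domain null models and richness-driver selection on elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mid-domain null models and richness-driver selection on elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevdiv)
```

`elevdiv` analyzes species richness along discrete elevational transects:
a bounded domain of `m` equal-width bands per mountain slope, with every
species occupying a contiguous run of bands. This vignette is the
package's own account of its models and the choices behind them.

## Ranges, interpolation, and groups

A species' *observed* range on a slope is the set of bands with at least
one capture or sighting (`count > 0`). Its *interpolated* range fills
every band between the lowest and highest detections: a species caught
both above and below a band is assumed present in it. Interpolation is
idempotent and can only add bands, so interpolated richness dominates
observed richness bandwise — a structural identity the tests assert.

Range size is counted in occupied bands (an integer `1..m`); the meter
extent reported alongside is `range_size * band_step`, an equivalent
quantity up to scale on a regular band design. Species present on both
slopes get independent per-slope ranges.

Assemblages are partitioned three ways — insectivores vs rodents, endemic
vs non-endemic, and large- vs small-ranged — and each partition must sum
to the total richness bandwise. The range-size split calls a species
large when its range size *strictly exceeds* the pool median; ties at the
median are small. The median is computed per slope by default (each
slope's assemblage is analyzed as its own pool); a pooled flag exists
because survey reports are often ambiguous on this point, and the two
modes differ only when the slopes' size distributions differ.

## The discrete-domain MDE null model

Under the null, each empirical range of size `r` is placed with its start
band uniform over the `m − r + 1` feasible positions, independently
across species, holding the range-size multiset fixed — the whole
assemblage is re-placed once per simulated draw, and only the midpoints
are random. This yields the closed-form per-band expectation

$$E[S_j] = \sum_{\text{species}} \frac{\min(j,\,m-r+1) - \max(1,\,j-r+1) + 1}{m-r+1},$$

which conserves total occupancy ($\sum_j E[S_j] = \sum r$), is symmetric
about the domain center, and is unimodal — the geometric "hump". The
simulator (default 5,000 draws) reports the per-band mean and a 95%
percentile envelope (2.5th/97.5th percentiles, chosen over a normal
approximation because richness counts are small and bounded). The
per-band simulated *mean* is the MDE prediction used everywhere
downstream, both in the observed-vs-null regression (ordinary OLS of
observed richness on the *natural log* of the prediction, R² and a
two-sided t-test on the slope) and as the MDE candidate predictor in
driver selection.

Because the envelope is a percentile interval on a discrete count, its
realized coverage of null-generated data sits slightly above the nominal
95% (inclusive tails); the acceptance check brackets it at 95 ± 3
percentage points over 500 seeded draws.

## Polynomial trends and AICc

Richness–elevation trends are fit by OLS on powers 1–3 of centered
elevation (centering tames the collinearity of the raw power basis
without changing fitted values or fit statistics). Model comparison uses
the small-sample AICc, $-2\ell + 2K + 2K(K+1)/(n-K-1)$, with the Gaussian
log-likelihood at the ML variance and **K counting the residual variance
as a parameter** (a linear fit has K = 3). Consequences at a 6-band
transect: the cubic fit has K = 5 and `n − K − 1 = 0`, so its AICc is
undefined; such fits are returned with `aicc_available = FALSE` and
excluded from best-degree selection, and the same exclusion (with a
warning) removes over-rich interaction models from the 12-row driver
analysis. R² is ordinary, not adjusted — so R² is non-decreasing in
degree while AICc need not be, and the best degree by AICc is frequently
not the best by R². Significance stars on trend fits use the model
F-test. Ties in AICc resolve toward the lower degree (and, in driver
selection, toward fewer terms, then lexicographically) so results are
deterministic.

## Driver selection

The chain mirrors standard multimodel inference:

* **Screen.** Pairwise Pearson correlations among the environmental
  covariates; within each connected component of the |r| > 0.7 graph only
  the highest-priority covariate survives. The priority list is an
  explicit user argument (default preferring NDVI over the temperature
  and humidity it integrates) because the retention choice is ecological,
  not algorithmic. A component rule is used rather than iterative pair
  deletion; when a chain of correlations links many covariates (as in the
  packaged fixture, where plant richness tracks temperature which tracks
  NDVI) the screen is correspondingly aggressive, and the global model is
  built from whatever survives.
* **Transforms.** The elevational variables (area, MAT, MAH, NDVI, PSR)
  enter on the natural-log scale; the MDE prediction enters untransformed;
  slope is a two-level factor. Transformed columns keep their names, with
  the transform recorded in an attribute.
* **Candidates.** All subsets of
  `slope * (MDE + surviving covariates)` under marginality (an
  interaction requires both parents). The family is Gaussian with
  identity link — OLS — because R² is the fit statistic reported
  throughout; a Poisson-log option exists behind a flag for count
  responses.
* **Selection and averaging.** AICc ranking, Akaike weights, and model
  averaging over the smallest top-ranked set whose cumulative weight
  reaches 0.95 (weights renormalized within the set). Per-term relative
  importance is the summed weight of set members containing the term;
  importance is method-invariant, while averaged coefficients default to
  the full (zero-substitution) method, with conditional averaging
  available — the full average shrinks toward zero for terms absent from
  part of the set, never the reverse.
* **Diagnostics.** VIF per predictor of the best model (flag at 5);
  Moran's I on the best model's residuals, with first-order chain
  adjacency within each slope (slopes disconnected), row-standardized,
  as the default weighting — the natural neighbor graph for bands along
  a transect. The variance uses the randomisation (kurtosis-corrected)
  formula with a two-sided normal-approximation p; an inverse-distance
  scheme is available, and results are scheme-dependent as always with
  Moran's I.

## The synthetic survey generator

`generate_dataset()` emulates a two-slope trapping survey so every stage
above is testable without field data. Its defaults describe the packaged
"Ailao-like" fixture and are the package's standing study conditions:

* **Domain.** 6 bands per slope, 200-m steps from 1,800 m; two slopes
  with 27 and 33 species sharing 23 (pool of 37).
* **Ranges.** Sizes drawn from a mildly U-weighted distribution over 1–6
  (many narrow ranges plus a tail of full-domain generalists, so the
  median split lands near half large-ranged); placement uniform over
  feasible midpoints (`mde_null`) or Gaussian-weighted around an optimum
  band (`environmental`).
* **Detection.** Abundance per occupied band is Poisson (mean 11.4);
  each individual is detected with probability
  `1 − (1 − 0.001)^2200 ≈ 0.89` over the band's 2,200 trap-nights
  (1,100 per season, two seasons), and detections split evenly at random
  between seasons. These values make the expected overall trap success
  ≈ 7.9%, the scale typical of snap/Sherman transect surveys.
* **Covariates.** MAT falls 0.55 °C per 100 m from 16 °C; MAH rises from
  70%; NDVI is a decreasing linear function of MAT (plus humidity), which
  reproduces the strong negative MAT–NDVI and positive MAH–NDVI
  correlations of humid montane forests; PSR declines with elevation.
  Band areas are irregular rather than monotone — as real topography is —
  so area correlates only weakly (|r| ≈ 0.3–0.45) with the smooth climate
  covariates and survives the 0.7 screen on its own. All covariates are
  generated on the natural scale; the analysis applies its own log
  transforms.
* **Reproducibility.** Everything derives from one integer seed through
  named per-stage substreams (an FNV-1a hash of stage label + seed), so
  identical configurations yield byte-identical datasets and the
  caller's RNG state is never disturbed.

What the generator deliberately does *not* emulate: within-band trap
placement, seasonal phenology, species-specific detectability,
abundance-dependent range edges, or observation of the same individual
twice. Tests passing on this generator therefore validate the *analysis
machinery* — range building, the null model, the selection chain — not
any claim about real assemblages.

`generate_richness_from_model()` complements it for parameter-recovery
experiments: richness simulated as a known linear function of (already
transformed) design columns plus Gaussian noise. The packaged recovery
experiment uses a 2-slope × 30-band design (n = 60), true effects on
log(area) and log(NDVI) with noise at a signal-to-noise ratio of 3, and
asks the selection chain to put both true terms in the best model and
give them the top-2 importances — which it does in well over 90% of 200
seeded replicates.

## Problem sizes and numerical notes

Default problem sizes throughout the package's own experiments: 5,000
null-model draws per envelope; 500 seeded draws for envelope
calibration; 200 replicates at n = 60 for recovery — sizes at which the
Monte-Carlo error is comfortably below the decision tolerances (per-band
binomial SE of a 5,000-draw mean is below 0.01 of a coverage
probability). Zero-residual fits return a divergent log-likelihood and
are given AICc −∞ so a perfect model dominates rather than errors;
rank-deficient designs are rejected with the offending coefficients
named; constant inputs to correlations and Moran's I raise errors rather
than returning NaN. Capture-file elevations snap to the nearest band
within ±25 m (the sampling tolerance of transect-based designs) and
error otherwise, naming the offending row.

## Known limitations

Richness responses are modeled as Gaussian at n = 12 bands; with 6 bands
per slope the data cannot support interaction-rich models (AICc is
undefined for them) and the package excludes rather than approximates
them. The MDE null randomizes midpoints only — range-size resampling and
continuous-domain variants are out of scope. Moran's I values depend on
the weighting scheme; only chain adjacency and inverse distance are
provided. The screen's component rule can remove covariates a
practitioner would retain on ecological grounds; the priority list is
the intended lever for that judgment.
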