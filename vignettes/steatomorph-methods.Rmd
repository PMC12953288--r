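---
title: "Models and methods behind steatomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind steatomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatomorph)
```

# The problem

Hepatic steatosis is graded in two very different ways. Pathologists look at
a biopsy under conventional microscopy and estimate the fraction of
hepatocytes containing a *large* lipid droplet (LD) that displaces the
nucleus, banding that fraction into S0 (< 5%), S1 (5–33%), S2 (34–66%) and
S3 (> 66%). MRI proton density fat fraction (PDFF) measures the fat signal
fraction of the whole liver and is banded at validated thresholds of 5.75,
15.5 and 21.35%. The two scales disagree in a substantial minority of
patients, and the hypothesised driver is droplet size: pathologists ignore
tiny and small droplets by design, whereas MRI integrates fat regardless of
droplet morphology.

Digital image analysis (DIA) of adipophilin-stained sections offers a
droplet-level ground truth: every droplet is segmented, sized and expressed
as a *proportionate area* — percent of scanned tissue area — in three
classes: tiny (< 1 µm²), small (1 to < 100 µm²) and large (≥ 100 µm²), the
lower bound of each band inclusive. steatomorph implements that measurement
chain, both grading rules, and the statistical battery used to explain
histology–PDFF discordance, together with calibrated synthetic generators
that stand in for the (undeposited) study images and patient tables.

# Synthetic image model

`generate_image()` renders an 8-bit raster emulating a scanned
adipophilin-stained section at a default calibration of 0.25 µm/pixel
(≈ 40× scan), so a 1 µm² droplet covers ~16 pixels and even tiny droplets
are resolvable objects. Choices worth knowing:

* **Geometry.** Tissue is a centred rectangle covering `tissue_fraction`
  (default 0.8) of the raster, at mid intensity (120/255) with Gaussian
  texture (sd 8); non-tissue background is dark (30/255). Droplet lumina are
  bright ellipses (235/255) with a one-pixel darker rim (70/255) emulating
  the stain boundary; axis ratios are drawn in \[0.7, 1\] and orientations
  uniformly. Intensities are separated by many noise standard deviations, so
  a fixed lumen threshold of 0.75 cleanly separates lumina from tissue.
* **Ground truth is the rasterized area.** Each droplet's requested area is
  drawn log-uniformly within per-class bounds, but the *recorded* truth is
  its rasterized pixel count × pixel area, resampled until it stays inside
  the intended class and above the 2-pixel floor. Segmentation accuracy is
  therefore measured against a realizable target, not a continuous ideal.
* **Non-overlap by construction.** With `overlap_allowed = FALSE` (default)
  droplets keep a 2-pixel guard margin via bounded rejection sampling;
  exhausting the budget is an explicit placement error. This is what makes
  count-level precision/recall a meaningful oracle.
* **What is not modelled.** Real tiny-droplet signal is described as
  diffuse, faint and foamy — a sub-resolution photometric regime. The
  generator renders tiny droplets as discrete resolvable objects instead,
  which is precisely what makes exact ground truth possible; conclusions
  about real faint-signal behaviour do not follow from these tests. No
  whole-slide pyramids, no stain deconvolution, no biopsy-needle geometry.

# Segmentation chain

`segment_tissue()` thresholds with the between-class-variance (Otsu)
criterion, fills enclosed background and removes components below 64 px.
Hole-filling floods from the raster border rather than filling per-object
holes: a stain rim is a *ring-shaped* hole that encloses a further bright
component (the lumen), and per-object filling leaves such rings open, which
would silently delete every droplet lumen from the tissue mask.

`segment_droplets()` thresholds bright lumina inside the mask (default
0.75), labels connected components (8-connected by default; the
4-connected labelling of the underlying toolkit is augmented with a
union–find merge of diagonally adjacent labels), fills per-component holes,
optionally splits touching droplets by a watershed on the distance
transform (off by default, since the generator's default is non-overlapping),
and filters by size (≥ 2 px; 0.125 µm² at default calibration, below the
tiny ceiling so tiny droplets remain countable) and by circularity
4πA/P² ≥ 0.6, with the boundary-pixel-count perimeter estimator of the
toolkit and values clipped at 1. The clipping matters: boundary-pixel counts
underestimate perimeter for small objects, inflating circularity above 1;
clipping keeps compact small objects and the filter then mostly removes
elongated artifacts, which is its purpose — "ovoid or circular" is a
qualitative criterion and 0.6 is a configurable default, not an estimate.

`compute_profile()` divides per-class droplet area by tissue area; the
total is defined as the sum of the three class percentages, so additivity is
exact by construction and is asserted to 1e-9 in the invariant tests.

# Synthetic cohort model

`generate_cohort()` draws, per patient:

1. **Total LD proportionate area** T from a gamma distribution
   reparametrized to mean 8.7% and SD 7.2%, truncated by rejection to
   \[0.5, 35.8\]%. Truncation pulls the realized moments slightly inward
   (mean ≈ 8.6, SD ≈ 6.6 at n → ∞), well within the ±1.0 calibration band
   the tests check.
2. **Composition.** The expected large-droplet share of T follows a
   saturating curve L(T) = L·T²/(T² + h²) with L = 0.65 and
   h = 12%: tiny/small droplets dominate low-fat livers and large droplets
   take over as fat accumulates. The realized share adds logit-scale
   Gaussian jitter (sd 0.3), and the non-large remainder is split by a
   Beta(45, 5) tiny fraction (mean 0.9, tiny ≫ small). Both random
   components are deliberate: real composition scatters around the trend
   (quadratic fits to it have R² well below 1), and — decisively — a
   deterministic split would make the class areas exact functions of T,
   with pairwise correlations at or near 1, so no multivariable model on
   them would be estimable. The split is exactly additive:
   tiny + small + large = T to machine precision. On this construction the
   tiny+small share is concave-down in T and the large share concave-up,
   which `quad_fit()` recovers at the sign level.
3. **PDFF** = T + N(0, σ), truncated at 0. The default σ = 3.69 solves the
   attenuation identity r = sd(T)/√(sd(T)² + σ²) for r = 0.89 at
   sd(T) = 7.2, so the PDFF–total-LD correlation is calibrated by
   construction, not fitted.
4. **Histology grade** from a perceived large-droplet hepatocyte fraction
   min(100, k · large_pct · bias) passed through the S0–S3 bands. The
   area-to-hepatocyte-fraction slope k and the multiplicative pathologist
   overestimation bias are free calibration knobs — no study quantifies the
   mapping, only that pathologist estimates systematically exceed measured
   proportions. Defaults k = 8, bias = 1.15 were chosen once so that the
   simulated primary endpoint lands where real cohorts put it
   (simulated discordance ≈ 37%, grade prevalences ≈ 37/37/14/12%); with a
   strictly linear area→fraction map, middle grades stay somewhat
   overrepresented relative to real data, a known limitation of the
   two-parameter mapping.
5. **Covariates.** Microvesicular steatosis from a logistic link on tiny
   area (intercept −2.6, slope 0.4 per %, ≈ 40% prevalence); age
   N(55, 10) truncated to 18–90; sex Bernoulli(0.59 female); significant
   fibrosis from a logistic link increasing in T; inflammation
   Bernoulli(0.3); biopsy length N(18, 4) mm; portal tracts 1 + Poisson(11).
   These are documentation-level defaults for exercising the modelling
   code, not epidemiological claims.

Because histology grading keys on the large class only while PDFF integrates
everything, discordance *emerges* from the model rather than being planted:
MRI overestimation concentrates where tiny/small droplets are abundant and
underestimation where large droplets are sparse — the qualitative structure
the package's analysis battery is designed to detect.

# Statistical battery

* **Discordance summary**: rate with exact (Clopper–Pearson) binomial CI,
  counts by magnitude and direction, 4×4 cross-tabulation.
* **Group comparisons**: t-test or Mann–Whitney for continuous variables,
  chi-square or Fisher for categorical; `test = "auto"` picks t only when
  Shapiro–Wilk holds in both groups at 0.05, and Fisher when an expected
  cell is below 5. The choice is also exposed as an explicit argument.
* **Logistic modelling** is staged the way concordance studies report it:
  every candidate is screened univariably; candidates with p < 0.05 enter
  the multivariable model alongside forced age and sex adjustment. Odds
  ratios are per unit (per % for areas, per year for age) with Wald 95% CIs
  exp(β ± 1.96·SE) — the standard for reported OR tables when the CI method
  is otherwise unstated. Two collinearity rules apply: a derived sum
  variable (total LD) is removed whenever one of its components entered,
  and of any pair with |r| > 0.9 the larger univariable p is dropped.
  Separation is flagged and warned, never returned silently. Interaction
  terms (e.g. fibrosis × droplet size) can be added to the final fit.
* **Correlations**: Pearson's r and Spearman's ρ (midranks, asymptotic p).
* **Paired tests**: Wilcoxon signed-rank per histology-grade stratum,
  asymptotic with continuity correction; strata under 5 pairs are flagged
  not-computed, and an all-zero-differences stratum is degenerate by
  convention with p recorded as 1.
* **Sample size**: n = ⌈z² p(1−p)/d²⌉ for estimating a prevalence p to
  absolute precision d at two-sided α — (0.6, 0.05, 0.05) gives 369. This
  precision formula fully reproduces that worked value without any power
  term; how a stated 80% power figure would enter such a formula is left
  undetermined rather than guessed.
* No multiple-testing correction is applied anywhere: the battery reports
  raw p-values, as discordance studies conventionally do.

# Parameter-recovery design

The recovery tests plant a known discordance mechanism on simulated
predictors: logit P(discordant) = −2.0 + 0.40·tiny + 1.2·small − 0.15·large.
The magnitudes were chosen (before the tests were frozen) to emulate the
*joint* structure real concordance data show — all three droplet classes
marginally associated with discordance, with the large-droplet effect
flipping negative once tiny/small are adjusted for. That flip is the
scientifically interesting regime: large-droplet area correlates positively
with discordance through its correlation with total fat, yet protects from
discordance conditionally. Planting much weaker direct effects makes the
large class's *marginal* association cancel to nearly zero, so it would
fail any univariable entry screen most of the time — an emulation failure,
not a model failure. Across 200 cohorts of n = 355 the staged model recovers
all three conditional signs in ≈ 99% of runs and excludes the sum variable
in all of them.

# Numerical conventions and degenerate inputs

* Histology bands are printed on integers with gaps on the continuum
  (33→34, 66→67); inputs are rounded half-up to integer percent before
  banding, since pathologists report integer percentages. PDFF and area
  class bounds are lower-inclusive, as the "≥" notation implies.
* The distance-to-threshold feature uses only the three grade thresholds,
  never 0 or 100 — the convention that reproduces both printed worked
  examples (3% → 2.75, 18.25% → 2.75).
* `quad_fit()` reports curvature "none" within an absolute tolerance of
  1e-8 on the quadratic coefficient and returns R² = 0 for constant
  response; rank-deficient designs are errors.
* Blank or uniform rasters raise an explicit no-tissue error rather than an
  empty mask; droplet area exceeding tissue area raises a calibration error.
* All generators consume one integer seed; the pipeline derives per-stage
  seeds deterministically from a single global seed, and identical
  configurations produce byte-identical artifacts.

# Problem sizes

The test and validation workloads use cohorts of n = 355 (10 replicate
seeds for calibration checks, 200 replicates for sign-recovery rates) and
batches of twenty 512×512 images with ~20 droplets each for the
segmentation oracle; the imaging arm of the pipeline validates a handful of
patients per run. These sizes give stable Monte-Carlo estimates for every
check while keeping a full run in minutes on a single CPU.

# Known limitations

* Tiny-droplet signal is modelled as discrete objects, not diffuse stain;
  whether real DIA measured tiny LDs as objects or as a stained-fraction
  signal is unknowable from the printed record, and the discrete commitment
  is stated, not validated.
* The pathologist model is a two-parameter deterministic mapping; it
  reproduces endpoint-level behaviour (discordance rate, direction pattern)
  but not inter-rater variability or grade-specific biases.
* The synthetic cohort reproduces marginals, one correlation and the
  composition-shift pattern; it does not claim to reproduce any real
  patient-level coefficient table, and the package's acceptance checks are
  correspondingly directional for the modelling layer.
* Passing tests on synthetic rasters show the operator chain is correct and
  calibrated on its own terms; they do not certify performance on real
  stained sections, where illumination, stain variability and touching
  droplets dominate.
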