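# steatomorph

Lipid-droplet morphometry and histology–MRI steatosis concordance analysis.

## The problem

Liver steatosis is graded on two scales that routinely disagree.
Pathologists band the fraction of hepatocytes containing **large** lipid
droplets (LDs) into S0 < 5%, S1 5–33%, S2 34–66%, S3 > 66% — tiny and small
droplets are disregarded by design. MRI proton density fat fraction (PDFF)
integrates *all* liver fat and is banded at PDFF-S1 ≥ 5.75%, PDFF-S2 ≥ 15.5%,
PDFF-S3 ≥ 21.35%. Digital image analysis (DIA) of adipophilin-stained
sections sits between the two: it segments every droplet, classifies it by
cross-sectional area into tiny (< 1 µm²), small (1 to < 100 µm²) or large
(≥ 100 µm²), and reports each class as a **proportionate area** — percent of
scanned tissue area. With DIA as ground truth, the droplet-size composition
explains *why* the scales disagree: abundant tiny/small droplets push MRI
above histology, and sparse large droplets pull it below.

steatomorph is for methodologists and imaging scientists who want that whole
chain as reusable, tested code:

* **synthetic generators** — calibrated adipophilin-style tissue rasters
  with exact droplet ground truth, and patient cohorts whose total-LD
  distribution (8.7 ± 7.2%, range 0.5–35.8%), size-composition shift and
  PDFF correlation (r ≈ 0.89) emulate a real chronic-liver-disease cohort;
* **droplet morphometry** — Otsu tissue masking, connected-component
  segmentation with hole filling, optional watershed splitting, circularity
  filtering (4πA/P² ≥ 0.6), size classification and proportionate areas;
* **both grading rules** plus the discordance constructs (direction,
  magnitude, distance of PDFF to its closest grade threshold);
* **the statistical battery** — discordance rates with exact binomial CIs
  and 4×4 cross-tabulation, stratified concordant-vs-discordant
  comparisons, staged univariable → multivariable logistic modelling with a
  p < 0.05 entry rule, forced age/sex adjustment and collinearity screening,
  Pearson/Spearman correlations, per-grade paired Wilcoxon tests, quadratic
  size-composition curves, and the precision-based sample-size formula
  n = ⌈z²·p(1−p)/d²⌉;
* **a reproducible pipeline** — one seed, byte-identical artifacts, a
  human-readable run report, and a thin CLI
  (`inst/scripts/steatomorph-cli.R`).

## Worked example

```r
library(steatomorph)

coh <- grade_cohort(generate_cohort(cohort_spec(seed = 42)))  # n = 355
discordance_summary(coh)
#> Discordance: 131/355 (36.9%), 95% CI 31.9-42.2%
#> By magnitude:
#>   1   2   3
#> 125   6   0
#> By direction:
#> concordant   mri_over  mri_under
#>        224         38         93
#> Cross-tabulation (histology rows, PDFF columns):
#>     pdff
#> hist   0   1   2   3
#>    0 113  30   0   0
#>    1  37  79   6   0
#>    2   1  29  13   2
#>    3   0   5  21  19
```

About 37% of simulated patients are discordant, almost always by a single
grade, and MRI *under*-grading dominates in higher histology grades — the
signature of pathologists keying on large droplets only. PDFF tracks the
DIA total closely:

```r
correlate(coh, "pdff_pct", "total_pct", "pearson")$coefficient
#> [1] 0.8789615

multivariable_logit(coh, candidates = c("pdff_distance", "microvesicular",
                                        "fibrosis_f2_4", "tiny_pct",
                                        "small_pct", "large_pct", "total_pct"))
#> Logistic model (n = 355)
#>      predictor odds_ratio ci_low ci_high  p_value
#>            age      0.999  0.977   1.020 9.49e-01
#>        sexmale      0.902  0.558   1.460 6.74e-01
#>  pdff_distance      0.719  0.625   0.827 3.75e-06
#>       tiny_pct      1.150  0.999   1.320 5.23e-02
#>      small_pct      1.140  0.581   2.250 6.98e-01
#>      large_pct      0.999  0.905   1.100 9.82e-01
#> Excluded (collinearity): total_pct
```

The entry rule admitted the significant univariable predictors, age and sex
entered as forced adjustments, and the total-LD area — the sum of its three
components — was removed by the collinearity rule. A PDFF far from its
closest grade threshold protects strongly against discordance (OR 0.72 per
percent).

The imaging arm works the same way from pixels:

```r
im   <- generate_image(image_spec(n_tiny = 10, n_small = 5, n_large = 2, seed = 4))
mask <- segment_tissue(im$image)
dr   <- segment_droplets(im$image, mask, pixel_size_um = 0.25)
compute_profile(dr, sum(mask) * 0.25^2)
#> Morphometry profile (% of tissue area)
#>   tiny 0.022 | small 0.323 | large 5.387 | total 5.732
#>   tissue area: 13108 um^2; droplets: tiny=10 small=5 large=2
```

All 17 generated droplets are recovered with their exact rasterized areas.

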