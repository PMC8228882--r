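# mammodensity

Quantification and spatial-pattern analysis of mammographic breast density
(MBD) from masked grayscale mammograms, with a synthetic phantom generator
that makes the whole pipeline testable against known ground truth.

## The problem

MBD — the share of radiodense fibroglandular tissue in the breast — is a
strong breast-cancer risk factor, and its *spatial arrangement* carries
information beyond the amount alone: dense tissue may be clustered in one
zone of the breast or scattered across it. This package implements, as a
reproducible pipeline, the analysis chain used in density studies of
screening mammograms:

1. **Segmentation.** Within the breast mask, the radiodense class is
   separated from the radiolucent (adipose) class by the maximum-entropy
   (Kapur) threshold: the level `t` maximizing
   `ψ(t) = H_low(t) + H_high(t)`, the summed Shannon entropies of the two
   histogram classes the threshold induces.
2. **Percent density.** Overall PD = 100 × dense pixels / breast pixels;
   regional PDs over an 8 × 6 grid of 48 equal rectangular sub-regions;
   zonal PDs as the mean regional PD in the posterior / middle / anterior
   column bands between chest wall and nipple.
3. **Spatial autocorrelation.** Global Moran's I over the 48 regional PDs,

       I = N / (ΣᵢΣⱼ wᵢⱼ) · ΣᵢΣⱼ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / Σᵢ (xᵢ − x̄)²,

   with inverse-square-distance weights `wᵢⱼ = 1/d²ᵢⱼ` between tile
   midpoints; `I > 0` is a clustered pattern, `I ≈ 0` random, `I < 0`
   scattered.
4. **Cohort statistics.** Pearson correlation of overall PD with age,
   chi-square tests of pattern by BI-RADS density group, Kruskal–Wallis /
   Friedman / Mann–Whitney comparisons of zonal PDs, and stratified mean
   regional-PD heatmaps.

Clinical mammograms are consumed as PNG images plus a breast mask (or ROI
polygons); since no clinical archive ships with the package, a phantom
module generates MLO-like synthetic cohorts (curved breast contour,
pectoral cut-out, fibroglandular blobs with controllable dense fraction and
placement, Gaussian noise) with exported ground-truth masks.

## Worked example

```r
library(mammodensity)

ph <- generate_phantom(phantom_spec(dense_fraction = 0.25, seed = 7))
ph
#> phantom: 160x128, 13901 breast px, planted dense fraction 0.250
#> (target 0.250), placement uniform, seed 7

q <- quantify_density(ph$image, ph$breast_mask)
q$threshold          # 97  (maximum-entropy split of the noisy bimodal histogram)
q$overall_pd         # 28.3  (percent; planted truth is 25.0)
round(q$zonal, 1)
#> posterior    middle  anterior
#>      19.2      36.2       3.0
q$moran
#> Moran's I = 0.2371 over N = 48 tiles (inverse_distance_squared weights):
#> clustered pattern
```

The threshold lands between the adipose (80) and dense (200) intensity
modes, overall PD recovers the planted 25% to within the noise-induced
bias, and the blob-grown dense tissue is correctly read as a clustered
spatial pattern.

## Analysis workflow

The `analysis/` scripts run the full study-style workflow on a 200-subject
synthetic cohort and write tables under `results/` (figures under
`scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R     # cohort with planted age slope + clustering shares
Rscript analysis/02_quantify_density.R    # per-subject segmentation and PDs
Rscript analysis/03_spatial_patterns.R    # Moran patterns vs density groups
Rscript analysis/04_cohort_comparisons.R  # age/zonal/group comparisons + heatmaps
```

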