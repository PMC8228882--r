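---
title: "Methods: density quantification, spatial autocorrelation, and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density quantification, spatial autocorrelation, and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mammodensity)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and what validation
on synthetic phantoms does and does not establish.

## Segmentation model

A masked mammogram is a mixture of two intensity populations: radiolucent
adipose tissue (dark) and radiodense fibroglandular tissue (bright). The
package separates them with the maximum-entropy threshold: over the 256-bin
intensity histogram of the *in-mask* pixels, it picks the level $t$
maximizing

$$\psi(t) = H_{low}(t) + H_{high}(t), \qquad
H_{low}(t) = -\sum_{i \le t,\, p_i > 0} \frac{p_i}{P_t}\ln\frac{p_i}{P_t},
\quad
H_{high}(t) = -\sum_{i > t,\, p_i > 0} \frac{p_i}{1-P_t}\ln\frac{p_i}{1-P_t},$$

with $p_i$ the bin probabilities and $P_t$ the cumulative mass at or below
$t$. Conventions, fixed once and tested everywhere:

* natural logarithms, $0 \ln 0 := 0$ (zero bins skipped); the log base only
  rescales $\psi$ and cannot move the argmax;
* candidates are levels with mass on both sides ($0 < P_t < 1$); ties in
  $\psi$ break toward the smallest level, so the result is deterministic
  (a two-bin histogram has a flat $\psi$ plateau and returns the lower bin);
* a pixel is *dense* iff it is in-mask and **strictly above** $t$: the
  threshold level itself belongs to the lower class;
* the histogram is restricted to the mask by default (`hist_scope =
  "mask"`). Thresholding the whole cropped frame would let the black
  background dominate the low class; because interactive tools typically
  threshold whole frames, the frame-scope variant is kept available, and
  which scope produced a given result is the caller's explicit choice.

Overall percent density is $100 \times$ dense pixels / breast pixels.

## Regional grid, zones

The frame is split into an 8 × 6 grid of 48 rectangular tiles. Non-divisible
dimensions assign the remainder pixels to the last tiles of each axis; tile
sizes never differ by more than one pixel and the tiles partition the frame
exactly (a tested invariant). Regional PD uses the whole tile area as
denominator by default — the grid is applied to the already-segmented binary
image, where off-breast background counts as non-dense — with a mask-aware
denominator (`denominator = "mask"`) available when per-tile breast coverage
should normalize the values.

Zones are contiguous two-column bands along the chest-wall→nipple axis:
posterior (2 columns nearest the chest wall), middle, anterior. The split is
a package convention — three equal bands — exposed through
`default_zones()` / `ZoneDefinition`-style configuration, with the chest
wall side an explicit parameter (`left` for left-MLO). Zonal PD is the
unweighted mean of the zone's 16 regional PDs.

## Spatial autocorrelation

Global Moran's I over the 48 regional PDs:

$$I = \frac{N}{\sum_i \sum_j w_{ij}}\;
\frac{\sum_i \sum_j w_{ij}(x_i - \bar x)(x_j - \bar x)}
     {\sum_i (x_i - \bar x)^2}.$$

* **Weights.** Default $w_{ij} = 1/d_{ij}^2$ over *all* tile pairs, with
  $d_{ij}$ the Euclidean distance between tile midpoints in tile units
  (adjacent midpoints are distance 1). Midpoint units make $w$ dimensionless
  and image-size independent; any uniform rescaling of $d$ cancels between
  numerator and normalizer anyway. Because "adjacency" weighting is a common
  alternative reading, `rook` and `queen` contiguity schemes (inverse-square
  weights restricted to neighbours: 1 for edge neighbours, 1/2 for queen
  diagonals) are provided, and every result records its scheme.
* **Tiles included.** All 48 tiles enter, including breast-exterior tiles
  whose PD is 0, keeping the fixed 48-region design comparable across
  subjects.
* **Degenerate input.** A constant field has zero variance and Moran's I is
  undefined; the package raises an error rather than returning a value.
* **Pattern rule.** $I > \varepsilon$ clustered, $|I| \le \varepsilon$
  random, $I < -\varepsilon$ scattered; $\varepsilon = 0$ by default (the
  strict sign rule), configurable for floating-point robustness.

Correctness is established against a brute-force triple-loop implementation
of the double sums (relative error below $10^{-10}$ on random grids under
all three schemes) and hand-checked micro-cases: a 2 × 2 checkerboard gives
$I = -0.6$; a 1 × 4 line with values $(1,1,0,0)$ gives $I = 7/65 \approx
+0.108$.

## Phantom generator

Phantoms emulate what the downstream stages need from an MLO mammogram, not
breast physics:

* **Breast mask**: a half-ellipse (semi-axes $0.97w$, $0.48h$) clipped to
  the chest-wall edge, minus a corner triangle ($0.32w \times 0.38h$) for
  the pectoral muscle — under 15% of the breast area. Simple shapes suffice
  because the pipeline only needs a realistic mask topology.
* **Dense tissue**: `blob_count` disc seeds with radii drawn uniformly in
  $[0.06, 0.16]\cdot\min(h,w)$. Every in-breast pixel gets a scaled squared
  distance $q = \min_b d_b^2/r_b^2$ to the blob seeds and the planted mask
  is the `round(dense_fraction × breast pixels)` smallest-$q$ pixels — the
  nested union of all discs grown jointly until the target is met. The
  planted fraction is therefore exact to one pixel (well inside the ±0.02
  generation tolerance), and an unreachable target raises an error
  reporting the shortfall.
* **Placement**: blob centres confined to the posterior / middle / anterior
  column bands (the same zone definition the measurement side uses, so
  planted and measured zones coincide by construction), `uniform` anywhere
  in the breast, or `checkerboard` — alternating grid tiles filling from
  their midpoints, a planted negative-autocorrelation (scattered) pattern.
  Checkerboard tissue can occupy at most roughly half the breast, so the
  cohort generator caps checkerboard subjects' fractions at 0.45.
* **Rendering**: adipose level 80, dense level 200 (separation 120, typical
  of film-screen contrast after windowing), Gaussian noise of SD 10 inside
  the mask only, rounded and clipped to [0, 255] so phantoms are valid
  8-bit rasters; off-mask pixels are exactly 0. Identical spec + seed is
  bit-reproducible, and generation restores the caller's RNG state.

Cohorts draw ages uniformly on 35–90 years; the planted dense fraction is
`base_fraction + age_slope × (age − mean age) + N(0, fraction_sd)` clipped
to [0, 1], with defaults `base_fraction = 0.25`, `fraction_sd = 0.05`, and
`age_slope = -0.004`/year (−0.4 PD points per year — a decline of the size
density studies report across the 35–90 range). BI-RADS-like groups A–D are
assigned by planted-fraction quartiles so every group is populated at any
cohort size; each group's clustered-placement share defaults to the
clustered-pattern proportions reported for screening BI-RADS groups
(74.0 / 66.1 / 46.2 / 49.2%). Clustered placements favour the middle zone
in mature (< 65) subjects (probabilities 0.2 / 0.6 / 0.2 over posterior /
middle / anterior) and split posterior–middle in older subjects
(0.45 / 0.45 / 0.10), planting the mature middle-zone excess the cohort
statistics look for.

What phantoms do **not** emulate: X-ray physics, breast thickness and
compression, film-digitization artefacts, skin-line gradients, or
anatomically textured fibroglandular tissue. Passing the phantom suite
shows the pipeline recovers what was planted under its own image model; it
does not certify accuracy on clinical mammograms, where ROI quality and
histogram shape differ.

## Cohort statistics

All tests are two-sided at $\alpha = 0.05$. Age groups: mature 35–64,
older 65–90. Density groups: less dense {A, B} vs denser {C, D}.

* Pearson correlation for age vs overall PD.
* Chi-square (no continuity correction) for pattern-by-group tables; a
  low-expected-count condition is flagged, not fatal.
* Kruskal–Wallis for a zonal PD across groups.
* Friedman within subject across the three zones, with the three pairwise
  signed-rank follow-ups reported both raw and Bonferroni-adjusted (the
  adjustment is named in the output rather than silently applied).
* Mann–Whitney for a zonal PD between age groups: exact null distribution
  when both groups have ≤ 20 observations, otherwise the normal
  approximation with continuity and tie correction.
* Full-tie degenerate inputs (every observation equal) return statistic 0
  and $p = 1$ instead of the NaN the raw tests produce.
* Zonal summaries report median, IQR and SD side by side, so results can be
  compared against conventions that pair medians with either spread
  measure.

## Validation design and problem sizes

The validation suite runs at desk scale, chosen so the full suite completes
in minutes on one CPU:

* phantoms 96 × 72 pixels (the spatial statistics operate on the 48-tile
  grid, which is size-independent; larger frames only refine the planted
  fraction's granularity);
* density recovery: 20 seeds per planted fraction {0.10, 0.25, 0.50} at
  noise SD 10;
* pattern recovery: 100 seeds per pattern class;
* cohort reproduction: 100 cohorts of 200 subjects. With the
  clinically-calibrated default clustering shares (~0.70 vs ~0.48 after
  collapsing groups), a two-proportion power calculation at $n = 200$ gives
  only ~87% power for the pattern-by-density-group chi-square, so the
  validation cohorts plant a stronger contrast (shares 0.85 / 0.80 vs
  0.35 / 0.30), sized a priori so a correctly implemented pipeline detects
  the planted effect in ≥ 95% of seeds. The defaults remain the clinical
  values; the analysis workflow uses them and reports whatever it finds.
* type-I calibration: 1000 null cohorts of 80 subjects, generated directly
  at the record level (`simulate_null_records()`): every cohort test is a
  function of the record table alone, so image-level nulls would add
  runtime, not coverage.

## Known limitations

* The in-mask histogram scope is a deliberate deviation from whole-frame
  interactive thresholding; on clinical images the two scopes can give
  different thresholds, which is why the scope is explicit and recorded.
* Kapur thresholding assumes a usable bimodal structure; on nearly
  fraction-0 or fraction-1 breasts the entropy split falls inside the
  single mode and overestimates the minority class. The generator's default
  fraction range keeps clear of these regimes; real "entirely fatty"
  breasts are the clinically analogous failure mode.
* The 2/2/2 zone split and the all-pairs inverse-square weighting are
  documented conventions where the underlying field practice varies; both
  are configurable, and the alternatives (mask-aware denominators,
  contiguity weights) ship behind explicit parameters.
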