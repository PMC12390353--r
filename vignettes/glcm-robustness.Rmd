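---
title: "Quantifying the robustness of GLCM texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the robustness of GLCM texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmrobust)
```

## The problem

Second-order texture features computed from the gray-level co-occurrence
matrix (GLCM) are popular radiomic measurements, but their raw magnitudes
are driven as much by *estimation choices* — gray-level quantization `Q`,
region-of-interest (ROI) size, pixel offset `d`, angle policy, and
post-processing filters — as by the tissue being imaged. When images from
different vendors or processing chains are pooled, these choices differ,
and models inherit the resulting instability. `glcmrobust` measures these
effects on controlled synthetic slabs and implements a multi-resolution
min-max normalization that removes quantization-scale disparities while
preserving trends.

## The synthetic phantom

Clinical or physics-simulated tomosynthesis slabs are large, proprietary,
or both, so the package generates its own study material: a two-tissue
slab with controllable composition and spatial correlation.

* A white-noise field is smoothed with an isotropic Gaussian kernel whose
  standard deviation is the `correlation_length` (default 4 px — at the
  0.27 mm in-plane resolution typical of reconstructed DBT slabs this
  puts tissue structures at the millimeter scale).
* The smoothed field is thresholded at the `1 - density_fraction`
  quantile, so the realized dense-class area fraction matches the target
  up to pixel-count resolution by construction. The study arms use 25%
  and 50%, the two compositions of interest.
* The two classes are mapped to mean intensities
  `tissue_values = c(adipose = 1200, fibroglandular = 900)`. Intensities
  are *detector-count-like*: the quantum-noise stage below is a Poisson
  process, which only makes sense for count-type signals, and in count
  space the denser, more attenuating fibroglandular tissue yields the
  lower signal. This convention also fixes the sign behavior of the
  odd-moment cluster shade: at 25% density the dark minority class skews
  the GLCM negative, while the symmetric 50% composition sits near zero,
  so shade separates the density arms with 50% above 25%.
* Acquisition noise is `Poisson(gain * pixel) / gain` followed by
  additive Gaussian electronic noise. Defaults `quantum_gain = 1`,
  `electronic_sigma = 15` give a total noise SD of about 35 intensity
  units against a 300-unit tissue contrast — quantum-limited imaging with
  a small electronic floor.
* An optional half-ellipse breast outline restricts the analysis mask and
  exercises the boundary-ROI exclusion rules; by default the field is
  full-rectangle and the mask is all-true.

Every stage is seeded; identical seeds give bit-identical slabs.

## Pre-processing

**Adaptive Wiener filter.** The local minimum-mean-square-error denoiser:
per-pixel window mean `m` and variance `v` (default 5×5, truncated at
borders), noise estimate `vbar` = mean of local variances over the mask,
and output `m + max(0, v - vbar) / max(v, vbar) * (x - m)`. This is the
classic parameter-free local-statistics filter: smooth regions collapse
to their mean, structured regions pass through.

**Quantization.** Pixels inside the mask are min-max scaled to `[0, 1]`,
multiplied by `Q - 1`, and rounded to the nearest integer with halves
away from zero (fixed for cross-platform reproducibility). Scaling by
`Q - 1` rather than `Q` is a deliberate choice: multiplying by `Q` would
produce `Q + 1` possible integers, whereas the analysis requires exactly
`Q` levels so that a `Q`-level image yields a `Q × Q` GLCM. Min and max
are computed per slab within the mask — the only self-contained reading
when each image must be processable on its own. Constant slabs are a
degenerate-normalization error.

## GLCM construction and features

The image is tiled from the top-left into non-overlapping `s × s`
windows; incomplete boundary tiles are discarded (padding would inject
synthetic texture), and windows with less than 50% in-mask pixels are
dropped and recorded in the lattice's coverage policy. Within a window,
ordered pairs at the displacement for angle `θ` and offset `d` are
counted with both endpoints required in-mask; the transpose is added
*before* normalization (Haralick's convention — opposite directions are
transposes, so four angles suffice), and the counts are divided by their
total. Offsets with `d >= s` have no pairs and are skipped and logged at
pipeline level rather than raising errors, which matters for the ROI of
10: only offsets 1, 5 and 7 exist there.

The ten features are the standard sums over `G(i,j)` with 0-based levels.
Three numerical decisions:

* **GLCM variance.** The feature is reported as
  `σx = sqrt(Σ G (i - μx)²)`, the standard definition; a first-power
  "variance" would be identically zero for any distribution.
* **Degenerate correlation.** A window that quantizes to a single level
  has `σx σy = 0`; correlation is set to 0 with a degeneracy flag so ROI
  averages stay finite. Constant windows carry no texture signal, and 0
  is the neutral correlation.
* **Entropy** uses the natural logarithm, with `0·ln 0 := 0`.

Magnitudes are averaged per feature over the four angles (angular
isotropy is assumed, as is conventional), then unweighted over retained
ROIs. Weighting by pair counts was considered and rejected: it would
couple the ROI mean to the offset.

## Robustness metrics

* **Consecutive-offset deltas**: mean change and mean percentage change
  over the pairs (7−5), (10−7), (15−10), (20−15); offset 1 is excluded
  because the short-offset region is where features are least robust, and
  the percentage denominator is the value at the smaller offset —
  computed pairwise and then averaged, which preserves the sign of
  monotone drifts. Zero denominators drop out of the percentage mean with
  a flag.
* **Cross-quantization range tables**: per (feature, ROI size, Q) minima
  and maxima of the per-image means across images and offsets, pairing a
  low and a high quantization.
* **Condition contrasts**: paired differences of every parameter
  combination across a two-level condition (filter arm or density arm).

## Multi-resolution normalization

Within each series — the offsets of one ROI size (`fixed_roi`, default)
or the ROI sizes at one offset (`fixed_offset`) — values are min-max
rescaled to `[0, 1]`, independently per quantization level and condition.
The map is invariant to positive affine rescaling of the raw feature,
which is precisely the mechanism by which quantization-scale disparities
collapse: on the synthetic ensemble the raw contrast ratio between
`Q = 128` and `Q = 8` exceeds two orders of magnitude while the
normalized curves differ by well under 1% of the unit scale, with rank
correlation 1 between raw and normalized monotone series. Constant series
are mapped to 0 and flagged degenerate rather than producing 0/0.

## Statistical analysis

Feature columns are first screened for redundancy: pairwise absolute
Pearson correlations, computed within each scenario stratum (density ×
filter arm) and averaged across strata, feed a greedy filter that drops
one member of every pair with mean |r| above 0.85 (the member with the
larger mean correlation to everything else; constant columns are dropped
first). The stratified mean guards against correlation inflated purely by
arm-to-arm mean shifts.

Per retained feature, fixed-effects linear models of the magnitude on
ROI size, offset and quantization — all categorical, since the study
grids are small and discrete — are fit with main effects, all 2-way
interactions, and the 3-way term. Per-term F tests use Type II sums of
squares (`car::Anova`), which remain well defined for this necessarily
unbalanced design: offset ≥ ROI cells simply do not exist, and Type II
respects marginality without depending on an arbitrary contrast coding.
R² is reported per model order and is non-decreasing by nesting.
Significance is flagged at α = 0.01. The multivariate analysis stacks
the retained features and reports the Pillai trace by default — the most
robust of the classical MANOVA statistics to covariance heterogeneity —
with Wilks, Hotelling-Lawley and Roy available.

On surfaces simulated with known factor structure the machinery recovers
it: a constructed dominant quantization effect yields the largest F by a
wide margin, absent three-way interactions are rejected at the nominal
1% rate, and built-in interactions are detected with high power.

## Problem sizes

The test suite and the acceptance script run the full method at reduced
scale: slabs of 160×160 (analysis scripts use 240×240), two images per
density arm, ROI sizes {10, 25, 50} ({10, 25, 50, 100} in the analysis
scripts), the full quantization set {8, 32, 64, 128} and offset set
{1, 5, 7, 10, 15, 20}. These sizes were chosen so that each ROI size
retains at least four windows per slab and the complete grid runs in
about a minute; all qualitative conclusions are stable across seeds at
this scale.

## What the phantom does and does not emulate

The generator reproduces the *statistical* structure the analysis needs:
two tissue classes at an exact density fraction, millimeter-scale spatial
correlation, count-domain quantum plus electronic noise, and a
denoisable/filterable arm. It deliberately omits X-ray projection
physics, detector blur, reconstruction artifacts, and anatomical ductal
structure. Passing tests therefore demonstrate correctness of the texture
mathematics and the direction of parameter effects on images with this
statistical character — not quantitative agreement with any clinical
dataset.

One consequence deserves emphasis. In a strictly two-valued phantom the
slab's intensity extremes are set by *noise tails*, not anatomy. Because
quantization normalizes by the per-slab min-max range, denoising shrinks
that range and thereby *raises* quantized contrast wherever tissue
structure dominates pixel differences (offsets ≥ 5); only at offset 1,
where noise dominates, does Wiener filtering lower contrast. Clinical
slabs behave differently — their intensity range is anatomy-dominated,
so filtering lowers contrast across offsets. This is a real and
instructive interaction between min-max quantization and noise filtering,
and it is a known limitation of two-valued phantoms: conclusions about
the *direction* of filter effects on quantized features do not transfer
from this phantom to anatomy-dominated images.

Other known limitations: the phantom is 2D only (no 3D/VOI co-occurrence),
the density label is a free parameter rather than a clinical
distribution, and the ANOVA treats per-image surface values as
independent replicates, ignoring within-slab spatial correlation between
ROI means.
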