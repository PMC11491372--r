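---
title: "Methods: quantifying ER remodeling at the B-cell immune synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ER remodeling at the B-cell immune synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isquant)
```

## Scope and conventions

`isquant` quantifies organelle redistribution in single-cell, multi-channel
confocal Z-stacks of B cells forming an immune synapse (IS). A stack is one
cropped cell; voxel sizes `(dz, dy, dx)` are carried in micrometres, and
**slice 1 is always the slice nearest the coverslip** — readers flip
source data stored in the opposite order (`z_flip = TRUE`). Intensities are
kept in their native scale; there is no background subtraction, rescaling or
deconvolution anywhere in the pipeline.

The synapse plane is operationalized as the first `⌈0.1 · n_z⌉` slices. The
ceiling guarantees at least one slice for short stacks; at the reference
acquisition (0.14 µm z-step, 20 slices) it is 2 slices ≈ 0.28 µm, a thin
slab whose physical depth is comparable across cells imaged with the same
settings. The fraction (default 0.10) is a parameter everywhere it is used.

## Segmentation

All statistics are computed inside a cell mask. The original macro-based
workflow implies a manually drawn ROI; to keep the pipeline unattended the
mask is computed automatically: Gaussian smoothing (σ = 1 px in XY, 0.5
slice in Z — enough to suppress shot noise without moving boundaries at the
scale of the metrics), a global Otsu threshold, box closing (radius 1×2×2
voxels), 3-D hole filling, and retention of the largest 26-connected
component. A user-supplied mask TIFF bypasses all of this, so hand-drawn
ROIs can be reproduced exactly. A mask covering more than half the stack, or
an empty mask, is treated as a hard error rather than a warning.

The **actin footprint** (spreading area) thresholds the actin channel within
the synapse slab, projects to XY, fills the interior of the cortical ring
and keeps the largest component, clipped to the XY projection of the cell
mask. The **MTOC** is the maximum of the Gaussian-smoothed tubulin channel
inside the mask — on an aster this is the centrosomal punctum, and it
matches the "best slice for MTOC visualization" reading used when such data
are scored by eye. Ties break deterministically toward the lowest
`(z, y, x)` index. Beads are unlabeled latex in the underlying experiments,
so bead positions are annotations, not detections.

One difference from the original per-slice ROI workflow is documented
rather than hidden: a full 3-D mask is used for all slices instead of a
single 2-D ROI, and per-slice sums are restricted to that mask (not the
whole frame), which makes the Z-scan robust to off-cell debris.

## The statistics

**Z-scan / IS fraction.** `raw_k` is the channel sum over mask ∩ slice `k`;
`pct_k = 100 raw_k / Σ raw_j`. The percentages sum to 100 up to float
tolerance by construction, are invariant to any positive intensity gain,
and a zero whole-cell total is an explicit error, never a NaN row. The IS
fraction sums `pct` over the synapse slab.

**Polarity index.** For bead conjugates (no coverslip, so no slab
statistic): `PI = ((F − C) · û) / R`, with `C` the mask centroid, `F` the
intensity-weighted centroid, `û` the unit vector from `C` to the bead and
`R` the distance from `C` to the mask boundary along `û`, all in physical
units so the anisotropic z-step is handled correctly. `R` is measured by
ray-marching the mask at quarter-voxel steps. Values marginally outside
`[−1, 1]` (possible through discretization) are clamped with a warning. The
exact formula of the originally cited polarity macro is not published with
the experiments this mirrors; this centroid-projection definition follows
the published measurement scheme and is stated here as this package's
definition.

**Pearson colocalization.** Plain (non-thresholded) Pearson `r` over the
mask voxels of the synapse slab. The headline Pearson coefficient of the
Coloc2-style analysis is the non-thresholded one, so Costes thresholding and
Manders coefficients are deliberately out of scope. Zero variance in either
channel is an explicit error.

**MTOC-proximal density.** Mean fluorescence over pixels whose centers fall
inside a circle of physical diameter 4 µm (preset "A20") or 2 µm
("primary"), on the MTOC slice and its two neighbors. The circle is *not*
intersected with the cell mask — it is the circle as drawn in the original
analysis. Design choices made where the published description is silent:
the mean pools the voxels of the three slices (identical to the mean of
slice-means only when all slices contribute equal counts, which they do
here); pixels are included by a center-in test without partial-pixel
weighting; and at the stack boundary the missing neighbor slice is dropped
(2-slice cylinder) with a warning rather than reflected.

**Morphometry.** ER area at the synapse: Otsu threshold computed *within
the cell mask* (off-cell background would dominate a whole-frame
histogram), binary OR projection over the slab, pixel count × pixel area.
The projection covers the slab rather than a single slice because the
synapse "plane" is the slab defined above. ER volume: same in-mask Otsu,
26-connected components (the Fiji 3D Objects Counter convention),
components below `min_object_voxels = 5` discarded as noise speckle (the
original settings are unstated; the filter is declared and configurable),
volume = retained voxels × voxel volume. An empty result is volume 0 with
`n_objects = 0`, and a cell with no supra-threshold ER at the synapse
legitimately reports area 0 with a warning (unspread cells).

**Group statistics.** Per-cell values are pooled across experiments
(whether the original analyses pooled per-cell or per-experiment is
unstated; pooling is the declared choice, and no per-experiment nesting or
mixed models are attempted — a documented limitation). One-way ANOVA with
Tukey HSD for ≥ 2 groups, Student's equal-variance t-test for 2 groups
(the classical "Student's test" reading), means ± SEM, and the conventional
asterisk thresholds. Fully degenerate input (all observations identical)
reports the null identity F = 0, p = 1 explicitly.

## The synthetic world

The generator exists so that every statistic can be validated against known
truth. Its central contract: **every `SceneTruth` field is measured on the
noise-free stack by direct per-voxel summation, never copied from the
request**. Recovery tests therefore test the pipeline, not the generator's
calibration, and a request the geometry cannot realize fails loudly.

**Coverslip cell** (`generate_coverslip_cell()`): a hemispheroid (default
lateral radius 5 µm, axial semi-axis 2.2 µm — an A20-like cell spread on
glass) resting on slice 1, sampled at 0.14 × 0.2 × 0.2 µm over a
20 × 72 × 72 stack. The actin channel is a cortical shell plus a synaptic
actin layer and a dim cytoplasmic fill; tubulin is an aster of rays from a
bright MTOC punctum. The ER is painted on a support of `top-N` voxels
(N = ER volume / voxel volume, default 12 µm³) ranked by a score combining
a smooth random texture (correlation length 0.5 µm), an attraction onto the
microtubule ray lattice (`er_tubulin_coupling` — ER tubules ride
microtubules, and this is what the colocalization statistic sees), an
attraction to the MTOC region (`mtoc_pool`, the perinuclear pool), and an
axial term `−λz`. λ is calibrated by root finding so the noise-free synapse
slab holds the requested fraction of ER signal to within 1%. The axial term
is signed: the slab share of a *uniform* painting is ~0.13–0.18 for this
geometry, and requests below that floor are legitimate (resting cells), so
λ < 0 tilts the support upward. Placement (rather than an exponential
intensity gradient) carries the enrichment so that thresholded volume
recovery remains well-posed: an intensity-only exponential would make
upper-cell ER arbitrarily dim and undetectable by any threshold.

Per-cell biological variability multiplies the ER support volume and the
whole-cell total by lognormal factors (CV 12%, a typical cell-to-cell
spread for organelle content). Without it, between-condition tests would
see only technical noise and reject null contrasts on artifacts.

**Noise**: Poisson on the noise-free signal (peak ≈ 200 counts), Gaussian
read noise σ = 2 counts, rounded and clamped at zero — integer camera
counts, chosen so recovery tolerances are attainable but not trivial.
An optional PSF blur exists but defaults off: the statistics are
intensity-sum statistics largely insensitive to modest blur.

**Bead conjugate** (`generate_bead_conjugate()`): a 3.2 µm-radius sphere
with the bead adjacent along a configurable axis, 40 × 0.25 µm slices. The
ER support (default 8 µm³) is placed by the same top-N mechanism with an
axial score `+k·proj` along the cell–bead axis, and the within-support
intensity is tilted by the same rate capped at 5; `k` is calibrated so the
realized, noise-free normalized centroid offset equals the requested
polarization. Two numbers explain the defaults: a support much larger than
~8 µm³ cannot concentrate enough mass near the pole to realize |PI| = 0.8
at all (the centroid of the corresponding spherical cap sits below 0.8 R),
and an uncapped intensity tilt makes most of the organelle so dim that the
clamped read-noise floor — whose centroid is the cell center — visibly
shrinks the estimate toward zero. With texture off the support is placed
radially, so a zero-polarization cell is genuinely symmetric.

**Coupled channels** (`generate_coupled_channels()`): ER = `coupling` ×
(scaled tubulin pattern) + (1 − coupling) × independent smooth pattern over
the cell body, before noise; truth records the measured noise-free Pearson
r in the mask. At coupling 1 and zero noise the channels are exact
rescalings (r = 1 exactly).

**The four-condition demo** (`run_paper_demo()`): presets for resting,
activation on glass, and on 13 kPa / 0.3 kPa polyacrylamide gels encode the
experimental phenotypes as generator parameters — synapse-slab fraction
0.15 / 0.60 / 0.42 / 0.25, spreading radius 3.5 / 5.5 / 4.6 / 3.8 µm, MTOC
pooling 0.10 / 0.90 / 0.40 / 0.18, ER–microtubule coupling 0.55 / 0.20 /
0.35 / 0.55 (soft substrates fail to trigger decolocalization), with ER
support volume and whole-cell totals held constant across conditions
(activation redistributes the ER without net growth). The demo runs the
full pipeline on 10 cells per condition and checks the directional
orderings plus the two null contrasts (volume, whole-cell total) on the
pipeline's own output.

## What a green test does and does not establish

The generator emulates the geometry and noise that the statistics are
sensitive to: axial mass distribution, spreading footprint, a bright MTOC,
channel coupling, camera noise. It does not emulate real optics (no
realistic PSF by default, no spectral bleed-through), membrane-contact-site
microstructure, ER sheet/tubule morphology, multi-cell fields, or live-cell
dynamics. Recovery within tolerance therefore establishes that the
*computations* are correct and robust at realistic SNR — not that the
biological estimates from any particular microscope are unbiased.

Known quantitative limitations, visible in the package's own tests:

- The summed noise floor over the mask dilutes extreme slab fractions
  (a true 90% bottom fraction reads ≈ 86% at default noise) and shrinks
  extreme polarity indices by a few percent. Real measurements summing raw
  intensities over an ROI share this property.
- Whole-cell totals include the noise floor integrated over the mask, so
  cells segmented with different mask volumes differ slightly even at equal
  true totals; with many cells this makes the "no change in total
  fluorescence" null contrast mildly anticonservative. At the demo's sample
  size (10 cells/condition, 12% biological CV) it behaves as a null at the
  default seed, but across many seeds it rejects somewhat more often than
  5%.
- ANOVA type-I error is calibrated (5% ± 1.5% over 1000 null simulations in
  the acceptance suite), but the demo's ordering checks compare group means
  directionally and are not themselves significance tests.

## Numerical choices

- Otsu thresholds use a 256-bin histogram between the observed min and max;
  `x > threshold` is foreground.
- Gaussian smoothing uses reflect-101 boundaries and truncates kernels at
  3σ; closing uses a separable box element.
- Connected components use an explicit-stack flood fill (no recursion
  limits); hole filling floods the background from the array border with
  6-connectivity.
- Root-finding calibrations (`λ`, `k`) use `uniroot` on measured
  quantities; the realized value is re-measured afterwards and generation
  aborts if it misses the request by more than the documented tolerance
  (0.01 for fractions).
- All RNG is seeded per cell; `(params, seed)` is a pure function of the
  output, and generators save and restore the caller's RNG state.
- Line scans sample at unit-pixel spacing with bilinear interpolation;
  reversing the endpoints reverses the profile exactly.
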