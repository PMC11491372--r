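# isquant

Quantification of endoplasmic-reticulum (ER) remodeling at the B-cell immune
synapse from multi-channel 3-D confocal stacks.

When a B cell meets surface-tethered antigen it forms an immune synapse (IS):
the cell spreads over the antigen-presenting surface, the microtubule-
organizing center (MTOC) repositions toward the contact site, and the ER is
redistributed — enriched in the synapse-proximal optical slices, pooled
around the MTOC, and extended laterally with the spreading actin ring. This
package implements the image-quantification statistics used to measure that
remodeling, for researchers analyzing per-cell confocal Z-stacks of B cells
(or similar immune cells) with ER, α-tubulin and actin channels:

- **Z-scan profile** — per-slice fluorescence of a channel inside the cell
  mask, each slice expressed as a percentage of whole-cell fluorescence:
  `pct_k = 100 * raw_k / Σ_j raw_j`. The **IS fraction** is the summed
  percentage over the synapse plane, defined as the first `⌈0.1 n_z⌉` slices
  nearest the coverslip.
- **Polarity index** (bead conjugates) — with cell-mask centroid `C`,
  fluorescence centroid `F`, unit cell→bead axis `û` and centroid-to-boundary
  distance `R` along `û`: `PI = ((F − C)·û) / R ∈ [−1, 1]`.
- **Pearson colocalization** — plain Pearson `r` of two channels over the
  cell-mask voxels of the synapse slab.
- **MTOC-proximal density** — mean channel fluorescence in a circle (4 µm for
  A20 cells, 2 µm for primary B cells) centered on the MTOC, pooled over the
  MTOC slice and its two neighbors.
- **Morphometry** — ER area at the synapse plane, actin-delimited spreading
  area, their ratio, and 3-D ER volume by 26-connected components
  ("3D Objects Counter" style), all in physical units.
- **Group statistics** — one-way ANOVA with Tukey HSD, Student's t-tests,
  group means ± SEM, asterisk thresholds 0.05/0.01/0.001/0.0001.

Because no raw imaging data are publicly deposited for this kind of
experiment, the package ships a **synthetic stack generator**
(`generate_coverslip_cell()`, `generate_bead_conjugate()`,
`generate_coupled_channels()`) that simulates spread B cells and
bead conjugates with Poisson + Gaussian camera noise, and records *measured*
ground truth (slab fraction, polarization, Pearson r, painted volume) from
the noise-free stack. Every statistic above is validated end-to-end against
that truth in the test suite.

## Worked example

```r
library(isquant)

# a simulated activated cell: 60% of ER fluorescence in the synapse slab
gen <- generate_coverslip_cell(coverslip_params(bottom_fraction = 0.6), seed = 42)
q   <- quantify_cell(gen$stack, "demo_cell", condition = "activated_glass",
                     timepoint_min = 60)
str(q$record$metrics)
#> List of 8
#>  $ is_fraction_pct        : num 57.4
#>  $ whole_cell_fluorescence: num 275470
#>  $ pearson_r              : num 0.0712
#>  $ mtoc_density           : num 39.1
#>  $ er_area_um2            : num 35.9
#>  $ actin_area_um2         : num 79
#>  $ spreading_ratio        : num 0.454
#>  $ er_volume_um3          : num 14
gen$truth$true_bottom_fraction   # measured generator truth: 0.6002
gen$truth$true_object_volume_um3 # 14.04
```

The cell was generated with 60% of its ER in the synapse slab; the pipeline
reads back 57.4% (the summed noise floor over the mask dilutes the slab share
slightly), recovers the 14.04 µm³ painted ER volume as 14.0 µm³, and reports
a spreading ratio of 0.45 — ER covering about half the actin footprint
(79 µm² ≈ π·5² for the 5 µm spreading radius used).

Batch analysis: `generate_condition_suite()` → `run_pipeline()` →
`records.csv`, `zprofiles.csv`, `stats.csv` and a run log;
`run_paper_demo()` runs a four-condition suite (resting, activation on
glass, 13 kPa and 0.3 kPa polyacrylamide gels) and checks the expected
phenotype orderings on the pipeline's own output. A thin CLI over the same
functions is in `inst/scripts/isquant-cli.R`
(verbs `generate`, `quantify`, `stats`, `demo`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full demonstration analysis from scratch: it generates the
four-condition synthetic suite at the given seed, runs segmentation,
quantification and group statistics through the installed package, prints
every between-condition comparison (group means ± SEM, ANOVA F/p, Tukey
pairs) and the phenotype-ordering checks, and writes the results JSON to
`--out`.
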