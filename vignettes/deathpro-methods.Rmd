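---
title: "Methods: live/dead imaging drug screens from pixels to pharmacogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: live/dead imaging drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deathpro)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## The assay model

A well is stained with two DNA dyes: Hoechst enters all cells (dim in live
nuclei, bright in dead ones), propidium iodide (PI) only enters dead cells.
Confocal stacks taken at the same stage position at 0, 72 and (in 3D
culture) 144 h are collapsed to maximum-intensity projections. All
downstream quantities are *area* measurements on binary masks — not object
counts — because coarse projections of organoids do not resolve single
nuclei and areas are robust to morphology:

* death ratio = PI-mask area / (Hoechst ∪ PI)-mask area, in [0, 1];
* growth = total-mask area at t divided by the area at 0 h.

## Segmentation

Each channel is median-smoothed (disk kernel; the default radius 0.5 is
the 5-pixel cross under the source platform's radius convention; radius
below 0.5 is the identity) and thresholded by the local-mean rule
`pixel > mean(window) + c` with a square window of side `2·radius + 1` and
reflected borders. Two passes for Hoechst:

1. a coarse pass at a radius calibrated from untreated-control images
   (below), capturing large structures;
2. a fine pass at `small_radius` (default 5 px ≈ one nucleus diameter at
   2.767 µm/px) for small low-contrast live nuclei.

PI gets one pass; we use the control-derived large radius because dead
organoid material forms large PI-bright structures (the original workflow
does not state the PI radius; it is configurable).

**Offsets.** The additive offset `c` defaults to +5 intensity units on the
0–255 working scale for Hoechst and PI. A zero offset marks roughly half
of all pure-background pixels (noise is symmetric about its local mean),
and at that density 4-connected noise clusters routinely survive any
sensible small-object filter — the background percolation threshold is
0.593, uncomfortably close. An offset just above the noise floor (5 ≈ 1.7
noise SD at the default render noise, far below the 30-unit live-signal
contrast) suppresses background detections entirely while leaving nuclei
intact. The tracker (fibroblast) channel uses the stated radius 35,
`c = −2`: the exclusion mask should err on the generous side.

**Control-radius calibration.** The coarse radius is the equivalent-circle
radius (rounded up) of the largest connected component found in the
controls, bounded to `[initial_radius, image_size/2]`. A window smaller
than a structure sees no background from its interior, so a single pass
only detects the rim of large organoids; the estimate is therefore
iterated (threshold with the current radius, re-estimate, ≤ 5 rounds) and
converges in two or three rounds. "Radius of the largest structure" is
operationalised as equivalent-circle radius rather than half the
bounding-box diagonal: it is insensitive to ragged component shapes.

**Outlier images.** High drug concentrations can shift whole-image Hoechst
intensities. With at least 3 control images per plate, an image whose
global median deviates from the median of control medians by more than
3×MAD is flagged, re-thresholded with offsets scaled by 0.5 (more
sensitive), and marked `outlier_intensity;rethresholded` in its area
record. The 3×MAD rule and the 0.5 scale operationalise the qualitative
"adapted sensitivity parameters" of the source workflow.

**Cleanup.** `total = Hoechst ∪ PI` minus any fibroblast mask; 4-connected
components below `min_object_area` (default 20 px ≈ 150 µm², sub-nuclear
debris) are removed; `dead = PI ∩ total`, so `dead ⊆ total` by
construction.

## Dose-response metrics

Two imaging positions per well are the only technical replicates. Death
ratios per dose are computed from *summed* areas across positions (a ratio
of sums is robust to a near-empty position), while the ANOVA gate and the
curve fit use per-position ratios as observations; growth is clamped per
position (an artefact in a single image would otherwise distort the whole
series) and averaged per dose.

Corrections, in order and each idempotent:

1. dead-cell loss: PI area at 144 h is floored at the 72-h value at the
   same position (dead cells disintegrate and lose stain, but cannot
   leave);
2. growth < 1 is set to 1 (cells migrating out of frame);
3. growth is capped at 8 (three doublings in three days — anything larger
   is an artefact) and, for drug-treated wells, at twice the median
   control growth `mgc`;
4. 144-h growth is floored at the 72-h growth.

`m` (median control death ratio) and `mgc` pool untreated and solvent
controls. `mgc` is computed from control growths clamped by rules 1, 2
and 4 only — the 2·mgc cap would be circular for controls.

**LD50.** Fitting is gated by a classic one-way ANOVA (death ratios;
groups = control plus each dose) at `p < 0.0005`, strict. The gate
prevents meaningless fits to flat series. The fitted model is the
increasing four-parameter log-logistic
`f(x) = c + (d − c)/(1 + (LD50/x)^h)` with `0 ≤ c ≤ d ≤ 1` and `h > 0` —
the "Hill slope positive" constraint is taken to mean the *kill* curve
increases with dose. LD50 is optimised on the log scale by bounded
L-BFGS-B from three data-driven starts (midpoint-crossing dose and the
geometric mid-dose, Hill slopes 1/2/4), best residual kept; a soft penalty
enforces `c ≤ d`. Non-convergence, a closed gate, or fewer than 4 distinct
doses yield `nd`, which propagates as missing everywhere except clustering
feature matrices, where an `nd` scaled LD50 is imputed as 0 (no kill
within the dose range) and flagged in an audit attribute.

**AUC.** Both AUCs integrate the *measured* per-dose values (not the
fitted curve — the fit can be `nd` while AUCs are always reported) by the
trapezoid rule over the equally spaced log3-dose index grid, divided by
the grid span, so they are dimensionless and comparable across drugs with
different absolute dose ranges. AUCd subtracts `m` and normalises positive
areas by `1 − m`, negative by `m`, giving [-1, 1]. AUCpi uses per-dose
inhibition `(mgc − growth)/(mgc − 1)` clipped to [-1, 1]; when controls
did not grow (`mgc ≤ 1 + 1e-6`) the metric is undetermined rather than a
division by near-zero. The display scaling of LD50 maps the log-dose range
onto [0, 1] (1 = minimum dose, 0 = maximum).

## Screen-level analytics

Profiles (per cell line × culture, AUCd and AUCpi across the drug panel)
cluster with Euclidean distance and complete linkage; drugs (triplet AUCd,
AUCpi, scaled LD50 averaged over cell lines) with average linkage. Rows
are sorted by key before clustering so ties break deterministically and
dendrograms are identical across input orders. Profiles with more than
half their entries missing are excluded; remaining gaps are column-mean
imputed and recorded.

The therapeutic index is `log10(LD50_normal / LD50_cancer)`: the source
figure calls favourable indices "positive" while describing a
PDCL-over-normal ratio, and this orientation makes favourable = positive;
it is antisymmetric under swapping the roles. Culture comparisons use
two-sided Welch t-tests per drug across cell lines (≥ 3 lines with both
values), combination-vs-single comparisons a paired t-test (≥ 3 pairs;
identical vectors give p = 1), replicate concordance a plain Pearson r
(≥ 3 complete pairs; zero variance gives an undefined, flagged result).
The clustering timepoint is a selector argument — which timepoint the
original profile clustering used is not documented.

## HRD-LOH scoring and association

Segments come from an allele-specific copy-number caller as
`chrom start end tcn cn_a cn_b` (0-based half-open); the package does not
estimate ploidy or call CNVs. Classification: gain when
`tcn > gain_threshold`, loss when `tcn < loss_threshold` (2.7/1.3 for
near-diploid lines, 4.7/2.3 for 3n–4n), LOH when the minor allele's copy
number is below 0.5 (configurable — e.g. a contaminated sample may need a
higher cutoff).

The modified score merges book-ended LOH segments per chromosome into
maximal regions (a region inherits loss/neutral status from its
length-weighted mean total copy number), then counts regions that are
strictly longer than 10 Mb, are losses (copy-neutral *and* gained LOH are
excluded — the source states only the copy-neutral exclusion; treating
gain-LOH as "not a loss" is this package's reading), and do not span the
chromosome's full extent *as present in the table* (testable without a
cytoband reference). Autosomes only, chromosome 17 included. A `classic`
switch restores the original 15 Mb / chromosome-17-excluded /
copy-neutral-counted variant. Scores ≥ 10 define the HRD-high stratum.

Associations regress each drug × metric (× culture × timepoint) on the
per-line scores (QR least squares; R² and slope; ≥ 4 complete lines). The
FDR of the observed R² values is estimated by re-assigning the score
vector to cell lines at random: `FDR(t) = mean null count{R² ≥ t} /
max(1, observed count{R² ≥ t})`, clipped to [0, 1], reported at each
observed R²; 1,000 samplings resolve 0.001 at the 0.1 significance cutoff
used with the R² > 0.61 rule. The estimator is calibrated in the median
but, on a single 44-value screen, its denominator is a small binomial
count — individual estimates at extreme thresholds scatter widely around
1 on null data, which is worth remembering when reading single FDR values
near a decision boundary.

## The synthetic-data generators

All generators are pure functions of their parameters and a seed (the
caller's RNG stream is restored). They emulate the study conditions:
512×512 two-channel projections at 2.767 µm/px; nuclei as hard
(non-anti-aliased) disks of 4–7 px radius so truth areas are exact pixel
counts; intensities background 10, live Hoechst 40 (signal-to-background
4, comfortably above the assay's minimum of 2), dead Hoechst 80, dead PI
60, live PI at background, Gaussian noise SD 3; ≤ 10% disk overlap via
rejection sampling. Dose series follow the same log-logistic kill model
plus an arrest model `g(x) = 1 + (mgc − 1)/(1 + (x/GI50)^k)`; plates use 8
doses in 1:3 steps, 2 positions, 0/72/144 h, controls growing 2-fold per
72 h. Segment tables plant tagged LOH regions (loss, copy-neutral,
whole-chromosome, sub-threshold) on a heterozygous background; cohorts
plant linear score→metric effects.

What the passing tests show — and do not. The renders have flat-intensity
nuclei, spatially white noise, no point-spread blur, bleaching,
autofluorescence or vignetting, and no true 3D overlap beyond disk
packing. Segmentation fidelity on them (Dice > 0.9, death-ratio error
< 0.05) demonstrates the thresholding logic is correct, not that the
default offsets are optimal for any particular microscope; on real data
the offsets, `min_object_area` and the outlier rule need per-screen
inspection. Likewise LD50 recovery under Gaussian noise says nothing about
systematic staining artefacts, which the correction rules only partially
address.

## Numerical choices and degenerate inputs

* Borders: symmetric reflection everywhere (areas near edges are not
  biased toward background).
* Local means via a summed-area table — exact for integer-valued images,
  and verified pixel-for-pixel against loop oracles on random images.
* The ANOVA gate returns p = 1 (closed) on zero-variance data.
* `area_total = 0` flags the record `empty`; ratios become `NA`, never
  divisions by zero. After the dead-cell-loss correction a ratio may
  nominally exceed 1 (the later total area shrank); it is capped at 1.
* Fit tolerances: L-BFGS-B with `factr = 10`; noiseless model data are
  recovered to better than 1e-6 relative in LD50.
* Clustering ties break by lexicographic key order; permutation FDR is
  deterministic under its seed and invariant to cell-line relabelling.
* Simulation scales used by the test-suite and the acceptance script —
  100 rendered wells, 200 dose-response replicates, 1,000 random segment
  tables, 1,000 FDR samplings, one full rendered plate (54 images) —
  were chosen as the sizes at which the checked quantities stabilise.

## Known limitations

* No per-cell statistics, tracking, or 3D slice-wise segmentation: the
  method quantifies projected areas by design.
* The original workflow's exact small radius, offsets and min-object size
  are unpublished; the defaults here are the package's own and are all
  config-exposed.
* Whether the original analysis merged adjacent LOH segments before length
  thresholding is unstated; this package merges book-ended segments (and
  its brute-force test oracle does the same independently).
* The sampling-FDR estimator is noisy at extreme thresholds on small
  screens (see above); interpret borderline FDRs with its variance in
  mind.
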