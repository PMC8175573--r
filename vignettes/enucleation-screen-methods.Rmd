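---
title: "Methods: simulating and scoring an imaging-based enucleation screen"
author: "enucleoscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring an imaging-based enucleation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enucleoscreen)
```

## The assay being modeled

Immortalized human erythroid progenitor lines carry a fluorescent reporter
(Kusabira Orange, KuO) coupled to their immortalizing transgene, so every
viable cell of the line is KuO-positive. Staining a culture with a
cell-permeant nucleic-acid dye (SYTO 16) and a cell-impermeant one
(SYTOX Red) separates four biologically meaningful object classes in a single
imaging pass:

| KuO | SYTO 16 | SYTOX Red | interpretation |
|-----|---------|-----------|----------------|
| +   | +       | -         | viable nucleated cell |
| +   | -       | -         | enucleated cell (reticulocyte-like) |
| +   | +       | +         | dead cell |
| -   | +       | +         | extruded free nucleus (pyrenocyte) |

Any other signal combination is debris. The screen statistic is the
*enucleation frequency*: enucleated cells divided by intact,
reporter-positive cells (viable nucleated + enucleated). A compound's effect
is summarized as the fold change of this frequency, and of the
reporter-positive cell count, against the mean of the DMSO vehicle wells of
the *same plate*; a compound x concentration is a hit when the enucleation
fold exceeds 9.0 (strictly) and the cell-number fold is at least 0.25
(inclusive). Flow cytometry provides an orthogonal readout: enucleated cells
are SYTO 16- 7AAD- events among all (FSC-high plus FSC-low) cells.

This package implements the complete computational side of such a screen —
simulation with known ground truth, image quantification, truth-table
classification, plate-normalized scoring and hit calling, flow-style gating,
and the gene-list overlap summary used downstream — so that every stage can
be exercised and validated without any proprietary instrument data.

## What the simulator emulates

`make_library()` builds a compound set in which named compounds carry exact
true effects (fold change on the baseline enucleation frequency and on the
seeded cell number, the scale of the published hit table) while the rest are
nulls with folds near 1 plus a small cytotoxic tail (5% by default, cell
number folds in 0.02-0.2). `make_plate_layouts()` places every compound at
0.5 and 10 uM on 96-well plates, each plate carrying its own DMSO wells split
between the two volume classes that match the two test concentrations; the
volume classes are layout tags only and have no effect on the simulated
biology, mirroring vehicle controls that show no volume effect.

`preset_well_truth()` fixes the two study conditions on the scale of the
screen's own statistic: a vehicle composition whose enucleation frequency
among intact cells is 4%, and a treated composition at 23% (the cytospin
estimates for vehicle- and HDAC-inhibitor-treated cultures). Both include 3%
dead cells; free nuclei are 2% (vehicle) and 4% (treated), deliberately far
below the enucleated fraction because expelled nuclei are short-lived in
culture. Wells seed 10,000 cells by default. `sample_well_population()`
applies a compound's true folds: the realized count is
Poisson(baseline x cell-number fold); the enucleated fraction is scaled by
the enucleation fold (clamped at 0.95) with the other fractions rescaled
proportionally. Because the scaling acts on the raw enucleated fraction while
the screen measures a ratio among intact cells, the measurable
frequency-fold is slightly compressed relative to the generator's nominal
fold (about 2% at an 11.6-fold effect); recovery tests account for this by
comparing against the truth within a +/-10% band.

`render_field_images()` treats the imaged fields as a census of the well:
cells are allocated multinomially across fields, so ground-truth object
counts are conserved exactly — a deliberate simplification (a real
instrument images 50 of an unknown number of available fields) that makes
conservation testable. Objects are disks (radius 3-5 px by state) convolved
with a Gaussian point-spread function (sigma 1 px), placed with a minimum
pairwise separation of 14 px; amplitudes are log-normal per state and channel
(positive-channel median 10,000 counts, negative 300, sdlog 0.35) on a
Gaussian background (offset 200, sigma 50) clamped to the 16-bit camera
range. These values were chosen once to give clean per-channel bimodality at
default noise. A configurable `rupture_fraction` of enucleated cells renders
as 2-5 small fragments that fall below the detection area floor, emulating
damaged enucleated cells; the presets leave it at 0 and rupture is exercised
as an explicit option, since damaged cells are counted only on cytospin
slides, not by the screen. Dead cells render KuO-positive by default
(`dead_kuo_pos = 1`): a KuO-negative dead cell is indistinguishable from a
free nucleus under the truth table, and the reporter status of dead cells is
not observable in principle.

What the simulator does *not* model — and what passing tests therefore do
not demonstrate about real data: optical aberrations and uneven
illumination, dye spectral bleed-through, cell clumping beyond the
minimum-separation constraint, focus drift, and any correlation between a
compound's toxicity and image artifacts. The detection and classification
accuracies reported by the test-suite are upper bounds specific to this
rendering model.

## Quantification choices

Detection runs on the pixel-wise maximum across the three channels, so
objects bright in only one channel (KuO-only enucleated cells, dye-only free
nuclei) are found by the same pass. The background is estimated per image as
the median (robust up to ~30% foreground coverage); the foreground threshold
is 6 robust (MAD) standard deviations above it. Touching objects are split by
a watershed on the distance map of the foreground mask. Objects touching the
field border are flagged and excluded from counting (partial objects bias
intensity means; since fields sample the well, exclusion is unbiased).
Defaults: `min_area = 20` px (also the floor that rupture fragments fall
under), `min_separation = 5` px at the default render scale. Mean per-object
channel intensities are measured after subtracting each channel's own median
background, which makes them invariant to constant offsets.

Positivity cutoffs are calibrated per plate from that plate's DMSO wells
only — the same in-plate philosophy as the fold normalization. The default
method is Otsu's criterion (maximum between-class variance over a 256-bin
histogram of log10 intensities). A vehicle well is heavily imbalanced in
some channels (e.g. ~98% of objects are reporter-positive), which classical
variance-ratio bimodality checks handle poorly, so the degenerate-channel
guard is a mode-gap criterion instead: calibration fails unless the 5th
percentile of the upper class exceeds the 95th percentile of the lower class
by at least 0.5 total standard deviations (a unimodal Gaussian scores about
0.1; cleanly separated modes score far above 1 even at strong imbalance). A
`quantile_midpoint` alternative (geometric mean of the 10th percentile of the
positive mode and the 90th of the negative mode, modes seeded by a
deterministic two-means split) is retained for sensitivity analysis.

## Classification and scoring

`classify_object()` is the truth table above, total over all 8 triples, with
one documented ambiguity: (KuO-, SYTO16+, SYTOXRed-) — a membrane-intact
stained object without the reporter — is debris by default and reassignable
to `free_nucleus` by flag, because the assay's catalogue never enumerates it.

Two denominators for the enucleation frequency are retained because the
assay descriptions admit both: `methods` (enucleated over viable + enucleated,
i.e. reporter-positive and impermeant-dye-negative cells; the default) and
`kuo_total` (additionally counting dead cells, i.e. all reporter-positive
events). They differ exactly when KuO+ dead cells exist, in which case the
`methods` frequency is the larger; which one the original instrument used is
not recoverable, so both are first-class options.

Fold changes divide each well's frequency and reporter-positive count by the
mean of the same plate's DMSO wells, using the volume class matching the
well's test concentration when that class has scorable controls and pooling
otherwise. By construction the mean control fold is exactly 1 per plate, and
folds are invariant to rescaling all frequencies on a plate. Wells with a
zero denominator are dropped with a warning rather than imputed; a plate
whose control mean is zero fails as a whole. Hit calling follows the dual
criterion with the published boundary semantics (strict 9.0, inclusive 0.25),
and the ranked report sorts by enucleation fold descending with ties broken
by cell-number fold, then name, rendering folds to two decimals half-up.
The enucleation fold is the frequency fold; the enucleated-cell *number*
fold, which some displays plot instead, can be derived from the emitted
columns but is not the hit metric.

## Flow-cytometry stage

The flow simulator draws each event's FSC, SYTO 16, 7AAD and KuO signals
log-normally around state medians (FSC medians 10/8 for whole cells vs 3/2.5
for enucleated cells and free nuclei; dye positives 1000 vs negatives 30;
sdlog 0.25-0.35). Conventions are deliberately assay-local: in flow,
membrane-intact free nuclei are 7AAD-negative and SYTO 16-positive, which
differs from the imaging assay, where extruded nuclei stain with the
impermeant dye — the two assays' stated behaviours disagree and each module
follows its own. Gating removes the lowest 2% of FSC as debris, splits the
rest by a deterministic two-means on log FSC (centers initialized at the
extremes; boundary at the geometric mean of the centers), falling back to a
fixed cutoff with a warning when two groups are not separable, and computes
the enucleation percentage as double-negative events over all gated events.
The exact FSC boundary an instrument operator would draw is unknowable; any
defensible split gives the same enucleation percentage here because the
denominator pools both FSC groups.

The imaging and flow statistics are *structurally* different: imaging
excludes dead cells and free nuclei from its denominator, flow includes
them, and the debris floor trims mostly low-FSC (enucleated/free-nucleus)
events. On the preset compositions these effects amount to 1-2 percentage
points, which is why the cross-assay consistency test uses a +/-3-point
band rather than exact agreement — the same order of agreement one expects
when validating an imaging screen by flow in practice.

## Numerical and reproducibility choices

All randomness flows from one master seed through `derive_seed()`, a string
hash onto 31-bit integers, giving every (plate, well, field, stage) an
independent, individually reproducible substream; every emitter is
bit-reproducible for a fixed seed. Rendering accumulates object patches as
sparse index/value pairs and adds them to the background in one pass, so a
5,000-cell well renders in seconds and plates are processed well-by-well in
constant memory. Percentages printed to one decimal and folds to two use
half-up rounding to match the conventions of the published tables (base R
rounds half-even).

Problem sizes in the test-suite and drivers — 2-5 wells per condition at
5,000 cells and 10 fields for preset recovery, one plate at 5,000 cells per
well for fold recovery, 10,000-20,000 flow events — were chosen as the
smallest sizes at which sampling noise is comfortably inside each check's
tolerance (binomial SE under 0.5 percentage points for preset recovery;
combined control-mean and well noise near 4% for an 11.6-fold recovery
checked at +/-10%).

## Known limitations

* The rendering model is idealized (see above); absolute detection
  performance does not transfer to real microscopes.
* The hit criterion is applied to the frequency fold; if a screen's
  published folds were count-based, its table would need re-deriving before
  comparison.
* Free nuclei fractions are low in both presets; classification accuracy for
  the `free_nucleus` class is therefore estimated from few objects per well.
* No plate-effect correction (B-score, loess) or replicate-based quality
  statistics (Z', SSMD) are provided — the modeled screen uses none.
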