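---
title: "Micronucleus scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micronucleus scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnquant)
```

## What is being measured, and why a frequency

A micronucleus is a small DNA-containing body outside the primary nucleus,
produced when a whole chromosome or a fragment fails to be packaged into a
daughter nucleus at mitosis. Counting micronuclei *per nucleus* turns a
qualitative hallmark of chromosome instability into a quantity that can be
compared across drug doses, gene knockdowns, and cell lines. `mnquant`
computes that frequency from single-channel DNA-stain (Hoechst-type)
micrographs of fixed cells in multiwell plates, then aggregates it into
dose-response and silencing statistics.

Two acquisition conventions the model assumes: exposure is fixed across the
whole experiment and chosen so typical interphase nuclei sit near (not at)
saturation — around 80% — so that dim micronuclei stay measurable
(`check_saturation()` flags fields that look clipped); and fields are taken
from the well centre (nine per well by default) to avoid edge stacking.

## The segmentation model

All thresholds are **absolute intensities in camera units** and all sizes are
**equivalent circular diameters in micrometres**. Nothing is normalised
before thresholding: the published per-cell-line profiles are stated in raw
16-bit a.u., and rescaling would silently invalidate them. This is also why
`pixel_size_um` is mandatory everywhere and never defaulted — the µm/px of
the instrument is not knowable from the image, and every size filter depends
on it.

1. **Primary (nuclear) mask.** Global threshold at `DT₁`, 8-connected
   components, interior holes filled (Hoechst-stained nuclei often have
   dimmer interiors but are treated as solid), then the
   \[`Min OS`, `Max OS`\] equivalent-diameter window. There is no watershed
   splitting and no adaptive thresholding by default: the source protocol
   resolves under/over-segmentation by adjusting the threshold per cell
   line, and this package reproduces that method first; both would be
   silent behaviour changes if defaulted on.
2. **Secondary (cell body) mask.** Each cell body is approximated by a ring
   of width `w` grown from the nuclear periphery. Where rings would
   overlap, each pixel goes to the nucleus whose region is nearest in
   Euclidean distance, ties to the lower label. The tie rule is arbitrary
   but must exist: without a deterministic partition, spot-to-cell
   assignment would depend on processing order.
3. **Spot detection.** Threshold at `DT₂ < DT₁` outside all primary
   regions, 8-connected components, \[`Min SS`, `Max SS`\] window, then two
   membership rules:
   - *Majority-area rule*: a component straddling a ring boundary is kept
     iff ≥ 50% of its area lies inside the ring union, is assigned to the
     ring holding its largest overlap, and is clipped to it. The size
     window is evaluated on the detected component, before clipping.
   - *Mask-adjacency rule*: a component that touches a primary region
     (8-neighbourhood) is discarded. Any smooth nuclear edge — real optics
     or synthetic softening — necessarily produces a thin band of pixels
     whose intensity falls between `DT₂` and `DT₁` just outside the
     primary mask; tangential runs of such pixels are exactly the
     "partial nucleus scored as micronucleus" false positive, and a
     genuine micronucleus, being a separate body, does not touch the
     mask. The rule is `drop_mask_adjacent_spots` in `seg_params()` and
     can be switched off.

Optional features mirror the standard acquisition-software toolbox:
`reduce_primary_mask_um` erodes nuclei before ring construction (helps
separate a micronucleus hugging its nucleus), and `background_flatten`
subtracts a rolling-ball background (grayscale opening with a disc) before
thresholding; choose the ball comfortably larger than the objects to keep.
Whether the original acquisition software thresholds raw or flattened
intensities is not documented; here flattening applies to thresholding only
when enabled, and **object intensities are always measured on the raw
image**, so the bright-body filter sees true stain brightness.

## Exclusion filters

* **Periphery band** (default 30 µm): a nucleus whose mask intersects the
  band is excluded together with its micronuclei — a nucleus truncated by
  the field edge is small and bright, i.e. a perfect fake micronucleus.
  Exclusion is whole-object, not clipping.
* **Maximal mean intensity**: mitotic chromosomes and apoptotic bodies
  fluoresce brighter than interphase nuclei. The cutoff is calibrated as
  the midpoint between the sampled means of the two populations
  (`calibrate_intensity_cutoff()`), and errors out if they overlap. It is
  off until calibrated — there is no safe universal default. The filter is
  also applied to spots, since bright chromosome fragments can be
  spot-sized.
* **Size cap**: micronuclei are at most a fraction (default 1/3) of the
  average control nucleus. The protocol's wording mixes "diameter" and a
  computed "1/3 area" threshold; the explicitly computed quantity wins, so
  the default mode is area-based with diameter mode available
  (`mn_size_mode`). The cap is inclusive, and calibration pools control
  wells across the plate for stability.

Filters only ever add flags; none removes rows or clears another's flag, so
the three commute and the retained set is order-independent (property-tested
over all six orderings).

## Quantification and statistics

The well statistic is the ratio of totals — micronuclei summed over fields
divided by nuclei summed over fields — not a mean of per-field ratios:
fields carry weight proportional to the cells they contain, which also
corrects for confluency differences between conditions. A well with zero
retained nuclei is flagged and dropped with a warning rather than scored 0;
cytotoxic doses detach exactly the cells that would have been counted, and
a zero would bias the top of the dose curve. SD is the sample (n−1)
standard deviation.

Dose-response tables are expressed relative to the single vehicle-control
group (its relative mean is 1 by construction); silencing fold changes
divide every replicate by the mean siControl frequency, forcing the
siControl folds to average to exactly 1.

`mann_whitney()` uses midrank U with an exact branch by full enumeration of
all `choose(n1+n2, n1)` rank assignments when the pooled sample is tie-free
and `n1 + n2 ≤ 16` (at most 12 870 terms; the replicate counts this assay
produces are tiny, and a 3-vs-3 comparison can never go below p = 0.1
two-sided — worth knowing before powering an experiment). Ties force the
normal approximation with tie-corrected variance and a 0.5 continuity
correction, whose null rejection rate at α = 0.05 simulates to ≈ 0.043 at
n = 10 per group. No multiple-testing correction is applied, mirroring the
fixed-α practice of the source protocol; flag this when screening many
genes. `ks_two_sample()` compares micronuclear size distributions via the
asymptotic two-sample Kolmogorov–Smirnov test at the effective sample size.

## The synthetic generator as the study conditions

`synthetic_spec()` fixes the conditions every quantitative claim in the test
suite is made under. Defaults, chosen once as plausible for a 20× plate
imager and not revisited:

| parameter | default | note |
|---|---|---|
| field | 768 × 768 px at 0.65 µm/px | ≈ 500 µm square; the true instrument µm/px is undocumented, so a typical 20× CCD sampling was fixed instead |
| interior nuclei | 110 per field, 12–22 µm | ~990 analysable nuclei per 9-field well, matching the ≥ 1000-nuclei-per-well acquisition guidance |
| nucleus intensity | 45 000 ± 3 000 a.u., truncated ±2 sd | ≈ 0.69 × saturation, per the ~80% exposure rule; truncation keeps the population cleanly below the bright-body cutoff |
| micronuclei | Bernoulli per nucleus; 1.8–4.5 µm; 9 000 ± 1 200 a.u. (floored at 4 000); planted 1.5–4.5 µm beyond the parent boundary | inside the narrowest built-in ring (10 µm) and spot window (1–5 µm) with margin for rasterisation |
| bright bodies | 3 per field, 12–16 µm, 63 000 a.u. | near saturation; within the nuclear size window so only the intensity filter can remove them |
| edge nuclei | 6 per field, centres within 25 µm of an edge | guaranteed periphery-band violators |
| background / noise | 500 a.u.; Gaussian sd 300; ramp 0 | noise 5 sd below the spot threshold keeps false spot pixels negligible |
| edge softening | Gaussian σ = 0.35 px | small enough that the sub-`DT₁` halo stays one pixel thin (see mask-adjacency rule) |

Bright bodies cannot be "2× nucleus intensity" when nuclei sit at 0.7 ×
saturation in 16 bits; near-saturation is used instead. Placement is
rejection sampling with explicit clearances (3 µm between objects, 2 µm
between interior nuclei and the periphery band, and every micronucleus
strictly nearer its parent than any other object by more than its own
diameter). The clearances are not cosmetic: they make the planted geometry
unambiguous at pixel resolution, so the geometric checker
(`expected_counts()`) can state exact expected counts and the noise-free
render is a legitimate exact-match surface. With `noise_sd_au = 0` the same
generator produces that surface; with noise it produces the statistical
surface used for recovery tests. A spec too crowded to satisfy the
clearances fails with an error naming the attempt budget rather than
degrading silently.

What the generator deliberately does **not** emulate: optics (no PSF, no
chromatic blur), micronucleus clusters, overlapping or touching nuclei,
focus drift, or 3-D structure. Passing tests therefore demonstrate that the
*rules* are implemented correctly and recover planted truth under idealised
image formation — they do not certify performance on real images, where
threshold optimisation per cell line remains the user's job.

## Numerical choices and degenerate inputs

* 8-connectivity for objects, with the 4-connected dual for background when
  filling holes; labels are renumbered in column-major first-occurrence
  order so labeling is deterministic.
* Pixel-centre convention throughout: pixel (x, y) sits at
  ((x−0.5)·psz, (y−0.5)·psz) µm; the periphery band test uses it, so a
  "30 µm" margin means what it says regardless of pixel size.
* Size windows and the 1/3 cap are inclusive at both boundaries.
* Ring distances compare exact Euclidean pixel distances; ties go to the
  lower label. Distances are square roots of integers, so cross-route
  float disagreement is not a practical concern.
* Empty fields, empty wells, and empty spot sets flow through as empty
  tibbles; undefined quantities (frequency with zero nuclei, SD of one
  replicate, fold changes with a zero siControl mean) are flagged `NA` or
  raised as errors, never silently zeroed.
* Micronucleus intensity draws are floored well above `DT₂` and nucleus
  draws truncated at ±2 sd: recovery tests need planted objects to be
  detectable and classifiable *by construction*, otherwise they would
  measure the generator's tails, not the pipeline.

## Validation architecture

Three independent routes must agree:

1. the production pipeline (EBImage-backed, `segment_field()`);
2. `reference_counts()` — an exhaustive flood-fill reimplementation of all
   per-field rules in plain R, sharing no algorithmic code with the
   pipeline;
3. `expected_counts()` — counts derived from planted geometry alone,
   without looking at pixels.

The test suite holds the three equal on noise-free fields, checks planted
5% frequencies are recovered within binomial error on noisy plates, that a
planted probability ladder yields strictly increasing vehicle-anchored
dose-response means, and that identical seeds give byte-identical images
and CSVs. Problem sizes in routine runs (256 px oracle fields, 9-field
wells of ~110-nuclei 768 px fields, 10⁴-replicate null simulations) were
chosen to exercise every rule at full fidelity while keeping the suite
fast on one CPU.

## Known limitations

* One micronucleus cluster counts as one spot (or none, if it exceeds the
  size window); clustered micronuclei are out of scope.
* The intensity filter is brightness-only; it cannot separate a mitotic
  cell whose brightness overlaps interphase nuclei.
* Exact Mann–Whitney p-values with ties are not enumerated; ties fall back
  to the approximation.
* Absolute reproduction of any particular vendor's segmentation output is
  not attempted: vendor pixel sizes and threshold semantics are not fully
  documented, so fidelity is to the published *rules* and profiles.
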