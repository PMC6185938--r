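---
title: "Quantifying primary cilium length and incidence: methods and design"
author: "cilimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying primary cilium length and incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilimetry)
```

## The measurement problem

Ciliopathy and retinal-degeneration studies routinely read out two numbers
from immunofluorescence micrographs: how long primary cilia are, and what
fraction of cells carry one. Cells are co-stained with a ciliary membrane
marker (typically ARL13B) and a nuclear stain (DAPI); each field of view
yields a set of thin, curved, bright cilia and a set of large, compact
nuclei. The per-field readouts are the mean cilium length (in micrometres)
and the **incidence**

$$\mathrm{incidence} = \frac{n_\mathrm{cilia}}{n_\mathrm{nuclei}} \times 100\%$$

with nuclei standing in for cells. Group differences (patient lines,
knockdowns, gene-corrected clones versus unaffected controls) are then
tested on these readouts.

cilimetry implements this chain end to end — image import, segmentation,
per-object morphometry, per-field summaries, group statistics — together
with a synthetic-field generator that provides exact ground truth, so every
stage can be validated without access to any particular microscope's data.

## Segmentation model

Each channel of the (maximum-intensity-projected) field is segmented
independently by the same three-stage chain.

**Hysteresis dual thresholding.** Pixels strictly above an upper threshold
seed objects; every pixel strictly above the lower threshold that is
8-connected to a seed through above-lower pixels is appended. Compared with
a single low threshold this keeps dim cilium tips attached to their bright
shafts while rejecting isolated background fluctuations that happen to
exceed the lower value. Strict inequalities are used at both thresholds, so
a constant image exactly at threshold yields an empty mask, and
`hysteresis_segment(img, t, t)` reduces to a simple strict threshold.
8-connectivity is used everywhere in 2-D: cilia are thin and often run
diagonally, and 4-connectivity fragments them.

Thresholds are specified either as absolute intensities (for calibrated or
simulated acquisitions) or as quantiles of the image's own intensity
distribution (type-7 empirical quantiles, the R default). Quantile mode,
resolved **per image**, is the shipped default (low 0.90, high 0.99)
because absolute intensities vary with acquisition settings and between
fields; the resolved absolute values are always attached to the output for
provenance.

**Size filtering.** Connected components smaller than `min_object_area_px`
are removed as noise. The default for cilia is 5 px at 0.1 µm/pixel — half
the area of the shortest biologically plausible cilium at that scale — and
200 px for nuclei, orders of magnitude below a real nucleus but far above
any noise clump. Both are configurable and logged.

**Watershed splitting.** Touching objects are divided on the Euclidean
distance transform of the binary mask. Seeds are the regional maxima of the
h-maxima transform of the distance map — peaks whose prominence above the
surrounding saddle exceeds `watershed_tolerance` (default 1 px) — thinned so
that accepted peaks are at least `split_min_distance_px` apart; flooding
then proceeds from the seeds in order of decreasing distance value,
restricted to the mask, with ties broken by raster order so the result is
fully deterministic. The prominence criterion is what keeps elongated thin
objects intact: the distance ridge of a cilium carries many quantised local
maxima, but none rises a full pixel above its neighbours, so a lone cilium
keeps a single label, while two overlapping nuclei (whose peaks rise well
above the waist between them) are split. Two overlapping discs of radius
8 px with centres 1.5 radii apart have a prominence of about 2.3 px at the
lower peak and are reliably separated.

## Morphometry

Per object, the package reports pixel area, physical area, mean intensity
over the **original** (pre-threshold) intensity image, centroid, and two
length estimates:

* `length_um` — the object is thinned to a 1-px-wide skeleton (Guo–Hall
  thinning, which preserves endpoints and 8-connectivity) and the longest
  geodesic path along the skeleton is measured, counting 1 px per axial and
  $\sqrt{2}$ px per diagonal step. This is the default estimate for curved
  cilia.
* `major_axis_um` — the ellipse-equivalent major axis from normalised
  second central moments (the `regionprops` convention, including the 1/12
  per-pixel correction). Classical region-property tools report "length"
  this way, so both readings are emitted and either can be used downstream.

Two numerical properties of the skeleton estimate are worth knowing.
First, the $(1, \sqrt{2})$ step weighting is exact for segments at 0°, 45°
and 90° but overestimates digitised straight lines at intermediate angles by
up to ~8% (the classical chamfer-metric bias, worst near 22.5°); the test
suite pins the axial/diagonal cases exactly and bounds arbitrary angles at
8.5% relative error. Second, no endpoint (+1 px) correction is applied: the
estimate is the path length between skeleton endpoint centres. Both choices
favour simple, documented behaviour over ad hoc constants; the validation
below shows the net effect is small at the scales of interest.

Coordinates are reported 1-based, row-major `(y, x)` with the origin at the
top-left pixel — R's native indexing — and this one convention is used for
masks, label maps and centroids alike.

**Choosing absolute thresholds for length work.** When the imaging model is
known (as for the simulator, or a calibrated acquisition) the lower
threshold should sit at background plus half the blurred ridge amplitude of
a cilium: thresholding a Gaussian-blurred line at half its amplitude places
the mask boundary at the true endpoint (the full-width-at-half-maximum
rule), so skeleton shortening from thinning and mask extension from the
point-spread blur roughly cancel. At the simulator defaults (background
100 DN, ridge amplitude ≈ 250 DN after a 0.15 µm PSF) this gives a low
threshold of 225 DN, with seeds at background + 10 noise standard
deviations (250 DN).

## Statistics

Group summaries are mean ± SEM (sample standard deviation over $\sqrt n$).
The omnibus test is classical one-way ANOVA; control-referenced comparisons
use Dunnett's procedure: per-treatment t statistics on the pooled
within-group variance, with two-sided family-wise-adjusted p values from the
equicorrelated multivariate-t null (correlations
$\sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}$ in the unbalanced case). The
multivariate-t probability is evaluated by quasi-Monte-Carlo integration
(`mvtnorm`) to an absolute tolerance of about $10^{-5}$ under a fixed
internal RNG state, so results are deterministic and the caller's RNG
stream is untouched; with a single treatment group the computation reduces
analytically to the pooled two-sided t test. Adjusted p values are clamped
to be no smaller than the raw pairwise p. Significance is annotated with
the conventional stars (\*: p < 0.05, \*\*: < 0.01, \*\*\*: < 0.001,
\*\*\*\*: < 0.0001).

The observational unit is a genuine design choice: per-cilium lengths give
the test the full sample size (hundreds of cilia), while per-field means
are more conservative when fields, not cilia, are the independent unit.
Both are supported (`run_stats(unit =)`), the choice is recorded in the
output, and incidence is always a per-field quantity.

Minimum-count quality rules annotate, and never block, the outputs: at
least 150 cilia measured per sample, at least 300 cells counted per sample,
at least 100 cells per population, counted from **more than** 10 fields of
view (exactly 10 fields is flagged).

## The synthetic-field generator

`render_field()` draws a two-channel field from a fully specified
generative model, so that the truth of every downstream number is known:

* **Nuclei** — `n_nuclei` ellipses (semi-major axis `nucleus_radius_um`,
  default 3.0 µm with 10% uniform jitter; aspect 0.8; uniform orientation)
  placed by rejection sampling so that they do not overlap (an overlap mode
  exists specifically to exercise watershed splitting), rendered at
  `nucleus_intensity` (500 DN).
* **Cilia** — each nucleus carries a cilium with probability
  `ciliation_probability` (default 0.7, a typical serum-starved control
  ciliation rate); true per-field incidence is therefore Binomial. Arc
  lengths are log-normal with median `length_median_um` (default 3.5 µm, a
  typical control RPE cilium) and geometric SD 1.25 — strictly positive and
  right-skewed, as biological length data are. The centreline is a
  fixed-step random walk (step 0.05 µm, per-step turn uniform in
  ±`curvature_max`, default 0.15 rad), anchored just outside the nucleus
  border and heading outward, rasterised as a 1-px-wide anti-aliased
  stroke at `cilium_intensity` (800 DN). Cilia are re-drawn rather than
  allowed to touch another cilium or leave the field, so objects are
  non-touching by construction.
* **Optics and camera** — Gaussian PSF blur (`psf_sigma_um`, default
  0.15 µm, a realistic confocal scale at 0.1 µm/pixel), constant background
  (100 DN), Poisson shot noise on the expected intensity, additive Gaussian
  read noise (SD 10 DN), then quantisation to 16-bit digital numbers. This
  is the standard fluorescence camera model; at the defaults the
  background-relative SNR is far above the ≥5 regime in which length
  recovery is validated.

All randomness flows from one integer seed; identical configurations and
seed reproduce every pixel and every truth record byte for byte, and
`simulate_experiment()` derives per-field seeds deterministically from its
master seed.

What the simulator does **not** emulate: tissue autofluorescence texture,
uneven illumination, multi-nucleated or overlapping cell layers (organoid
sections), out-of-focus light beyond a single Gaussian scale, 3-D structure
(fields are single-plane; z-stacks are supported in I/O and collapsed by
maximum-intensity projection), photobleaching, and marker-specific
staining heterogeneity. Passing the validation suite therefore demonstrates
correctness of the algorithms under a clean, known model — not robustness
to every pathology of real organoid imaging; on real data the segmentation
thresholds remain the user's scientific responsibility.

## Validation surface and problem sizes

The test suite validates each stage against independent oracles — an
iterative-dilation flood fill for hysteresis, single-seed relabelling for
component filtering, explicit per-pixel accumulation for region properties,
`multcomp` for Dunnett — and the whole chain against simulator ground
truth. The heavier properties run at deliberately modest sizes chosen to
keep the full suite around half a minute on one core while leaving the
statistical assertions sharp: 200 random 32×32 images for the hysteresis
oracle; ~200 rendered cilia across 22 fields of 512×512 px for length
recovery (asserting mean absolute relative error below 10% for true lengths
2–6 µm; the observed error is well under half that); 500 null replicates
(3 groups × n = 30) for ANOVA/Dunnett type-I calibration within
[0.02, 0.08] at α = 0.05; and 100 replicate two-group experiments (150
cilia per group, control 3.5 µm vs patient 2.5 µm, SD 0.8) for power,
asserting detection in at least 95% of replicates.

`scripts/acceptance.R` reruns the pipeline's headline computation from
scratch at the same scales and writes the resulting numbers as JSON.

## File formats and provenance

Images are read from TIFF/OME-TIFF (`CYX` or `CZYX` planes). OME-XML
metadata supplies channel names, the channel/z layout and the physical
pixel size; a user-supplied pixel size always overrides metadata, and
anisotropic in-plane metadata is rejected rather than averaged because all
length formulas assume one scale. Intensities are handled as non-negative
reals internally whatever the on-disk bit depth. The simulator writes
16-bit OME-TIFF (the OME-XML block is spliced into the `ImageDescription`
tag, as `tiff::writeTIFF` exposes no custom tags), and a write-then-read
round trip is bit-exact. Every batch run logs the per-image resolved
thresholds, counts and package version to `run_log.json` beside the CSV
outputs.

## Known limitations

* Lengths are measured on 2-D projections; a cilium steeply inclined to the
  imaging plane is foreshortened. The study design this package supports
  compares groups imaged identically, where the bias is shared.
* The chamfer bias (+≤8% at unlucky orientations) and the absence of an
  endpoint correction partially offset each other but are not separately
  corrected.
* Incidence attributes cilia to fields, not to individual cells; it can
  exceed 100% under multiciliation or over-segmentation, and such fields
  are flagged (`multiciliation_or_oversegmentation`) rather than clamped.
* Quantile thresholds degenerate on images whose foreground fraction is far
  from the quantile assumptions (e.g. noise-free synthetic fields, where
  the 0.99 quantile is the constant signal value itself and the strict
  inequality leaves the mask empty); absolute mode is the right choice
  there.
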