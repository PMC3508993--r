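---
title: "Quantifying cone survival on retinal whole mounts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cone survival on retinal whole mounts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conetop)
```

## The estimation problem

In retinal degenerations such as the rd10 mouse model of retinitis
pigmentosa, cone photoreceptors die with strong spatial structure: a
cone-depleted central zone (a scotoma) expands while peripheral islands
retain high density, and the surviving mosaic is locally anisotropic.
A single "representative field" count therefore badly misestimates the
whole-retina population. `conetop` implements a stratified estimator
built for exactly this situation:

1. A low-resolution montage of the opsin-stained whole mount is
   background-corrected and smoothed into a *brightness map*; brightness
   is a monotone proxy for local cone density.
2. The masked map is partitioned into `n_levels` *isodensity regions*
   (quantile bins of brightness, dark to bright). Regions may be
   multiply connected, matching patchy degeneration.
3. Absolute densities are measured on high-resolution 125 x 125 um
   fields, two per location, at 16 locations spaced along the
   dorso-ventral and naso-temporal meridians so that every isodensity
   region is sampled. The ~32 fields cover roughly 3.8% of a ~13.2 mm^2
   whole mount.
4. The total is the stratified sum over regions of mean sampled density
   times region area,
   `N = sum_i d_i * A_i`,
   reported with the sampling fraction and, optionally, as a percent of
   a wildtype reference population (180,000 cones by default, a
   literature value exposed in `run_config()`).

If the true density field is constant within each region and the
sampled locations are representative, the estimator is exact; the
property suite verifies the exact case and the sampling error on rough
profiles.

## The synthetic retina and what it does (and does not) emulate

No raw micrographs accompany the published counts, so every stage is
validated by parameter recovery on synthetic whole mounts with known
ground truth.

**Geometry.** The flattened retina is modeled as a disc of radius
2.05 mm (~13.2 mm^2), consistent with flat-mount mouse retina sizes and
with a 0.5 mm^2 sample being ~3.8% of the surface. Relief cuts are not
modeled.

**Density profiles.** Density is zero inside a central scotoma, rises
from `d_min` at the scotoma edge to `d_max` at the retinal margin along
a Gaussian-CDF ramp in the normalized radius, and is exactly `d_min` /
`d_max` at the two ends for every angle. The presets encode the
published density ranges at P60: `rd10_st` spans 3,000-50,000 cones/mm^2
with a 0.5 mm scotoma, `rd10_ee` spans 4,000-85,000 cones/mm^2 with a
0.15 mm scotoma; `wildtype` is uniform at 13,600 cones/mm^2, whose
integral over the disc is ~180,000 cones. The radial form of the decay
is not published; the CDF ramp (width 0.18 in normalized radius) is a
modeling choice that keeps the profile strictly monotone with gentle
saturation at both ends, so the innermost and outermost sampling
locations sit in near-plateau zones and the printed extremes are
recoverable. Anisotropy enters as an angular exponent warp
(`u^exp(a*cos 2*theta)`), which mimics meridian-dependent degeneration
speed without moving the endpoint densities. **Consequently the
synthetic per-retina totals are emergent quantities** and are not tuned
to any published group mean; recovery tests always compare against the
generated ground truth.

**Point process.** Cone positions are an inhomogeneous Poisson process
thinned to a hard core (Matern type II with uniform marks). Real
mosaics are more regular than Poisson; the hard core is the simplest
regularity the detector must tolerate. The default exclusion radius is
1.5 um: the Matern capacity with a radius r is 1/(pi r^2), about
141,000/mm^2 at 1.5 um, whereas a 4 um hard core could not reach the
85,000/mm^2 upper end of the published range (hexagonal packing bound
~72,800/mm^2). The candidate intensity is inflated by the closed-form
Matern inverse `lambda = -log(1 - d*pi*r^2)/(pi*r^2)`, so thinning
costs regularity, not intensity: realized counts match the density
integral to well under the 5% design bound at all published densities.

**Rendering.** Each cone becomes an isotropic Gaussian spot
(sigma = 1.2 um, the confocal-scale blur of a cone outer segment) of
unit peak amplitude on a constant background (0.2) with additive
Gaussian read noise at SNR 10; fields are rasterized at 0.25 um/pixel,
montages at 10 um/pixel with cones binned and blurred so individual
cells merge into local brightness. Not emulated: uneven staining,
folds, bleaching, rods, or the morphological distinction between cones
with and without outer segments (one spot class is rendered). Passing
tests therefore demonstrate correctness of the measurement chain under
idealized optics, not robustness to staining artifacts.

## Spot detection on crowded fields

At the upper end of the published densities the mosaic is crowded in a
precise sense: at 85,000/mm^2 the mean nearest-neighbour distance
(~1.7-2 um) is below the two-peak resolution limit of 1.2 um spots
(two equal Gaussians merge into a single maximum below a separation of
2 sigma = 2.4 um), so *most* neighbouring spots merge. Local-maximum
counting alone undercounts by tens of percent there, and
watershed-style declumping cannot help, because merged pairs have no
intensity saddle to split. The detector therefore counts by flux
quantization:

* **Matched filter and mean removal.** The field is convolved with the
  expected spot kernel; subtracting the global mean removes both the
  background and the mean "continuum" of overlapping spot tails, so no
  background estimate is ever needed (a background error of `delta`
  would otherwise bias the count by `delta x pixels / spot flux`, about
  13% per 0.1 amplitude units on a 500 x 500 field).
* **Greedy template subtraction.** One fixed-amplitude template (plus a
  compensating uniform offset equal to the template flux spread over
  the field) is subtracted at the residual maximum, with sub-pixel
  parabolic refinement, until the residual peak falls below
  `stop_frac` (0.54) of the template peak or the noise floor. Because
  each subtraction removes exactly one spot's worth of signal, a merged
  pair is counted twice: the first subtraction leaves one template of
  signal behind.
* **Amplitude self-calibration.** The single-spot amplitude is the
  median of local least-squares fits (spot + neighbouring candidates +
  local constant) around isolated maxima of a denoised copy of the
  field, keeping only fits whose center-weighted residual is below
  `shape_tol` (4%) of the amplitude - this rejects unresolved pairs,
  which fit poorly near their center. All thresholds are relative, so
  detection is invariant to uniform intensity rescaling.

Self-calibration is reliable up to roughly 50,000/mm^2. Beyond that,
nearly every candidate contains an unresolved partner and blind
single-field calibration becomes ill-posed - a physical resolution
limit, not an implementation one. The pipeline therefore calibrates per
*session*: a first pass fits the amplitude on every field, and the
median over fields with trustworthy calibrations (at least 10 validated
isolated spots) is applied uniformly in a second pass. This mirrors
configuring the counting routine once per acquisition session, and it
is how the crowded EE-like fields inherit their calibration from
sparser fields imaged with the same settings. With session calibration
the median count error is within ~3% at 3,000, 50,000 and 85,000
cones/mm^2 at the default SNR.

The two fields collected at a location are combined by their arithmetic
mean (the original protocol does not state a rule); a flagged field
(saturated, empty, off-nominal size) is dropped and the flag
propagated.

## Mapping and sampling choices

* **Background correction** of the montage uses a grey opening with a
  square structuring element of 500 um half-width - a rolling-ball-style
  estimate that keeps the map linear in the input intensities.
* **Smoothing** is a mask-normalized Gaussian at 100 um, so tissue near
  the outline is not dimmed by the empty surround; the number of
  isodensity levels defaults to 5 and level placement uses quantile
  (equal-pixel-mass) bins, which are robust to skewed brightness
  histograms. How many curves the original analysts traced, and
  whether at fixed values or visual steps, is unstated; sensitivity to
  `n_levels` is part of the test suite.
* **Cluster thresholding** (Otsu on the masked map) is provided as the
  digital analogue of the published "thresholded to isolate cone
  clusters" step and is used as a QC layer; the partition itself is
  quantile-based.
* **Sampling locations**: four per half-meridian, evenly spaced between
  the scotoma margin and the retinal margin (buffered so each field
  lies fully inside the outline), with the radii staggered by a quarter
  step across the four half-meridians so the 16 locations stratify the
  whole radial span - with one shared set of radii, a partition with
  more annular regions than radii per ray could never be covered. The scotoma margin is auto-detected
  as the first radius where a lightly smoothed (25 um) montage exceeds
  3% of its dynamic range above the central level, with the crossing
  required to persist over 25 um (so a single noisy pixel cannot fake
  an edge) and a 25 um outward offset keeping the innermost field clear
  of the cone-free zone - the coarse map cannot be used here because
  100 um smoothing blurs the scotoma edge outward. The margin-side
  buffer is the smallest offset that keeps a field square inside a
  circular outline (plus 15 um), so the outermost locations sit as
  close to the margin as the protocol allows. If a region ends up
  unsampled, locations are shifted locally in 25 um steps up to 200 um,
  trying perpendicular displacements first and then diagonal and radial
  ones (annular regions and speckled level sets are unreachable by
  purely perpendicular moves); an unreachable region is a hard error
  rather than silent imputation.

## Companion measurement rules

* **ERG b-wave**: five traces per flash luminance are averaged
  pointwise; the amplitude is the difference between the pre-stimulus
  baseline mean (default window 20 ms, configurable - the published
  methods do not state the duration) and the post-stimulus peak. The
  0.3-500 Hz band-pass of the acquisition chain is assumed already
  applied.
* **Visual water task**: a stimulus level is perceived when the success
  rate is *strictly above* 70% (literal reading of "above 70% of the
  trials"); the acuity threshold is the highest spatial frequency such
  that it and all easier levels pass, the contrast threshold the lowest
  contrast likewise. Requiring the monotone run guards against isolated
  lapses; no interpolation between tested levels is performed.
* **Relative qPCR**: `Rq = 2^-(dCt - dCt_calibrator)` with GAPDH as
  reference and the standard-housing group as calibrator; triplicates
  with Ct standard deviation above 0.5 are flagged, not dropped.
* **Densitometry**: band readings divide by their lane's loading
  control; group results are compared as percent difference of means.

## Numerical choices and degenerate inputs

Raster areas are always pixel counts times the squared pixel size, so a
partition's region areas sum to the outline area exactly. Quantile ties
that would produce an empty region raise an error, as does requesting
more levels than distinct intensities. A constant brightness map
thresholds to all-foreground with a warning. Degenerate fields (empty,
saturated) yield zero counts with flags instead of aborting a run. All
randomness flows from a single integer seed; a fixed seed reproduces
mosaics, renders, and the entire pipeline report byte for byte.

## Problem sizes used by the test suite

The packaged test-suite and acceptance checks choose sizes that keep
the full chain honest while remaining desk-scale: extreme-density
recovery runs full-size (2.05 mm) ST and EE retinas over a few seeds
and compares per-condition medians, as in the original multi-retina
design; the 50-run bias suite uses geometrically scaled retinas
(1.0 mm radius, scotoma scaled proportionally) with the full density
ranges, which preserves the per-field counting problem exactly while
scaling only the number of fields' worth of mosaic to generate.
Detector error medians use 20 seeded fields per density.

## Known limitations

* Absolute totals of the synthetic presets are not calibrated to any
  published group mean (the true radial decay is unpublished); only
  densities, geometry and the sampling scheme are anchored.
* Blind amplitude calibration on a single crowded field
  (> ~50,000 cones/mm^2) is ill-posed; such fields need the session
  calibration path and are flagged otherwise.
* Brightness is assumed monotone in density on the montage; strongly
  uneven staining would break the isodensity partition in ways the
  generator does not emulate.
* The estimator reports no per-retina confidence interval, matching the
  original design where dispersion is reported across animals.
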