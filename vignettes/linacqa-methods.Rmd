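---
title: "Methods and design notes for linacqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for linacqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`linacqa` implements the quantitative analyses of a linac SRS/SBRT
commissioning program. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not establish.

## Coordinate and geometry conventions

A `planar_image` stores a raster with its detector pixel pitch and the
source-to-axis (SAD, default 1000 mm) and source-to-detector (SDD)
distances. Every reported distance is an isocenter-plane millimetre:
detector mm divided by the magnification SDD/SAD. Pixel coordinates are
0-based pixel centres; x runs to the viewer's right along columns and y
downwards along rows (beam's-eye view at collimator 0), which coincides
with the left(-)/right(+), up(-)/down(+) convention used for reporting
portal-image offsets. The default synthetic geometry is an aSi MV portal
imager: 0.392 mm pitch at SDD 1500 mm (magnification 1.5, so 0.2613 mm per
pixel at the isocenter). The EPID SDD of a given clinical acquisition is
not knowable from the image alone, so it is always a user-supplied
(sidecar or `meta`) parameter.

One sign convention deserves a note: combining the four cardinal-angle
Winston-Lutz offsets into a 3D position uses
`rl = (G0.x - G180.x)/2`, `ap = (G90.x - G270.x)/2` and
`is = mean of the four y offsets`. The simple average in the third formula
is only valid if the raster y axis keeps a consistent sense relative to
the patient superior/inferior axis at all four gantry angles; the package
(and its generators) adopt that convention, and table-angle images are
reported individually but never enter the 3D combination.

## Winston-Lutz detection

Field edges are defined at 50% of (in-field plateau - exterior baseline).
The two reference levels are estimated robustly as the median of the top
intensity decile inside, and of the bottom decile outside, a coarse Otsu
split; the BB dip lies well below the top decile so it cannot bias the
plateau. Edges are located as the outermost sub-pixel linear
interpolations of the 50% level along mean line profiles (a 2 mm band)
through the field centre, iterated once. The same detector serves square
MLC apertures and circular cones, since axis profiles through the centre
of a circle also cross its edge at the diameter.

The BB is segmented inside an interior disc (field half-width minus a
1.5 mm margin) by thresholding at half the dip depth below the plateau;
the centre is the centroid weighted by `(threshold - intensity)+`. Because
the weight vanishes at the segmentation boundary, including or excluding a
boundary pixel does not move the centroid — this is what makes the
estimate sub-pixel. Exactly one connected candidate (4-connectivity,
minimum 4 px) is required; zero or several is a detection error.

## MLC tests

**Picket fence.** The raster is averaged across the leaf-travel-orthogonal
direction; bands above half prominence are detected from the mean
profile. Per picket, the FWHM comes from sub-pixel half-prominence
crossings and the position from a centroid weighted by the height above
the half level (again, boundary-vanishing weights). Deviation is measured
against a best-fit equispaced grid at the nominal spacing with a free
phase, because the test evaluates straightness and equidistance, not an
absolute position. The phase is the *median* of `position - index *
nominal`: with a single outlying picket the median anchors the grid on the
good pickets, so an injected 0.5 mm error is reported as 0.5 mm (a
mean-anchored phase would smear it to 0.4 mm across five pickets).

**Star shot.** Dark slit pixels (below half of the background-to-minimum
depth) are clustered by angle about their intensity-weighted centroid in
0.5-degree bins, ignoring sparsely hit bins and a 5 mm hub radius where
slits overlap. Clusters whose perpendicular residuals are bimodal are
split (two separated parallel slits share an angle range). Each spoke is
fitted by darkness-weighted total least squares, then every pixel is
re-assigned to its nearest line (within 2 mm) and the fits are repeated.
The wobble statistic is the exact minimum enclosing circle of all pairwise
intersections, found by the two-point/three-point candidate search; the
test oracle instead minimizes the maximum distance numerically, so the two
routes are independent. An all-parallel line set has no intersections and
raises a geometry error.

**Dynamic leaf gap.** The sweeping-gap model is linear in the nominal gap:
`D - Dleak = b (gap + 2 delta)`. The leakage dose is an input (it is
measured separately with the leaves closed and offset), and the fit is
unweighted ordinary least squares — the measurement procedure does not
state a weighting, and the noise on an ion-chamber reading is not
gap-dependent to first order. The zero-dose gap is the root of the fitted
line and the leaf shift is its negative half. A non-positive slope is a
fit error.

## Beam data

Profile percent levels (50/80/20) are taken relative to the central-axis
value rather than the global maximum so that off-axis horns of flattened
fields do not bias the penumbra. All interpolation is piecewise linear;
this keeps the worked examples exact and makes the closed-form checks
(erf-edge penumbra `1.6832 sigma`, Gaussian FWHM `2.3548 sigma`) hold to
the sampling error. Output-factor daisy-chaining re-anchors a small
detector's readings at an intermediate field (default 30 mm) to a
reference chamber normalized at 100 mm; at or above the intermediate field
the reference chamber is used directly. Output factors are keyed by
equivalent square side; rectangular fields are out of scope.

The synthetic detector model is a radial flat-top with Gaussian shoulders
(penumbra sigma 1.5 mm — a fixture choice, not a physics claim, since no
numeric penumbra width for the real 6 MV SRS beam is available as a
default) scaled by a saturating output-factor curve. A detector reading is
the true disc average of that fluence over the active diameter, which is
what makes volume averaging — the 6 mm chamber under-reading a 5 mm field
— an exact property of the generator rather than an assumption of the
test.

## Image quality

Modulation per line-pair group is Michelson contrast
`(P_high - P_low)/(P_high + P_low)` of the median local peak and trough of
the ROI-mean profile, normalized to the 0.5 lp/mm group. Median peak and
trough values are robust with as few as two full periods per group; a
Fourier-amplitude estimator was rejected because at 2-4 periods per group
the leakage correction would dominate. The normalized curve is exactly
invariant to intensity gain; a pure offset changes Michelson contrast
slightly (the tests bound the effect at 0.02 for a 12% baseline shift on
the synthetic phantom), which is acceptable because detector offsets are
calibrated out upstream. ROI placement is user-supplied; automatic phantom
registration is out of scope, so the published f50 of a real phantom image
is not a reproducible target — the tests instead check the measured curve
against a numeric convolution oracle with the known PSF.

## Localization statistics

Residual statistics are per-axis sample means and standard deviations
(n - 1 denominator; whether published tables use n or n - 1 is usually
unstated, and n - 1 is the conservative choice) plus the mean and standard
deviation of the per-trial Euclidean vector length. The vector-length
statistic is computed per trial and then averaged — the only reading under
which its mean can exceed the norm of the per-axis means, as published
tables show. Rotation exceedance is the empirical tail fraction with a
binomial standard error. The couch-rotation verification fits a rigid
transform to corresponding BB positions by the Kabsch/SVD method and
decomposes the rotation as `Rz(r_si) Ry(r_pa) Rx(r_lr)`; below a few
degrees the decomposition order matters at less than 0.01 degrees, so the
fixed order is a documented convention rather than a modelling choice.

## End-to-end verification

Film conversion interpolates a strictly monotone per-channel
pixel-to-dose curve and averages the requested channels; out-of-domain
pixels are clamped and counted. Scanner nonuniformity correction is out of
scope (a flat-field map can be applied to the image before conversion).

The gamma index uses a search disc of radius `3 * DTA` sampled at a
`DTA/10` sub-pixel step with bilinear interpolation of the evaluated grid,
and is normalized either to the reference global maximum (default, common
film-QA practice) or locally; the default low-dose cutoff is 10% of the
reference maximum. The step/radius choice is not asserted to be exact in
general — instead a brute-force per-pixel oracle over the same candidate
set pins the implementation to 1e-9, and the flat-field closed form
`gamma = |dD|/DD` checks that the distance term can never help when there
is no gradient. Offsets are searched in order of increasing radius and the
search stops when the pure distance penalty exceeds the worst current
pixel, which is an exact (not approximate) pruning.

## Synthetic data: what a green test establishes

Generators render analytic intensity models — blurred indicator apertures
(Gaussian edge blur, default sigma 0.5 mm standing in for source
penumbra), a blurred-disc BB attenuation, Gaussian picket ridges and slit
lines, erf-rendered line-pair bars — with optional additive Gaussian noise
on the normalized intensity (default off) and a seed; every generator
restores the caller's RNG state and echoes its truth in a manifest. The
stated world of the tests is: offsets uniform in [-1.5, 1.5] mm, noise up
to 2% of the plateau, 5 pickets at 30 mm spacing with 2.2 mm FWHM, gaps
1-100 mm with 0.2% dose noise for the DLG Monte-Carlo.

They emulate sub-pixel geometry faithfully but not detector physics: no
scatter, heel effect, glare, film grain, dead pixels, or realistic MV
noise spectra. A green recovery test therefore establishes that the
estimators are unbiased at the stated noise level and geometry, not that
they are robust to every clinical artifact. Conversely the numbers the
package reproduces exactly (the cardinal-angle combination, the
sweeping-gap worked example, the dose-report table) are arithmetic
identities of the published procedures and hold regardless of the
generators.

## Degenerate inputs and error taxonomy

All user-facing failures are classed conditions (`linacqa_format_error`,
`linacqa_config_error`, `linacqa_validation_error`,
`linacqa_detection_error`, `linacqa_geometry_error`, `linacqa_fit_error`,
`linacqa_range_error`, `linacqa_metric_error`, `linacqa_chaining_error`,
`linacqa_comparison_error`, `linacqa_generation_error`), so callers can
distinguish a bad file from a bad measurement. Uniform images, missing 50%
crossings, absent or multiple BB candidates, parallel-only star-shot
lines, collinear BB configurations, non-monotone calibrations and
mismatched dose grids all fail fast with the appropriate class.

## File formats

Rasters are ASCII PGM (P2, integer, bit-exact round-trip) or a headered
CSV raster carrying full geometry at double precision; dose grids are CSV
with a three-line header (pitch, origin, units); tables are plain CSV with
mandatory headers, comma separator and '.' decimal; manifests, sidecars
and CLI reports are JSON. Binary formats (TIFF/PNG/DICOM) are not read in
this build — no reader is available in the supported dependency set — and
the geometry `meta` argument plays the role a DICOM header otherwise
would.

## Known limitations

- No automatic gantry-angle inference from image content; angles are
  metadata.
- Star-shot analysis assumes spokes cross within a few millimetres of the
  image centroid region; widely separated hubs are not handled.
- The gamma search is planar (2D) only.
- Output factors assume square fields.
- The RMTF estimator requires user ROIs and at least two periods per
  group.
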