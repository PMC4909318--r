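---
title: "2.5D analysis of fluorescent spheroid cultures: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{2.5D analysis of fluorescent spheroid cultures: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidal)
```

## The problem

Multi-cellular spheroids grown in an extracellular matrix are imaged as
confocal z-stacks with two fluorescent channels: a *stable* whole-cell
label present in every tumor cell (e.g. a cytoplasmic RFP) and a
*specific marker* staining a subset of nuclei (e.g. EdU in proliferating
cells). Two facts shape the analysis. First, full 3D segmentation of
large stacks is expensive, and the axial resolution (z-steps of ~10 µm)
is far coarser than the lateral one, so little is gained by treating z
as an equivalent third dimension. Second, absorption and scattering
attenuate the signal with depth; spheroids beyond roughly 100 µm
diameter are never imaged completely, and a naive count of
marker-positive cells is biased low in exactly the samples with the
largest spheroids.

`spheroidal` implements a 2.5D analysis addressing both: spheroids are
segmented in 2D from the maximum intensity projection (MIP) and its
height view, extrapolated to 3D ellipsoids using the axial intensity
profile, classified by how much of each spheroid remains measurable
under attenuation, and marker-positive nuclei are counted with an
explicit extrapolation from the analyzable region to the whole
ellipsoid.

## The model, stage by stage

### Projection and 2D segmentation

For every lateral position the MIP stores the maximal intensity over z
and the height view (Z-buffer) the slice index where it occurred, ties
resolved toward the shallowest slice. Over an object the height view is
locally smooth — neighboring pixels take their maxima from nearby
slices — while over background it is essentially random. A disk range
filter (local max − min of the height view, radius `r_range` = 3 µm,
one quarter of a cell diameter) therefore separates the two: foreground
is where the local z-range is at most `max_z_range`.

`max_z_range` defaults to a data-driven value: the histogram of integer
z-ranges (bin width one slice) is smoothed with a 3-bin moving average,
the first nonzero peak located, and the threshold placed at the first
bin whose smoothed count falls below 10% of that peak — the extent of
the low-range foreground peak. Degenerate histograms (constant range
image, or no resolvable low-range peak, as in a pure-noise field) fall
back to half the slice count with a warning; with that fallback a
noise-only image segments to zero objects, which is the correct answer.

Thresholding is followed by majority smoothing (a pixel is foreground
when at least 5 of its 3×3 neighborhood are), hole filling, removal of
objects smaller than one cell footprint π(`cell_diameter`/2)², and
8-connected labeling. Finally objects whose mean MIP intensity falls
below `min_mip` (default: the mean background MIP intensity of the same
image) are discarded as spurious. Objects touching the image border are
kept but flagged.

### Ellipses, circularity, ellipsoids

Each 2D mask gets the ellipse minimizing the symmetric-difference area
against it, initialized from the mask's second-order central moments
and refined by Nelder–Mead; for the convex, compact masks this method
produces, the moment estimate is already within a pixel of the optimum
and the refinement is a safeguard. Masks are scored with a Podczeck
shape factor, area over the circle circumscribed on the maximal Feret
diameter, which is 1 for a disk and b/a for an ellipse. Laterally
overlapping or wrongly merged spheroids produce elongated unions that
score low and are excluded as "non-elliptical"
(default `min_circularity` 0.8; the filter deliberately errs toward
excluding irregular objects, which may also remove genuinely invasive,
non-compact structures). The Feret caliper spans the pixel footprint
(largest center-to-center hull distance plus one pixel); measured
center-to-center it would systematically overestimate circularity
deficits for small masks.

The third ellipsoid semi-axis is assumed to lie along z. Its center
depth z_c is the median height-view z over the mask's outer rim — at
the rim the vertical chords are short, so the MIP arrives near the
equatorial plane regardless of attenuation. Because hundreds of rim
pixels quantized to whole slices make a plain median snap to a slice
(and amplify any sub-slice tie imbalance into a ±z_step/2 error), the
median is computed with grouped-data linear interpolation inside the
median bin. The top coordinate z_top is the inflection point of the
axial profile I(z) — the mean over the 3×3 neighborhood of the ellipse
center per slice, restricted to z_c ± 4a — after Gaussian smoothing at
one z-step: scanning down from the flat background side, the first
convex-to-concave curvature crossing marks the rising edge, with linear
sub-slice interpolation and crossings below 5% of the window's maximal
curvature ignored as texture noise. Then c = |z_c − z_top| and
V = (4/3)πabc. Masks with equivalent radius below `min_radius` (24 µm)
carry too little axial information at ~10 µm z-steps, so their vertical
semi-axis falls back to the mean in-plane semi-axis (a+b)/2, as does
any profile without a detectable inflection.

### Attenuation and the analyzable region

The stable marker is assumed constant within a spheroid, with
absorption constant inside tissue and zero outside, so its axial
profile through the center measures attenuation directly: the retained
percentage is P_att(z) = 100·I(z)/I_max. Given a minimal retained
percentage P_min (default 50%), the analyzable depth is the distance
from z_top to the first crossing of P_att below P_min strictly beyond
the profile maximum (sub-slice interpolated, on the smoothed profile).
Comparing that depth with the vertical diameter 2c yields the
visibility class: `full` (depth ≥ 2c), `half` (the center is reached,
depth ≥ c), or `not_analyzable`. Equality joins the more permissive
class. Two practical points:

* A profile can also drop below P_min because the tissue simply *ends*
  — below the spheroid there is nothing to emit. When the caller knows
  the spheroid bottom (the pipeline passes z_c + c), crossings beyond
  it, within one z-step of measurement resolution, are reclassified as
  "uncapped": the whole spheroid is analyzable.
* P_att is computed on intensities as stored; the method presumes
  background-corrected input. A camera offset of 15% of the signal
  shifts the 50% crossing visibly (it adds a constant to both I(z) and
  I_max), which is why background correction is a stated precondition
  rather than part of the method.

### Spot detection and corrected counts

Marker-positive nuclei are bright blobs; they are detected as local
minima of the scale-normalized Laplacian-of-Gaussian response
(26-connectivity in 3D; in the fast 2.5D mode the stack is replaced by
its MIP with 8-connectivity and z is read from the height view). The
scale is optimized on the marker MIP by grid search over 20 log-spaced
values in [`max_spot_radius`/10, `max_spot_radius`], scoring each scale
by the strongest blob response. The raw "sum of the LoG image" is not
usable as a score — a Laplacian is zero-sum, so the image-wide sum
vanishes identically, and minima-sum variants reward the many
edge-ripple minima of small scales — whereas the peak response is the
classical scale-selection functional: maximal at σ = s for a Gaussian
blob of standard deviation s and near r/√2 for a disk of radius r.

Minima within `max_spot_radius` (8 µm, an average nucleus) of a
stronger minimum are merged by greedy, anisotropy-aware non-maximum
suppression, so one textured nucleus yields one spot while separate
nuclei stay distinct. Two filters follow. Minima weaker than 5% of the
strongest blob response are discarded as noise curvature. And spots
dimmer than the median spheroid intensity of the MIP are discarded;
the median is taken over the *stable*-channel MIP restricted to the
segmented masks. The stable channel is what defines "spheroid
intensity", and this choice makes the filter self-calibrating: since
the stable signal attenuates identically, for nuclei about twice as
bright as the tissue the cutoff sits at the 50%-retention plane — the
same analyzable region the counting step extrapolates from. A spot's
recorded intensity is the original-image maximum over the 3×3×3
neighborhood of its minimum, since a 10 µm slice grid easily samples an
off-center value.

Spots are assigned to the spheroid whose 2D mask contains their lateral
position. Counts are corrected by visibility class: `full` keeps the
raw count; for `half`, spots above the analyzable-depth plane are
scaled by the ratio of the ellipsoid volume to the cap volume
V_cap(h) = π·a·b·h²(3c − h)/(3c²), which reduces to the classical
doubling of the upper hemisphere at h = c; `not_analyzable` spheroids
get no count (their spots stay in the table, flagged). The baseline 2D
mode — every spot inside a 2D mask counts, no correction — is retained
for comparison; on scenes with only fully visible spheroids the two
agree exactly, and on half-visible spheroids the baseline is biased
low.

### Ground-truth validation

Automatic masks are compared against manual 2D masks by majority
overlap: a ground-truth region is matched by the candidate covering
more than half its area (two candidates cannot both do so; one
candidate dominating several ground-truth regions is assigned to the
best-covered one and the event recorded). Sensitivity TP/(TP+FN)
carries a Wilson score interval, which keeps coverage at small n and
never leaves [0, 1]. Matched pairs are scored by a sigmoid-weighted
contour accuracy: every pixel of the symmetric difference is penalized
by f(x) = 1/(1 + exp(−k(x − x₀))) of its Euclidean distance from the
ground-truth contour, with x₀ = 1.5 µm and k = 2 µm⁻¹, normalized by
the ground-truth area — sub-pixel boundary jitter is nearly free while
gross errors saturate at weight 1, so the accuracy 1 − e can go
negative for grossly oversized masks (a clamped value is attached as an
attribute). Ground truth is ingested from ImageJ RoiManager archives
with the 5-class color convention (red, green, magenta, cyan, blue for
well-separated, overlapping-brighter, overlapping-dimmer, touching, and
border spheroids); a store-only ZIP writer is included so archives can
be produced without ImageJ.

## The synthetic scene generator

`generate_scene()` produces two-channel stacks with complete ground
truth, emulating exactly the assumptions the analysis makes: ellipsoids
placed in a calibrated volume; a stable channel that is constant inside
tissue (default 500 a.u.) with 25% cell-scale modulation from
overlapping Gaussian blobs at sampled cell positions (a whole-cell
label is never dark between nuclei); a marker channel with
nucleus-sized blobs at a known subset of cells; Beer–Lambert
attenuation exp(−µ · vertical tissue path) applied identically to both
channels; anisotropic Gaussian PSF blur; constant background plus
Gaussian noise, quantized to 16 bits. Defaults mirror a 10×/0.4 NA
spinning-disk acquisition: 10 µm z-step, 1.3 µm pixels, 12 µm cells,
µ = 0.01 µm⁻¹ (half-intensity depth ln 2/µ ≈ 69 µm, in the range seen
for dense micro-tumors).

Positive cells are an exact-count random subset of the cells; when a
minimum spacing is requested (so that counting tests measure the
attenuation correction rather than the resolving power of an 8 µm merge
radius), they are drawn instead from a Matérn-II hard-core process over
the ellipsoid *enlarged* by the spacing radius, then clipped to the
tissue — candidates near the surface compete with discarded outside
candidates, keeping the process stationary. A greedy in-domain sampler
would over-seed the boundary by several percent, which is visible in
any volume-proportional count comparison.

What the generator does **not** emulate: physically rigorous optics
(spherical aberration, depth-dependent PSF, scattering anisotropy),
inhomogeneous absorption, necrotic cores, stromal-cell channels, uneven
background illumination, or invasive non-ellipsoidal morphologies.
Tests passing on these scenes show the implementation is faithful to
the model and unbiased under its assumptions — not that the model
captures every real culture.

## Numerical choices worth knowing

* Ties in the MIP resolve to the shallowest slice; on quantized
  intensities this leaves a sub-µm shallow bias in rim-height medians.
* The height view stores slice indices; conversion to µm happens at use
  sites. Exports write 0-based pixel coordinates alongside µm values.
* The range-filter radius converts to pixels as round(r/pixel size),
  minimum 1 px; border neighborhoods clip to valid pixels.
* Profile smoothing is fixed at one z-step; the analyzable-depth
  reference is the smoothed-profile maximum (`z_ref` in the return
  value), which is also where the crossing search starts.
* The ellipse refinement stops after 150 Nelder–Mead iterations or an
  objective change below 10⁻³ of the mask area.
* Cross-channel attenuation equivalence is assumed, valid when the two
  wavelengths are close; both synthetic channels obey it exactly.
* All randomness flows through a single integer seed per scene;
  identical seeds give bit-identical stacks and byte-identical result
  files.

## Study sizes used by the automated checks

The test-suite and acceptance script run entirely on synthetic scenes,
sized to exercise each claim: random 4×4×4–32×32×16 stacks against
brute-force projection oracles; 50 rasterized ellipses for the fit;
20 attenuation-free spheres (radius 30–60 µm, 10 µm z-step) for
ellipsoid recovery; spheres at µ = 0.01 µm⁻¹ with 5 µm z-steps and low
texture for the Beer–Lambert closed form (the closed form presumes the
uniform-stain assumption, so texture is turned down where it is being
tested); a five-point size sweep at µ = 0.025 µm⁻¹ for the visibility
classes; 100 spaced nuclei at 5:1 contrast for spot detection; and 100
half-visible spheroids (radius 50 µm, µ = 0.012 µm⁻¹, 6% positive
fraction, 18 µm spacing, background-corrected) for the unbiasedness of
attenuation-corrected counts against the uncorrected 2D baseline.

## Worked example

```{r example, eval = FALSE}
library(spheroidal)

scene <- generate_scene(scene_spec(n_spheroids = 3, seed = 1))
result <- run_pipeline(scene$stable, scene$marker, run_config())
result
tidy(result)       # per-spheroid feature table
glance(result)     # one-row run summary
plot_overlay(result)
```

## Known limitations

* Laterally overlapping spheroids are excluded (by circularity), not
  split; sensitivity on crowded fields drops accordingly.
* The vertical-axis estimate degrades when fewer than ~3 slices span a
  spheroid; such objects should rely on the `min_radius` fallback.
* The 2.5D spot mode inherits the MIP's occlusions: of two nuclei
  sharing a lateral position only the brighter is seen, and the height
  view assigns its z to both.
* Visibility classification near the class boundaries is sensitive to
  the measured depth at one-z-step resolution; equality cases join the
  more permissive class by convention.
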