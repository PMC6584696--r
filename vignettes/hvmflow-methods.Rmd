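---
title: "Quantifying the sublingual microcirculation from handheld vital microscopy"
author: "hvmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the sublingual microcirculation from handheld vital microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvmflow)
```

## The measurement problem

Handheld vital microscopy (HVM; incident or sidestream dark-field optics)
images the sublingual microcirculation at the bedside: hemoglobin absorbs
the illumination, so moving red blood cells (RBCs) appear as dark blobs on
a bright tissue background. The clinically used summary parameters are

* **TVD** (total vessel density): summed capillary centerline length per
  field-of-view area, mm/mm²;
* **FCD** (functional capillary density): the same sum restricted to
  *perfused* capillaries;
* **PPV** (proportion of perfused vessels): the length-weighted perfused
  fraction, identically FCD/TVD;
* **RBCv**: red blood cell velocity, µm/s, per path, per vessel (mean over
  paths) and per field (capillary-length-weighted mean).

`hvmflow` computes all of these fully unattended from a video or image
stack plus a device profile (pixel pitch in µm/px, frame rate). Capillaries
are vessels with mean diameter ≤ 20 µm (boundary inclusive); everything
larger is reported as a venule. An operator-supplied Massey quality score
gates the input: scores below 10 are analyzable.

## Pipeline

### Stabilization

Corner features (Shi–Tomasi minimum-eigenvalue criterion, default cap 500,
minimum spacing 8 px) detected in the first frame are tracked into every
later frame with sparse iterative Lucas–Kanade optical flow on a 3-level
image pyramid (window half-size 10 px, up to 30 iterations). A similarity
transform (translation, rotation, scale — 4 dof) is fitted to the
correspondences by least squares with median-absolute-deviation outlier
gating. Two deliberate choices differ from the textbook chain-of-pairs
construction:

* frames are intensity-normalized (zero mean, unit variance) before
  tracking, because global brightness flicker otherwise violates the
  brightness-constancy assumption and masquerades as a radial flow that
  the similarity fit absorbs into a spurious scale drift;
* every frame is tracked against the *first* frame rather than its
  predecessor, which removes the random-walk accumulation of per-pair
  errors. Frames with too few tracked features inherit the previous
  transform.

The cumulative trajectory is smoothed by a centered moving average
(default window 15 frames; the symmetric window shrinks at the sequence
ends, so constant and linear trajectories — i.e. deliberate physiological
panning — pass through unchanged) and only the residual raw-minus-smoothed
motion is corrected. Warped frames are cropped to the intersection of all
valid regions and the field-of-view area is recomputed from the crop.

### Vessel recognition

The temporal mean image fills the apparent discontinuities that plasma
gaps cause in single frames. Each detection pass first applies
contrast-limited adaptive histogram equalization (CLAHE): per-tile
histograms (default 8 × 8 grid) are slope-limited (relative clip 3, excess
redistributed uniformly) and each pixel's output is the bilinear blend of
the four surrounding tile mappings,
$s' = (1-y)\,((1-x)\,g_A(s) + x\,g_B(s)) + y\,((1-x)\,g_C(s) + x\,g_D(s))$.
With one tile and no clipping this reduces exactly to global histogram
equalization, which the tests exploit as an oracle.

Centerlines come from a principal-curvature line detector in the tradition
of Steger's curvilinear-structure work: the image is convolved with first-
and second-derivative Gaussian kernels,
$g''_\sigma(x) = \frac{x^2-\sigma^2}{\sqrt{2\pi}\,\sigma^5}
 e^{-x^2/(2\sigma^2)}$,
the Hessian eigenvector of the largest (most positive; vessels are dark)
eigenvalue gives the line normal, and a subpixel point is accepted where
the first directional derivative vanishes inside the pixel. The response
is scale-normalized ($\sigma^2 \lambda$, intensities on [0, 1]) so that one
threshold pair serves all scales; hysteresis applies: chains may pass
through points above the low threshold but must contain a point above the
high threshold. Two additions proved necessary on realistic backgrounds:
chains are cut back when a sub-high-threshold tail extends more than
2σ beyond the outermost strong point (such tails follow faint tissue-
texture ridges), and link candidates must lie in a 60° forward cone of the
direction of travel (sideways hops onto a parallel neighbour would
otherwise zigzag between close structures). Linking itself accepts
candidates within distance *l* (default 2.5 px) and tangent-angle
difference *h* (default 0.5 rad), nearest first with the angle difference
as tie-break, so junction continuations prefer the minimal angle change.
Polylines shorter than 10 px are discarded.

Line width is estimated per point by locating the gradient extremum along
the normal on both sides; the detector-scale broadening is removed per
side as $\sqrt{d^2-\sigma^2}$ (for a Gaussian-profile line the smoothed
edge sits at $\sqrt{\sigma_p^2+\sigma^2}$), with a fallback cap of 2.5σ
per side when no interior extremum exists. A vessel's diameter is the mean
of its per-point widths times the pixel pitch; "diameter" here means the
full width at half maximum of the dark cross-profile.

Two passes run independently: a capillary pass at `sigma_capillary`
(default 5 px, adequate for lines up to about $2\sqrt{3}\sigma \approx 17$
px) and a venule pass at `sigma_venule` (default 28 px at full scale)
executed on an image block-downsampled by 4. A scale of at least
$w/(2\sqrt{3})$ is required to detect a line of width *w*; the defaults
build in roughly a factor-2 margin. Venule-pass line points within one
local vessel width of a surviving capillary-pass point are removed before
linking, so a mid-sized vessel found by both passes yields one segment.

The hysteresis thresholds (`steger_high` 0.105, `steger_low` 0.08) were
fixed once against the reference synthetic suite so that the capillary
ridge response separates from CLAHE-amplified tissue texture; they play
the role of the device-specific parameter table a clinical deployment
would carry in its configuration file.

### Space–time velocimetry

Each frame is histogram-equalized individually (removing inter-frame
flicker, which would imprint vertical stripes on the diagrams) and
Gaussian-smoothed (default σ 1 px). For every vessel, intensities are
sampled bilinearly at ~1 px arclength spacing along the centerline in
every frame and appended column-wise into a space–time diagram
(kymograph); the diagram is then histogram-equalized. Sampling skips
`sigma_capillary` px at both centerline ends, where line-point
localization is least reliable and reading static background would
imprint stationary bands.

The same line detector (σ 1.5 px, thresholds 0.10/0.05) runs on the
diagram; each linked centerline, ordered by time, is one RBC path. Path
velocity is the mean first derivative of space with respect to time:
subpixel samples are collapsed to one mean position per frame and the
time-weighted mean of |Δs|/Δt is scaled by pitch × frame rate; the
outermost (partial) frame bins are dropped when at least four exist. Paths
spanning fewer than four frames instead use the principal-axis (total
least squares) slope of the raw samples — steep bands cross the vessel in
very few frames and per-frame centroids would truncate them.

A path is discarded as an artifact if its length is below
`min_path_length` (10 px), its curvature index (straight-line endpoint
distance over actual path length) is below 0.8, its velocity exceeds the
vessel's maximum measurable velocity $v_{max} = l f / 3$ (vessel length l
in µm, frame rate f in 1/s), or its time span is below two frame
intervals (a time derivative is not measurable from fewer than three time
samples). Remaining paths are low flow below the species-specific
`low_flow_cutoff` (default 25 µm/s) and normal flow otherwise.

Near-horizontal traces are then resolved against the vessel's own path
population: slow paths are genuine non-moving cells only when more than
95% of the vessel's path velocities lie below the low-flow cutoff (the
barcode situation); in a vessel with substantial moving traffic such
traces are detection artifacts — typically residual static structure
along the centerline — and are reclassified as artifacts. Vessel RBCv is
the plain mean over the remaining non-artifact paths. Perfusion is then
decided on the velocity *distribution* rather than the mean: if more than
95% of path velocities lie below the low-flow cutoff the vessel is
non-perfused unconditionally — robust to a fast minority of spurious
paths — and otherwise the vessel is perfused exactly when the normal-flow
fraction strictly exceeds 95%. One consequence worth knowing: a vessel
with intermittent flow (1-s stalls between flowing episodes) is reported
*perfused*, because its stalled-phase traces are resolved away as a
minority; bedside MFI-style scoring would call such a vessel
non-perfused. The generator's truth labels follow the algorithm's
semantics (a vessel counts perfused when it carries flowing cells at
all). The fraction threshold
is the default operationalization; a variant that fits a normal
distribution to the velocity sample and thresholds its tail masses is
available via `perfusion_mode = "normal_fit"` for users who prefer the
distribution-fit reading, since the two constructions coincide only
asymptotically. Vessels with no usable path are non-perfused with
undefined RBCv; they still count toward TVD but are excluded from the
field RBCv mean entirely (both numerator and denominator).

### Aggregation

TVD sums capillary lengths (µm/1000) over the field-of-view area; FCD
restricts to perfused capillaries; PPV = FCD/TVD (0 when TVD is 0); field
RBCv is the capillary-length-weighted mean of defined vessel RBCv values.
Length weighting makes all field metrics invariant to a capillary being
reported as several abutting segments, e.g. when the focal plane cuts it.

## The synthetic scene generator

`renderScene()` produces HVM-like sequences with exact ground truth: dark
anisotropic-Gaussian cells (about 7 µm along the flow direction) advected
along smooth natural-spline centerlines at specified velocities, plasma
gaps set by a cell spacing, a bright background with a static smooth
tissue texture, global per-frame brightness flicker, translational jitter,
and additive Gaussian sensor noise, all driven by one seed (bit-identical
re-renders). Several generator choices matter and are deliberate:

* **Irregular plasma gaps** (±40% around the nominal spacing, cells never
  interpenetrating): a perfectly periodic cell train strobe-aliases at
  video frame rates, something real, irregular cell columns do not do.
* **60 frames/s** for the reference scenes — the upper end of the 25–60
  fps range of bedside devices. At 25 fps a 300 µm/s cell advances farther
  per frame than its own length and its kymograph band decoheres into
  unconnected dots; the same consideration motivates high-frame-rate HVM
  hardware.
* **Texture damping under tubes** (85%): the plasma-filled lumen
  homogenizes the optical path, so background texture is not seen through
  a vessel. Without this, long plasma gaps expose static texture that
  imprints stationary bands on the diagrams.
* **No-flow vessels hold a packed stagnant cell column** (tight spacing):
  a stalled capillary retains its cells, which is also what makes the
  barcode sign visible at all.
* **Cell trains at high velocity**: above roughly 800 µm/s individual
  cells are not resolvable at video rates; the hyperdynamic scene moves
  25 µm cell trains separated by long plasma gaps.
* **Cells slide in and out** over a short centerline extension rather than
  teleporting at a wrap point, which would create spurious fast
  "emergence fronts" in the diagram.

`defaultSuite()` bundles seven scenes: the four flow archetypes (normal,
hyperdynamic, intermittent with 1-s stalls, no flow), a 512 × 512,
100-frame multi-vessel density scene at 1.3 µm/px (six capillaries of
6–15 µm plus one 55 µm venule) in noise-free and noisy variants, and a
stress scene combining flicker, jitter and noise.
`velocitySweepScene()` builds a short (~45 px) capillary whose cell length
and gap spacing grow with the expected band slope, so that injected
velocities up to 0.8 v_max remain resolvable at the sampling rate; it is
the scene used to validate velocimetry against ground-truth centerlines,
mirroring validation studies in which centerlines are drawn manually
before space–time analysis.

What the generator does *not* emulate: out-of-focus blur and focal-plane
drift, vessel-wall structure, leukocytes and plasma heterogeneity,
non-rigid tissue deformation, rolling-shutter artifacts, and realistic
tissue texture statistics. Passing tests on these scenes therefore
demonstrate correctness of the algorithmic chain under controlled
conditions, not clinical performance on real recordings.

## Numerical choices and degenerate inputs

Gray values live on [0, 255]; histogram equalization rounds to 8-bit
levels first and degenerate (single-level) histograms pass through
unchanged. Gaussian kernels are truncated at 3.5σ and renormalized for
exact response to constant, linear and quadratic ramps. Subpixel positions
are 0-based (row, col) with the origin at the top-left pixel center;
arclength is cumulative Euclidean distance. Bilinear interpolation is used
for all subpixel sampling and warping; samples outside the raster are
invalid and drive the stabilization crop. An empty crop intersection
raises an error ("stabilization failed"); a centerline leaving the cropped
field is trimmed to its longest interior run with a warning. Velocities
are magnitudes; flow direction is not reported.

## Problem sizes used by the tests and the acceptance script

The bundled checks run the density scenes at 512 × 512 × 100 frames, the
archetypes at 160 × 160 × 120–240 frames, the velocity sweep at
160 × 160 × 300 frames, and stabilization fixtures at 128–160 px and
12–20 frames; statistical identities use 1000 random vessel populations
and 10⁴-draw agreement samples. These sizes were chosen to exercise every
code path at full algorithmic fidelity while keeping a complete run in the
minutes range on a single core.

## Known limitations

Parameters are calibrated for capillary-scale structures at ~1–1.5 µm/px;
other devices, tissues or species need their own configuration (that is
why every tunable is config-exposed). Venule-pass diameters are coarse
(downsampled pass) — classification is reliable, the venule width estimate
is indicative. Velocity measurement degrades near v_max by construction;
the v_max discard rule is the guard, not a fix. Intermittent-flow vessels
are reported perfused as a whole (see above); modelling within-diagram
flow episodes is out of scope, as are arteriole classification, automated
quality (Massey) scoring, and AVI container IO (lossless TIFF/PNG stacks
are used instead).
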