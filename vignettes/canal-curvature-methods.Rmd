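---
title: "Methods: canal-based lumbar curvature assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canal-based lumbar curvature assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalcurve)
```

## The measurement model

`canalcurve` measures lumbar curvature as the geometry of the spinal canal
centerline rather than of vertebral landmarks. The underlying assumptions
are: (i) the canal is a connected, roughly tubular structure whose contents
(CSF, cord, roots) are darker than the surrounding bone; (ii) its medial
axis is a smooth space curve that follows the spinal curvature; (iii) the
lumbar segment is well delimited by two user-supplied planes through the
T12 inferior and S1 superior endplates. Nothing in the pipeline identifies
vertebrae — osteophytes or endplate irregularities at worst perturb the
canal wall locally, which the medial-axis path integrates away.

All volumes are brought into one anatomical frame at load time (X+ right,
Y+ ventral, Z+ cranial; mm). With that fixed frame the lordosis peak is
simply the Y-maximum of the normalized curve, and a minor right scoliosis
appears as positive X. The alternative — carrying per-stage orientation
metadata — is where sign errors breed, so it is resolved once at I/O.

## Segmentation

**Seeding.** The mid-axial slice is scanned for in-band
(`[-100, 150]` HU by default) connected regions that look like a canal
cross-section: area within `[30, 600]` mm², circularity
`4πA/P² ≥ 0.4` (with the perimeter estimated by exposed pixel-edge
counting, a digital disk scores ≈ 0.62, so 0.4 is a generous roundness
floor), and an enclosing shell that is mostly above-band (bone-like).
Among candidates the one nearest the dorsal third of the slice wins — the
canal lies dorsal to the vertebral body. If the mid slice happens to fall
on a disc level with no candidate, neighboring slices are scanned outward.

**Region growing.** The canal is propagated from the seed slice outward,
one slice at a time in both directions. Each slice's candidate
cross-section is flooded (8-connected) through the intensity band,
restricted to voxels within `drift_mm = 2` mm of the previous slice's
accepted region — the canal drifts slowly across slices, while escape
routes through disc-level wall openings require larger in-plane jumps —
and accepted only if it passes the same area/circularity screen. A slice
that fails the screen (typically because a nerve-root window let the
region mushroom) is bridged by re-flooding within the previous
cross-section's exact footprint, for at most `bridge_slices = 6`
consecutive slices. A leak guard aborts if the total mask exceeds 10× the
expected canal volume from the radius prior (8 mm). This cross-section
propagation is the package's reading of "morphological region growing":
growth is iterative and each iteration's candidate regions are screened by
shape and size. It deliberately restricts the 26-connected growth
neighborhood to in-plane + adjacent-slice moves, because unconstrained
3-D growth cannot recover once a leak and the canal merge within a slice.

**Refinement.** A narrow-band binary surface evolution sharpens the coarse
mask: candidate voxels 6-adjacent to the surface are added when their
intensity matches the coarse region (gate = mean ± max(3·SD, 20) HU) and
the Gaussian-gradient edge indicator `1/(1 + (|∇G_σ I|/λ)²)` (σ = 1 mm,
λ = 100 HU/mm) shows no strong edge; voxels whose intensity squarely
matches the region (half-width gate) may be added even against the edge
indicator — the outermost canal voxels sit inside the spilled-over
gradient of the bone interface and would otherwise be unreachable.
Boundary voxels failing the gate are removed. Additions with weak
intensity evidence need two set neighbors (a curvature-like penalty on
one-voxel tendrils). All movement is confined to ±2 voxels around the
coarse surface and runs a fixed 50 iterations for reproducibility. On
noiseless phantoms every addition is a true canal voxel and every removal
a non-canal voxel, so refinement provably never decreases Dice there.

## Centerline

The speed map is the Euclidean distance to the mask boundary (exact
separable transform, anisotropic spacing) normalized to `(0, 1]` inside
and `10⁻⁶` outside; eikonal fronts therefore travel fastest along the
medial axis and essentially cannot leave the canal. First-order fast
marching with the 6-neighbor upwind stencil computes arrival times from
the caudal slice centroid; the path is back-traced from the cranial
centroid by steepest descent with 0.25·min-spacing steps and a discrete
26-neighbor fallback wherever the interpolated gradient stalls. A
disconnected mask is detected by the arrival cost: crossing any
epsilon-speed space inflates the cost by orders of magnitude over the
chord-length bound. The raw path is resampled at 1 mm arc length and
smoothed with a centered 5-point moving average, endpoints fixed. On
seeded phantoms the extracted centerline lies within a fraction of a voxel
of the analytic truth (mean ≈ 0.23 mm at 0.8/0.8/1.5 mm spacing); tests
additionally verify the eikonal cost against an independent Dijkstra
shortest path on the voxel graph (within 5% on 20³ grids).

## Normalization and descriptors

The centerline is cropped at its unique intersections with the two
endplate planes (linear interpolation between bracketing samples). The
normalization rotates only about Z (axis standardization, not chord
alignment — aligning the chord would destroy exactly the cranial-station
Y asymmetry the group comparison is about), translates B to the origin and
divides by the projected extent `Az − Bz` (not the 3-D chord: the two
differ when the chord is oblique, and the projected extent is what makes
`curvedness = 1` for a straight chord). `scale_mm` preserves the mm scale
for the two length descriptors.

The peak P is taken on polyline samples without interpolation; with ≥ 200
resampled points the location quantization (< 0.005) is an order of
magnitude below the reference cohort's between-subject SDs (0.075–0.086).
Ties within 10⁻⁹ resolve to the median index of the maximal set, which is
stable on flat-topped curves. Peak heights are reported as nonnegative
magnitudes in the ventral-positive frame. A peak falling on an endpoint
degenerates the height definitions; the package warns and reports anyway.

## Population models and comparison

"Cross-sections along the curves" are planes of constant Z — consistent
with the comparison stage's equal Z partition. The model curve is the
component-wise (X and Y separately) sample median per station, with the
per-axis sample SD; component-wise rather than geometric median because
the downstream tables treat X and Y separately. Extracted polylines may
locally backtrack in Z, so station lookup takes the first crossing along
arc length (monotone-Z repair).

Comparison resamples every curve at K = 20 stations, drops the common
origin, and runs a two-tailed pooled-variance Student t-test per station
and axis (Welch available by flag), most-cranial location first. No
multiple-testing correction is applied by default: station coordinates
along one curve are strongly dependent, and a Bonferroni-style correction
is inappropriate there; a `bonferroni` flag exists as a documented
deviation. An optional dorsal-positive display flag negates reported Y
means only — reference tables print the sagittal offsets with the
opposite sign convention from the internal ventral-positive frame; only
signs, never p-values, are affected. The embedded reference sagittal
table prints its most cranial location as "P value >0.01" while its
source text counts seven significant cranial locations; the package
stores that entry as 0.009 (below 0.01, consistent with the count) and
flags it in a `note` column.

## The phantom: what it emulates and what it does not

`synthesize_volume()` builds a CT-like scan around an analytic
centerline: the lumbar curve is the unique cubic `y(z)` fixed by the four
constraints `y(0) = 0`, `y(zₚ) = h_caudal`, `y'(zₚ) = 0`,
`y(1) = h_caudal − h_cranial`, plus a sinusoidal lateral bow; it is
extended straight to the scan borders so the canal spans the whole volume
as in a real acquisition, and the endplate planes are emitted as the
cropping landmarks. A cubic cannot also have its arc length prescribed, so
curvedness is emergent (≈ 1.02 at the reference descriptor means) rather
than imposed; tests treat it that way. The sample grid always contains
`z = zₚ` exactly (uniform points within 2·10⁻³ of it are dropped so a
floating-point near-tie cannot shadow the peak sample), which is what
makes the descriptor round-trip exact to 10⁻⁶ and better.

The tube (default radius 8 mm) is wrapped in a 1200 HU bone ring, 5 mm
thick, interrupted every 35 mm by a 6 mm disc band where the ring drops
to 200 HU (a weak edge, just above the acceptance band) and is cut open
laterally over ±25° around the left/right directions — nerve-root windows
with no edge at all, the canonical leak paths that make canal segmentation
hard. Soft tissue is 40 HU, canal contents 10 HU, and seeded Gaussian
noise (default SD 20 HU) is added last. Intensities are plausible
defaults, not calibrated to any scanner. Default spacing is
(0.8, 0.8, 1.5) mm and the default grid 256 × 256 × 300 voxels, inside
the reference cohort's stated acquisition ranges.

Synthetic curve populations draw each subject's descriptors independently
from per-sex Gaussians (reference means/SDs), truncated by rejection to
valid ranges (peak location clipped to [0.05, 0.95]; the reference min/max
columns show bounded ranges). What the phantom does **not** emulate:
trabecular texture, beam hardening or metal artifacts, patient motion,
inter-subject variation in canal caliber along Z, or correlation between
descriptors (real curves likely correlate peak location with heights).
Passing phantom tests therefore demonstrates correctness of the
machinery, not clinical-grade robustness on pathological anatomy.

## Numerical choices and problem sizes

* Intensity band, area band, circularity floor, drift, band width and
  iteration counts are all exposed in `segmentation_params()`; defaults
  above.
* Fixed iteration counts instead of convergence detection — bitwise
  reproducibility given a seed.
* The descriptor t-test calibration runs 500 replicate experiments at the
  reference sample sizes (81 vs 77) with per-replicate generator seeds
  drawn from a single master stream (arithmetically related seed pairs
  measurably distorted the empirical type-I rate); the closed-form
  noncentral-t power is the oracle. Unit tests use small phantoms
  (64 × 64 × 80) and populations of tens to hundreds of curves; the
  acceptance script uses the full default phantom and 2000-curve
  populations where convergence matters.

## Known limitations

* T12/S1 landmark planes are supplied, not detected; automated vertebral
  labeling is out of scope.
* The active-surface refinement is a morphological variant, not a PDE
  level set; its narrow band means the coarse mask must already be within
  ±2 voxels of the true boundary.
* Per-station model SD is per-axis; a radial SD around the model curve is
  a defensible alternative reading and would differ where X and Y spreads
  are unequal.
* Only NIfTI volumes are read; DICOM series must be converted upstream.
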