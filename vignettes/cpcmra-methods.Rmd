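---
title: "Composite phase-contrast MR angiography: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite phase-contrast MR angiography: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cpcmra)
```

## The problem

A 4D flow MRI acquisition encodes, per cardiac frame, an anatomical
magnitude image and three signed velocity components, with a velocity
encoding limit (VENC, here 1.5 m/s) above which phase wraps.  The
magnitude images of such research sequences have low signal-to-noise and
poor lumen/tissue contrast, so they are a weak basis for segmenting the
vessel.  The velocity field, however, is zero in static tissue and large
in the lumen during systole.  `cpcmra` synthesizes an angiogram from it
and carries the result through geometric and hemodynamic validation.

## The CPC-MRA model

At a cardiac frame the speed volume `|v| = sqrt(vx^2 + vy^2 + vz^2)` is
resliced into an image stack (transverse, coronal or sagittal; trilinear
interpolation, native in-plane spacing, slice gap 0.35 mm by default) and
mapped to intensity:

- `|v| >= v_threshold` (default 0.25 m/s): `I = I_max * min(|v|, v_ceiling) / v_ceiling`,
  an affine image of speed.  `v_ceiling` defaults to VENC so the map covers
  the encodable range; the source procedure says only "proportional", and
  an affine map to the encoding limit is the least-arbitrary reading.
- below threshold: background — either 0 (`suppress`) or the anatomical
  magnitude image rescaled to at most 25% of `I_max`
  (`retain-magnitude`), so lumen signal always dominates.

Blood arrives at different territories at different phases of the cycle,
so one frame under-renders distal and recirculating regions.  Three
frames — systolic acceleration (SA), peak systole (PS), systolic
deceleration (SD) — are merged slice-by-slice.  The slice-wise "sum" of
the three stacks is deliberately implemented as **equal-weight alpha
blending (mean)** rather than a literal sum: a raw sum triples intensity
where all phases overlap, which contradicts the stated goal of uniform
lumen intensity; the mean (followed by a full-range contrast stretch)
reproduces a uniform bright lumen wherever any phase is bright.
`pixel-max` is available as an alternative with the same above-threshold
mask.  This ambiguity between the written sum and the described alpha
blending was a genuine design fork; the mean was chosen and the
alternative kept accessible.

The final composite is contrast-stretched: a linear remap sending the
`saturation` quantile (default 1% per tail, the conventional default of
full-range intensity adjustment) to 0 and the `1 − saturation` quantile to
`I_max`, with clipping; constant images pass through unchanged.

Per-pixel provenance (which phases exceeded the threshold) is retained,
which yields the false-color view: white where all three phases agree,
magenta where PS dominates, green where SD dominates.

### Automatic phase selection

The manual choice of frames (near 0.21 T / 0.26 T / 0.36 T) is automated:
PS is the frame maximizing the spatial-mean speed over the above-threshold
mask; SA is the frame before PS with mean at least 50% of the PS mean and
the steepest rising mean; SD is the symmetric choice after PS.  The search
is circular; explicit frame indices in `cpc_config(phases = ...)` override
it.  A constant-flow dataset degenerates to adjacent frames with a
warning; zero flow is an error.

### Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `v_threshold` | 0.25 | m/s | best contrast with low noise; 0.25–0.40 m/s is the useful band — lower admits noise, higher underestimates the lumen |
| `v_ceiling` | VENC (1.5) | m/s | affine speed→intensity map over the encodable range |
| `slice_gap` | 0.35 | mm | the finest reslicing gap of the reference workflow |
| `n_slices` | 1200 / 500 / 500 | — | transverse / coronal / sagittal defaults |
| `stretch_saturation` | 0.01 | fraction per tail | conventional full-range remap default |
| `I_max` | 4095 | — | 12-bit DICOM-style intensity ceiling |
| `intensity_threshold` (segmentation) | 0.1 | fraction of `I_max` | see below |

### Segmentation threshold

In the manual workflow this package automates, an operator lowers the
rendering threshold until the whole vessel is visible and then contours
by intensity thresholding.  On an alpha-mean composite, a near-wall pixel that is
bright in only one of the three phases keeps about one third of the full
blended intensity before stretching; a segmentation threshold near 0.5
therefore carves the wall away.  The default is deliberately low (10% of
`I_max`): with a suppressed background every above-threshold pixel is
lumen signal, and noise speckle is removed afterwards by
largest-component filtering and 1-voxel morphological closing (which is
unioned with its input so it remains extensive at the grid boundary).

## Geometry pipeline

**Surfacing.** The binary mask is iso-surfaced at 0.5 with marching
tetrahedra (the Kuhn 6-tetrahedron cube subdivision, face-consistent
across cubes, hence watertight by construction; watertightness is
asserted after every extraction), then smoothed by 10 iterations of
uniform Laplacian relaxation with a volume constraint (rescaling about
the centroid after each pass restores the enclosed volume, so smoothing
removes staircase area without shrinkage).  Marching tetrahedra was
implemented in preference to marching cubes to avoid importing the
classic 256-entry case tables; on binary data at these resolutions the
two are equivalent for the metrics used here.

**Voxelization** of a watertight surface is a parity ray-cast along +x at
every voxel center, with a sub-voxel irrational jitter of the ray origins
so edge and vertex hits have measure zero.

**Centerlines** are minimum-cost paths on the 26-connected voxel graph
with per-voxel cost `1/(dt + eps)`, `dt` the Euclidean distance transform
(exact, anisotropic) and `eps = 0.1 mm`; this reproduces the
maximal-inscribed-sphere semantics of Voronoi-based centerline tools
without their dependency stack, and on tubular phantoms the two coincide
within a voxel.  The per-point radius is `dt` at the path point.  Two
consequences worth knowing:

- the discrete `dt` measures distance to the nearest *background voxel
  center*, which on coarse anisotropic grids underestimates the distance
  to the true wall by up to about half a voxel diagonal.  On the 2 mm
  straight-tube phantom the recovered mean radius is 4.39 mm against a
  6 mm truth — inside the one-voxel tolerance, with the bias explained by
  the discrete EDT plus the velocity-threshold loss at the slow-moving
  wall layer (the parabolic profile drops below 0.25 m/s at about 0.9 R);
- the raw path is a staircase; the resampling/smoothing protocol below is
  what regularizes it (and the curvature computed from it).

**Resampling and smoothing.** Uniform arc-length resampling to (close to)
3 mm, then 100 iterations of endpoint-pinned Laplacian relaxation
`p_i <- p_i + 0.5 ((p_{i-1} + p_{i+1})/2 − p_i)`.  The "factor 0.5, 100
iterations" wording is interpreted as this per-iteration relaxation
weight — the semantics of the centerline-smoothing tool the protocol
invokes; a cumulative-fraction reading was considered and rejected as not
matching any common implementation.  Note the smoother contracts genuine
low-frequency curvature slightly: on an 87-point arc the slowest mode
keeps about 97% of its amplitude after 100 iterations, which is why
end-to-end curvature recovery is quoted with a 5% tolerance.

**Curvature and tortuosity.** `kappa = |c' x c''|/|c'|^3` with central
differences on the arc-length parameterization (endpoints copy their
interior neighbour; degenerate triples give 0), reported in 1/m;
`chi = L/D − 1`.  End-to-end summaries use the mean over interior points
(more than 10 mm from either end): endpoint one-sided differences and the
pinned smoother distort the first and last few millimetres, and on the
torus phantom the interior mean is stable across seeds where the median
carries a small positive staircase bias.

**Bifurcation angle.** The bifurcation plane is spanned by the two
daughter initial tangents (least-squares direction of the first 10 mm)
through the reference point; the angle is between the in-plane daughter
directions.  The full bifurcation-reference-system decomposition is out
of scope — only the daughter angle is reported.  In the end-to-end
pipeline the daughter centerlines are seeded one tube radius beyond the
apex: within one radius of the junction the lumen is a merged bulge with
no well-defined branch axis, and tangents fitted there bias the angle low
(about 4–5 degrees on the 70-degree phantom); seeded at one radius the
recovery is within 3 degrees.

**Alignment, Dice, Hausdorff.** Rigid alignment uses exactly two
landmarks (bifurcation reference point, left-iliac endpoint): translation
superposes the first pair, the minimal rotation maps the landmark
difference vector, and roll about that axis is left at zero — it is
unresolvable from two points, which is a documented limit of the
protocol, not of the implementation.  Dice is computed from voxel
cardinalities on a shared 0.5 mm grid.  The slice-wise Hausdorff protocol
intersects both meshes with 1000 equally spaced transverse planes over
the shared axial extent, samples each section contour at 0.1 mm or finer
(making the 2D point-set HD insensitive to tessellation), computes the
exact symmetric HD per plane, skips-and-counts planes missing either
surface, and summarizes with mean, SD and the 95th percentile (linear
interpolation between order statistics).  Comparisons follow the
truncation protocol: models are trimmed to a common extent at shared
landmarks before Dice/HD, which is how the end-to-end Dice criterion is
evaluated (tube mouths taper through boundary interpolation and are not
part of the shared anatomy).

## Hemodynamics post-processing

TAWSS and OSI are trapezoidal cycle integrals of the per-element WSS
vector series; the cycle is closed periodically by wrapping the last
sample to `t = T` with the first (CFD exports rarely duplicate the
endpoint).  OSI is clamped into [0, 0.5] only through the ratio bound;
elements with zero total shear are defined as 0.  Extreme regions use
count-based quantiles (ties included), matching the element-count
phrasing of the reference analysis.  Flow waveforms sum through-plane
velocity times pixel area over lumen pixels on 5 transverse planes and
interpolate with a natural cubic spline to 1 ms; "a cubic function" does
not name a dialect, and the natural spline is the default choice, with
the property (asserted in tests) that it passes through the raw samples.
TAWSS normalization against an outlet value is exposed as a user-supplied
scalar divisor rather than guessed.

## Statistics

The Wilcoxon signed-rank statistic is `W = min(W+, W−)` over signed
midranks with zero differences dropped.  For n ≤ 25 the two-sided p is
exact, computed by a tie-aware dynamic program over the generating
polynomial of signed midranks — mathematically identical to enumerating
all `2^n` sign patterns (the test suite verifies this against a literal
enumeration for n ≤ 12) but polynomial in cost.  Beyond n = 25 a normal
approximation with continuity and tie correction is used.  One signed-rank
procedure is provided; no distinct non-Wilcoxon variant exists here.
Bland–Altman limits are
`median(d) ± 1.45 × IQR(d)` with type-7 quartiles — the nonparametric
variant chosen for non-normal differences; classical mean centering is an
option.

## The phantom: what it emulates, and what it does not

`phantom_spec()` states the acquisition world once: 20 frames per 1 s
cycle; VENC 1.5 m/s; anisotropic 3.6 × 2.4 × 2.6 mm default spacing
(isotropic fine grids for convergence work); a systolic raised-cosine
waveform peaking at frame 6 (0.25 T, between the reference SA/PS/SD
marks) with peak mean velocity 0.6 m/s — i.e. a 1.2 m/s parabolic
centerline peak, a realistic aortic value at 80% of VENC — and a 0.03 m/s
diastolic baseline; Rician noise on magnitude and Gaussian noise on
velocity components (both scaled from one `noise_sigma`, standard MR
statistics); an optional distal lag of the pulse along the axis.  All
randomness flows from one seed and outputs are bit-identical across
calls.

The distal-lag configuration used to demonstrate the compositing
rationale (lag 4 frames, pulse width 5 frames) deliberately exaggerates
the physiological pulse-wave delay: it models the *phenomenon* — distal
territories dark at the proximal peak-systole frame and bright at a later
frame — at a magnitude resolvable on a 2 mm grid, not a literal pulse
wave velocity.  With it, the PS-only above-threshold mask strictly
under-covers the distal third while the SA+PS+SD composite restores it.

Limits of fidelity, hence of what a green test establishes: voxel values
are the analytic field at voxel centers (no intravoxel dephasing or
partial-volume averaging); no eddy-current offsets, no velocity wrap, no
Womersley (annular) profiles, no dissection/false-lumen or stent-artifact
models; the Y-junction truth surface is produced by fine voxelization and
iso-surfacing of the analytic indicator (a synthetic stand-in, since the
union of two capped tubes has no simple closed mesh), whereas tube and
torus truths are exact parallel-transport tube meshes.

## Numerical choices and degenerate rules

- Trilinear interpolation everywhere; samples outside a grid are 0;
  voxel centers at `origin + index * spacing` in an LPS frame
  (transverse = fixed z, coronal = fixed y, sagittal = fixed x).
- Contrast stretch on a constant image: identity.  Dice of two empty
  masks: 1, with a warning.  OSI with zero total shear: 0.  Coincident
  tortuosity endpoints: error.  Parallel bifurcation daughters: 0 with a
  warning.
- Quantiles are type 7 (linear interpolation) throughout — stretch tails,
  HD 95th percentile, extreme regions, Bland–Altman quartiles.
- Endpoints offered to `extract_centerline` snap to the nearest
  foreground voxel within 3 mm; beyond that they are an error.
- NIfTI-1 volumes are written as float32 with a diagonal sform; geometry
  metadata round-trips exactly, voxel data to one float32 unit.  DICOM is
  not supported in this build (no codec available); the documented layout
  is NIfTI + JSON sidecar, and `read_flow4d(format = "dicom-series")`
  fails with a clear message.  Phase-encoded integer sources are rescaled
  `p / phase_scale * VENC` at read time; velocity lives in m/s in memory,
  always.

## Known limitations

Two-landmark alignment leaves roll unresolved by construction.  The
slice-wise HD protocol is tied to transverse planes in the aligned frame.
Branch splitting handles one bifurcation, not arbitrary trees.  The
segmentation inherits the velocity-threshold bias: slow near-wall flow
renders dark, so radii from velocity-derived angiograms tend to sit below
the anatomical wall — visible in the phantom recoveries and consistent
with the modality's physics rather than a defect of the implementation.
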