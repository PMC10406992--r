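---
title: "Quantitative methods in petquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods in petquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

petquant is a scriptable toolbox for dynamic PET quantification: image
I/O with frame timing, region definition and statistics, time-activity
curves, graphical and compartment-model kinetics, entropy-based rigid
co-registration, and left-ventricular polar maps. This vignette explains
the models and algorithms, the defaults and their rationale, the
numerical choices, and what the seeded phantom generators do and do not
emulate.

## The image model

All readers normalise into one container: a 4D voxel array `(x, y, z,
frame)` with a 4x4 voxel-to-world affine in the RAS+ convention (0-based
indices, world in mm) and a per-frame `(start, end)` schedule in seconds
post-injection. A static image is the one-frame case with schedule
`(0, 0)`, so VOI statistics and segmentation work uniformly on static
and dynamic data. Time is seconds everywhere internally; rate constants
are converted to per-minute only at reporting boundaries, which is how
the kinetic literature quotes them.

NIfTI-1 and Analyze 7.5 go through the `RNifti` library; DICOM series
are read by a small built-in parser for uncompressed little-endian
encodings, one slice per file, which covers dynamic PET exports: slices
are sorted along the slice normal and grouped into frames by
FrameReferenceTime when present, else AcquisitionTime. Images are
assumed decay-corrected by the scanner, as reconstruction pipelines
normally do before export. Frame schedules travel in a 3-column
plain-text sidecar (`start_s end_s dur_s`), since NIfTI itself has no
per-frame timing.

## Regions of interest

The single containment rule everywhere is **voxel-center containment
with inclusive boundary**: a voxel belongs to a shape iff its center
lies inside or on it. This makes every rasterisation deterministic and
lets brute-force enumeration serve as an exact oracle in the tests.
Planar shapes (rectangle, circle, ellipse, polygon, closed spline) live
in continuous 0-based grid coordinates on one slice; 3D primitives
(ball, cylinder) live in world mm. Closed splines are periodic
interpolating cubics densified to a polygon at quarter-voxel steps
before rasterisation.

The mesh tool fills slices between key ROIs by linear interpolation of
per-slice **signed distance fields** (negative inside), thresholded at
zero; key slices are overwritten with their exact rasters. Signed
distance was chosen because it interpolates shape, not intensity: two
circles of radius 4 and 12 eight slices apart yield a radius-8
cross-section halfway, and identical circles reproduce the analytic
cylinder voxel-for-voxel. The interpolation basis is a design choice of
this package; other shape-interpolation bases would differ between key
slices.

Seeded auto-contouring is plain region growing: the 26-connected
component of voxels at or above an absolute or fraction-of-seed
threshold. Dynamic-data segmentation is supported by letting the seed
grow on any frame or on the duration-weighted time-summed image rather
than by a bespoke 4D algorithm. VOI statistics use the sample (n-1)
standard deviation; users comparing against population-SD software
should scale by `sqrt((n-1)/n)`.

## Kinetic analysis

Tissue curves are unweighted in-mask voxel means per frame. Integrals
of sampled curves are trapezoidal with `(0, 0)` prepended — zero tracer
at injection — and linear interpolation to interior endpoints.

**Graphical methods.** Patlak: `y = Ct/Cp` against `x = int Cp / Cp`;
after the equilibration time `t*` the points are linear with slope `Ki`
(net influx, reported 1/min) and intercept the initial distribution
volume. Logan: `y = int Ct / Ct` against `x = int Cp / Ct`, slope `VT`
(mL/mL). Both are ordinary least squares over frames with mid-time at
or past `t*`; frames violating positivity preconditions are dropped
with a warning. `t*` is user-supplied — no automatic search is
attempted, since any such rule embeds a bias model; instead
`summary()` of a fit reports the maximum relative residual as a
curvature diagnostic for choosing a later `t*`. FUR is
`Ct(T) / int_0^T Cp` at the frame nearest `T`; on constructions with
zero Patlak intercept it equals the Patlak slope, which the tests
verify numerically.

**Compartment models.** The generic 1T/2T impulse response is the
standard mono/bi-exponential; tissue curves are computed by *analytic*
convolution of the linearly interpolated input with each exponential on
a fine grid (0.5 s default, <= 1 s), implemented as a first-order
recursive filter that is exact for piecewise-linear inputs — no ODE
solver, no step-size artifacts. The measured signal is
`(1-Vb) Ct + Vb Cb` with whole blood defaulting to the input, averaged
over each frame. An independent stiff ODE integration cross-checks the
2T output to 0.1% in the test suite.

Fitting is bounded Levenberg-Marquardt (`minpack.lm`) on weighted
residuals. Weights default to frame durations — the usual surrogate for
count-statistics precision when true variances are unknown — and can be
set uniform. A fixed multi-start grid (no randomness) guards against
local minima; bounds are K1 in [0,5] mL/mL/min, rate constants in
[0,5] /min, Vb in [0,0.5]. Standard errors come from the numerical
Jacobian at the optimum. Failure to converge from every start returns a
report flagged `converged = FALSE`, never an exception, so voxel-wise
and batch use cannot abort.

The radiowater perfusion model is the one-tissue special case
`Ct = F * PTF * exp(-(F/p) t) (x) Ca` with flow `F` and perfusable
tissue fraction `PTF` free and the partition coefficient fixed at 0.91
mL/g (configurable), the standard literature value for myocardial
radiowater.

Parametric maps apply Patlak/Logan/FUR per voxel in closed form
(vectorised OLS). Voxels outside the mask, all-zero voxels, and voxels
failing positivity preconditions become `NaN` rather than propagating
nonsense values.

## Rigid co-registration

A 6-DOF transform (rotations applied `Rz Ry Rx` about the fixed
volume's center, then translation; it maps moving-image world points
into the fixed frame) is scored by similarity metrics over the overlap
of the fixed grid with the transformed moving image, using trilinear
interpolation: MI, NMI, ECC from a 64-bin equal-width joint histogram
(entropies in bits, no kernel smoothing), and zero-normalised
cross-correlation. ECC is computed as `2 - 2/NMI`, algebraically equal
to `2 MI / (H(A)+H(B))`. Fewer than 100 overlap samples is an error;
the sample count is what makes the metrics comparable across grids of
different sizes and voxel dimensions.

Optimisation is derivative-free Nelder-Mead over a 3-level factor-2
multi-resolution pyramid (block-mean downsampling), started from
center alignment, with one simplex restart at full resolution —
restarting re-inflates the simplex and recovers the fraction of runs
where it shrinks prematurely. On large grids the metric subsamples the
fixed grid with a deterministic stride capped at 40k samples per
evaluation. Everything is deterministic given inputs and options; a
search that fails to improve on its start returns the start with a
warning flag. Frame-wise motion correction registers every frame to a
reference frame and passes near-empty frames (< 2% of the reference's
total activity) through unchanged, since noise-only frames carry no
signal to align on.

## Cardiac analysis

Axes are inputs — apex, base center, and a roll reference fixing the
sector-zero direction — mirroring the manual axis-definition step of
clinical workflows. Short-axis reorientation resamples onto an
isotropic grid with the long axis along +z, apex at low z, and apex at
the new origin.

Wall segmentation casts radial rays from the long axis (36 angles per
axial station, half-voxel radial steps), smooths each profile with a
1-voxel Gaussian, and takes the parabolic-refined argmax as the
mid-wall radius and the FWHM as the local thickness. Myocardium is the
shell within half a thickness of the ridge; the cavity is inside
`ridge - thickness`, deliberately conservative so the image-derived
input function avoids wall spill-in. Failure to find a ridge on more
than half the rays raises "LV not detected".

Polar maps project the wall onto a ring x sector grid (default 10 x 36,
apex innermost) under one of two surface models: a cylinder with a
hemispherical apex cap, or a truncated prolate spheroid. The ring
coordinate maps meridian arclength from the apex pole to the base rim
uniformly; each bin samples the image along the outward surface normal
across a +-5 mm window and reduces with `max` (default, the common
choice for perfusion PET) or `mean`. The prolate surface is a single
coordinate chart and therefore continuous across the apex/body
junction, where the two-chart cylinder+hemisphere model has a seam —
the uniform-phantom tests measure exactly this. The 17-segment summary
partitions ring fractions into apex / apical / mid / basal quarters and
the standard 4/6/6 angular wedges from the roll reference; sector zero
and counter-clockwise angles viewed from the apex are package
conventions, documented rather than inferred, since anatomical
RV-insertion alignment is a display concern.

## Phantoms: what they do and do not show

All tests run on seeded generators that are pure functions of their
arguments: synthetic bolus inputs (gamma-variate and Feng-style
tri-exponential, both with closed-form integrals), region phantoms
whose labelled regions follow exact compartment-model curves, LV shells
with programmable sector defects, and misaligned pairs with stored
truth transforms. Gaussian noise with variance proportional to
1/frame-duration stands in for count statistics; true Poisson-on-counts
noise needs calibration factors that are out of scope. Grids are kept
at or below 64^3 (2 mm voxels) so the full suite runs in minutes;
kinetic studies use a 34-frame one-hour schedule with 100 replicates in
the Monte-Carlo bias check.

Passing on these phantoms demonstrates the *mathematics* — recovery,
identities, invariances — under ideal geometry. It does not demonstrate
robustness to scanner resolution, partial-volume effects, scatter,
reconstruction artifacts, metabolite contamination of the input, or
patient motion beyond rigid shifts; none of these are modelled.

## Numerical choices and limitations

- Binary masks only: no partial-volume voxel weighting in TACs.
- Patlak/Logan drop non-positive frames rather than fitting through
  them; a zeroed frame still perturbs running integrals of later
  frames.
- Histogram bins are equal-width over each image's observed range;
  constant images get a degenerate single bin guarded by an epsilon.
- Transform composition/inversion is exact (closed form); Euler angles
  near gimbal lock fall back to a fixed convention.
- Reference-region (input-free) Logan variants, 3-tissue models,
  spectral analysis, SUV, metabolite and dispersion corrections, and
  deformable registration are out of scope.
- Project files serialise numbers at 17 significant digits, which
  round-trips IEEE doubles exactly; reloading a project restores every
  stored result bit-identically.
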