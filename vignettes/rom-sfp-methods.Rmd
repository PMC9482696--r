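---
title: "Quantifying joint range of motion with spherical frame projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying joint range of motion with spherical frame projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romsfp)
```

## The problem

A joint's rotational range of motion (RoM) is the set of relative
orientations the distal bone can take with respect to the proximal bone.
Reporting only the per-axis maxima misses the central phenomenon of
*interaction of degrees of freedom*: how far a salamander can flex its hip
depends on how abducted and how internally rotated the femur currently is.
`romsfp` implements a complete pipeline for this kind of analysis —
anatomical coordinate systems (ACSs) from bone landmarks, rigid pose
recovery from motion-capture markers, Z-Y-X Euler decomposition of relative
rotation, spherical frame projections (SFPs) of the pose space, per-axis RoM
tables with concomitant angles, and the comparison of in vivo stride data
against pooled ex vivo pose space — together with simulators of the ex vivo
sweep protocol and the in vivo stride, so that every stage runs and is
tested on synthetic joints with known ground truth.

## Conventions

All limb ACSs are right-handed triads with **Z = flexion/extension (FE)**,
**Y = abduction/adduction (ABAD)**, **X = long-axis rotation (LAR)**; Z is
assigned to the axis with the most expected motion so that the Z-Y-X
(FE-first) Euler order keeps gimbal lock away from the data. Joint pose is
the orientation of the distal ACS expressed in the proximal ACS,
`t(R_prox) %*% R_dist`; the *null pose* is the configuration with both
frames aligned. Euler angles are always degrees, with
`abad_y` in [-90, 90] and the other two in (-180, 180]. At gimbal lock
(`|abad_y| = 90` within `1e-8` on `cos(abad)`) FE and LAR act about the same
world axis; only their combination is observable, and the convention here
sets `lar_x = 0`, folding the residual into `fe_z`. Those frames are
retained and counted in a warning rather than dropped.

Left-side joints are transformed to the right-side convention by
conjugating each pose with the reflection `diag(1, -1, 1)` across the
proximal X-Z plane — the unique orientation-consistent choice once the
mirror plane (perpendicular to the mediolateral Y axis) is fixed. In Euler
terms `(fe, abad, lar) -> (-fe, abad, -lar)`; the operation is an involution
and preserves geodesic distances between poses.

## ACS construction

Perimeter landmarks on the articular ends of a long bone define a
preliminary long axis (proximal mean to distal mean) and a preliminary FE
axis (total-least-squares line through one perimeter). Bone morphology
makes these not exactly perpendicular, so one axis is retained and the
other recomputed from the cross products: the proximal femur and the
tibia/fibula keep the long axis (X), the distal femur keeps the FE line
(Z). The cross-product order is chosen so the triad satisfies
`x_axis x y_axis = z_axis`; axis signs are then anchored by named reference
points — a ventral-surface point constrains Z, a flexor-surface point
constrains Y, and in the `keep_fe_axis` mode X is first pinned along the
anatomical long axis so the retained Z sign cannot drift under landmark
noise. Without any reference point the line-fit sign falls back to a
lexicographic rule and the result is flagged.

The pelvis is built from geometric primitives: least-squares spheres on the
two acetabula (algebraic fit, then Gauss-Newton refinement of radial
residuals), whose centroids give the mediolateral Y axis and, midway, the
origin; and a least-squares cylinder on the sacral vertebral body (PCA
initialisation, then joint refinement of axis and radius) whose axis gives
the anteroposterior direction. Because the sacral vertebra can sit with
both pitch and yaw relative to the pelvis, only its pitch defines the
pelvis X: when a vertical reference is supplied the axis is rebuilt in the
midline sagittal plane with its elevation preserved exactly; otherwise it
is orthogonally projected onto the plane perpendicular to Y (which perturbs
the pitch by under a degree for yaws up to ~20 degrees). Each acetabular
ACS re-labels the pelvis axes so hip X (LAR) points laterally out of the
acetabulum, hip Z (FE) stays dorsoventral and hip Y completes the
right-handed triad; this re-labeling is a documented convention of this
package — the anatomically motivated choice that makes the null pose a
laterally extended femur with femoral axes matching the acetabular ones.

Construction is covariant: rigidly moving all landmarks moves every output
ACS by the same transform (to 1e-9). Orthogonality, unit norm and
handedness residuals are checked at 1e-9 after construction.

## Marker processing

Rigid pose recovery from the 7-marker tree uses the closed-form SVD
(Kabsch) solution with determinant correction so a reflection is never
returned; frames with fewer than three visible markers are dropped and
reported, never interpolated. Transform chains
(world-from-markers, markers-from-plate, plate-from-bone) compose
associatively and match the 4x4 homogeneous product. Trial quality follows
two rules: a *pose-jump screen* flags any frame whose geodesic rotation
step from the previous frame exceeds a threshold (default 15 degrees at
30 Hz — real damage screening criteria are partly qualitative, so the
number is this package's choice and is configurable), and the
*sufficiency rule* marks a specimen usable only when all three planar
trials are present and clean and at least two interaction-of-DoF trials
survive the screen.

## Spherical frame projections and regions

The SFP traces the tips of the distal ACS's unit axes on a sphere fixed in
the proximal ACS — the three columns of each relative rotation matrix
(blue = FE/z, green = ABAD/y, red = LAR/x). Distances on the sphere
approximate true pose differences without the distortion of Euler-angle
plots, and a pure FE rotation leaves the FE tip exactly fixed.

Pose-space regions are built per axis in a gnomonic chart about the tips'
spherical centroid (great circles map to straight lines, so a spherical
convex hull is the planar hull in the chart). Tips must fit inside an open
hemisphere; wider data should be split. Two boundary methods are provided
because the published polygons could be either: the default convex hull,
and an `alpha_shape` that hugs non-convex clouds — implemented as the
boundary of the union of spherical caps of radius `alpha_deg`
(default 15 degrees) around the tips, extracted by contouring the
nearest-tip distance field on a grid sized by the tips' angular extent.
The alpha method assumes a connected cloud (the longest closed contour is
kept) and thins dense clouds to ~`alpha/5` resolution first, which leaves
the union of caps unchanged at the contour scale. Membership testing uses
the region's own chart (half-plane tests for hulls, crossing number with an
on-edge tolerance otherwise); boundary points count as inside. The test
suite checks membership against an independent spherical winding-number
oracle on 10^4 random queries.

## RoM tables

`rom_summary()` reports, per axis, the unrounded extrema, their range, and
the rotations about the other two axes at the extremal frames (ties broken
by earliest frame). The presentation view rounds every cell to the nearest
degree *half away from zero* (base `round()` is round-half-even and does
not reproduce the published integer tables), and rounds the range computed
from unrounded extrema — which is why a printed range can differ by one
degree from rounded-max minus rounded-min, exactly as in a handful of the
published cells. The package ships those published extremal poses
(`salamander_rom_reference()`) as the worked example for this arithmetic.

## The synthetic joint model

The original experiments measure real joints; this package's generators
stand in for them with the simplest smooth model exhibiting interaction of
degrees of freedom: a **coupled ellipsoid in Euler space**,
feasible set `{e : ||C (e - c) / s|| <= 1}` with center `c`, semi-axes `s`
and a well-conditioned coupling matrix `C`. Passive torque is zero inside
and rises linearly with the Euler-space distance beyond the boundary along
the ray from the center (default stiffness 2 N mm/deg, threshold
tau = 10 N mm; rig values are unpublished, so these are package defaults,
stated once and not revisited).

The ex vivo simulator reproduces the hierarchical sweep protocol: for a
sequence such as FAL, the FE axis is swept in both directions until the
passive torque at the next step would reach tau, then ABAD is incremented
and the sweep repeats, then LAR, until the limits about LAR are reached.
Because the rule stops strictly *before* the threshold, a zero threshold
emits only the center pose, and the emitted boundary sits up to
`tau/stiffness` degrees beyond the zero-torque surface — so the generator's
documented ground truth is the *torque-limited* boundary. Two details
emulate the experimenters' live-feedback practice of following the pose
space rather than returning to a fixed null: each sweep line starts from
its torque-minimising pose, and each new line is entered from whichever end
is nearer the previous pose. The emitted poses therefore tile the whole
torque-admissible grid, per-axis extrema match a brute-force grid oracle
within one step, and consecutive-frame steps stay below the
`~sqrt(2 * extent * step)` bound set by sweep-line collapse at the region
edge. The closed-form `model_axis_extents()` adds `tau/stiffness` exactly
along axis-aligned support directions and is an upper bound for coupled
models; the grid oracle is the exact reference there.

Strides are per-axis sinusoids over one periodic cycle (401 frames,
matching a rotoscoped stride; 500 Hz video rate), optionally jittered under
a fixed seed, and validated against a containment margin (default 10%)
inside a joint-limit model. `contained_stride_spec()` guarantees
containment for any phases by capping each amplitude at `frac` of the
axis-aligned feasible extent (`3 * frac <= 1 - margin`).

The presets put the pieces together: the hip and knee joint-limit presets
take their centers and semi-axes from the pooled published per-axis
extremes (so the hip's feasible set lies entirely internally rotated and
*excludes the null pose*, as observed in the real joints), and the stride
presets reproduce the in vivo per-axis ranges (hip FE 117, ABAD 40,
LAR 97; knee FE 114, ABAD 37, LAR 31 degrees). What the sinusoidal stride
does *not* emulate is the timing structure of real walking — dwell near
extremes, stance/swing asymmetry — so passing tests say the pipeline's
geometry and bookkeeping are right, not that real salamander kinematics are
sinusoidal. Likewise the ellipsoid model cannot represent non-convex or
multi-lobed real pose spaces; the alpha-shape regions exist precisely
because real polygons may hug such shapes.

## Numerical choices

* Rotation validity: orthonormality and determinant residuals at 1e-9
  (construction) and 1e-6 (file input).
* Gimbal tolerance `|cos(abad)| < 1e-8`; lock convention `lar_x = 0`.
* Sphere/cylinder fit degeneracy: coplanarity or collapse detected via
  singular-value ratios (~1e-8 relative); fits refined to `reltol 1e-14`.
* Euler ties at -180 map to +180.
* Extremal-frame ties: earliest frame wins.
* Region membership tolerance 1e-9 in chart units (closed boundary).
* Problem sizes used in the shipped analyses: sweep steps of 2-6 degrees
  per axis (10^4-10^5 frames per six-sequence protocol), 401-frame strides,
  10^5-triple Euler round-trip checks, 10^4-query membership oracles.
  These sizes were chosen so each analysis stage has comfortably more
  samples than the geometry needs.

## Repository shape

The package's computation lives in `R/` and is exercised three ways: the
testthat suite, the numbered narrative drivers under `analysis/`
(`01_landmarks_acs.R` ... `05_sfp_compare.R`, each writing its tables under
`results/`), and `scripts/acceptance.R`, which recomputes the headline
quantities from scratch. The drivers plus the exported functions are the
intended user surface; there is no separate shell CLI.

## Known limitations

* The acetabular-from-pelvis re-labeling and the mirroring plane are
  documented conventions; other labs' conventions may differ by fixed
  rotations, which shift Euler values but not ranges.
* The alpha-shape boundary is raster-derived (161^2 grid): vertex
  placement is accurate to the grid cell, and disconnected clouds must be
  split by the caller.
* Translational RoM is out of scope throughout; pose sequences carry
  rotations only.
* `model_axis_extents(torque_limited = TRUE)` is exact only for
  axis-aligned models (see above).
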