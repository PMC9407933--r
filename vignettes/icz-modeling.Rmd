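---
title: "Modeling and matching individual convenient zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and matching individual convenient zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iczone)
```

## The model

The individual convenient zone (ICZ) of a person is the space their upper
limb can reach from a fixed standing position, annotated at every point with
the maximum force the person can exert **upward** at that point.  The zone is
heterogeneous — the farther the hand is from the body, the lower the liftable
force — and it differs strongly between individuals, especially for seniors
and people with motor impairments whose capabilities population-average
anthropometric atlases do not describe.  `iczone` represents the zone in a
body-centered cylindrical frame:

* `alpha` — horizontal angle about the vertical body axis, in degrees;
  0 is the sagittal plane (straight ahead), positive angles turn toward the
  measured limb's side;
* `z` — height above the floor, in cm;
* `r` — radial distance from the body axis, in cm.

Only the upward lifting force is modeled.  Multi-directional force fields,
joint torques and muscle physiology are out of scope: the model is purely
phenomenological, an interpolation of what was measured.

Laboratory measurement of a full zone is expensive (on the order of a
hundred supervised force exertions), so the package implements a three-part
workflow: (1) fully measured subjects are stored in a **repository**;
(2) a new user is measured with just **five quick values**, and the most
similar repository subject is retrieved; (3) that subject's complete zone
then stands in for the user's in **ergonomic layout assessment**.

## Strength-field interpolation

`build_strength_field()` turns a force point cloud into a field on a regular
`(alpha, z, r)` lattice.  The scheme is deliberately simple and fully
reproducible:

1. **Per-ray monotone correction.**  Measurements are grouped into rays
   (fixed `alpha`, `z`; at least three distinct radii each — fewer raises a
   coverage error naming the deficient ray).  Duplicate radii are averaged,
   then the ray's forces are projected onto the monotone non-increasing cone
   by least-squares isotonic regression (`stats::isoreg` on negated values,
   equivalent to pool-adjacent-violators).  This encodes the one physical
   prior the model commits to: liftable force cannot increase with distance
   from the body.  The correction is idempotent and leaves already-monotone
   rays untouched.
2. **Radial interpolation.**  Corrected knots are interpolated linearly in
   `r`.  Toward the body axis (below the innermost measured radius) the
   innermost segment is continued linearly — because the knots are
   non-increasing this can only raise the value, which matches the physical
   expectation that strength grows closer to the body.  Beyond the outermost
   knot the value is held constant and then masked to zero past the reach
   boundary.
3. **Transverse interpolation.**  When the measured rays form a complete
   `alpha x z` grid, the field and the reach boundary are interpolated
   bilinearly between rays; otherwise each lattice node takes its nearest
   ray (distance scaled by the lattice steps).  Convex combinations of
   non-increasing radial profiles are non-increasing, so monotonicity holds
   on every lattice column by construction.

The default lattice is 5 degrees x 5 cm x 1 cm (`grid_spec()`): finer than a
realistic laboratory sampling of ~100 points, coarse enough that a full
field builds in well under a second.  The reach boundary defaults to the
largest measured radius per ray, since quick protocols rarely measure reach
separately from the outermost force point.

Two consequences of these choices are worth knowing.  Piecewise-linear
interpolation is exact for affine force profiles, so closed-form test cases
are reproduced to rounding error.  And the field at a sample location equals
the measured value *up to the monotonicity correction* — a deliberately
visible adjustment, never a silent smoothing.

## Constant-strength layers and force rescaling

`extract_constant_strength_layer(field, L)` finds, per lattice ray, the
largest radius at which the piecewise-linear field still reaches `L` newtons
(0 where it never does), capped at the reach boundary.  Layers nest: for
`L1 < L2` the stronger layer lies inside the weaker one on every ray.  A
level above the field's global maximum yields an *empty* layer with an
explicit flag rather than an error, so sweeping level lists is safe.

Laboratory limit forces `F` are reduced to allowable working forces
`F_d = k * F` (`rescale_forces()`, `k` in (0, 1]) to account for convenience,
load duration and holding time.  The package exposes `k` as a single
user-supplied scalar (default 1) rather than deriving it: correction-factor
models are a separate literature, and a scalar keeps the central guarantee
simple — rescaling is proportional, so the layer of the rescaled field at
`k * L` is geometrically identical to the layer of the original field at
`L`.  Numerically, that identity is bit-for-bit when `k` is a dyadic
fraction (0.5, 0.25, ...), because scaling by a power of two is exact in
IEEE-754 arithmetic; for arbitrary `k` it holds to about 1e-9 relative
accuracy, which is how the property is asserted in the test suite.

Layers export to ASCII OBJ or STL meshes (`export_layers()`, units cm,
z up, sagittal direction mapped to +y) for use in CAD alongside a digital
human model.

## The five-feature simplified model

A prospective user is characterized by five quickly measurable values
(`extract_simplified_features()` computes the same five from a full model,
which is how repository rows are produced):

| feature | definition | units |
|---|---|---|
| `D1` | anterior reach at shoulder height, sagittal plane | cm |
| `F1` | strength at full reach `D1`, shoulder height, `alpha = 0` | N |
| `F2` | strength at full reach, shoulder height, `alpha = 60` | N |
| `F3` | strength at mid-reach `D1/2`, shoulder height, `alpha = 0` | N |
| `F4` | strength at full reach, elbow height, `alpha = 0` | N |

Whether `D1` is measured to the handgrip axis or the fingertips is a
protocol convention that differs between measuring rigs; it is stored as a
flag on the model (`d1_convention`) and not otherwise interpreted.

## Normalization and similarity

Features are made commensurable by min-max normalization against the
repository's own per-feature bounds:

`a_i = (A_i - A_i_min) / (A_i_max - A_i_min)`

Bounds are computed **over repository rows only** — the query user is never
pooled in, so a query cannot shift the scale it is judged on, and the
worksheet shipped with the package reproduces exactly under this convention.
Two degenerate cases are defined explicitly: user values outside the
repository bounds are clamped to [0, 1] with a warning, and a feature with
zero spread normalizes to 0 for all inputs, again with a warning.  (The
min-max form is sometimes loosely called a zero standard score in the
ergonomics literature; what is implemented, and what all reference numbers
require, is min-max.)

Dissimilarity between a repository entry `b` and the user `u` is the
weighted mean absolute difference of normalized features,

`sim(x) = sum_i w_i * |a_ib - a_iu|`,

with equal weights `w_i = 1/5` by default (all five features are treated as
equally informative; the weight vector is exposed for sensitivity
analyses).  `sim` is a pseudometric: 0 means entirely similar, 1 entirely
different.  `match_features()` ranks all entries ascending and returns the
first; ties are broken by table order, which makes results deterministic
and permutation checks exact up to that documented rule.  An optional
acceptance threshold flags — without hiding — a best match whose score is
still too dissimilar to use.

All arithmetic is done at full precision; 3-decimal values appear only in
display fields and reports.  The matcher accepts either raw newton/cm
measurements (normalized internally) or an already-normalized vector.  The
dual path matters for the bundled worksheet, which contains a genuine
internal inconsistency: the user's raw `F4` is 110 N while the recorded
normalized `f4 = 0.739` corresponds to 118 N under the worksheet's own
bounds (30, 149).  The package takes no position on which number was
intended — the reference scores pin the normalized row (entry 7 total
0.085), the raw path is also supported (entry 7 total 0.095), and entry 7 is
the best match either way.

## Ergonomic layout assessment

`assess_layout()` checks task points (shelf positions, appliance handles,
each with a required lifting force) against a field: a point is `OK` when it
is inside the reach boundary and the allowable force `k * F` at the point
covers the requirement, `FORCE_INADEQUATE` when reachable but too weak, and
`OUT_OF_REACH` otherwise — with a distinct note when the point lies outside
the modeled angular/height region entirely, which is a modeling-coverage
statement rather than a biomechanical one.  Available force is reported as
0 for unreachable points.  Verdicts are consistent with layers by
construction: a point requiring `L` newtons is `OK` exactly when it lies
inside the `F_d = L` layer.

Task points are specified in the body frame; `body_frame_points()` converts
room-plan Cartesian coordinates given the body position and facing angle,
reflecting the core use case of a person working from one standing spot.

## The synthetic generator

Real laboratory point clouds are scarce, so `generate_icz()` produces them
from a separable phenomenological surface:

`F(alpha, z, r) = peak * (1 - falloff * |alpha| / 60) * h(z) * max(0, 1 - r / R_d)^p`

with `h(z)` linear between `elbow_ratio` at elbow height and 1 at shoulder
height, optional Gaussian measurement noise (truncated at 0 N), and a fixed
seed recorded in the generated file.  The default sampling — 5 angles x 4
heights x 5 radii = 100 points — mirrors the scale of a realistic protocol.

The radial decay scale `R_d` (`decay_radius_cm`) defaults to the reach
radius, making force vanish exactly at full reach.  Real subjects, however,
retain substantial strength at full reach (the repository rows have
full-reach strengths of 27-105 N), so `R_d` may be set beyond the reach to
leave a positive residual there.  `synthetic_spec_from_features()` exploits
this: given five target features with `F3 > F1` it solves `R_d`, the peak,
the angular falloff (`1 - F2/F1`) and the elbow ratio (`F4/F1`) in closed
form so that the noiseless generated model reproduces the targets exactly —
the round-trip that anchors the extraction tests.

What the generator does *not* emulate is worth stating: real zones are not
separable in angle, height and radius; strength surfaces have posture- and
joint-specific asymmetries; noise is not homoscedastic Gaussian; and reach
varies per ray.  Passing round-trip tests therefore demonstrates that the
interpolation and extraction machinery is self-consistent, not that the
five features suffice to reconstruct an arbitrary real zone — the whole
point of the repository approach is that they do not, and that a full
measured model must stand in for the user.

## Numerical choices, problem sizes, limitations

* Geometric comparisons use absolute tolerances of 1e-9 cm; reach
  containment uses 1e-6 cm; boundary-membership checks in the test suite
  skip points within 1e-6 cm of a layer boundary, where the verdict is
  legitimately tie-dependent.
* The dense-scan oracle for layer boundaries uses a 0.01 cm grid; matcher
  properties are checked against an exhaustive argmin over 100 random
  repositories of 25 entries; monotone correction is checked against a
  hand-written pool-adjacent-violators implementation on random rays of
  length 3-40.  These sizes make the full suite run in seconds while
  leaving no code path untested at scale.
* Ray grouping uses exact `(alpha, z)` equality; measurement protocols that
  jitter ray coordinates should round them before model construction.
* Nearest-ray fallback (incomplete ray grids) produces piecewise-constant
  transverse behavior; prefer complete grids when designing protocols.
* Left/right limbs are a stored flag, not a mirror transform; a model
  measured on one limb should be matched against repositories of the same
  limb.
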