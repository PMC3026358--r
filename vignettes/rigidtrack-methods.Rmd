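---
title: "rigidtrack: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rigidtrack: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidtrack)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not show
about real capture data.

## The setting

A mixed-reality surgical simulator tracks physical mock-ups (e.g. plastic
vertebra models fixed in an ellipsoid mold) and real instruments with an
optical motion-capture system, and renders their virtual counterparts
aligned in the same scene. Three computations make that possible offline:
registering virtual models to tracked bodies, conditioning the captured
pose streams, and knowing — from a finite-element model — how much force
an instrument may apply before it would injure tissue, so the simulator
can warn the trainee.

## Rotation representations

Capture systems deliver rotations as **exponential maps**: a 3-vector
whose direction is the rotation axis and whose magnitude is the angle in
radians. For composition, interpolation and rendering these are converted
to unit quaternions.

Conventions (fixed once, used everywhere): scalar-first quaternions
`(w, x, y, z)`; canonical sign `w >= 0`; right-handed frames; canonical
exponential maps with magnitude in `[0, pi]`. The conversion uses the
closed form `q = (cos(theta/2), sin(theta/2) * axis)`; below `1e-8` rad a
second-order series for `sin(theta/2)/theta` avoids dividing by a
vanishing angle. Whether a capture system emits radians or degrees is a
dialect question; the capture CSV header records `rotation=expmap_rad`
and radians are assumed throughout (the standard for exponential maps).

A numerical point that matters for verification: the geodesic angle
between two nearly equal rotations cannot be computed reliably as
`2*acos(|<q1, q2>|)` — the `acos` of a dot product near 1 loses half the
available precision (about `2e-8` rad). `quat_angle()` therefore uses the
chord identity `|q1 - q2| = 2 sin(theta/4)` and `asin`, which is exact
and well conditioned at zero; round-trip errors measure at `~1e-13` rad.

## Registration

**Reverse direction** (captured markers onto the virtual surface): given
corresponded pairs — virtual surface points `p_i` and captured marker
positions `q_i` — the rigid transform minimizing
`sum_i ||R p_i + t - q_i||^2` is found by centering both sets, taking the
SVD of the 3x3 cross-covariance, and correcting a reflection by flipping
the singular direction with the smallest singular value so `det(R) = +1`
(the standard Kabsch construction). Tests cross-check every fit against
an independently implemented Horn quaternion-eigenvector solution.

Degeneracy: a unique rotation exists exactly when the centered source
configuration has rank at least 2. The implemented test is
`s2 < 1e-9 * s1` on the singular values of the centered source matrix —
i.e. *collinear* sets are rejected. (Testing the smallest singular value
`s3` instead would reject every 3-point set, since three points are
always coplanar; coplanarity is harmless because the `det(R) = +1`
constraint resolves the remaining ambiguity.) Fewer than three pairs is
likewise underdetermined — the three-marker minimum familiar from rigid
tracking practice.

Choices made where the design was open: unweighted least squares (no
per-marker confidence is available from the file formats we read); no
scale estimation (unit conversion is a separate, exact step in the motion
pipeline); per-pair residuals are always reported, because the dominant
practical failure is one wrong manual association, which the largest
residual pinpoints for re-registration.

**Forward direction** (virtual markers first): feature points are picked
on the virtual surface, snapped to the nearest point of the triangle mesh
(exact point–triangle projection, searched over all faces), and written
out as a tracking model whose coordinates are relative to the root
segment at the origin. The snap tolerance defaults to 1% of the mesh
bounding-box diagonal — an interactive-picking detail with no external
ground truth; picks farther away are rejected rather than silently moved.
A proximity warning fires when two markers are closer than a configurable
minimum separation, since crowded markers degrade tracking accuracy.

## The tracking-model (VSK) dialect

The capture system needs an XML subject file before it can track a rigid
body. The dialect written here contains exactly the elements such files
are built from: a `Parameters` block naming every marker coordinate, one
root `Segment` declared as a free joint with six degrees of freedom, a
`MarkerSet` joining every marker to the root, and a `Radius` element
(default 0.5, the small retro-reflective spheres used on instruments),
plus `VERSION` and `UNITS="mm"` attributes. Numbers are serialized with a
fixed 6-decimal format and LF endings, so write–read–write is
byte-identical and golden-file tests are meaningful.

Reading is lenient, writing strict: unknown elements (e.g. a
`Covariance` tag from a real export — a tracker-internal likelihood
parameter we record but do not interpret) are preserved by name; a
missing `Radius` falls back to 0.5 with a warning. Articulated
multi-segment chains are out of scope: models here are single rigid
bodies, which is also why marker coordinates are always root-relative and
independent of where the mesh happens to sit in world coordinates.

## The motion pipeline

Streams are replayed offline from CSV (`frame, time_s, object, tx_mm,
ty_mm, tz_mm, rx, ry, rz, visible_markers`; occluded poses are empty
fields). The nominal 200 Hz capture / ~30 Hz render rates of a live rig
are metadata here — nothing in the offline pipeline depends on wall
time.

**Conversion.** Translations arrive in millimetres and are scaled by 0.1
to centimetre scene units (exact, invertible); rotations are converted to
unit quaternions as above.

**Low-pass filter.** Residual rig vibration leaks into captured poses as
frame-rate jitter. The simplest causal smoother is the single pole
`y[t] = alpha x[t] + (1-alpha) y[t-1]`, with magnitude response
`|H(w)| = alpha / sqrt(1 + (1-alpha)^2 - 2 (1-alpha) cos w)`: DC gain
exactly 1 (a stationary object never drifts), Nyquist gain
`alpha/(2-alpha)`, and `alpha = 1` the identity. Rotations are smoothed
by slerping from the previous filtered orientation toward the current
measurement with fraction `alpha` — filtering exponential-map components
independently is not rotation-consistent. The price of smoothing is
latency: the group delay is about `(1-alpha)/alpha` frames, which at
200 Hz is a few milliseconds for moderate `alpha` — visible as a slight
motion lag, not as misalignment.

*Study conditions for the noise-reduction claim.* The filter helps
exactly when per-frame jitter exceeds the per-frame signal change times
the filter lag. The tests therefore emulate fine manipulation: a smooth
rigid path with 5 mm amplitude (peak speed ~16 mm/s, i.e. ~0.08 mm per
frame at 200 Hz) with iid Gaussian jitter of sigma in {0.1, 0.5, 1.0} mm
added to the streamed pose translations, and noise-matched smoothing
(`alpha` = 0.7, 0.4, 0.3 respectively — heavier noise affords heavier
smoothing). Under these conditions the filtered translation RMSE is
strictly below the raw RMSE at every sigma, by roughly a factor of two at
sigma = 0.5. The converse is worth stating: for a fast-moving, many-marker
body whose pose noise is already averaged down to tens of microns, no
causal one-pole setting beats the raw stream — the lag bias dominates.
The filter is for vibration, not a free accuracy upgrade.

**Occlusion gaps.** Interior gaps of at most `max_gap` frames (default 3,
i.e. 15 ms at 200 Hz) are filled by linear interpolation of translation
and slerp of rotation between the flanking observed poses; longer gaps
and gaps touching the stream boundary are reported, never extrapolated.
Originally observed frames are never altered, which makes the operation
idempotent.

**Orientation flips.** A body reconstructed from too few visible markers
can come back upside down for a frame. Frames whose geodesic rotation
distance to the previous observed frame exceeds a threshold (default
pi/2) are flagged; at 200 Hz no plausible hand motion rotates 90 degrees
in 5 ms, so false positives require extreme motion.

**Force monitor.** One warning event per contiguous excursion of the
applied force above the critical threshold, stamped at the first
exceeding sample, with a strictly-greater comparison (a sample exactly at
threshold does not warn). The default threshold is 20 N — the critical
rasping force above which the vertebral endplate and spinal cord are at
risk; exceeding it in a session is exactly what the trainee must learn to
avoid. One event per excursion (rather than per sample) keeps a sustained
press from flooding the log; the event carries the timestamp, force and
threshold so downstream tooling can count or re-bin as it likes.

## Static FEM and the critical force

The solver is deliberately the simplest family that supports the
critical-force computation: 4-node constant-strain tetrahedra, isotropic
linear elasticity, static equilibrium `K u = f`.

* Element stiffness `Ke = V * B' D B` with the constant
  strain-displacement matrix from the shape-function gradients; element
  orientation is fixed at construction (negative signed volume swaps two
  nodes) and near-zero volumes are a mesh-quality error.
* Dirichlet conditions are per-DOF `(node, dof, value)` triples imposed
  by row/column elimination — exact and well conditioned, unlike penalty
  methods. Per-DOF constraints matter for verification: roller supports
  (normal DOF only) make the axial-bar benchmark's uniaxial state exactly
  representable, so the computed tip displacement `F L / (E A)` and
  uniform stress `F / A` are reproduced to machine precision, while
  clamping all three DOFs (also supported) introduces the Poisson
  constraint that mesh refinement then converges through.
* Surface loads are entered as consistent nodal forces
  (`face_traction_loads()`: one third of `area * traction` per triangle
  node).
* A factorization that "succeeds" on a semi-definite system is caught by
  a residual check; insufficient constraints raise an error naming the
  null-space dimension (6 for a free-free body).
* Verification follows standard practice: the patch test (prescribed
  uniform strain on all boundary nodes of a 2x2x2-element block — one
  interior node — must reproduce the analytic uniform stress to 1e-8
  relative; a single-layer block would have no interior node and the test
  would be vacuous), global equilibrium of reactions against applied
  loads, exactly six near-zero eigenvalues of the free-free stiffness,
  and monotone convergence of the clamped bar under refinement.

**Critical force.** The failure criterion is a user-supplied yield value
for the maximum von Mises stress,
`sqrt(0.5[(s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2] + 3(s12^2 + s23^2 + s13^2))`.
There is deliberately no default yield: the stress at which a real
vertebral endplate is harmed is a biological quantity this package cannot
supply, and the bundled bone-like elastic constants (E = 12000 MPa,
nu = 0.3 in the block generator) are placeholders for exercising the
solver, not literature values. Because the problem is linear, stress
scales exactly with load magnitude, so one unit-load solve gives
`F_crit = yield / max_vm_per_unit_load`; a bisection that re-solves at
each trial magnitude is kept as the fallback for future nonlinear
extensions and must agree with the closed form within the force tolerance
(it does, to the bisection's own resolution). The highest-stressed region
is reported as the elements at or above the `(1 - fraction)` stress
quantile — the red zone of a stress plot; with the `>=` convention a
uniform field returns every element, and `fraction = 1` always does.

Scope: static linear elasticity only. Contact, large deformation and
impact are out of scope, and desk-scale block geometry cannot reproduce
any particular anatomical result — patient geometry and calibrated
material data are simply not available. What the FEM module does claim,
and tests, is correctness of the discretization and of the critical-force
procedure on problems with exact solutions.

## Synthetic fixtures — what they do and do not show

All generators are pure functions of their parameters and an explicit
seed.

* `gen_marker_cloud(n, min_separation, seed)` rejection-samples marker
  positions in a 100 mm cube with a minimum pairwise separation
  (default 10 mm) and **enforced asymmetry**: any candidate set mapped
  onto itself by a non-trivial rotation or reflection (found by a
  distance-matrix automorphism search, each candidate permutation checked
  with a Procrustes fit) is rejected. Asymmetric placement is what lets a
  tracker distinguish a body from its mirror image — a square of markers
  would have indistinguishable flipped poses.
* `gen_rigid_trajectory(spec, markers)` emulates what the tracker
  delivers: ground-truth poses along a smooth incommensurate-sinusoid
  path (default 30 mm amplitude, 1 rad/s, 200 Hz), marker world positions
  with iid isotropic Gaussian noise (default 0.1 mm, sub-millimetre
  optical accuracy), the streamed pose re-estimated from those noisy
  markers by the same least-squares fit a tracker uses, and Bernoulli
  frame dropout for occlusion. Ground truth is returned for recovery
  tests.
* `gen_block_tetmesh` (Kuhn 6-tet subdivision, conforming, closed-form
  node/element counts) and `gen_ellipsoid_mesh` (subdivided icosphere,
  vertices exactly on the ellipsoid) supply solid and surface geometry.

What passing these tests shows: the algebra, estimators, filters and
solver are correct on data matching their assumptions. What they do not
show: robustness to what real optical capture adds — correlated and
marker-dependent noise, partial marker visibility (here dropout is
all-or-nothing per frame), mislabeled markers, camera calibration drift,
and soft or flexing bodies. The pipeline's diagnostics (residual reports,
flip detection, unresolved-gap lists) are the intended handles on those
conditions, but no synthetic pass certifies them.

## Problem sizes and determinism

The test and acceptance workloads are sized for a laptop-class single
CPU: 1000-transform registration sweeps, 300–400-frame streams, FEM
blocks up to 6x2x2 elements (63 nodes) with dense eigenvalue checks only
on the 24-DOF free-free cube; the full suite runs in well under a minute
and the acceptance script in seconds. Every random quantity is seeded;
the pipeline writes fixed-format text, so identical configurations
produce byte-identical outputs.

## Known limitations

* Registration assumes correspondences are given; there is no automatic
  matching (no ICP) and no outlier rejection beyond the residual report.
* The VSK dialect is a documented reconstruction of the format family,
  not a bit-compatible clone of any vendor's schema; lenient reading is
  the interoperability mechanism.
* One filter pole means the smoothing/latency trade-off is global; there
  is no per-axis or adaptive tuning.
* Tet4 elements are stiff in bending; the FEM module is a verification-
  grade solver for critical-force procedures, not a clinical analysis
  tool.
* The offline pipeline replays files; live acquisition, rendering and
  haptics are out of scope.
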