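---
title: "Model-based kinematic reinforcement of skeleton-tracker streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based kinematic reinforcement of skeleton-tracker streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfilt)
```

## The problem

Consumer RGB-D skeleton trackers (OpenNI/NITE-style middleware over a
PrimeSense/Kinect depth sensor) emit, at ~30 fps, a 3D centroid per body
part together with a confidence value in {0, 0.5, 1}. The stream is cheap
and markerless, but nothing guarantees that the centroids form a valid
human pose: limb lengths fluctuate with noise and held objects, elbows can
bend the wrong way, occluded hands inherit the depth of whatever occludes
them, and self-intersecting poses are never rejected.

`kinfilt` reinforces such a stream with an articulated upper-body model.
Every emitted pose satisfies, by construction, three families of
constraints: segment lengths, joint-angle limits, and absence of
self-collision. In parallel, the model's limb lengths are learned online
from the same stream so the constraints fit the performer rather than a
population average.

## The model

Eight joints are tracked: torso (root), head, both shoulders, elbows and
hands. The torso frame is the coordinate system of all processing:
right-handed, millimetres, origin at the torso centroid, +x toward the
performer's left, +y up, +z toward the camera. Head and shoulders are
fixed offsets from the torso; each arm contributes four rotational
degrees of freedom (three at the shoulder — frontal abduction, sagittal
rotation, axial/swivel rotation — plus elbow flexion). In the zero-angle
reference pose the arms hang along the body.

Dimensions derive from the stature *H* through an editable table of body
segment fractions (the classical Drillis–Contini proportions for the
limbs: upper arm 0.186 *H*, forearm 0.146 *H*; frame offsets and collision
radii are package defaults chosen so that the reference pose is collision
free). *H* itself can be estimated from the tracked face centroid through
the anthropometric relation *H* = *H~e~*/0.936, where *H~e~* is the
floor-to-eye distance:

```{r}
estimate_stature(936)        # a 936 mm eye height implies a 1 m performer
m <- build_default_model(1750)
m
```

Joint-angle limits ship as a default range-of-motion table (e.g. elbow
flexion 0–145°, no hyperextension), also plain configuration. All of
model serialization (`model_to_config()`, `write_model_config()`) is
human-readable YAML so a calibrated model can be reused across sessions.

## Per-frame filtering

Each frame passes through three stages.

**Confidence gating.** Centroids with confidence below 0.5 are replaced:
hands (end effectors) by their previous *observation*, elbows
(intermediate joints) by the model's previous position. The asymmetry is
deliberate — the hand observation is the driving measurement and holding
it preserves the last real evidence, while the elbow is a derived
quantity that the model knows better than the tracker. A flag
(`ee_gate_source = "model"`) switches the end effectors to model holds
too.

**Constrained pose estimation.** For each arm, the (gated) hand centroid
is clamped into the reachable annulus around the shoulder — between
|l~upper~ − l~fore~| + 1 mm and l~upper~ + l~fore~ — so a centroid pushed
out of reach by a held object simply stretches the arm fully toward it.
The analytic inverse kinematics then fixes elbow flexion by the law of
cosines and leaves one redundant degree of freedom: the swivel angle of
the elbow on its circle about the shoulder–hand axis. The solver takes
the swivel closest to the *observed* elbow centroid (projection onto the
circle), so the model elbow is the kinematically admissible point nearest
the measurement — this is precisely why elbow error drops below the raw
tracker's. If that swivel violates joint limits or collides, 64
discretized candidates are scanned in order of increasing swivel change;
ties prefer the smaller change, then the positive offset. When no swivel
is feasible the pose is *replaced*: the target is first pulled back along
the straight path from the previous hand position (bisection), which
parks the hand on the obstacle surface it would otherwise pass through —
an occluded hand held behind the head or torso therefore stays behind it
instead of teleporting to the geometrically nearest free spot — and only
if that whole path is infeasible does a deterministic expanding grid
search run, with the neutral pose as the guaranteed fallback.

**Validated interpolation.** Between consecutive key poses a third-order
(cubic Hermite) spline interpolates the end-effector trajectories, with
knot slopes from finite differences over the last three key points;
every substep is re-solved through the same IK pipeline, so interpolated
poses are as valid as key poses. Because the slope at the older knot is a
central difference, the emitted stream lags the input by exactly two
samples (~66 ms at 30 fps); a linear interpolator (one-sample lag) or no
interpolation are available where latency matters
(`filter_config(interpolator=)`).

One deliberate addition beyond the constraint set: during *occlusion
recovery* — from the frame an end effector is gated until its model hand
catches up with the observation — the hand target is rate-limited to
`max_ee_speed` (default 3600 mm/s, well above natural reach speeds). A
30-frame occlusion then re-acquires smoothly instead of snapping across
the workspace, while fully observed motion, including the instant
full-arm stretch toward an unreachable target, is never slowed.

## Self-collision detection

Collision proxies are capsules (head: sphere; trunk: a vertical capsule
spanning the torso) whose radii are ratio-table entries. Detection is
two-level: axis-aligned bounding boxes (conservative, inflated by the
capsule radius) gate an exact capsule–capsule test (minimum
segment–segment distance against the radius sum). Boundary contact counts
as collision, so the filter errs toward separation. Adjacent bodies —
those sharing a joint — are excluded automatically from the pair list.
Capsules were chosen over detailed meshes because they admit a
closed-form narrow phase that an independent numerical oracle can verify
exactly, while preserving the two-level architecture.

## Learning the performer's limb lengths

The instant length of a limb is the Euclidean distance between its two
ending centroids; frames where either confidence is below 1 are
discarded (estimated centroids would bias the lengths). Estimates follow
a cumulative running average with time-varying coefficients
α = (k−1)/k, β = 1/k — exactly the arithmetic mean of the accepted
samples while k ≤ N. After N samples the limb *fixates*: the estimate
freezes unless the disparity between estimate and measurement exceeds
`MaxDist`, in which case the counter resets and learning restarts from
the new measurement. The reset reading restores fast adaptation after a
genuine change (different performer, recalibrated sensor); the
alternative — keep averaging with the tiny β the guard alone would give —
is available as `learner_config(reset_on_disparity = FALSE)`.

Defaults: `N = 200` accepted frames (about 6.7 s of standing at 30 fps,
one stable initialization phase) and `MaxDist = 50` mm (several times
the noise-induced spread of instant lengths at typical sensor noise, so
fixation is not reset by noise). Euclidean distances of noisy centroids
overestimate the true length (a chi-distribution bias of about
3σ²/(2l) for per-axis difference noise σ); an optional correction
subtracts it when a noise estimate is configured
(`learner_config(bias_sigma=)`).

Learning and filtering interleave deterministically per frame: the
learner consumes the *raw* centroids, the filter consumes the current
length estimates.

## Cross-system calibration and alignment

To compare streams from two capture systems, the package provides the
4-point block transform **RT** = *B·A*⁻¹ (solved literally from
homogeneous coordinates, faithful to the construction but sensitive to
marker noise since nothing forces the linear block to be a rotation) and
a least-squares orthogonal mode (Kabsch/SVD), the default for practice.
Trajectories are resampled to a common rate with cubic splines, and
temporal offsets are found by normalized cross-correlation: one candidate
lag per joint (hand, elbow, shoulder; per-axis Pearson correlations
averaged), then the candidate maximizing the mean correlation across all
three joints wins — a consensus that survives one heavily corrupted
joint. Flat trajectories carry no evidence and are excluded. Instant
position errors are per-frame Euclidean distances with mean and
population SD.

## The synthetic tracker

Because no deposited recordings exist, the package ships a generator that
emulates the tracker including its documented failure modes; all tests
and the acceptance analyses run on it.

* **Truth motion**: smooth joint-angle trajectories through random
  way-poses inside the joint limits (one way-pose per second,
  rejection-sampled against inflated collision proxies so the
  interpolated path stays clear), or a task-space `torso_reach` preset in
  which the right hand cycles front → around the side → behind the torso,
  the way a person actually hides a hand behind the back. Deterministic
  under a seed.
* **Corruption**: per-joint Gaussian centroid noise; elbow noise
  multiplied by 1 + g·r with r the arm-extension ratio (default g = 2),
  reproducing oscillation that grows as the arm stretches; occlusions at
  confidence 0 (frozen stale position) or 0.5 (stale position plus a slow
  random-walk drift — the real tracker estimates occluded centroids, but
  how is undocumented, so the drift is an explicit stand-in);
  depth-hijack events that replace the hand's camera-axis coordinate with
  a donor joint's while keeping confidence 1; object-in-hand displacement
  along the forearm axis. `camera_occluded_intervals()` derives realistic
  hijack intervals (hand inside the trunk silhouette, behind it) from a
  truth sequence.
* **Scoring**: joints are labeled `behind` / `aligned` / `in_front` of a
  reference joint by thresholding the difference of camera distances at
  Θ~d~ (camera default 1.7 m toward +z; farther = behind, sign
  configurable), and estimates are scored by category agreement.

What the generator does *not* emulate: depth-image formation, the
tracker's internal body-part classifier, soft-tissue artifacts, or
correlated (non-Gaussian) noise. Passing tests therefore demonstrate the
mechanisms — validity enforcement, noise rejection on the elbow locus,
occlusion behaviour — not sensor-specific error magnitudes on real
recordings.

## Numerical choices and degenerate inputs

* Inner reach boundary margin: 1 mm (avoids the singular folded-elbow
  configuration); a target coincident with the shoulder falls back to the
  caller-supplied ray, else straight down.
* The elbow-flexion limit bounds the feasible hand–shoulder distance from
  below; the solver detects this analytically and the resolver clamps its
  candidates into the feasible radial range instead of scanning swivels
  that cannot help.
* Straight-arm targets leave the swivel undefined; the previous axial
  rotation is kept.
* Euler decomposition of the shoulder direction has two branches; both
  are checked against the limits and the first feasible one is used.
* Cross-correlation peak ties break toward the smaller |lag|; swivel
  candidate ties toward the smaller absolute change, then the positive
  offset.
* Timestamps must be strictly increasing; the first frame passes the gate
  unchanged (no history); with fewer than three key poses the spline
  slopes fall back to linear differences.

## Problem sizes used by the test-suite analyses

The stochastic analyses run at sizes a desk check can afford while still
estimating rates meaningfully: 20 seeded 30 s streams for the elbow
comparison, 20 seeded 20 s torso-occlusion streams for the categorical
comparison, 100 seeds for limb-length recovery, 10⁴ fuzzed frames for the
validity audit, and 10⁴ posed capsule pairs against the independent
narrow-phase oracle. The numerical IK oracle (box-constrained L-BFGS-B
over the four arm angles, multi-start) is compared on 100 targets where
its global convergence can be verified through its own objective.

## Known limitations

* Shoulders are fixed offsets of the torso; shoulder-girdle elevation and
  torso articulation are not modeled, so extreme overhead reaches are
  approximated (the spec's upstream system notes the same limitation).
* Hand *pose* (wrist, fingers) is out of scope; the hand is a point.
* The elbow is a pure hinge; forearm pronation is folded into the
  shoulder's axial degree of freedom.
* The resolver's path search is a straight segment; a hand that would
  have to slide around a corner of the body in a single frame stops at
  the obstacle instead (it catches up in later frames as the observations
  move).
* Lower body: out of scope by design.
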