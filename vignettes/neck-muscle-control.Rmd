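---
title: "Methods: omni-directional neck-muscle feedback control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: omni-directional neck-muscle feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckcontrol)
```

# The control problem

During pre-crash evasive maneuvers an occupant's neck muscles keep the
head roughly stationary in space — the vestibulocollic reflex. Active
human body models emulate this with feedback controllers on head
kinematics. `neckcontrol` implements two such controllers and every
piece of scaffolding needed to exercise them: a surrogate head-neck
plant, maneuver pulse generators, the spatial-tuning-pattern (STP)
machinery for intermuscular load sharing, sequential-response-surface
gain tuning, and objective corridor/correlation rating. This vignette
records the model, its assumptions, and the design choices made where
the problem was genuinely open.

# Frames, rotations and error signals

All internal angles are radians; the frame is x forward, y to the
occupant's right, z **down**, right-handed. Under this convention a
positive rotation about +y is extension (nose up), −y flexion, +x right
lateral bending, +z right axial rotation.

The rotational controller builds a rotation matrix from successive z,
y, x rotations and converts it to the axis-angle pair `(v, θ)`. Two
readings of "successive rotations around z, y and x" exist — intrinsic
z–y′–x″ (`Rz Ry Rx`) and extrinsic fixed-axis (`Rx Ry Rz`). They agree
to first order in the angles, and the maneuvers of interest involve
small combined angles, so the package makes the convention a
configuration option with **intrinsic** as the documented default; the
exact elemental product is printed in `?rotation_matrix_zyx`.

Numerical choices in the axis-angle extraction:

* `θ < 1e-9 rad`: the axis is undefined. The documented default
  `(0, 0, 1)` is returned with a `degenerate` flag, and the controller
  emits **zero directional drive** for degenerate errors, so no NaN can
  propagate at maneuver start.
* `θ` near π: the sine-based axis formula degenerates; the axis is
  taken from the dominant column of `(R + I)/2`, sign-matched to the
  skew part.

The scalar error of the rotational controller is `θ` of
`t(R_ref) %*% R_cur`; the axis drives load sharing. Mapping the axis to
the STP direction coordinates follows from the frame convention:

| head deviation       | rotation axis | STP query                      |
|----------------------|---------------|--------------------------------|
| forward flexion      | (0, −1, 0)    | bend azimuth 0                 |
| right lateral bend   | (+1, 0, 0)    | bend azimuth +π/2              |
| extension            | (0, +1, 0)    | bend azimuth π                 |
| right axial rotation | (0, 0, +1)    | axial component +1             |

i.e. `bend_azimuth = atan2(vx, −vy)`, `axial_component = vz`.

The translational controller senses the angular deviation of the
T1→head-CoG link from its pre-maneuver reference, both expressed in a
frame that follows T1 in yaw; its load-sharing azimuth is the
horizontal direction of the head displacement, and it queries only the
no-axial-rotation slice of the STPs (its source experiments were
horizontal-plane perturbations).

# Spatial tuning patterns

The STP grid is fixed: 8 bend azimuths at 45° spacing × 3 axial levels
plus 2 pure axial rotations = 26 directions; 11 bilateral muscle
groups. Source records from multiple experiments are merged by a strict
priority — dynamic MVIC-normalized, then dynamic peak-normalized, then
isometric — with ties broken by experiment id; a group absent from all
sources at a direction inherits its registry substitute's value with
provenance `substituted:<group>`. Right-side patterns are mirrored
(azimuth reflected about the sagittal plane, axial level swapped) and
every direction is normalized by its maximum over all groups and sides,
so each direction has a unit maximum; the operation is idempotent and
scale-invariant per direction. A consequence worth knowing: after
per-direction normalization the *relative* activity of one muscle
across directions is no longer meaningful — only the load sharing
within a direction is.

Querying arbitrary directions requires interpolation the grid does not
define. The package uses the simplest continuous scheme honoring the
grid: periodic linear interpolation in azimuth between adjacent 45°
nodes, and piecewise-linear interpolation in `|axial_component|` —
from the no-axial level at 0 to the signed level at the
`pure_axial_threshold` (default 0.5), then on to the pure-axial entry
at 1. The threshold is exposed in configuration precisely because the
source data say nothing about how the pure-axial entries blend.

The 11 default groups, their substitutes, preferred directions and
effective strengths live in `default_muscle_registry()` and are
package choices, labelled as such; the appendix-level group membership
of the original experiments is not available.

# The controller chain

```
e(t−τ) → PID → clamp [0, ceiling] → STP weights → + baseline → 2×first-order → Na
```

* **Delay** τ (default 25 ms) represents neural transmission and
  processing; `e(t−τ)` is read from the sampled history by linear
  interpolation, and pre-history error is defined as 0 (controllers
  initialize during gravity settling from rest).
* **PID**: parallel form with trapezoidal integral and
  backward-difference derivative. Gains carry units 1/rad, 1/(rad ms),
  ms/rad; controller time is milliseconds throughout.
* **Clamp**: negative responses are clamped to 0 — muscles only pull;
  antagonists are recruited by the direction query, not by negative
  drive. The chain emits one common activity level for all muscles.
* **Load sharing**: weights from the STP query using the *current*
  (undelayed) kinematics by default while the error magnitude is
  delayed; a configuration switch (`direction_from_delayed`) selects
  the fully delayed reading, since the source material does not fix it.
* **Baseline**: quiet-sitting activity, per muscle the minimum of its
  normalized STP weights times `baseline_scale` (default 1), present
  for the full duration including gravity settling. Baseline is added
  **before** the unit cap (`drive = min(1, u·w + b)`); cap-last is a
  documented package choice, not an assertion about the original
  implementation.
* **Activation dynamics**: two cascaded first-order stages (neural
  excitation, default τ = 35 ms; active state, default τ = 15 ms)
  advanced with the exact exponential update for piecewise-constant
  input, so the single-stage step response passes through `1 − 1/e` at
  `t = τ` exactly and outputs cannot leave [0, 1]. The delay and the
  two time constants are not published quantities for this controller
  family; they are configuration values with the defaults above, and
  every output file header records the values used.

# The surrogate plant

The plant is explicitly a stand-in: a rigid head (mass 4.5 kg, inertia
diag(0.020, 0.022, 0.015) kg m², CoG 2 cm anterior / 15 cm above the T1
joint) on passive visco-elastic elements, with gravity torque from the
anterior CoG, muscle-group forces along fixed lines of action, and T1
following the vehicle pulse through a first-order seat-compliance
filter (τ = 50 ms, pass-through selectable). Two calibration choices
matter and are deliberate:

* **Damping** (rotational 6, 6, 4 N m s/rad; translational 150, 150,
  1500 N s/m) puts the passive head response in the strongly damped,
  non-oscillatory regime. Volunteer head displacement histories in
  these maneuvers are smooth; an underdamped surrogate rings, and its
  tuning objective then develops narrow resonant basins no
  small-budget metamodel optimizer (the point of SRSM) could navigate.
  The damping is part of what "surrogate for a soft-tissue-damped
  human" means here.
* **Effective muscle strengths** (`fmax_n`, 10–50 N per group-side) are
  far below anatomical group forces, because the surrogate concentrates
  each group into a single line of action on a 5 cm lever. They are
  sized so that proportional/derivative gains of the magnitude
  published for full human body models (Kp of order 1 1/rad, Kd of
  order 100–500 ms/rad) drive the surrogate in its sensible operating
  range, which keeps the published tuning bounds meaningful.

Integration is semi-implicit Euler at dt = 1 ms (velocity before
position, world-frame diagonal inertia, incremental Rodrigues rotation
update with periodic re-orthonormalization). Halving dt changes peak
displacements by well under 1% on the reference configuration, and the
passive plant dissipates mechanical energy monotonically. Divergence
(non-finite state or |rotation| > π/2) raises an instability error
naming the step; the gain tuner treats such designs as maximally bad
rather than aborting.

Maneuver pulses: braking is a −x haversine-onset/plateau/release pulse
(defaults 11 m/s², 2.5 s); the lane change is two opposite-sign
haversine lobes (+y first: right turn) with peak 6 m/s² over 2 s, zero
net impulse. The haversine shape is the package's choice; only peak and
duration are prescribed quantities. Default phase timing is the
head-neck sub-system convention (250 ms gravity settling + 2250 ms
loading for braking, 250 + 1450 ms for lane change); the pipeline smoke
runs use the longer full-body phases (750 + 2300, 650 + 2150 ms). The
reference posture is captured at the end of settling by default; the
exact reference time is configurable because it is not otherwise fixed.

# Gain tuning

The tuner is a sequential response surface method with domain
reduction: per iteration a 200-point Latin-hypercube candidate pool is
drawn in the current region, the region center plus 6 greedily
D-optimal designs are simulated, linear metamodels are fitted to the
scalarized objective and the constraint, and the constrained metamodel
optimum (searched over the pool and the region vertices — a linear
objective attains its box optimum at a vertex) becomes the next region
center. Termination on *relative* design change and objective change
below 0.01 (the tolerances' absolute/relative reading was open;
relative is chosen and documented) or 10 iterations.

Domain reduction is adaptive per axis: the contraction interpolates
between the base factor 0.6 (interior optimum) and 1 (optimum at the
region edge — pure panning), with an extra 0.7 damping when the pan
direction flips sign; the first region spans 0.45 of each variable's
global range around the starting design, and panning is clipped to the
global bounds. A fixed 0.6 contraction on every axis was tried first
and collapses the region before a panning search can cross the design
space; the adaptive rule is the conventional cure. With `zoom = 1` the
method reduces to repeated single-stage RSM, kept as a regression
baseline. An incumbent safeguard re-anchors the region on the best
*simulated* feasible design whenever a metamodel prediction
underperforms it, and the reported optimum is always the best simulated
feasible design — if none is feasible the run is flagged
`constraint_violated`.

Objectives: the curve-mapping discrepancy per objective channel
(loading-direction translation, principal rotation, or both, per
maneuver), scalarized with equal weights — the aggregation of the
multi-objective set is a package choice exposed in configuration. The
metric normalizes both curves by the reference peak and the common
duration, parameterizes each by normalized arc length, and averages the
pointwise distance between arc-length-matched points; it is anchored on
the reference and not symmetric. The exact curve-mapping algorithm of
commercial optimizers is proprietary, so this documented
partial-curve-mapping-style implementation is the package's own, with a
plain RMS-after-resampling metric (`rms_distance`) available for
sensitivity checks.

Constraint: maximum allowed activity 0.99 on the saturated PID response
(configurable to the post-dynamics activation; published tables report
the PID response, so pre-dynamics is the default), with the total
saturated duration added (scale 1 per second, configurable — the units
of the added duration are not otherwise fixed). This keeps the
constraint strictly increasing in saturated duration so the optimizer
can distinguish brief from sustained saturation. Starting values sit at
the low end of the ranges so the very first simulated design is
feasible; an infeasible first iteration is a hard error. The Ki bound
is `Ki = Kp²/(4 Kd)` (from Ti = 4 Td, Td = Kd/Kp) maximized over the
published reference controllers and rounded up to the nearest order of
magnitude: 0.1.

`tune_controller()` wraps all of this as the package's fitting
function; the returned `neck_tune` object carries the usual methods
(`coef`, `summary`, `plot` for convergence, `simulate` for re-running
the plant at the tuned gains, `residuals`/`fitted` on the objective
channels).

# Bio-fidelity rating

`cora_score()` combines, with equal top-level weights, (a) a corridor
sub-score — per-sample 1 inside the inner corridor, 0 outside the
outer, linear between, time-averaged; corridors are ±1/±2 SD where the
reference provides SD, else 5%/50% of the reference peak — and (b)
correlation sub-scores: shape (maximum normalized cross-correlation
over shifts up to 20% of the interval, clamped to [0, 1]), size (ratio
of smaller to larger L2 norm), phase (1 − normalized optimal shift),
weighted 0.5/0.25/0.25. A flat signal against a structured reference
scores 0 on all correlation sub-scores. Every constant lives in
`cora_settings()`; the scheme is comparable in structure, not
numerically, to CORAplus. Rating thresholds default to the common
ladder 0.94/0.80/0.58 (boundaries belong to the higher label) and are
configuration, because the original threshold table is not available.

The overall score weights channel scores by the **absolute peak** of
the reference displacement within each family (peak-to-peak was the
alternative; absolute peak is the documented choice), then averages the
translation and rotation composites with equal value. Muscle-activity
similarity is a time-averaged activation compared against the
volunteer mean ± 1 SD with inclusive bounds, over the maneuver-specific
window (1.6–1.8 s in braking; phase windows <0, 0–1, 1–2 s in lane
change).

# Synthetic fixtures

No EMG tables or volunteer corridors ship with the package; generators
produce them deterministically from a seed. The STP fixture emulates
three experiments spanning the priority classes — horizontal-plane
dynamic MVIC-normalized perturbations (8 no-axial directions, 8
groups), a dynamic peak-normalized experiment covering all 26
directions but with deliberate pure-axial holes for one group, and an
isometric peak-normalized experiment covering everything — using
cosine tuning about each group's preferred direction, axial-level
modulation and multiplicative log-normal noise (SD 0.08). The corridor
fixture produces smooth braking (forward translation 0.15 m, flexion
−0.25 rad, small vertical drop) and lane-change (biphasic lateral
translation with exactly one sign reversal, roll, yaw) means with
strictly positive SD bands (25% of |mean|, floored at 5% of peak) and a
seeded low-frequency ripple.

What passing tests on these fixtures shows: the merging, mirroring,
normalization, interpolation, control, tuning and rating machinery is
correct and deterministic. What it does not show: that the surrogate
plant or the synthetic corridors reproduce any particular human or
finite-element response — conclusions about real bio-fidelity require
the real model and volunteer data.

# Problem sizes used by the test suite

The suite runs every simulation at dt = 1 ms: braking 2.5 s (2501
samples), lane change 1.7 s, a 10 s settling run for the static-balance
check, and a parameter-recovery tuning of 70 plant simulations
(7 designs × 10 iterations, braking, two objectives) — the full suite
completes in under two minutes on one CPU. The recovery harness
generates its reference trajectories from known feasible gains
(0.35, 1e-5, 250) and requires the tuned trajectories to sit within 5%
peak-normalized curve-mapping discrepancy of them; because the
objective has a flat valley in which gain combinations trade off with
nearly identical trajectories (the derivative/proportional trade-off is
a property of the chain, and re-tuned gains of this family are known to
be insensitive over ranges of ±20%), agreement is asserted at
trajectory level, not gain level.

# Known limitations

* One rigid body; no cervical-spine articulation, no protraction /
  retraction sensing (invisible to the rotational controller by
  construction), no muscle force-length/velocity properties beyond the
  activation signal.
* The rotational controller's reference frame is globally fixed; for
  maneuvers with large vehicle yaw a torso-following frame would be
  needed.
* Per-direction normalization discards between-direction activity
  ratios, as discussed above.
* The curve-mapping and rating implementations are structural
  re-creations of proprietary tools, not numerical replicas.
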