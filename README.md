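# neckcontrol

Feedback control of neck-muscle activation for simulating how a vehicle
occupant's head moves during evasive maneuvers (hard braking, lane
changes). Active human body models used in crash safety research drive
their neck muscles with reflex-emulating controllers; this package
implements that control layer — two controller variants, the spatial
tuning patterns that distribute one common drive across muscles, the
gain-tuning optimizer and the objective bio-fidelity rating — together
with a surrogate rigid-body head-neck plant so the whole
control → tune → rate loop runs and can be tested on a desktop, without
a proprietary finite-element human body model.

It is written for biomechanics and vehicle-safety researchers who want
to study, re-tune or extend these controllers outside a full crash-code
environment.

## The model

Both controllers emulate the vestibulocollic reflex: a deviation of the
head from a reference posture is sensed, delayed, and converted into
muscle activations.

* **Rotational controller** — head orientation is tracked as a rotation
  matrix `R` (successive z, y, x rotations) and converted to the
  axis–angle representation `(v, θ)`. The angle `θ` relative to the
  reference orientation is the scalar error; the axis `v` selects the
  direction for intermuscular load sharing.
* **Translational controller** — the angular deviation of the link from
  T1 (first thoracic vertebra) to the head centre of gravity, in a frame
  that follows T1 in yaw, is the error; the horizontal direction of the
  head displacement selects the load-sharing direction.

The common chain is

```
e(t−τ) → PID → saturation [0,1] → STP load sharing → + baseline → activation dynamics → Na
```

with the parallel PID form

    u(t) = Kp e(t) + Ki ∫₀ᵗ e dτ + Kd de/dt,
    Kp [1/rad], Ki [1/(rad·ms)], Kd [ms/rad],

the standard form `u = Kp (e + ∫e/Ti + Td ė)` used for starting-value
estimates, and two first-order stages (neural excitation, active state)
filtering the drive. Spatial tuning patterns (STPs) map each of 11
bilateral muscle groups to a weight over a 26-direction grid — eight
flexion/extension–lateral-bending azimuths at three axial-rotation
levels plus two pure axial rotations — built by priority-merging EMG
source tables (dynamic MVIC-normalized ≻ dynamic peak-normalized ≻
isometric), mirroring right-side patterns to the left, and normalizing
each direction by its maximum across all muscles and sides.

Gains are tuned by the sequential response surface method (SRSM) with
domain reduction: 7 simulations per iteration selected D-optimally,
linear metamodels, at most 10 iterations, change tolerances 0.01, a
maximum-activity constraint of 0.99 with the saturated duration added to
the constraint response, and a curve-mapping discrepancy against
reference displacement histories as the objective. The integral-gain
bound comes from the Ziegler–Nichols step-response rules,
`Ki = Kp²/(4 Kd)`, evaluated over published reference controllers and
rounded up to the nearest order of magnitude (0.1).

Simulated channels are rated against mean ± 1 SD reference corridors
with a corridor + cross-correlation (shape/size/phase) score in [0, 1],
classified excellent/good/fair/poor, and aggregated with weights
proportional to the reference peak magnitudes (translations and
rotations of equal value).

## Worked example

```r
library(neckcontrol)

## Ziegler-Nichols integral gains of the published reference controllers
ref <- reference_controller_gains()
data.frame(model = ref$model, ki = ziegler_nichols_ki(ref$Kp, ref$Kd))
#>               model           ki
#> 1     SAFER HBM v10 0.0009003197
#> 2             THUMS 0.0533333333
#> 3             GHBMC 0.0090000000
#> 4 GHBMC (two-level) 0.0003147309
ki_tuning_ceiling()
#> [1] 0.1

## spatial tuning patterns from the synthetic EMG source tables
stps <- stp_set_from_combined(combine_sources(generate_stp_fixture(seed = 1)))
stps
#> <stp_set> 11 groups x 2 sides over 26 directions (normalized)

## simulate braking (11 m/s2, 2.5 s) with the translational controller
res <- simulate_plant(head_neck_plant(), braking_pulse(),
                      controller_gains(Kp = 0.35, Ki = 1e-5, Kd = 250),
                      stps, controller_config("translational"))
res
#> <simulation_result> braking, 2501 samples @ 1 ms (2.50 s)
#>   peak |tx, ty, tz| = 0.0719, 0.0000, 0.0252 m; peak |rx, ry, rz| = 0.0000, 0.4350, 0.0000 rad
#>   max activation 0.361, max PID response 0.254
```

The head translates about 7 cm forward and pitches 0.43 rad under the
pulse; the PID response peaks at 0.25 (no saturation) and activations
stay below 0.37. Rating the run against the synthetic volunteer-like
corridors:

```r
corr <- generate_corridor_fixture(seed = 1, maneuver = "braking")
rows <- do.call(rbind, lapply(names(corr), function(ch) {
  sc <- cora_score(res$time_s, res$channels[, ch], corr[[ch]])
  data.frame(channel = ch,
             family = ifelse(grepl("_t", ch), "translation", "rotation"),
             score = sc$score, peak = max(abs(corr[[ch]]$mean)))
}))
overall_score(rows)
#> <bio_fidelity_report>
#>   head_tx   translation score 0.545 (poor), peak 0.1535
#>   head_tz   translation score 0.882 (good), peak 0.03
#>   head_ry   rotation    score 0.491 (poor), peak 0.2559
#>   translation composite 0.600 | rotation composite 0.491
#>   overall 0.545 (poor)
```

The corridors are synthetic stand-ins, not tuned to the surrogate, so
the untuned run scores poorly on the large-magnitude channels — which is
exactly what the score is for. `tune_controller()` returns a fitted
`neck_tune` object (`coef`, `summary`, `plot`, `simulate`, `residuals`)
whose gains minimize that mismatch subject to the activity constraint.

Scores are comparable in structure, not numerically, to CORAplus
ratings: the corridor widths, sub-weights and rating thresholds
(defaults 0.94/0.80/0.58) are package configuration.

## Limitations

The plant is a deliberately simple rigid-head surrogate (documented
parameters, no seat/belt environment, no FE soft tissue); every result
against it is a property of the control architecture, not a prediction
for a specific human body model. EMG source tables and volunteer
corridors are generated synthetic fixtures, labelled as such.
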