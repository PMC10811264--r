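# The feedback chain shared by both controllers:
#   delayed error -> PID -> saturation -> STP load sharing -> baseline
#   -> activation dynamics.
# Controller time is in milliseconds throughout; gains carry units
# Kp [1/rad], Ki [1/(rad ms)], Kd [ms/rad] so that errors in radians give
# dimensionless activation levels.

#' Parallel-form PID gains
#'
#' The parallel formulation `u = Kp e + Ki int(e) + Kd de/dt` keeps the
#' three gains independent and is the form used for tuning.
#'
#' @param Kp proportional gain, 1/rad.
#' @param Ki integral gain, 1/(rad ms).
#' @param Kd derivative gain, ms/rad.
#' @return object of class `controller_gains`.
#' @export
controller_gains <- function(Kp, Ki, Kd) {
  stopifnot(is.finite(c(Kp, Ki, Kd)), Kp >= 0, Ki >= 0, Kd >= 0)
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd), class = "controller_gains")
}

#' @export
print.controller_gains <- function(x, ...) {
  cat(sprintf("<controller_gains> Kp = %g 1/rad, Ki = %g 1/(rad ms), Kd = %g ms/rad\n",
              x$Kp, x$Ki, x$Kd))
  invisible(x)
}

#' Standard-form PID gains
#'
#' The standard form `u = Kp (e + int(e)/Ti + Td de/dt)` is used for
#' estimating starting values because classical tuning rules are stated
#' in it.
#'
#' @param Kp proportional gain, 1/rad.
#' @param Ti integral time, ms (> 0).
#' @param Td derivative time, ms (>= 0).
#' @return object of class `standard_form_gains`.
#' @export
standard_form_gains <- function(Kp, Ti, Td) {
  stopifnot(is.finite(c(Kp, Ti, Td)), Kp >= 0, Ti > 0, Td >= 0)
  structure(list(Kp = Kp, Ti = Ti, Td = Td), class = "standard_form_gains")
}

#' Convert between standard and parallel PID forms
#'
#' `Ki = Kp / Ti`, `Kd = Kp * Td`; the inverse recovers `Ti = Kp / Ki`,
#' `Td = Kd / Kp` and is undefined for `Kp = 0` or `Ki = 0`.
#'
#' @param g gains in the source form.
#' @return gains in the target form.
#' @export
standard_to_parallel <- function(g) {
  stopifnot(inherits(g, "standard_form_gains"))
  controller_gains(g$Kp, g$Kp / g$Ti, g$Kp * g$Td)
}

#' @rdname standard_to_parallel
#' @export
parallel_to_standard <- function(g) {
  stopifnot(inherits(g, "controller_gains"))
  if (g$Kp == 0 || g$Ki == 0)
    stop("standard form undefined for Kp = 0 or Ki = 0")
  standard_form_gains(g$Kp, g$Kp / g$Ki, g$Kd / g$Kp)
}

#' Ziegler-Nichols step-response integral gain
#'
#' From the step-response rules `Ti = 4 Td` with `Td = Kd / Kp`, the
#' theoretical integral gain of a PD-tuned controller is
#' `Ki = Kp^2 / (4 Kd)`.
#'
#' @param Kp proportional gain, 1/rad (> 0).
#' @param Kd derivative gain, ms/rad (> 0).
#' @return Ki in 1/(rad ms).
#' @export
ziegler_nichols_ki <- function(Kp, Kd) {
  if (any(Kd <= 0) || any(Kp <= 0))
    stop("ziegler_nichols_ki undefined for Kp <= 0 or Kd <= 0")
  Kp^2 / (4 * Kd)
}

#' Published reference controller gains
#'
#' Proportional and derivative gains of previously published active
#' head-neck muscle controllers, used to bound the integral gain during
#' tuning. The `ki_printed` column holds each model's published
#' theoretical Ziegler-Nichols integral gain at its printed precision.
#'
#' @return data.frame with columns `model`, `Kp` (1/rad), `Kd` (ms/rad),
#'   `ki_printed` (1/(rad ms)).
#' @export
reference_controller_gains <- function() {
  data.frame(
    model = c("SAFER HBM v10", "THUMS", "GHBMC", "GHBMC (two-level)"),
    Kp = c(1.301, 8.0, 3.0, 0.78),
    Kd = c(470, 300, 250, 483.27),
    ki_printed = c(9e-4, 0.05, 0.009, 3e-4),
    stringsAsFactors = FALSE)
}

#' Upper tuning bound for the integral gain
#'
#' The maximum theoretical Ziegler-Nichols `Ki` across the reference
#' controllers, rounded up to the nearest order of magnitude. With the
#' default reference set the maximum is the THUMS value (0.05,
#' rounded from 0.0533), giving a ceiling of 0.1.
#'
#' @param reference data.frame as from [reference_controller_gains()].
#' @return the Ki ceiling in 1/(rad ms).
#' @export
ki_tuning_ceiling <- function(reference = reference_controller_gains()) {
  kis <- ziegler_nichols_ki(reference$Kp, reference$Kd)
  10^ceiling(log10(max(kis)))
}

#' Delayed error lookup
#'
#' Returns `e(t - tau)` from a sampled error history by linear
#' interpolation. Pre-history error is defined as zero (`t < tau` gives
#' 0): controllers initialize during gravity settling from rest.
#'
#' @param times sample times, ms, ascending from 0 at fixed spacing.
#' @param values error samples (radians).
#' @param t query time, ms.
#' @param tau delay, ms (>= 0).
#' @return the delayed error value(s).
#' @export
delay_signal <- function(times, values, t, tau) {
  if (tau < 0) stop("delay tau must be >= 0")
  tq <- t - tau
  out <- numeric(length(tq))
  inside <- tq >= 0
  if (any(inside))
    out[inside] <- stats::approx(times, values, xout = tq[inside],
                                 rule = 2)$y
  out
}

#' PID response over a sampled error history
#'
#' `u(t) = Kp e + Ki int_0^t e dtau + Kd de/dt` with a trapezoidal
#' integral and backward-difference derivative at the sampling
#' resolution (the derivative at the first sample is 0).
#'
#' @param gains a [controller_gains()] object.
#' @param times sample times, ms, uniform from 0.
#' @param errors error samples, radians (typically already delayed).
#' @return numeric vector `u` at each sample, unsaturated.
#' @export
pid_response <- function(gains, times, errors) {
  stopifnot(inherits(gains, "controller_gains"),
            length(times) == length(errors), all(is.finite(errors)))
  n <- length(times)
  if (n == 0) return(numeric(0))
  dt <- if (n > 1) diff(times) else numeric(0)
  integ <- c(0, cumsum((errors[-n] + errors[-1]) / 2 * dt))
  deriv <- c(0, diff(errors) / dt)
  gains$Kp * errors + gains$Ki * integ + gains$Kd * deriv
}

#' Saturate an activation level
#'
#' Clamps the common PID response to `[0, ceiling]`. Negative responses
#' are clamped to zero because muscles only pull; antagonist recruitment
#' is handled entirely by the directional STP query.
#'
#' @param u response value(s).
#' @param ceiling maximum activity (default 1).
#' @return clamped value(s).
#' @export
saturate <- function(u, ceiling = 1) {
  stopifnot(all(is.finite(u)), ceiling > 0, ceiling <= 1)
  pmin(ceiling, pmax(0, u))
}

#' Distribute a common drive across muscle groups
#'
#' `drive_i = min(1, u_sat * w_i + b_i)`: the saturated common activity is
#' scaled by the STP weight of each group/side and the per-muscle baseline
#' (present for the full duration, including gravity settling) is added;
#' the sum is capped at 1. Adding the baseline before the cap is the
#' documented package choice.
#'
#' @param u_sat saturated common activity, fraction.
#' @param weights per-group STP weights in `[0, 1]`.
#' @param baseline per-group baseline activity in `[0, 1]`.
#' @return per-group drive in `[0, 1]`.
#' @export
distribute <- function(u_sat, weights, baseline) {
  stopifnot(all(weights >= 0 & weights <= 1),
            all(baseline >= 0 & baseline <= 1))
  pmin(u_sat * weights + baseline, 1)
}

#' One step of the activation dynamics
#'
#' Two cascaded first-order low-pass stages representing neural
#' excitation and active state, each `dX/dt = (input - X)/tau`, advanced
#' with the exact exponential (exponential-Euler) update for a
#' piecewise-constant input. Outputs remain in `[0, 1]` for inputs in
#' `[0, 1]`.
#'
#' @param state list with `excitation` and `activation` vectors.
#' @param drive per-group drive in `[0, 1]`.
#' @param dt step, ms; must satisfy `dt <= min(tau)/2`.
#' @param tau_neural neural excitation time constant, ms.
#' @param tau_active active-state time constant, ms.
#' @return updated state list.
#' @export
activation_dynamics_step <- function(state, drive, dt, tau_neural = 35,
                                     tau_active = 15) {
  if (dt > min(tau_neural, tau_active) / 2)
    stop("configuration error: dt must be <= min(time constant)/2")
  an <- 1 - exp(-dt / tau_neural)
  aa <- 1 - exp(-dt / tau_active)
  e <- state$excitation + an * (drive - state$excitation)
  a <- state$activation + aa * (e - state$activation)
  list(excitation = e, activation = a)
}

#' Controller configuration
#'
#' Collects the chain parameters that are package defaults rather than
#' published constants: the neural delay, the two activation time
#' constants, the baseline scale and the reference time. Every simulation
#' output header records the values actually used.
#'
#' @param mode `"translational"` or `"rotational"`.
#' @param delay_ms neural transmission/processing delay tau (default 25 ms).
#' @param tau_neural_ms,tau_active_ms activation-dynamics stage time
#'   constants (defaults 35 and 15 ms).
#' @param baseline_scale baseline activity is `baseline_scale` times each
#'   muscle's minimum STP weight across directions (quiet-sitting
#'   activity); default 1.
#' @param reference_time_ms time at which the reference posture /
#'   orientation is captured; defaults to the end of gravity settling and
#'   is set by the simulation when `NA`.
#' @param saturation_ceiling PID saturation ceiling (default 1).
#' @param pure_axial_threshold STP axial blending threshold, see
#'   [lookup_weights()].
#' @param direction_from_delayed if TRUE the STP direction query uses the
#'   delayed kinematics; the default (FALSE) evaluates direction from the
#'   current kinematics while only the error magnitude is delayed.
#' @param euler_convention rotation composition convention, see
#'   [rotation_matrix_zyx()].
#' @param constraint_signal signal the tuning activity constraint reads:
#'   `"pid"` (the saturated PID response, default) or `"activation"`.
#' @return list of class `controller_config`.
#' @export
controller_config <- function(mode = c("translational", "rotational"),
                              delay_ms = 25, tau_neural_ms = 35,
                              tau_active_ms = 15, baseline_scale = 1,
                              reference_time_ms = NA_real_,
                              saturation_ceiling = 1,
                              pure_axial_threshold = 0.5,
                              direction_from_delayed = FALSE,
                              euler_convention = "intrinsic",
                              constraint_signal = c("pid", "activation")) {
  mode <- match.arg(mode)
  stopifnot(delay_ms >= 0, tau_neural_ms > 0, tau_active_ms > 0,
            baseline_scale >= 0, saturation_ceiling > 0,
            saturation_ceiling <= 1)
  structure(list(mode = mode, delay_ms = delay_ms,
                 tau_neural_ms = tau_neural_ms,
                 tau_active_ms = tau_active_ms,
                 baseline_scale = baseline_scale,
                 reference_time_ms = reference_time_ms,
                 saturation_ceiling = saturation_ceiling,
                 pure_axial_threshold = pure_axial_threshold,
                 direction_from_delayed = direction_from_delayed,
                 euler_convention = euler_convention,
                 constraint_signal = match.arg(constraint_signal)),
            class = "controller_config")
}

#' Baseline activity per muscle group
#'
#' Quiet-sitting activity: each group/side's minimum normalized STP
#' weight across the 26 directions, scaled by `baseline_scale`.
#'
#' @param stps normalized `stp_set`.
#' @param baseline_scale multiplier (default 1).
#' @return named vector over `<group>.<side>` rows.
#' @export
baseline_activity <- function(stps, baseline_scale = 1) {
  stopifnot(inherits(stps, "stp_set"))
  pmin(baseline_scale * apply(stps$weights, 1, min), 1)
}

#' One full controller step
#'
#' Composes the chain for a single sample: error from the sensed
#' kinematics, delayed error lookup, PID, saturation, STP direction
#' query, baseline addition, and one activation-dynamics step. Degenerate
#' directions (rotation angle below tolerance, or zero horizontal
#' displacement) emit zero directional drive so only baseline passes
#' through. This function is the single-step reference implementation;
#' [simulate_plant()] inlines the same chain for speed and is tested
#' against it.
#'
#' @param state controller state: list with `times`, `errors` (history up
#'   to and including `t`), `integral`, `prev_delayed`, `excitation`,
#'   `activation`.
#' @param error current scalar error (radians).
#' @param direction list with `bend_azimuth`, `axial_component`,
#'   `degenerate` (as from [axis_to_direction()] or
#'   [translational_error()]).
#' @param t current time, ms.
#' @param dt step, ms.
#' @param config a [controller_config()].
#' @param gains a [controller_gains()].
#' @param stps normalized `stp_set`.
#' @param baseline per-muscle baseline (from [baseline_activity()]).
#' @return updated state, with fields `u` (raw PID response), `u_sat`,
#'   `drive` and the new activation state.
#' @export
controller_step <- function(state, error, direction, t, dt, config, gains,
                            stps, baseline) {
  state$times <- c(state$times, t)
  state$errors <- c(state$errors, error)
  e_del <- delay_signal(state$times, state$errors, t, config$delay_ms)
  state$integral <- state$integral + dt * (state$prev_delayed + e_del) / 2
  deriv <- if (t <= 0) 0 else (e_del - state$prev_delayed) / dt
  u <- gains$Kp * e_del + gains$Ki * state$integral + gains$Kd * deriv
  state$prev_delayed <- e_del
  u_sat <- saturate(u, config$saturation_ceiling)
  if (isTRUE(direction$degenerate)) {
    w <- numeric(length(baseline))
  } else {
    w <- lookup_weights(stps, direction$bend_azimuth,
                        direction$axial_component,
                        config$pure_axial_threshold)
  }
  drive <- distribute(u_sat, w, baseline)
  dyn <- activation_dynamics_step(list(excitation = state$excitation,
                                       activation = state$activation),
                                  drive, dt, config$tau_neural_ms,
                                  config$tau_active_ms)
  state$excitation <- dyn$excitation
  state$activation <- dyn$activation
  state$u <- u; state$u_sat <- u_sat; state$drive <- drive
  state
}
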