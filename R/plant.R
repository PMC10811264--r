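# Surrogate head-neck plant: a rigid head on a T1 "neck joint" with
# passive translational and rotational visco-elasticity, gravity acting on
# an anterior centre of gravity, muscle groups pulling along fixed lines
# of action, and T1 following the vehicle pulse through a first-order
# seat-compliance filter. The plant is explicitly a desk-scale surrogate
# with human-scale default parameters; it exists so the controllers can be
# exercised, tuned and rated, and all tests against it are property-based.
#
# Integration: semi-implicit (symplectic) Euler at dt = 1 ms default,
# stable for the stiff passive elements at this scale. Translation is
# integrated about the gravity-preloaded equilibrium (the vertical spring
# carries the head weight at rest), while rotation carries the full
# gravity torque of the anterior CoG, so gravity settling produces the
# static forward pitch of a torsional pendulum.

#' Surrogate head-neck plant
#'
#' @param mass head mass, kg.
#' @param inertia principal head inertia about the CoG, kg m^2 (length 3,
#'   x/y/z).
#' @param cog_offset vector from the T1 joint to the head CoG in the
#'   neutral posture, m (frame: x forward, z down, so a head CoG 2 cm
#'   anterior and 15 cm above the joint is `c(0.02, 0, -0.15)`).
#' @param rot_stiffness,rot_damping passive rotational stiffness
#'   (N m/rad) and damping (N m s/rad) per axis.
#' @param trans_stiffness,trans_damping passive translational stiffness
#'   (N/m) and damping (N s/m) per axis.
#' @param gravity gravitational acceleration, m/s^2, along +z (down).
#' @param seat_tau_s time constant of the first-order seat-compliance
#'   filter between vehicle and T1 acceleration, s (0 = pass-through).
#' @param registry muscle registry supplying group names, maximum forces
#'   and preferred-direction geometry.
#' @param muscle_elevation_deg angle of the muscle lines of action below
#'   the horizontal (all muscles pull down toward the neck base).
#' @param attach_radius_m,attach_drop_m horizontal radius and vertical
#'   drop (below the CoG) of the skull attachment points.
#' @return object of class `head_neck_plant`.
#' @export
head_neck_plant <- function(mass = 4.5,
                            inertia = c(0.020, 0.022, 0.015),
                            cog_offset = c(0.02, 0, -0.15),
                            rot_stiffness = c(12, 12, 8),
                            rot_damping = c(6, 6, 4),
                            trans_stiffness = c(1500, 1500, 40000),
                            trans_damping = c(150, 150, 1500),
                            gravity = 9.81,
                            seat_tau_s = 0.05,
                            registry = default_muscle_registry(),
                            muscle_elevation_deg = 30,
                            attach_radius_m = 0.05,
                            attach_drop_m = 0.05) {
  stopifnot(mass > 0, all(inertia > 0), all(rot_stiffness >= 0),
            all(trans_stiffness >= 0), gravity >= 0, seat_tau_s >= 0)
  structure(list(mass = mass, inertia = inertia, cog_offset = cog_offset,
                 rot_stiffness = rot_stiffness, rot_damping = rot_damping,
                 trans_stiffness = trans_stiffness,
                 trans_damping = trans_damping, gravity = gravity,
                 seat_tau_s = seat_tau_s, registry = registry,
                 muscle_elevation_deg = muscle_elevation_deg,
                 attach_radius_m = attach_radius_m,
                 attach_drop_m = attach_drop_m),
            class = "head_neck_plant")
}

#' @export
print.head_neck_plant <- function(x, ...) {
  cat(sprintf("<head_neck_plant> mass %.2f kg, CoG offset [%.3f %.3f %.3f] m, %d muscle groups\n",
              x$mass, x$cog_offset[1], x$cog_offset[2], x$cog_offset[3],
              nrow(x$registry)))
  invisible(x)
}

#' Muscle geometry for the plant
#'
#' Derives, for every group and side, the skull attachment point
#' (relative to the head CoG, head frame), the line-of-action unit vector
#' (T1 frame, pulling toward the neck base) and the maximum force. A
#' muscle whose preferred corrected-deviation azimuth is `phi` attaches
#' on the opposite side of the head (`-phi` direction) and pulls along
#' `-phi` and downward, so activating it moves the head against a
#' deviation toward `phi`. Left-side muscles mirror the right.
#'
#' @param plant a [head_neck_plant()].
#' @return list with `names` (`<group>.<side>`), `attach` (m x 3),
#'   `dir` (m x 3 unit rows), `fmax` (N).
#' @export
muscle_geometry <- function(plant) {
  reg <- plant$registry
  alpha <- plant$muscle_elevation_deg * pi / 180
  nm <- c(paste0(reg$group, ".right"), paste0(reg$group, ".left"))
  phi <- c(reg$pref_azimuth_deg, -reg$pref_azimuth_deg) * pi / 180
  h <- cbind(cos(phi), sin(phi), 0)
  attach <- -plant$attach_radius_m * h
  attach[, 3] <- plant$attach_drop_m
  dir <- cbind(-sin(alpha) * h[, 1], -sin(alpha) * h[, 2], cos(alpha))
  list(names = nm, attach = attach, dir = dir,
       fmax = rep(reg$fmax_n, 2))
}

# ---- maneuver pulses -------------------------------------------------------

#' Braking deceleration pulse
#'
#' A -x vehicle acceleration profile with a haversine onset, constant
#' plateau at the stated peak and haversine release; the haversine shape
#' is the package's choice, only peak and total active duration are
#' prescribed quantities.
#'
#' @param peak peak deceleration magnitude, m/s^2.
#' @param duration active pulse duration, s.
#' @param settle gravity-settling phase before loading, s.
#' @param loading loading-phase duration, s (pulse is truncated if
#'   shorter than `duration`); defaults follow the head-neck sub-system
#'   phase timing of 250 ms settling + 2250 ms loading.
#' @param ramp_frac fraction of `duration` used by each haversine ramp.
#' @return object of class `maneuver_pulse` (channel `"x"`), with the
#'   velocity change (time integral) in field `delta_v`.
#' @export
braking_pulse <- function(peak = 11, duration = 2.5, settle = 0.25,
                          loading = 2.25, ramp_frac = 0.2) {
  stopifnot(peak >= 0, duration > 0, settle >= 0, loading > 0,
            ramp_frac > 0, ramp_frac <= 0.5)
  structure(list(type = "braking", channel = "x", peak = peak,
                 duration = duration, settle_s = settle,
                 loading_s = loading, ramp_frac = ramp_frac,
                 delta_v = -peak * duration * (1 - ramp_frac)),
            class = "maneuver_pulse")
}

#' Biphasic lane-change pulse
#'
#' Lateral vehicle acceleration for a right turn (first phase) followed
#' by a left turn (second phase): two full haversine lobes of opposite
#' sign, each reaching the stated peak magnitude, over the total active
#' duration; the signed time integral is zero.
#'
#' @inheritParams braking_pulse
#' @return object of class `maneuver_pulse` (channel `"y"`). The first
#'   lobe is +y (rightward acceleration of the vehicle in the right
#'   turn).
#' @export
lane_change_pulse <- function(peak = 6, duration = 2, settle = 0.25,
                              loading = 1.45) {
  stopifnot(peak >= 0, duration > 0, settle >= 0, loading > 0)
  structure(list(type = "lane_change", channel = "y", peak = peak,
                 duration = duration, settle_s = settle,
                 loading_s = loading, ramp_frac = NA_real_,
                 delta_v = 0),
            class = "maneuver_pulse")
}

#' Vehicle acceleration of a pulse
#'
#' @param pulse a `maneuver_pulse`.
#' @param t time since loading onset, s (vectorized).
#' @return signed acceleration on the pulse channel, m/s^2.
#' @export
pulse_accel <- function(pulse, t) {
  stopifnot(inherits(pulse, "maneuver_pulse"))
  a <- numeric(length(t))
  d <- pulse$duration
  inside <- t >= 0 & t <= d
  ti <- t[inside]
  if (pulse$type == "braking") {
    r <- pulse$ramp_frac * d
    shape <- ifelse(ti < r, 0.5 * (1 - cos(pi * ti / r)),
                    ifelse(ti > d - r, 0.5 * (1 - cos(pi * (d - ti) / r)), 1))
    a[inside] <- -pulse$peak * shape
  } else {
    half <- d / 2
    lobe <- 0.5 * (1 - cos(2 * pi * (ti %% half) / half))
    a[inside] <- pulse$peak * lobe * ifelse(ti < half, 1, -1)
  }
  a
}

#' @export
print.maneuver_pulse <- function(x, ...) {
  cat(sprintf("<maneuver_pulse> %s, channel %s, peak %.2f m/s^2, duration %.2f s, phases %g + %g ms\n",
              x$type, x$channel, x$peak, x$duration, 1000 * x$settle_s,
              1000 * x$loading_s))
  invisible(x)
}

# ---- fast internals --------------------------------------------------------

# STP lookup by integer column index; relies on the canonical grid column
# order (left 1:8, none 9:16, right 17:24, axial_left 25, axial_right 26).
.lookup_fast <- function(W, az_rad, axial, t0) {
  az <- (az_rad * 180 / pi) %% 360
  i0 <- floor(az / 45) %% 8
  fr <- az / 45 - i0
  i1 <- (i0 + 1) %% 8
  off <- c(left = 0L, none = 8L, right = 16L)
  lw <- function(o) (1 - fr) * W[, o + i0 + 1] + fr * W[, o + i1 + 1]
  sl <- if (axial >= 0) 16L else 0L
  pcol <- if (axial >= 0) 26L else 25L
  aa <- abs(axial)
  if (aa <= t0) {
    lam <- if (t0 > 0) aa / t0 else 0
    w <- (1 - lam) * lw(8L) + lam * lw(sl)
  } else {
    lam <- (aa - t0) / (1 - t0)
    w <- (1 - lam) * lw(sl) + lam * W[, pcol]
  }
  pmin(pmax(w, 0), 1)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rodrigues_vec <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3))
  v <- rv / th
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.orthonormalize <- function(R) {
  q <- qr(R)
  Q <- qr.Q(q)
  d <- sign(diag(qr.R(q)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# ---- simulation ------------------------------------------------------------

#' Simulate the head-neck plant under a maneuver
#'
#' Runs the gravity-settling phase (T1 stationary) followed by the
#' loading phase in which T1 follows the seat-filtered vehicle pulse as
#' prescribed motion. The head's 6-DOF state is integrated
#' semi-implicitly; each muscle group applies `activation * Fmax` along
#' its line of action at its skull attachment. The controller chain
#' (delayed error, PID, saturation, STP load sharing, baseline,
#' activation dynamics) runs at every step; the load-sharing direction is
#' evaluated from the current (undelayed) kinematics by default while the
#' error magnitude is delayed.
#'
#' @param plant a [head_neck_plant()].
#' @param pulse a [braking_pulse()] or [lane_change_pulse()].
#' @param gains a [controller_gains()].
#' @param stps normalized `stp_set`, or `NULL` to disable muscles
#'   entirely (passive plant).
#' @param config a [controller_config()]; its `reference_time_ms`
#'   defaults to the end of gravity settling.
#' @param dt_ms time step, ms (default 1).
#' @param initial_state optional list with `p`, `v` (m, m/s), `rotvec`,
#'   `omega` (rad, rad/s) overriding the neutral start (used for passive
#'   response tests).
#' @return object of class `simulation_result`: `time_s`, `channels`
#'   (n x 6 matrix `head_tx..head_rz`: head CoG displacement relative to
#'   its reference position including the rotation of the CoG about the
#'   joint, and the rotation-vector components), `activations` (n x
#'   muscles), `u`, `u_sat`, `t1_accel` (n x 3), `velocity`, `omega`,
#'   `events`, plus the configuration actually used.
#' @export
simulate_plant <- function(plant, pulse, gains = controller_gains(0, 0, 0),
                           stps = NULL,
                           config = controller_config("translational"),
                           dt_ms = 1, initial_state = NULL) {
  stopifnot(inherits(plant, "head_neck_plant"),
            inherits(pulse, "maneuver_pulse"), dt_ms > 0)
  dt <- dt_ms / 1000                       # s
  settle_ms <- 1000 * pulse$settle_s
  total_ms <- settle_ms + 1000 * pulse$loading_s
  n <- as.integer(round(total_ms / dt_ms)) + 1L
  t_ms <- (seq_len(n) - 1) * dt_ms
  t_s <- t_ms / 1000
  ref_time_ms <- if (is.na(config$reference_time_ms)) settle_ms else
    config$reference_time_ms

  # prescribed T1 acceleration: vehicle pulse through seat filter
  a_veh <- pulse_accel(pulse, t_s - pulse$settle_s)
  if (plant$seat_tau_s > 0) {
    af <- numeric(n)
    k <- dt / plant$seat_tau_s
    for (i in 2:n) af[i] <- af[i - 1] + k * (a_veh[i - 1] - af[i - 1])
    a_veh <- af
  }
  t1_acc <- matrix(0, n, 3)
  t1_acc[, match(pulse$channel, c("x", "y", "z"))] <- a_veh

  use_muscles <- !is.null(stps)
  if (use_muscles) {
    stopifnot(inherits(stps, "stp_set"), stps$normalized)
    geom <- muscle_geometry(plant)
    if (!identical(rownames(stps$weights), geom$names))
      stop("stp_set rows do not match the plant's muscle geometry")
    exp_cols <- build_direction_grid()$direction_id
    if (!identical(colnames(stps$weights), exp_cols))
      stop("stp_set columns are not in canonical grid order")
    W <- stps$weights
    base <- baseline_activity(stps, config$baseline_scale)
    m <- length(base)
  } else {
    m <- 0L
    base <- numeric(0)
  }

  mass <- plant$mass; I3 <- plant$inertia
  Kt <- plant$trans_stiffness; Ct <- plant$trans_damping
  Kr <- plant$rot_stiffness; Cr <- plant$rot_damping
  cj <- plant$cog_offset
  gvec <- c(0, 0, mass * plant$gravity)
  delay_steps <- config$delay_ms / dt_ms
  rotational <- config$mode == "rotational"
  t0_ax <- config$pure_axial_threshold
  an <- 1 - exp(-dt_ms / config$tau_neural_ms)
  aact <- 1 - exp(-dt_ms / config$tau_active_ms)
  if (dt_ms > min(config$tau_neural_ms, config$tau_active_ms) / 2)
    stop("configuration error: dt must be <= min(activation time constant)/2")

  # state
  p <- c(0, 0, 0); v <- c(0, 0, 0); R <- diag(3); w <- c(0, 0, 0)
  if (!is.null(initial_state)) {
    if (!is.null(initial_state$p)) p <- initial_state$p
    if (!is.null(initial_state$v)) v <- initial_state$v
    if (!is.null(initial_state$rotvec)) R <- .rodrigues_vec(initial_state$rotvec)
    if (!is.null(initial_state$omega)) w <- initial_state$omega
  }
  exc <- base; act <- base
  errs <- numeric(n)
  integral <- 0; prev_del <- 0
  Rref <- NULL; link_ref <- NULL; ref_captured <- FALSE; ref_step <- NA_integer_

  channels <- matrix(0, n, 6,
                     dimnames = list(NULL, c("head_tx", "head_ty", "head_tz",
                                             "head_rx", "head_ry", "head_rz")))
  activations <- matrix(0, n, m)
  if (m > 0) colnames(activations) <- geom$names
  u_raw <- numeric(n); u_sat_v <- numeric(n)
  vel_out <- matrix(0, n, 3); om_out <- matrix(0, n, 3)

  for (k in seq_len(n)) {
    aa <- .axis_angle_core(R)
    rotvec <- aa$axis * aa$angle
    disp <- p + as.numeric(R %*% cj) - cj
    channels[k, ] <- c(disp, rotvec)
    if (m > 0) activations[k, ] <- act
    vel_out[k, ] <- v; om_out[k, ] <- w

    if (k == n) break
    tk <- t_ms[k]

    if (!ref_captured && tk >= ref_time_ms) {
      Rref <- R; link_ref <- cj + disp
      ref_captured <- TRUE; ref_step <- k
    }

    # --- controller ---
    degen <- TRUE; azq <- 0; axq <- 0; err <- 0
    if (ref_captured) {
      if (rotational) {
        rel <- .axis_angle_core(crossprod(Rref, R))
        err <- rel$angle
        if (!rel$degenerate && all(is.finite(rel$axis))) {
          degen <- FALSE
          azq <- atan2(rel$axis[1], -rel$axis[2])
          axq <- min(1, max(-1, rel$axis[3]))
        }
      } else {
        link <- cj + disp
        ncur <- sqrt(sum(link^2)); nref <- sqrt(sum(link_ref^2))
        err <- acos(min(1, max(-1, sum(link * link_ref) / (ncur * nref))))
        delta <- link - link_ref
        horiz <- sqrt(delta[1]^2 + delta[2]^2)
        if (horiz > 1e-9) {
          degen <- FALSE
          azq <- atan2(delta[2], delta[1])
        }
      }
    }
    errs[k] <- err

    if (m > 0) {
      # delayed error by linear interpolation on the stored history
      tq <- k - 1 - delay_steps            # in steps, history index from 0
      if (tq < 0) {
        e_del <- 0
      } else {
        j <- floor(tq); fr <- tq - j
        e_del <- errs[j + 1] * (1 - fr) +
          (if (j + 2 <= k) errs[j + 2] else errs[j + 1]) * fr
      }
      integral <- integral + dt_ms * (prev_del + e_del) / 2
      deriv <- if (k == 1) 0 else (e_del - prev_del) / dt_ms
      u <- gains$Kp * e_del + gains$Ki * integral + gains$Kd * deriv
      prev_del <- e_del
      us <- min(config$saturation_ceiling, max(0, u))
      u_raw[k] <- u; u_sat_v[k] <- us
      wts <- if (degen) 0 else .lookup_fast(W, azq, axq, t0_ax)
      drive <- pmin(1, us * wts + base)
      exc <- exc + an * (drive - exc)
      act <- act + aact * (exc - act)
    }

    # --- dynamics ---
    aT1 <- t1_acc[k, ]
    Rc <- as.numeric(R %*% cj)
    tau <- .cross3(Rc, gvec) + .cross3(Rc, -mass * aT1) -
      Kr * rotvec - Cr * w
    Fl <- -Kt * p - Ct * v - mass * aT1
    if (m > 0) {
      f <- act * geom$fmax
      Fm <- colSums(f * geom$dir)
      Aw <- geom$attach %*% t(R)           # rows = R %*% attach_i
      Fi <- f * geom$dir
      tau_m <- c(sum(Aw[, 2] * Fi[, 3] - Aw[, 3] * Fi[, 2]),
                 sum(Aw[, 3] * Fi[, 1] - Aw[, 1] * Fi[, 3]),
                 sum(Aw[, 1] * Fi[, 2] - Aw[, 2] * Fi[, 1]))
      tau <- tau + tau_m
      Fl <- Fl + Fm
    }
    w <- w + dt * tau / I3
    R <- .rodrigues_vec(w * dt) %*% R
    v <- v + dt * Fl / mass
    p <- p + dt * v

    if (!all(is.finite(w)) || !is.finite(err))
      stop(sprintf("instability: non-finite state at step %d (t = %.3f s)",
                   k, t_s[k]))
    if (k %% 100 == 0) {
      R <- .orthonormalize(R)
      if (!all(is.finite(c(p, v, R))) || aa$angle > pi / 2)
        stop(sprintf("instability: non-finite state or |rotation| > pi/2 at step %d (t = %.3f s)",
                     k, t_s[k]))
    }
  }
  if (!all(is.finite(channels)))
    stop("instability: non-finite output channels")

  structure(list(time_s = t_s, channels = channels,
                 activations = activations, u = u_raw, u_sat = u_sat_v,
                 t1_accel = t1_acc, velocity = vel_out, omega = om_out,
                 events = list(reference_time_ms = ref_time_ms,
                               reference_step = ref_step,
                               settle_ms = settle_ms,
                               loading_ms = 1000 * pulse$loading_s),
                 gains = gains, config = config, plant = plant,
                 pulse = pulse, dt_ms = dt_ms),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  pk <- apply(abs(x$channels), 2, max)
  cat(sprintf("<simulation_result> %s, %d samples @ %g ms (%.2f s)\n",
              x$pulse$type, length(x$time_s), x$dt_ms, max(x$time_s)))
  cat(sprintf("  peak |tx, ty, tz| = %.4f, %.4f, %.4f m; peak |rx, ry, rz| = %.4f, %.4f, %.4f rad\n",
              pk[1], pk[2], pk[3], pk[4], pk[5], pk[6]))
  if (ncol(x$activations) > 0)
    cat(sprintf("  max activation %.3f, max PID response %.3f\n",
                max(x$activations), max(x$u_sat)))
  invisible(x)
}

#' @export
plot.simulation_result <- function(x, channels = c("head_tx", "head_ty",
                                                   "head_ry", "head_rx"),
                                   ...) {
  op <- graphics::par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (ch in channels) {
    graphics::plot(x$time_s, x$channels[, ch], type = "l",
                   xlab = "time [s]", ylab = ch, ...)
    graphics::abline(v = x$events$settle_ms / 1000, lty = 3)
  }
  invisible(x)
}

#' Total mechanical energy of a simulation state history
#'
#' Kinetic plus passive elastic energy at every sample; used to check
#' that the passive plant is dissipative.
#'
#' @param result a `simulation_result` from a passive run.
#' @return numeric vector of energies, J.
#' @export
mechanical_energy <- function(result) {
  # recorded displacement is p + (R - I) c; remove the rotation
  # contribution to recover the translational spring deflection p
  plant <- result$plant
  rot <- result$channels[, 4:6, drop = FALSE]
  n <- nrow(rot)
  ptrans <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- .rodrigues_vec(rot[i, ])
    ptrans[i, ] <- result$channels[i, 1:3] -
      (as.numeric(R %*% plant$cog_offset) - plant$cog_offset)
  }
  ke <- 0.5 * plant$mass * rowSums(result$velocity^2) +
    0.5 * rowSums(sweep(result$omega^2, 2, plant$inertia, "*"))
  pe <- 0.5 * rowSums(sweep(ptrans^2, 2, plant$trans_stiffness, "*")) +
    0.5 * rowSums(sweep(rot^2, 2, plant$rot_stiffness, "*"))
  ke + pe
}
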