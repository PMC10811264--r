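test_that("braking pulse reaches its plateau peak and handles the null case", {
  p1 <- braking_pulse(11, 2.5, settle = 0.75)
  tt <- seq(0, 2.5, by = 0.001)
  a <- pulse_accel(p1, tt)
  expect_equal(min(a), -11, tolerance = 1e-9)     # -x deceleration
  expect_true(all(a <= 0))
  p2 <- braking_pulse(9, 2.0, settle = 0.25)
  expect_equal(min(pulse_accel(p2, seq(0, 2, by = 0.001))), -9,
               tolerance = 1e-9)
  expect_true(all(pulse_accel(braking_pulse(0, 2.5), tt) == 0))
  # velocity change equals the analytic haversine integral
  expect_equal(sum(a) * 0.001, p1$delta_v, tolerance = 0.01)
})

test_that("lane-change pulse is biphasic with zero net impulse", {
  p <- lane_change_pulse(6, 2.0, settle = 0.65)
  tt <- seq(0, 2, by = 0.001)
  a <- pulse_accel(p, tt)
  expect_equal(max(a), 6, tolerance = 1e-6)
  expect_equal(min(a), -6, tolerance = 1e-6)
  sgn <- sign(a[abs(a) > 1e-9])
  expect_equal(sum(diff(sgn) != 0), 1)            # exactly one reversal
  expect_lt(abs(sum(a) * 0.001), 1e-6)            # antisymmetry
  expect_true(all(pulse_accel(lane_change_pulse(0, 2), tt) == 0))
})

test_that("phase timing: output length equals settle + loading exactly", {
  stps <- test_stps()
  plant <- test_plant()
  g <- controller_gains(0.2, 1e-6, 100)
  rb <- simulate_plant(plant, braking_pulse(), g, stps,
                       controller_config("translational"))
  expect_equal(length(rb$time_s), 2501)            # 250 + 2250 ms at 1 ms
  expect_equal(max(rb$time_s), 2.5)
  rl <- simulate_plant(plant, lane_change_pulse(), g, stps,
                       controller_config("translational"))
  expect_equal(length(rl$time_s), 1701)            # 250 + 1450 ms
})

test_that("zero pulse, zero gravity, neutral start leaves the head stationary", {
  plant <- head_neck_plant(gravity = 0)
  res <- simulate_plant(plant, braking_pulse(peak = 0, duration = 0.1,
                                             settle = 0, loading = 1))
  expect_equal(max(abs(res$channels)), 0)
})

test_that("gravity settling reaches the torsional-pendulum static balance angle", {
  plant <- test_plant()
  res <- simulate_plant(plant, braking_pulse(peak = 0, duration = 0.1,
                                             settle = 0, loading = 10))
  th_sim <- unname(res$channels[nrow(res$channels), "head_ry"])
  m <- plant$mass; g <- plant$gravity
  a <- plant$cog_offset[1]; h <- -plant$cog_offset[3]
  K <- plant$rot_stiffness[2]
  th_star <- stats::uniroot(function(th) K * th + m * g * (a * cos(th) -
                                                             h * sin(th)),
                            c(-1, 0))$root
  expect_lt(th_star, 0)                            # forward pitch
  expect_equal(th_sim, th_star, tolerance = 0.02)
})

test_that("the controller reduces peak forward excursion in braking", {
  stps <- test_stps()
  plant <- test_plant()
  cfg <- controller_config("translational")
  on <- simulate_plant(plant, braking_pulse(), controller_gains(0.5, 1e-5, 300),
                       stps, cfg)
  off <- simulate_plant(plant, braking_pulse(), controller_gains(0, 0, 0),
                        stps, cfg)
  expect_lt(max(on$channels[, "head_tx"]), max(off$channels[, "head_tx"]))
  # rotational controller likewise reduces peak pitch
  on_r <- simulate_plant(plant, braking_pulse(),
                         controller_gains(0.5, 1e-5, 300), stps,
                         controller_config("rotational"))
  expect_lt(max(abs(on_r$channels[, "head_ry"])),
            max(abs(off$channels[, "head_ry"])))
})

test_that("the passive plant dissipates mechanical energy", {
  plant <- head_neck_plant(gravity = 0, seat_tau_s = 0)
  res <- simulate_plant(plant, braking_pulse(peak = 0, duration = 0.1,
                                             settle = 0, loading = 2),
                        initial_state = list(rotvec = c(0.2, -0.3, 0.1),
                                             p = c(0.02, -0.01, 0.005),
                                             omega = c(0.5, 0, 0),
                                             v = c(0.1, 0, 0)))
  E <- mechanical_energy(res)
  expect_lt(max(diff(E)), 1e-8)
  expect_lt(E[length(E)], 0.01 * E[1])
})

test_that("halving the time step changes peak displacements by < 1%", {
  stps <- test_stps()
  plant <- test_plant()
  cfg <- controller_config("translational")
  g <- controller_gains(0.35, 1e-5, 250)
  r1 <- simulate_plant(plant, braking_pulse(), g, stps, cfg, dt_ms = 1)
  r2 <- simulate_plant(plant, braking_pulse(), g, stps, cfg, dt_ms = 0.5)
  for (ch in c("head_tx", "head_ry", "head_tz")) {
    p1 <- max(abs(r1$channels[, ch])); p2 <- max(abs(r2$channels[, ch]))
    expect_lt(abs(p1 - p2) / max(p2, 1e-9), 0.01)
  }
})

test_that("simulation is bit-reproducible", {
  stps <- test_stps()
  plant <- test_plant()
  cfg <- controller_config("rotational")
  g <- controller_gains(0.4, 1e-5, 200)
  r1 <- simulate_plant(plant, lane_change_pulse(), g, stps, cfg)
  r2 <- simulate_plant(plant, lane_change_pulse(), g, stps, cfg)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$activations, r2$activations)
})

test_that("all emitted activations lie in [0, 1] for feasible and saturating gains", {
  stps <- test_stps()
  plant <- test_plant()
  for (mode in c("translational", "rotational")) {
    for (g in list(c(0.1, 1e-6, 100), c(2, 1e-4, 1000))) {
      res <- simulate_plant(plant, braking_pulse(),
                            controller_gains(g[1], g[2], g[3]), stps,
                            controller_config(mode))
      expect_true(all(res$activations >= 0 & res$activations <= 1))
      expect_true(all(res$u_sat >= 0 & res$u_sat <= 1))
    }
  }
})

test_that("instability is reported with the offending step", {
  # an absurdly stiff undamped plant at a too-coarse step diverges
  plant <- head_neck_plant(rot_stiffness = c(5e5, 5e5, 5e5),
                           rot_damping = c(0, 0, 0), gravity = 0)
  expect_error(simulate_plant(plant, braking_pulse(),
                              initial_state = list(rotvec = c(0, 0.3, 0))),
               "instability")
})
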