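test_that("curve_mapping_distance is zero at identity and orders discrepancies", {
  t <- seq(0, 2, by = 0.01)
  y <- 0.1 * sin(pi * t)
  expect_equal(curve_mapping_distance(t, y, t, y), 0)
  # strictly increasing in a constant offset
  d <- vapply(c(0.005, 0.01, 0.02, 0.05),
              function(c) curve_mapping_distance(t, y + c, t, y),
              numeric(1))
  expect_true(all(diff(d) > 0))
  # larger amplitude error scores worse
  expect_gt(curve_mapping_distance(t, 2 * y, t, y),
            curve_mapping_distance(t, 1.5 * y, t, y))
  expect_error(curve_mapping_distance(t, y, t, rep(0, length(t))),
               "identically zero")
})

test_that("rms_distance agrees with the direct formula", {
  t <- seq(0, 1, by = 0.01)
  y <- sin(2 * pi * t)
  expect_equal(rms_distance(t, y + 0.1, t, y, n_map = length(t)), 0.1,
               tolerance = 1e-9)
  expect_equal(rms_distance(t, y, t, y), 0)
})

test_that("saturation-penalized activity orders runs by saturated duration", {
  mk <- function(u) {
    structure(list(u_sat = u, activations = matrix(0, length(u), 0),
                   dt_ms = 1,
                   config = list(constraint_signal = "pid")),
              class = "simulation_result")
  }
  # never saturated: response is the maximum activity itself
  expect_equal(saturation_penalized_activity(mk(c(0.2, 0.84, 0.5))), 0.84)
  # at the ceiling with zero additional duration contributes the ceiling
  expect_equal(saturation_penalized_activity(mk(c(0.5, 0.99))),
               0.99 + 0.001)
  # longer saturation gives a strictly larger response
  u_short <- c(rep(0.5, 100), rep(1, 100))    # 0.1 s saturated
  u_long <- c(rep(0.5, 100), rep(1, 400))     # 0.4 s saturated
  r1 <- saturation_penalized_activity(mk(u_short))
  r2 <- saturation_penalized_activity(mk(u_long))
  expect_gt(r2, r1)
  expect_equal(r2 - r1, 0.3, tolerance = 1e-9)
})

test_that("srsm_optimize recovers a convex quadratic optimum within 2% of range", {
  space <- default_design_space(start = c(a = 0.1, b = 0.1),
                                min = c(a = 0, b = 0),
                                max = c(a = 1, b = 1))
  sim <- function(d) list(objectives = (d[["a"]] - 0.7)^2 +
                            2 * (d[["b"]] - 0.3)^2, constraint = 0)
  for (sd in 1:3) {
    out <- srsm_optimize(sim, space, seed = sd)
    expect_lte(out$iterations, 10)
    expect_lt(abs(out$best_design[["a"]] - 0.7), 0.02)
    expect_lt(abs(out$best_design[["b"]] - 0.3), 0.02)
    expect_false(out$constraint_violated)
  }
})

test_that("a linear objective is fitted exactly by the linear metamodel", {
  space <- default_design_space(start = c(a = 0.5, b = 0.5),
                                min = c(a = 0, b = 0),
                                max = c(a = 1, b = 1))
  sim <- function(d) list(objectives = 2 + 3 * d[["a"]] - d[["b"]],
                          constraint = 0)
  out <- srsm_optimize(sim, space, max_iter = 2, seed = 1)
  # every simulated design must lie on the fitted plane: the minimum of a
  # linear objective over the region is at the vertex (0, 1)
  h <- out$history
  expect_equal(h$objective, 2 + 3 * h$a - h$b, tolerance = 1e-12)
  expect_equal(out$best_objective, min(h$objective))
})

test_that("region ranges stay within the global bounds and respect zoom = 1", {
  space <- default_design_space(start = c(a = 0.9, b = 0.1),
                                min = c(a = 0, b = 0),
                                max = c(a = 1, b = 1))
  sim <- function(d) list(objectives = (d[["a"]] - 0.95)^2 + d[["b"]]^2,
                          constraint = 0)
  out <- srsm_optimize(sim, space, seed = 2)
  reg <- out$regions
  expect_true(all(reg$center_a - pmin(reg$range_a, reg$center_a) >= 0))
  expect_true(all(reg$center_a <= 1 & reg$center_b <= 1))
  expect_true(all(h <- out$history$a <= 1 & out$history$a >= 0))
  # zoom = 1 disables domain reduction (single-stage RSM baseline)
  out1 <- srsm_optimize(sim, space, zoom = 1, osc_damp = 1, max_iter = 4,
                        seed = 2)
  expect_equal(out1$regions$range_a, rep(out1$regions$range_a[1], 4))
})

test_that("the optimizer is deterministic given the seed", {
  space <- default_design_space(start = c(a = 0.2, b = 0.2),
                                min = c(a = 0, b = 0),
                                max = c(a = 1, b = 1))
  sim <- function(d) list(objectives = (d[["a"]] - 0.6)^2 +
                            (d[["b"]] - 0.4)^2,
                          constraint = d[["a"]])
  o1 <- srsm_optimize(sim, space, seed = 7)
  o2 <- srsm_optimize(sim, space, seed = 7)
  expect_identical(o1$best_design, o2$best_design)
  expect_identical(o1$history, o2$history)
})

test_that("constraint handling reports violation and errors on infeasible starts", {
  space <- default_design_space(start = c(a = 0.5, b = 0.5),
                                min = c(a = 0, b = 0),
                                max = c(a = 1, b = 1))
  # constraint can never be met: best design flagged
  sim_bad <- function(d) list(objectives = d[["a"]]^2, constraint = 2)
  expect_error(srsm_optimize(sim_bad, space, seed = 1),
               "infeasible start")
  # feasible start but optimum at the constraint boundary
  sim_con <- function(d) list(objectives = (d[["a"]] - 1)^2,
                              constraint = d[["a"]])
  out <- srsm_optimize(sim_con, space, ceiling = 0.7, seed = 1)
  expect_false(out$constraint_violated)
  expect_lte(out$best_constraint, 0.7)
  expect_gt(out$best_design[["a"]], 0.5)
})

test_that("the design-space defaults match the published optimization settings", {
  sp <- default_design_space()
  expect_equal(sp$start, c(Kp = 0.1, Ki = 1e-6, Kd = 100))
  expect_equal(sp$min, c(Kp = 0, Ki = 0, Kd = 0))
  expect_equal(sp$max, c(Kp = 2, Ki = 0.1, Kd = 1000))
  # the Ki ceiling is the rounded-up maximum theoretical integral gain
  expect_equal(sp$max[["Ki"]], ki_tuning_ceiling())
})
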