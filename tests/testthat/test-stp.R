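test_that("direction grid has the fixed 26-entry structure", {
  g <- build_direction_grid()
  expect_equal(nrow(g), 26)
  expect_equal(sum(g$pure_axial), 2)
  expect_equal(sum(g$axial_level == "none" & !g$pure_axial), 8)
  expect_setequal(g$axial_level[g$pure_axial], c("left", "right"))
  expect_false(anyDuplicated(g$direction_id) > 0)
  # deterministic ordering: azimuth ascending within level, pure last
  expect_true(all(diff(g$bend_azimuth_deg[g$axial_level == "none" &
                                            !g$pure_axial]) > 0))
  expect_equal(which(g$pure_axial), c(25, 26))
})

test_that("default registry has 11 groups with acyclic substitutes", {
  reg <- default_muscle_registry()
  expect_equal(nrow(reg), 11)
  expect_true(all(stats::na.omit(reg$substitute) %in% reg$group))
})

test_that("combine_sources applies the source priority and substitutes", {
  grid <- build_direction_grid()
  reg <- default_muscle_registry()
  # two records for one direction: isometric beats nothing, dynamic+MVIC
  # beats both dynamic-peak and isometric
  rec <- data.frame(
    experiment_id = c("iso", "dyn_mvic", "dyn_peak"),
    condition = c("isometric", "dynamic", "dynamic"),
    normalization = c("peak", "MVIC", "peak"),
    muscle = "splenius", side = "right",
    direction_id = "b000_none",
    activity = c(0.3, 0.6, 0.9))
  # cover the rest of the grid from a single low-priority source for all
  # groups except the ones relying on substitutes
  fill <- expand.grid(muscle = setdiff(reg$group,
                                       c("multifidus", "suboccipital")),
                      direction_id = grid$direction_id,
                      stringsAsFactors = FALSE)
  fill <- fill[!(fill$muscle == "splenius" &
                   fill$direction_id == "b000_none"), ]
  fill <- data.frame(experiment_id = "iso", condition = "isometric",
                     normalization = "peak", muscle = fill$muscle,
                     side = "right", direction_id = fill$direction_id,
                     activity = 0.5)
  out <- combine_sources(rbind(rec, fill), reg)
  got <- out[out$group == "splenius" & out$direction_id == "b000_none", ]
  expect_equal(got$activity, 0.6)          # dynamic+MVIC wins
  expect_equal(got$experiment_id, "dyn_mvic")
  # substituted groups carry provenance and the substitute's value
  sub <- out[out$group == "multifidus", ]
  expect_true(all(sub$provenance == "substituted:semispinalis_cervicis"))
  expect_true(all(sub$activity == 0.5))
  # single-source identity (full single-experiment coverage)
  fill_full <- rbind(fill,
                     data.frame(experiment_id = "iso",
                                condition = "isometric",
                                normalization = "peak",
                                muscle = "splenius", side = "right",
                                direction_id = "b000_none",
                                activity = 0.5))
  one <- combine_sources(fill_full, reg)
  expect_true(all(one$activity == 0.5))
  # coverage gap raises an error naming the hole
  gap <- fill[fill$muscle != "sternocleidomastoid", ]
  expect_error(combine_sources(gap, reg), "coverage gap")
})

test_that("mirroring reflects azimuth, swaps axial levels and is an involution", {
  grid <- build_direction_grid()
  set.seed(5)
  w <- stats::setNames(runif(26), grid$direction_id)
  stp <- stp_pattern("splenius", "right", w)
  m <- mirror_right_to_left(stp)
  expect_equal(m$side, "left")
  # right lateral bend (azimuth 90, no axial) maps to left (270)
  expect_equal(unname(m$weights["b270_none"]), unname(w["b090_none"]))
  # flexion + right axial maps to flexion + left axial
  expect_equal(unname(m$weights["b000_left"]), unname(w["b000_right"]))
  expect_equal(unname(m$weights["axial_left"]), unname(w["axial_right"]))
  # involution: mirroring back recovers the original weights
  m2 <- mirror_right_to_left(structure(list(muscle_group = m$muscle_group,
                                            side = "right",
                                            weights = m$weights),
                                       class = "stp_pattern"))
  expect_equal(m2$weights[names(w)], w)
  expect_error(mirror_right_to_left(m), "right-side")
})

test_that("per-direction normalization is exact, idempotent and scale invariant", {
  stps <- test_stps()
  expect_true(all(abs(apply(stps$weights, 2, max) - 1) < 1e-12))
  # idempotence
  again <- normalize_per_direction(stps)
  expect_equal(again$weights, stps$weights)
  # scale invariance: scaling raw activities per direction by c > 0
  raw <- stp_set_from_combined(combine_sources(generate_stp_fixture(1)),
                               normalize = FALSE)
  scaled <- raw
  scaled$weights <- sweep(raw$weights, 2, seq(0.5, 3, length.out = 26), "*")
  expect_equal(normalize_per_direction(scaled)$weights,
               normalize_per_direction(raw)$weights, tolerance = 1e-12)
  # simple arithmetic case: weights {0.2, 0.4} -> {0.5, 1}
  two <- raw
  two$weights[] <- 0.3
  two$weights[1, ] <- 0.2; two$weights[2, ] <- 0.4
  nt <- normalize_per_direction(two)
  expect_equal(unname(nt$weights[1, 1]), 0.5)
  expect_equal(unname(nt$weights[2, 1]), 1.0)
  # degenerate direction errors
  zero <- raw; zero$weights[, 3] <- 0
  expect_error(normalize_per_direction(zero), "degenerate direction")
})

test_that("mirroring commutes with normalization", {
  combined <- combine_sources(generate_stp_fixture(1))
  # mirror-then-normalize is what stp_set_from_combined does; normalizing
  # the right-side block first and mirroring after must agree, because
  # the per-direction maximum is itself mirror-symmetric
  stps <- stp_set_from_combined(combined)
  grid <- build_direction_grid()
  map <- stats::setNames(
    colnames(stps$weights),
    vapply(colnames(stps$weights), function(id) {
      i <- match(id, grid$direction_id)
      if (grid$pure_axial[i])
        paste0("axial_", c(left = "right", right = "left")[grid$axial_level[i]])
      else
        sprintf("b%03d_%s", (360 - grid$bend_azimuth_deg[i]) %% 360,
                c(left = "right", none = "none",
                  right = "left")[grid$axial_level[i]])
    }, ""))
  for (g in c("splenius", "sternocleidomastoid")) {
    right <- stps$weights[paste0(g, ".right"), ]
    left <- stps$weights[paste0(g, ".left"), ]
    expect_equal(unname(left[map[names(right)]]), unname(right),
                 tolerance = 1e-12)
  }
})

test_that("lookup_weights interpolates the grid continuously and stays in [0, 1]", {
  stps <- test_stps()
  W <- stps$weights
  thr <- 0.5
  # grid-point identity at the three axial anchors
  expect_equal(lookup_weights(stps, 0, 0), W[, "b000_none"])
  expect_equal(lookup_weights(stps, pi / 2, thr), W[, "b090_right"])
  expect_equal(lookup_weights(stps, 3 * pi / 4, -thr), W[, "b135_left"])
  expect_equal(lookup_weights(stps, 1.234, 1), W[, "axial_right"])
  # azimuth midpoint = arithmetic mean of adjacent grid vectors
  mid <- lookup_weights(stps, 22.5 * pi / 180, 0)
  expect_equal(mid, (W[, "b000_none"] + W[, "b045_none"]) / 2,
               tolerance = 1e-12)
  # axial 0 uses only no-axial entries
  expect_equal(lookup_weights(stps, pi, 0), W[, "b180_none"])
  # periodic continuity in azimuth and continuity across the axial
  # threshold, bounded outputs
  eps <- 1e-7
  expect_equal(lookup_weights(stps, 2 * pi - eps, 0.3),
               lookup_weights(stps, 0, 0.3), tolerance = 1e-5)
  expect_equal(lookup_weights(stps, 1, thr - eps),
               lookup_weights(stps, 1, thr + eps), tolerance = 1e-5)
  set.seed(9)
  for (i in 1:50) {
    w <- lookup_weights(stps, runif(1, -10, 10), runif(1, -1, 1))
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_error(lookup_weights(stps, NaN, 0), "non-finite")
})

test_that("fast in-simulation lookup agrees with the reference implementation", {
  stps <- test_stps()
  set.seed(13)
  for (i in 1:50) {
    az <- runif(1, -2 * pi, 2 * pi); ax <- runif(1, -1, 1)
    expect_equal(neckcontrol:::.lookup_fast(stps$weights, az, ax, 0.5),
                 lookup_weights(stps, az, ax, 0.5), tolerance = 1e-12)
  }
})
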