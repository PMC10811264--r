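# Synthetic fixture generators. The appendix EMG tables and volunteer
# displacement corridors behind the original controllers are not
# redistributable, so the package ships generators for (a) cosine-tuned
# EMG source tables from three synthetic "experiments" spanning the three
# condition/normalization classes, and (b) smooth volunteer-like
# mean +/- SD displacement corridors for braking and lane change. Both
# are deterministic given their seed and are labelled synthetic in every
# output they produce.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# plausible activity of `group` (registry row) at one grid direction:
# cosine tuning about the group's preferred azimuth, modulated by axial
# level, floored at a small co-contraction level
.fixture_activity <- function(reg_row, az_deg, level, pure) {
  if (pure) {
    lv <- if (level == "right") 1 else -1
    act <- 0.1 + 0.8 * max(0, reg_row$pref_axial * lv)
  } else {
    lv <- c(left = -1, none = 0, right = 1)[[level]]
    cosal <- cos((az_deg - reg_row$pref_azimuth_deg) * pi / 180)
    act <- 0.15 + 0.85 * max(0, cosal)^2
    act <- act * max(0.05, 1 + 0.5 * reg_row$pref_axial * lv)
  }
  act
}

#' Generate synthetic EMG source tables for STP construction
#'
#' Three synthetic experiments spanning the source-priority classes:
#' `perturbations` (dynamic, MVIC-normalized, horizontal-plane
#' directions only, i.e. the 8 no-axial bend azimuths), `experiment1`
#' (dynamic, within-experiment-peak normalized, all 26 directions but
#' with deliberate holes at the pure-axial rows for the
#' sternocleidomastoid group) and `experiment2` (isometric,
#' peak-normalized, all 26 directions). Groups absent from all three
#' tables are covered through their registry substitutes, so the tables
#' jointly cover every (group, direction) cell and the priority merging
#' of [combine_sources()] is exercised end to end.
#'
#' Activities follow a cosine tuning curve about each group's preferred
#' direction with axial-level modulation and multiplicative log-normal
#' noise; peak-normalized experiments are rescaled to a within-experiment
#' maximum of 1.
#'
#' @param seed integer seed; generation is deterministic given the seed.
#' @param registry muscle registry (defines groups and preferred
#'   directions).
#' @param noise_sd log-scale SD of the multiplicative noise.
#' @return data.frame of source records (see [combine_sources()]).
#' @export
generate_stp_fixture <- function(seed = 1,
                                 registry = default_muscle_registry(),
                                 noise_sd = 0.08) {
  grid <- build_direction_grid()
  experiments <- list(
    perturbations = list(condition = "dynamic", normalization = "MVIC",
                         groups = c("sternocleidomastoid", "sternohyoid",
                                    "longus_colli", "scalenus",
                                    "trapezius", "splenius",
                                    "semispinalis_capitis",
                                    "semispinalis_cervicis"),
                         dirs = grid$direction_id[grid$axial_level == "none" &
                                                    !grid$pure_axial]),
    experiment1 = list(condition = "dynamic", normalization = "peak",
                       groups = c("sternocleidomastoid", "longus_colli",
                                  "scalenus", "trapezius", "splenius",
                                  "semispinalis_capitis",
                                  "semispinalis_cervicis"),
                       dirs = grid$direction_id,
                       holes = data.frame(group = "sternocleidomastoid",
                                          direction_id = c("axial_left",
                                                           "axial_right"))),
    experiment2 = list(condition = "isometric", normalization = "peak",
                       groups = c("sternocleidomastoid", "longus_colli",
                                  "scalenus", "trapezius", "splenius",
                                  "semispinalis_capitis",
                                  "semispinalis_cervicis"),
                       dirs = grid$direction_id))
  .with_seed(seed, {
    rows <- list()
    for (ex in names(experiments)) {
      spec <- experiments[[ex]]
      for (g in spec$groups) {
        reg_row <- registry[registry$group == g, ]
        for (d in spec$dirs) {
          if (!is.null(spec$holes) &&
              any(spec$holes$group == g & spec$holes$direction_id == d))
            next
          gr <- grid[grid$direction_id == d, ]
          act <- .fixture_activity(reg_row, gr$bend_azimuth_deg,
                                   gr$axial_level, gr$pure_axial)
          act <- act * exp(stats::rnorm(1, 0, noise_sd))
          rows[[length(rows) + 1]] <-
            data.frame(experiment_id = ex, condition = spec$condition,
                       normalization = spec$normalization, muscle = g,
                       side = "right", direction_id = d,
                       activity = act, stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rows)
    # MVIC-normalized values are fractions of MVIC (sub-maximal here);
    # peak-normalized experiments scale to a within-experiment max of 1
    for (ex in names(experiments)) {
      sel <- records$experiment_id == ex
      if (experiments[[ex]]$normalization == "peak") {
        records$activity[sel] <- records$activity[sel] /
          max(records$activity[sel])
      } else {
        records$activity[sel] <- 0.8 * records$activity[sel] /
          max(records$activity[sel])
      }
    }
    records
  })
}

# smoothstep on [0, 1]
.sstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Generate volunteer-like reference corridors
#'
#' Smooth mean +/- SD displacement corridors emulating volunteer head
#' responses: for braking, forward translation (`head_tx`), a small
#' vertical drop (`head_tz`) and forward-flexion pitch (`head_ry`,
#' negative under the package sign convention); for lane change,
#' biphasic lateral translation (`head_ty`, leftward first during the
#' right turn, with exactly one sign reversal), roll (`head_rx`) and yaw
#' (`head_rz`). Peaks rise after pulse onset and decay mildly during
#' steady state; SD bands are strictly positive. A seeded low-frequency
#' multiplicative ripple individualizes the means without breaking the
#' shape properties.
#'
#' @param seed integer seed.
#' @param maneuver `"braking"` or `"lane_change"`.
#' @param dt corridor sampling step, s.
#' @param settle settling time preceding loading onset, s.
#' @return named list of [reference_corridor()] objects.
#' @export
generate_corridor_fixture <- function(seed = 1,
                                      maneuver = c("braking",
                                                   "lane_change"),
                                      dt = 0.01, settle = 0.25) {
  maneuver <- match.arg(maneuver)
  .with_seed(seed, {
    if (maneuver == "braking") {
      tt <- seq(0, settle + 2.25, by = dt)
      u <- (tt - settle - 0.1) / 0.9          # rise over ~0.9 s
      rise <- .sstep(u)
      decay <- 1 - 0.08 * .sstep((tt - settle - 1.3) / 0.7)
      shape <- rise * decay
      ripple <- 1 + 0.04 * sin(2 * pi * tt / 0.9 +
                                 stats::runif(1, 0, 2 * pi)) * rise
      chans <- list(head_tx = 0.15 * shape * ripple,
                    head_tz = 0.03 * shape,
                    head_ry = -0.25 * shape * ripple)
    } else {
      tt <- seq(0, settle + 1.45, by = dt)
      tau <- pmin(1, pmax(0, (tt - settle) / 2))  # pulse fraction
      lobe <- sin(2 * pi * tau)                   # one sign reversal
      ramp <- .sstep(tau / 0.15)                  # soften onset
      ripple <- 1 + 0.04 * sin(2 * pi * tt / 0.8 +
                                 stats::runif(1, 0, 2 * pi)) * ramp
      chans <- list(head_ty = -0.05 * lobe * ramp * ripple,
                    head_rx = -0.12 * lobe * ramp,
                    head_rz = 0.06 * lobe * ramp * ripple)
    }
    out <- lapply(names(chans), function(ch) {
      m <- chans[[ch]]
      peak <- max(abs(m))
      reference_corridor(ch, tt, m, pmax(0.25 * abs(m), 0.05 * peak))
    })
    stats::setNames(out, names(chans))
  })
}
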