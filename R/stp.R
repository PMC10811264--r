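# Spatial tuning patterns (STPs): per-muscle-group maps from movement
# direction to normalized activation weight, used to distribute one common
# PID drive across the neck muscles. Directions live on a fixed grid of
# eight flexion/extension + lateral-bending azimuths (45 deg spacing) at
# three axial-rotation levels (left / none / right) plus two pure axial
# rotations: 8 * 3 + 2 = 26 directions. There is one pattern per muscle
# group and side; right-side patterns are built from source data and
# mirrored to the left.
#
# Bend azimuth convention: 0 = forward (flexion), +90 deg = rightward
# (right lateral bend), 180 = rearward (extension); azimuths are stored in
# [0, 360) degrees on the grid. A pattern value at a direction is the
# muscle's relative activity when returning the head from that deviation.

.AXIAL_LEVELS <- c("left", "none", "right")

#' The fixed 26-direction STP grid
#'
#' Eight bend azimuths (0, 45, ..., 315 degrees) at each of three axial
#' rotation levels, plus two pure axial rotations. Ordering is bend
#' azimuth ascending within axial level (left, none, right), pure-axial
#' entries last.
#'
#' @return data.frame with columns `direction_id`, `bend_azimuth_deg`,
#'   `bend_azimuth` (radians; `NA` for pure axial), `axial_level`
#'   (`"left"`, `"none"`, `"right"`), `pure_axial` (logical).
#' @export
build_direction_grid <- function() {
  az <- seq(0, 315, by = 45)
  bend <- do.call(rbind, lapply(.AXIAL_LEVELS, function(lv) {
    data.frame(direction_id = sprintf("b%03d_%s", az, lv),
               bend_azimuth_deg = az,
               bend_azimuth = az * pi / 180,
               axial_level = lv,
               pure_axial = FALSE,
               stringsAsFactors = FALSE)
  }))
  pure <- data.frame(direction_id = c("axial_left", "axial_right"),
                     bend_azimuth_deg = NA_real_,
                     bend_azimuth = NA_real_,
                     axial_level = c("left", "right"),
                     pure_axial = TRUE,
                     stringsAsFactors = FALSE)
  rbind(bend, pure)
}

#' Default neck muscle-group registry
#'
#' Eleven bilateral neck muscle groups with substitute-group links (used
#' when a group is absent from every EMG source for a direction), per-side
#' maximum forces, and the plant-facing geometry parameters: the preferred
#' corrected-deviation azimuth of the right-side muscle (degrees; 0 =
#' corrects forward deviation, positive = rightward) and an axial
#' preference in `[-1, 1]` (positive = recruited in right axial rotation).
#' Group membership, substitutes, forces and geometry are package defaults
#' chosen to be anatomically plausible, not measured quantities. The
#' `fmax_n` values are effective surrogate strengths, deliberately below
#' anatomical group forces: the surrogate concentrates each group on a
#' single line of action with a fixed lever, and the effective forces are
#' sized so that proportional/derivative gains of the magnitude used for
#' full human body models drive the surrogate in its sensible operating
#' range rather than into immediate saturation.
#'
#' @return data.frame of class `muscle_registry` with columns `group`,
#'   `substitute`, `fmax_n`, `pref_azimuth_deg`, `pref_axial`.
#' @export
default_muscle_registry <- function() {
  reg <- data.frame(
    group = c("sternocleidomastoid", "sternohyoid", "longus_colli",
              "scalenus", "trapezius", "levator_scapulae", "splenius",
              "semispinalis_capitis", "semispinalis_cervicis",
              "multifidus", "suboccipital"),
    substitute = c(NA, "sternocleidomastoid", "scalenus", NA, NA,
                   "trapezius", NA, NA, "semispinalis_capitis",
                   "semispinalis_cervicis", "semispinalis_capitis"),
    fmax_n = c(50, 10, 18, 24, 40, 24, 30, 36, 24, 16, 12),
    pref_azimuth_deg = c(160, 180, 175, 140, 30, 60, 20, 5, 10, 8, 2),
    pref_axial = c(-0.5, 0, 0, -0.2, 0.2, 0.3, 0.5, 0.1, 0.3, 0.3, 0.6),
    stringsAsFactors = FALSE)
  class(reg) <- c("muscle_registry", "data.frame")
  reg
}

.check_registry <- function(registry) {
  stopifnot(is.data.frame(registry),
            all(c("group", "substitute", "fmax_n") %in% names(registry)))
  subs <- registry$substitute
  bad <- !is.na(subs) & !(subs %in% registry$group)
  if (any(bad))
    stop("substitute groups not in registry: ",
         paste(subs[bad], collapse = ", "))
  # no cycles: follow each chain at most nrow steps
  for (g in registry$group) {
    seen <- character(); cur <- g
    while (!is.na(cur)) {
      if (cur %in% seen) stop("substitute cycle involving group ", g)
      seen <- c(seen, cur)
      cur <- registry$substitute[match(cur, registry$group)]
    }
  }
  invisible(registry)
}

.PRIORITY_LEVELS <- c("dynamic+MVIC" = 1L, "dynamic" = 2L, "isometric" = 3L)

.source_priority <- function(condition, normalization) {
  ifelse(condition == "dynamic" & normalization == "MVIC", 1L,
         ifelse(condition == "dynamic", 2L, 3L))
}

#' Merge EMG source tables into raw per-group activities
#'
#' For each (muscle group, direction) the single best source record is
#' selected by priority: (1) dynamic condition normalized by maximum
#' voluntary isometric contraction (MVIC), (2) dynamic with
#' within-experiment-peak normalization, (3) isometric. Ties within a
#' priority level are broken by experiment id (alphabetical, documented).
#' A group absent from every source at a direction takes the value of its
#' substitute group (resolved recursively), with provenance
#' `"substituted:<group>"`. Directions that remain uncovered raise a
#' coverage-gap error listing the holes.
#'
#' @param records data.frame of source records with columns
#'   `experiment_id`, `condition` (`"dynamic"`/`"isometric"`),
#'   `normalization` (`"MVIC"`/`"peak"`), `muscle`, `side` (`"right"`;
#'   sides are combined upstream), `direction_id`, `activity` (>= 0).
#' @param registry a [default_muscle_registry()]-style data.frame.
#' @return data.frame with one row per (group, direction): `group`,
#'   `direction_id`, `activity`, `experiment_id`, `priority`, `provenance`.
#' @export
combine_sources <- function(records, registry = default_muscle_registry()) {
  .check_registry(registry)
  need <- c("experiment_id", "condition", "normalization", "muscle",
            "side", "direction_id", "activity")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$activity < 0)) stop("activities must be >= 0")
  grid <- build_direction_grid()
  if (!all(records$direction_id %in% grid$direction_id))
    stop("unknown direction_id in records")
  if (anyDuplicated(records[c("experiment_id", "muscle", "side", "direction_id")]))
    stop("duplicate (experiment, muscle, side, direction) records")
  records$priority <- .source_priority(records$condition, records$normalization)

  pick <- function(group, dir) {
    cand <- records[records$muscle == group & records$direction_id == dir, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$priority, cand$experiment_id), ]
    cand[1, ]
  }
  rows <- vector("list", nrow(registry) * nrow(grid)); i <- 0L
  holes <- character()
  for (g in registry$group) {
    for (d in grid$direction_id) {
      best <- pick(g, d)
      prov <- "direct"
      src <- g
      while (is.null(best)) {                 # walk the substitute chain
        src <- registry$substitute[match(src, registry$group)]
        if (is.na(src)) break
        best <- pick(src, d)
        if (!is.null(best)) prov <- paste0("substituted:", src)
      }
      if (is.null(best)) { holes <- c(holes, paste(g, d, sep = "@")); next }
      i <- i + 1L
      rows[[i]] <- data.frame(group = g, direction_id = d,
                              activity = best$activity,
                              experiment_id = best$experiment_id,
                              priority = best$priority,
                              provenance = prov, stringsAsFactors = FALSE)
    }
  }
  if (length(holes))
    stop("coverage gaps (no source and no resolvable substitute): ",
         paste(holes, collapse = "; "))
  do.call(rbind, rows[seq_len(i)])
}

#' A single spatial tuning pattern
#'
#' @param muscle_group group label.
#' @param side `"left"` or `"right"`.
#' @param weights named numeric vector over all 26 `direction_id`s,
#'   values in `[0, 1]` after normalization (raw patterns may exceed 1).
#' @return object of class `stp_pattern`.
#' @export
stp_pattern <- function(muscle_group, side, weights) {
  grid <- build_direction_grid()
  stopifnot(side %in% c("left", "right"),
            setequal(names(weights), grid$direction_id),
            all(weights >= 0))
  structure(list(muscle_group = muscle_group, side = side,
                 weights = weights[grid$direction_id]),
            class = "stp_pattern")
}

# direction_id -> mirrored direction_id (sagittal-plane reflection:
# azimuth -> (360 - azimuth) %% 360, axial level left <-> right)
.mirror_direction_map <- function() {
  grid <- build_direction_grid()
  swap <- c(left = "right", none = "none", right = "left")
  mirrored <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lv <- swap[[grid$axial_level[i]]]
    if (grid$pure_axial[i]) {
      mirrored[i] <- paste0("axial_", lv)
    } else {
      az <- (360 - grid$bend_azimuth_deg[i]) %% 360
      mirrored[i] <- sprintf("b%03d_%s", az, lv)
    }
  }
  stats::setNames(mirrored, grid$direction_id)
}

#' Mirror a right-side STP to the left side
#'
#' Reflects the pattern about the sagittal plane: bend azimuth maps to
#' its mirror image and the axial-rotation level swaps left and right.
#'
#' @param stp an [stp_pattern()] with `side = "right"`.
#' @return the left-side `stp_pattern`.
#' @export
mirror_right_to_left <- function(stp) {
  if (!inherits(stp, "stp_pattern")) stop("stp must be an stp_pattern")
  if (stp$side != "right")
    stop("mirror_right_to_left applies to right-side patterns only")
  map <- .mirror_direction_map()
  w <- stp$weights
  out <- stats::setNames(w[names(map)], map)
  stp_pattern(stp$muscle_group, "left", out)
}

#' Build a full two-sided STP set from merged activities
#'
#' Turns [combine_sources()] output (right-side raw activities) into one
#' pattern per group and side by mirroring, then applies per-direction
#' normalization (see [normalize_per_direction()]).
#'
#' @param combined data.frame from [combine_sources()].
#' @param registry the muscle registry used.
#' @param normalize apply per-direction normalization (default TRUE).
#' @return object of class `stp_set`: list with `weights` (matrix, rows
#'   `<group>.<side>`, columns `direction_id`), `grid`, `registry`,
#'   `provenance`, `normalized`.
#' @export
stp_set_from_combined <- function(combined, registry = default_muscle_registry(),
                                  normalize = TRUE) {
  grid <- build_direction_grid()
  groups <- registry$group
  rows <- c(paste0(groups, ".right"), paste0(groups, ".left"))
  W <- matrix(NA_real_, length(rows), nrow(grid),
              dimnames = list(rows, grid$direction_id))
  for (g in groups) {
    sub <- combined[combined$group == g, ]
    w <- stats::setNames(sub$activity, sub$direction_id)
    right <- stp_pattern(g, "right", w[grid$direction_id])
    left <- mirror_right_to_left(right)
    W[paste0(g, ".right"), ] <- right$weights
    W[paste0(g, ".left"), ] <- left$weights[grid$direction_id]
  }
  out <- structure(list(weights = W, grid = grid, registry = registry,
                        provenance = combined, normalized = FALSE),
                   class = "stp_set")
  if (normalize) out <- normalize_per_direction(out)
  out
}

#' Per-direction normalization of an STP set
#'
#' Divides every weight at a direction by the maximum weight across all
#' groups and both sides at that direction, so the maximum at every
#' direction is exactly 1. Idempotent; a direction whose maximum is zero
#' is a degenerate-direction error.
#'
#' @param stps an `stp_set`.
#' @return the normalized `stp_set`.
#' @export
normalize_per_direction <- function(stps) {
  stopifnot(inherits(stps, "stp_set"))
  W <- stps$weights
  mx <- apply(W, 2, max)
  if (any(mx <= 0))
    stop("degenerate direction(s) with all-zero activity: ",
         paste(colnames(W)[mx <= 0], collapse = ", "))
  stps$weights <- sweep(W, 2, mx, "/")
  stps$normalized <- TRUE
  stps
}

#' @export
print.stp_set <- function(x, ...) {
  cat(sprintf("<stp_set> %d groups x 2 sides over %d directions (%s)\n",
              nrow(x$registry), ncol(x$weights),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Polar plot of one group's spatial tuning pattern
#'
#' @param x an `stp_set`.
#' @param group muscle group to plot.
#' @param side `"right"` or `"left"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stp_set <- function(x, group = x$registry$group[1], side = "right", ...) {
  w <- x$weights[paste0(group, ".", side), ]
  grid <- x$grid
  op <- graphics::par(mar = c(2, 2, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("STP %s (%s)", group, side), ...)
  for (lv in .AXIAL_LEVELS) {
    sel <- grid$axial_level == lv & !grid$pure_axial
    az <- grid$bend_azimuth[sel]; r <- w[grid$direction_id[sel]]
    o <- order(az); az <- c(az[o], az[o][1] + 2 * pi); r <- c(r[o], r[o][1])
    graphics::lines(r * sin(az), r * cos(az),
                    lty = match(lv, .AXIAL_LEVELS))
  }
  graphics::legend("topright", legend = paste("axial", .AXIAL_LEVELS),
                   lty = seq_along(.AXIAL_LEVELS), cex = 0.7, bty = "n")
  invisible(x)
}

#' Interpolated STP weights for an arbitrary direction
#'
#' Bilinear interpolation over the grid: periodic linear interpolation in
#' bend azimuth between the two adjacent 45-degree grid azimuths, and
#' linear interpolation in `|axial_component|` between axial levels. The
#' sign of `axial_component` selects the left/right level; for
#' `|axial_component|` at or below `pure_axial_threshold` the weights
#' blend between the no-axial and the signed level, above it they blend
#' from the signed level toward the pure-axial entry (reached at
#' `|axial_component| = 1`). Querying exactly on a grid direction (with
#' `|axial_component|` equal to 0, the threshold, or 1) returns the
#' stored weights. The blending threshold is a package configuration
#' choice, not an assertion about the source experiments.
#'
#' @param stps a normalized `stp_set`.
#' @param bend_azimuth radians (0 forward, +pi/2 right); periodic.
#' @param axial_component fraction in `[-1, 1]`, positive = right axial.
#' @param pure_axial_threshold `|axial_component|` at which the signed
#'   axial level sits (default 0.5).
#' @return named weight vector over `<group>.<side>` rows, all in `[0, 1]`.
#' @export
lookup_weights <- function(stps, bend_azimuth, axial_component,
                           pure_axial_threshold = 0.5) {
  stopifnot(inherits(stps, "stp_set"))
  if (!stps$normalized) stop("lookup_weights requires a normalized stp_set")
  if (!is.finite(bend_azimuth) || !is.finite(axial_component))
    stop("non-finite direction query")
  if (abs(axial_component) > 1) stop("axial_component must be in [-1, 1]")
  W <- stps$weights
  az_deg <- (bend_azimuth * 180 / pi) %% 360
  i0 <- floor(az_deg / 45) %% 8
  frac <- (az_deg - i0 * 45) / 45
  i1 <- (i0 + 1) %% 8
  level_w <- function(lv) {
    c0 <- sprintf("b%03d_%s", as.integer(i0 * 45), lv)
    c1 <- sprintf("b%03d_%s", as.integer(i1 * 45), lv)
    (1 - frac) * W[, c0] + frac * W[, c1]
  }
  a <- axial_component
  side_lv <- if (a >= 0) "right" else "left"
  t0 <- pure_axial_threshold
  if (abs(a) <= t0) {
    lam <- if (t0 > 0) abs(a) / t0 else 0
    w <- (1 - lam) * level_w("none") + lam * level_w(side_lv)
  } else {
    lam <- (abs(a) - t0) / (1 - t0)
    w <- (1 - lam) * level_w(side_lv) + lam * W[, paste0("axial_", side_lv)]
  }
  pmin(pmax(w, 0), 1)
}

#' Serialize / read an STP set as CSV
#'
#' One row per (group, side, direction); weights column plus the grid
#' coordinates, with a provenance comment header and a units row.
#'
#' @param stps an `stp_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stp_csv <- function(stps, path) {
  grid <- stps$grid
  rows <- do.call(rbind, lapply(rownames(stps$weights), function(rn) {
    parts <- strsplit(rn, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], side = parts[2],
               direction_id = grid$direction_id,
               bend_azimuth_deg = grid$bend_azimuth_deg,
               axial_level = grid$axial_level,
               pure_axial = grid$pure_axial,
               weight = as.numeric(stps$weights[rn, ]),
               stringsAsFactors = FALSE)
  }))
  units <- c("", "", "", "deg", "", "", "fraction")
  .write_table_csv(rows, path, units,
                   meta = c(sprintf("normalized=%s", stps$normalized)))
}

#' @rdname write_stp_csv
#' @param registry registry to attach to the read set.
#' @export
read_stp_csv <- function(path, registry = default_muscle_registry()) {
  rows <- .read_table_csv(path)
  rows$weight <- as.numeric(rows$weight)
  grid <- build_direction_grid()
  groups <- unique(rows$group)
  rn <- unique(paste0(rows$group, ".", rows$side))
  W <- matrix(NA_real_, length(rn), nrow(grid),
              dimnames = list(rn, grid$direction_id))
  for (i in seq_len(nrow(rows)))
    W[paste0(rows$group[i], ".", rows$side[i]), rows$direction_id[i]] <-
      rows$weight[i]
  structure(list(weights = W, grid = grid, registry = registry,
                 provenance = NULL,
                 normalized = all(abs(apply(W, 2, max) - 1) < 1e-9)),
            class = "stp_set")
}
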