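# Objective bio-fidelity rating of simulated channels against reference
# corridors (volunteer mean +/- 1 SD), combining a corridor sub-score with
# cross-correlation sub-scores (shape, size, phase). The structure follows
# the widely published corridor + correlation rating scheme; every
# constant lives in the settings object, and scores are comparable in
# structure, not numerically, to any particular rating software.

#' Reference corridor for one channel
#'
#' @param channel channel name (e.g. `"head_tx"`).
#' @param time time base, s (uniform).
#' @param mean corridor mean (channel units).
#' @param sd corridor standard deviation (>= 0, same units).
#' @return data.frame of class `reference_corridor`.
#' @export
reference_corridor <- function(channel, time, mean, sd) {
  stopifnot(length(time) == length(mean), length(mean) == length(sd),
            all(sd >= 0), !is.unsorted(time))
  out <- data.frame(channel = channel, time = time, mean = mean, sd = sd,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_corridor", "data.frame")
  out
}

#' Rating settings
#'
#' Corridor half-widths (SD-based where the corridor carries positive SD,
#' else fractions of the reference peak), the correlation sub-rating
#' weights and the top-level method weights. All defaults are package
#' configuration, not published constants.
#'
#' @param corridor_mode `"sd"` (inner/outer = multiples of the corridor
#'   SD) or `"peak"` (fractions of the reference peak magnitude).
#' @param inner_sd,outer_sd SD multiples for the inner and outer corridor.
#' @param inner_frac,outer_frac peak fractions for `"peak"` mode.
#' @param w_corridor,w_correlation top-level weights (sum to 1).
#' @param w_shape,w_size,w_phase correlation sub-weights (sum to 1).
#' @param max_shift_frac maximum allowed cross-correlation shift as a
#'   fraction of the evaluation interval.
#' @param interval optional evaluation interval `c(t0, t1)` in s.
#' @return list of class `cora_settings`.
#' @export
cora_settings <- function(corridor_mode = c("sd", "peak"),
                          inner_sd = 1, outer_sd = 2,
                          inner_frac = 0.05, outer_frac = 0.5,
                          w_corridor = 0.5, w_correlation = 0.5,
                          w_shape = 0.5, w_size = 0.25, w_phase = 0.25,
                          max_shift_frac = 0.2, interval = NULL) {
  stopifnot(abs(w_corridor + w_correlation - 1) < 1e-9,
            abs(w_shape + w_size + w_phase - 1) < 1e-9,
            inner_sd > 0, outer_sd > inner_sd,
            inner_frac > 0, outer_frac > inner_frac,
            max_shift_frac >= 0, max_shift_frac < 1)
  structure(list(corridor_mode = match.arg(corridor_mode),
                 inner_sd = inner_sd, outer_sd = outer_sd,
                 inner_frac = inner_frac, outer_frac = outer_frac,
                 w_corridor = w_corridor, w_correlation = w_correlation,
                 w_shape = w_shape, w_size = w_size, w_phase = w_phase,
                 max_shift_frac = max_shift_frac, interval = interval),
            class = "cora_settings")
}

#' Objective curve score against a reference corridor
#'
#' Weighted combination of (a) a corridor sub-score -- per-sample 1
#' inside the inner corridor, 0 outside the outer, linear between,
#' averaged over the evaluation interval -- and (b) correlation
#' sub-scores: shape (maximum normalized cross-correlation over the
#' allowed shift range, clamped to `[0, 1]`), size (ratio of the smaller
#' to the larger L2 norm) and phase (1 minus the normalized optimal
#' shift). A flat simulated signal against a structured reference scores
#' 0 on all correlation sub-scores.
#'
#' @param sim_t,sim_y simulated channel (time s, value).
#' @param corridor a [reference_corridor()].
#' @param settings a [cora_settings()].
#' @return list of class `cora_score` with `score` in `[0, 1]` and the
#'   sub-scores.
#' @export
cora_score <- function(sim_t, sim_y, corridor, settings = cora_settings()) {
  stopifnot(inherits(corridor, "reference_corridor"))
  tt <- corridor$time
  if (!is.null(settings$interval)) {
    keep <- tt >= settings$interval[1] & tt <= settings$interval[2]
    if (!any(keep)) stop("empty evaluation interval")
    corridor <- corridor[keep, ]
    tt <- corridor$time
  }
  if (max(sim_t) < min(tt) || min(sim_t) > max(tt))
    stop("empty evaluation interval: series do not overlap")
  ys <- stats::approx(sim_t, sim_y, tt, rule = 2)$y
  yr <- corridor$mean
  peak <- max(abs(yr))

  if (settings$corridor_mode == "sd" && all(corridor$sd > 0)) {
    inner <- settings$inner_sd * corridor$sd
    outer <- settings$outer_sd * corridor$sd
  } else {
    if (peak <= 0) stop("reference peak is zero; cannot build peak-based corridor")
    inner <- rep(settings$inner_frac * peak, length(tt))
    outer <- rep(settings$outer_frac * peak, length(tt))
  }
  dev <- abs(ys - yr)
  s <- ifelse(dev <= inner, 1,
              ifelse(dev >= outer, 0, (outer - dev) / (outer - inner)))
  corridor_score <- mean(s)

  n <- length(tt)
  max_shift <- floor(settings$max_shift_frac * n)
  sd_s <- stats::sd(ys); sd_r <- stats::sd(yr)
  if (sd_s == 0 || sd_r == 0) {
    shape <- 0; phase <- 0
  } else {
    shifts <- -max_shift:max_shift
    cors <- vapply(shifts, function(k) {
      if (k >= 0) {
        a <- ys[seq_len(n - k)]; b <- yr[seq_len(n - k) + k]
      } else {
        a <- ys[seq_len(n + k) - k]; b <- yr[seq_len(n + k)]
      }
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-1)
      stats::cor(a, b)
    }, numeric(1))
    kbest <- shifts[which.max(cors)]
    shape <- min(1, max(0, max(cors)))
    phase <- if (max_shift == 0) 1 else 1 - abs(kbest) / max_shift
  }
  n_s <- sqrt(sum(ys^2)); n_r <- sqrt(sum(yr^2))
  size <- if (max(n_s, n_r) == 0) 1 else min(n_s, n_r) / max(n_s, n_r)

  corr_score <- settings$w_shape * shape + settings$w_size * size +
    settings$w_phase * phase
  total <- settings$w_corridor * corridor_score +
    settings$w_correlation * corr_score
  structure(list(score = total, corridor = corridor_score, shape = shape,
                 size = size, phase = phase, channel = corridor$channel[1]),
            class = "cora_score")
}

#' @export
print.cora_score <- function(x, ...) {
  cat(sprintf("<cora_score> %s: %.3f (corridor %.3f, shape %.3f, size %.3f, phase %.3f)\n",
              x$channel, x$score, x$corridor, x$shape, x$size, x$phase))
  invisible(x)
}

#' Rating label from a score
#'
#' Bins a score into `excellent` / `good` / `fair` / `poor` using three
#' strictly decreasing cut points; a score exactly at a boundary takes
#' the higher label. The default ladder (0.94 / 0.80 / 0.58) is a common
#' bio-fidelity convention and is configurable.
#'
#' @param score numeric in `[0, 1]` (vectorized).
#' @param thresholds decreasing cut points for excellent/good/fair.
#' @return character vector of labels.
#' @export
classify_rating <- function(score, thresholds = c(0.94, 0.80, 0.58)) {
  if (length(thresholds) != 3 || is.unsorted(rev(thresholds), strictly = TRUE))
    stop("thresholds must be 3 strictly decreasing cut points")
  ifelse(score >= thresholds[1], "excellent",
         ifelse(score >= thresholds[2], "good",
                ifelse(score >= thresholds[3], "fair", "poor")))
}

#' Magnitude-weighted overall bio-fidelity score
#'
#' Channel scores are aggregated within the translation and rotation
#' families with weights proportional to the peak magnitude of the
#' reference (volunteer) displacement on each channel, so small-magnitude
#' channels carry less weight; the overall score is the unweighted mean
#' of the two family composites (translations and rotations attributed
#' equal value). The absolute peak (not peak-to-peak) is the documented
#' weighting choice.
#'
#' @param scores data.frame with columns `channel`, `family`
#'   (`"translation"` / `"rotation"`), `score`, `peak` (reference peak
#'   magnitude, channel units).
#' @param thresholds rating thresholds for [classify_rating()].
#' @return object of class `bio_fidelity_report` with per-channel scores
#'   and ratings, family composites and the overall score.
#' @export
overall_score <- function(scores, thresholds = c(0.94, 0.80, 0.58)) {
  need <- c("channel", "family", "score", "peak")
  stopifnot(all(need %in% names(scores)),
            all(scores$family %in% c("translation", "rotation")))
  composite <- function(fam) {
    s <- scores[scores$family == fam, ]
    if (nrow(s) == 0) return(NA_real_)
    wsum <- sum(abs(s$peak))
    if (wsum == 0)
      stop("undefined weighting: all reference peaks are zero for ", fam)
    sum(s$score * abs(s$peak)) / wsum
  }
  tc <- composite("translation"); rc <- composite("rotation")
  overall <- mean(c(tc, rc), na.rm = TRUE)
  scores$rating <- classify_rating(scores$score, thresholds)
  structure(list(channels = scores,
                 translation_composite = tc, rotation_composite = rc,
                 overall = overall,
                 overall_rating = classify_rating(overall, thresholds),
                 thresholds = thresholds),
            class = "bio_fidelity_report")
}

#' @export
print.bio_fidelity_report <- function(x, ...) {
  cat("<bio_fidelity_report>\n")
  for (i in seq_len(nrow(x$channels)))
    cat(sprintf("  %-9s %-11s score %.3f (%s), peak %.4g\n",
                x$channels$channel[i], x$channels$family[i],
                x$channels$score[i], x$channels$rating[i],
                x$channels$peak[i]))
  cat(sprintf("  translation composite %.3f | rotation composite %.3f\n",
              x$translation_composite, x$rotation_composite))
  cat(sprintf("  overall %.3f (%s)\n", x$overall, x$overall_rating))
  invisible(x)
}

#' Muscle-activity similarity classification
#'
#' Time-averages each muscle's activation over a window and classifies
#' it as `"similar"` when it falls within the reference mean +/- 1 SD
#' (inclusive bounds), `"dissimilar"` otherwise.
#'
#' @param time_s simulation time base, s.
#' @param activations matrix (samples x muscles) of activation signals.
#' @param window `c(t0, t1)` averaging window, s.
#' @param ref_mean,ref_sd named reference statistics per muscle column.
#' @return data.frame with `muscle`, `sim_mean`, `ref_mean`, `ref_sd`,
#'   `classification`.
#' @export
activity_similarity <- function(time_s, activations, window, ref_mean,
                                ref_sd) {
  keep <- time_s >= window[1] & time_s <= window[2]
  if (!any(keep)) stop("invalid interval: empty averaging window")
  muscles <- names(ref_mean)
  stopifnot(!is.null(muscles), all(muscles %in% colnames(activations)),
            identical(sort(muscles), sort(names(ref_sd))))
  sim_mean <- colMeans(activations[keep, muscles, drop = FALSE])
  lo <- ref_mean[muscles] - ref_sd[muscles]
  hi <- ref_mean[muscles] + ref_sd[muscles]
  data.frame(muscle = muscles, sim_mean = as.numeric(sim_mean),
             ref_mean = as.numeric(ref_mean[muscles]),
             ref_sd = as.numeric(ref_sd[muscles]),
             classification = ifelse(sim_mean >= lo & sim_mean <= hi,
                                     "similar", "dissimilar"),
             stringsAsFactors = FALSE)
}

#' Write / read a bio-fidelity report as CSV
#'
#' @param report a `bio_fidelity_report`.
#' @param path output file.
#' @return `path` invisibly; `read_report_csv` returns the report.
#' @export
write_report_csv <- function(report, path) {
  ch <- report$channels
  extra <- data.frame(channel = c("__translation_composite__",
                                  "__rotation_composite__", "__overall__"),
                      family = "", score = c(report$translation_composite,
                                             report$rotation_composite,
                                             report$overall),
                      peak = NA_real_,
                      rating = c("", "", report$overall_rating),
                      stringsAsFactors = FALSE)
  .write_table_csv(rbind(ch[names(extra)], extra), path,
                   units = c("", "", "score", "channel units", ""),
                   meta = sprintf("thresholds=%s",
                                  paste(report$thresholds, collapse = "/")))
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  meta <- attr(.read_table_csv(path), "meta")
  tab <- .read_table_csv(path)
  tab$score <- as.numeric(tab$score); tab$peak <- as.numeric(tab$peak)
  special <- grepl("^__", tab$channel)
  ch <- tab[!special, ]
  th <- as.numeric(strsplit(sub(".*thresholds=", "",
                                meta[grepl("thresholds=", meta)]),
                            "/")[[1]])
  overall_score(ch[c("channel", "family", "score", "peak")], thresholds = th)
}
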