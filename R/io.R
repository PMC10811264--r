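# File I/O and configuration. All tabular exchange is CSV with a '#'
# provenance comment header (package version, config hash, seed, frame
# convention), a mandatory column-name row and a units row. Structured
# configuration is YAML validated against a schema: unknown keys are
# rejected so every package-default constant in use is visible in the
# file.

.FRAME_NOTE <- "frame: x forward, y right, z down (right-handed); angles rad, time s"

# small deterministic config hash (FNV-1a over the deparsed object);
# the output location is not part of the scientific configuration
.config_hash <- function(x) {
  x$output_dir <- NULL
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.write_table_csv <- function(df, path, units, meta = character()) {
  stopifnot(length(units) == ncol(df))
  con <- file(path, "w"); on.exit(close(con))
  ver <- as.character(utils::packageVersion("neckcontrol"))
  writeLines(c(sprintf("# neckcontrol %s", ver),
               paste0("# ", .FRAME_NOTE),
               paste0("# ", meta)), con)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) stop("malformed CSV (need header and units rows): ", path)
  header <- strsplit(body[1], ",")[[1]]
  units <- strsplit(body[2], ",")[[1]]
  df <- utils::read.csv(text = paste(body[-(1:2)], collapse = "\n"),
                        header = FALSE, stringsAsFactors = FALSE)
  names(df) <- header
  attr(df, "units") <- units
  attr(df, "meta") <- sub("^# ?", "", meta)
  df
}

#' Write simulated kinematics as CSV
#'
#' Channels `head_tx, head_ty, head_tz` (m) and `head_rx, head_ry,
#' head_rz` (rad), time in s, in the package frame convention (stated in
#' the header).
#'
#' @param result a `simulation_result`.
#' @param path output file.
#' @param meta extra provenance lines.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(result, path, meta = character()) {
  df <- data.frame(time = result$time_s, result$channels,
                   check.names = FALSE)
  .write_table_csv(df, path, units = c("s", "m", "m", "m", "rad", "rad",
                                       "rad"),
                   meta = c(sprintf("maneuver=%s", result$pulse$type),
                            sprintf("mode=%s dt_ms=%g delay_ms=%g tau_neural_ms=%g tau_active_ms=%g baseline_scale=%g",
                                    result$config$mode, result$dt_ms,
                                    result$config$delay_ms,
                                    result$config$tau_neural_ms,
                                    result$config$tau_active_ms,
                                    result$config$baseline_scale),
                            sprintf("gains Kp=%g Ki=%g Kd=%g",
                                    result$gains$Kp, result$gains$Ki,
                                    result$gains$Kd), meta))
}

#' @rdname write_kinematics_csv
#' @export
read_kinematics_csv <- function(path) {
  df <- .read_table_csv(path)
  df[] <- lapply(df, as.numeric)
  df
}

#' Write per-muscle activations as CSV
#'
#' @inheritParams write_kinematics_csv
#' @export
write_activations_csv <- function(result, path, meta = character()) {
  df <- data.frame(time = result$time_s, result$activations,
                   check.names = FALSE)
  .write_table_csv(df, path,
                   units = c("s", rep("fraction", ncol(result$activations))),
                   meta = c(sprintf("maneuver=%s", result$pulse$type), meta))
}

#' Write / read a single-channel reference corridor as CSV
#'
#' Columns `time`, `mean`, `sd`; one file per channel, the channel name
#' in the provenance header.
#'
#' @param corridor a [reference_corridor()].
#' @param path output file.
#' @return `path` invisibly; the reader returns the corridor.
#' @export
write_corridor_csv <- function(corridor, path) {
  stopifnot(inherits(corridor, "reference_corridor"))
  .write_table_csv(corridor[c("time", "mean", "sd")], path,
                   units = c("s", "channel units", "channel units"),
                   meta = sprintf("channel=%s", corridor$channel[1]))
}

#' @rdname write_corridor_csv
#' @export
read_corridor_csv <- function(path) {
  df <- .read_table_csv(path)
  meta <- attr(df, "meta")
  ch <- sub(".*channel=", "", meta[grepl("channel=", meta)])[1]
  reference_corridor(ch, as.numeric(df$time), as.numeric(df$mean),
                     as.numeric(df$sd))
}

# ---- run configuration -----------------------------------------------------

.CONFIG_SCHEMA <- list(
  seed = NULL, output_dir = NULL,
  plant = list(mass = NULL, inertia = NULL, cog_offset = NULL,
               rot_stiffness = NULL, rot_damping = NULL,
               trans_stiffness = NULL, trans_damping = NULL,
               gravity = NULL, seat_tau_s = NULL),
  controller = list(mode = NULL, gains = list(Kp = NULL, Ki = NULL,
                                              Kd = NULL),
                    delay_ms = NULL, tau_neural_ms = NULL,
                    tau_active_ms = NULL, baseline_scale = NULL,
                    reference_time_ms = NULL, saturation_ceiling = NULL,
                    pure_axial_threshold = NULL,
                    direction_from_delayed = NULL,
                    euler_convention = NULL, constraint_signal = NULL,
                    stp_path = NULL),
  maneuver = list(type = NULL, peak = NULL, duration = NULL,
                  settle = NULL, loading = NULL),
  tuning = list(objective = NULL, n_designs = NULL, max_iter = NULL,
                tol = NULL, zoom = NULL, constraint_ceiling = NULL,
                metric = NULL),
  rating = list(thresholds = NULL, corridor_mode = NULL,
                inner_sd = NULL, outer_sd = NULL, inner_frac = NULL,
                outer_frac = NULL))

.validate_keys <- function(cfg, schema, path = "") {
  for (k in names(cfg)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!(k %in% names(schema)))
      stop("invalid config key: ", full, call. = FALSE)
    if (is.list(schema[[k]]) && length(schema[[k]]) > 0) {
      if (!is.list(cfg[[k]]))
        stop("config key ", full, " must be a block", call. = FALSE)
      .validate_keys(cfg[[k]], schema[[k]], full)
    }
  }
  invisible(cfg)
}

#' Default run configuration
#'
#' A full, schema-valid configuration for one maneuver with every
#' package-default constant written out. Default phase timings are the
#' head-neck sub-system values (250 ms settling + 2250 ms loading for
#' braking, 250 + 1450 ms for lane change).
#'
#' @param maneuver `"braking"` or `"lane_change"`.
#' @param mode controller mode.
#' @param seed integer seed recorded in outputs and used by fixture
#'   generation.
#' @param output_dir directory for pipeline outputs.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(maneuver = c("braking", "lane_change"),
                               mode = c("translational", "rotational"),
                               seed = 1, output_dir = tempdir()) {
  maneuver <- match.arg(maneuver)
  mode <- match.arg(mode)
  mv <- if (maneuver == "braking")
    list(type = "braking", peak = 11, duration = 2.5, settle = 0.25,
         loading = 2.25)
  else
    list(type = "lane_change", peak = 6, duration = 2, settle = 0.25,
         loading = 1.45)
  cfg <- list(seed = seed, output_dir = output_dir,
              plant = list(mass = 4.5, inertia = c(0.020, 0.022, 0.015),
                           cog_offset = c(0.02, 0, -0.15),
                           rot_stiffness = c(12, 12, 8),
                           rot_damping = c(6, 6, 4),
                           trans_stiffness = c(1500, 1500, 40000),
                           trans_damping = c(150, 150, 1500),
                           gravity = 9.81, seat_tau_s = 0.05),
              controller = list(mode = mode,
                                gains = list(Kp = 1.0, Ki = 1e-5, Kd = 400),
                                delay_ms = 25, tau_neural_ms = 35,
                                tau_active_ms = 15, baseline_scale = 1,
                                reference_time_ms = NA,
                                saturation_ceiling = 1,
                                pure_axial_threshold = 0.5,
                                direction_from_delayed = FALSE,
                                euler_convention = "intrinsic",
                                constraint_signal = "pid",
                                stp_path = NULL),
              maneuver = mv,
              tuning = list(objective = "T", n_designs = 7, max_iter = 10,
                            tol = 0.01, zoom = 0.6,
                            constraint_ceiling = 0.99,
                            metric = "curve_mapping"),
              rating = list(thresholds = c(0.94, 0.80, 0.58),
                            corridor_mode = "sd", inner_sd = 1,
                            outer_sd = 2, inner_frac = 0.05,
                            outer_frac = 0.5))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Validate a run configuration against the schema
#'
#' Rejects unknown keys (naming the offending path) and checks basic
#' value sanity.
#'
#' @param cfg a configuration list.
#' @return the config, classed `run_config`, invisibly on success.
#' @export
validate_run_config <- function(cfg) {
  .validate_keys(cfg, .CONFIG_SCHEMA)
  need <- c("seed", "output_dir", "plant", "controller", "maneuver")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("missing config blocks: ",
                         paste(miss, collapse = ", "))
  if (!cfg$maneuver$type %in% c("braking", "lane_change"))
    stop("invalid config value: maneuver.type")
  if (!cfg$controller$mode %in% c("translational", "rotational"))
    stop("invalid config value: controller.mode")
  class(cfg) <- c("run_config", "list")
  invisible(cfg)
}

#' Read / write run configuration YAML
#'
#' @param path YAML file.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml reads NA reference time as the string "NA" or NULL; normalize
  if (!is.null(cfg$controller$reference_time_ms) &&
      is.character(cfg$controller$reference_time_ms))
    cfg$controller$reference_time_ms <- NA_real_
  validate_run_config(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# build package objects from a config
.plant_from_config <- function(cfg) {
  p <- cfg$plant
  head_neck_plant(mass = p$mass, inertia = p$inertia,
                  cog_offset = p$cog_offset,
                  rot_stiffness = p$rot_stiffness,
                  rot_damping = p$rot_damping,
                  trans_stiffness = p$trans_stiffness,
                  trans_damping = p$trans_damping, gravity = p$gravity,
                  seat_tau_s = p$seat_tau_s)
}

.pulse_from_config <- function(cfg) {
  m <- cfg$maneuver
  if (m$type == "braking")
    braking_pulse(m$peak, m$duration, m$settle, m$loading)
  else
    lane_change_pulse(m$peak, m$duration, m$settle, m$loading)
}

.controller_from_config <- function(cfg) {
  ct <- cfg$controller
  ref <- ct$reference_time_ms
  if (is.null(ref)) ref <- NA_real_
  controller_config(mode = ct$mode, delay_ms = ct$delay_ms,
                    tau_neural_ms = ct$tau_neural_ms,
                    tau_active_ms = ct$tau_active_ms,
                    baseline_scale = ct$baseline_scale,
                    reference_time_ms = ref,
                    saturation_ceiling = ct$saturation_ceiling,
                    pure_axial_threshold = ct$pure_axial_threshold,
                    direction_from_delayed = isTRUE(ct$direction_from_delayed),
                    euler_convention = ct$euler_convention,
                    constraint_signal = ct$constraint_signal)
}

.stps_from_config <- function(cfg) {
  path <- cfg$controller$stp_path
  if (!is.null(path) && nzchar(path) && file.exists(path))
    return(read_stp_csv(path))
  records <- generate_stp_fixture(seed = cfg$seed)
  stp_set_from_combined(combine_sources(records))
}

#' Run one pipeline action from a configuration
#'
#' Dispatches the pipeline stages over a validated configuration:
#' `"fixtures"` writes the synthetic STP source tables and reference
#' corridors, `"build-stp"` merges sources into a normalized STP set and
#' writes it, `"simulate"` runs the plant and writes kinematics and
#' activation CSVs, `"rate"` scores a simulated kinematics file against
#' corridor files, and `"tune"` runs the SRSM gain tuning against the
#' corridor means and writes the history and tuned gains. All outputs
#' carry a provenance header (package version, config hash, seed).
#'
#' @param cfg a `run_config` (validated here).
#' @param action one of `"fixtures"`, `"build-stp"`, `"simulate"`,
#'   `"rate"`, `"tune"`.
#' @param sim_path,corridor_paths for `"rate"`: the kinematics CSV and
#'   the corridor CSVs (defaults: the files `"simulate"` and
#'   `"fixtures"` write under `output_dir`).
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(cfg, action = c("simulate", "build-stp", "rate",
                                         "tune", "fixtures"),
                         sim_path = NULL, corridor_paths = NULL) {
  action <- match.arg(action)
  validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  meta <- c(sprintf("config_hash=%s", hash), sprintf("seed=%d", cfg$seed))
  out <- list()
  pfx <- file.path(cfg$output_dir, cfg$maneuver$type)

  if (action == "fixtures") {
    records <- generate_stp_fixture(seed = cfg$seed)
    p <- paste0(pfx, "_stp_sources.csv")
    .write_table_csv(records, p,
                     units = c("", "", "", "", "", "", "fraction"), meta)
    out$stp_sources <- p
    corr <- generate_corridor_fixture(seed = cfg$seed,
                                      maneuver = cfg$maneuver$type)
    for (ch in names(corr)) {
      cp <- paste0(pfx, "_corridor_", ch, ".csv")
      write_corridor_csv(corr[[ch]], cp)
      out[[paste0("corridor_", ch)]] <- cp
    }
    return(invisible(out))
  }

  if (action == "build-stp") {
    stps <- .stps_from_config(cfg)
    p <- paste0(pfx, "_stp.csv")
    write_stp_csv(stps, p)
    return(invisible(list(stp = p)))
  }

  stps <- .stps_from_config(cfg)
  plant <- .plant_from_config(cfg)
  pulse <- .pulse_from_config(cfg)
  config <- .controller_from_config(cfg)

  if (action == "simulate") {
    g <- cfg$controller$gains
    res <- simulate_plant(plant, pulse,
                          controller_gains(g$Kp, g$Ki, g$Kd), stps,
                          config)
    kp <- paste0(pfx, "_kinematics.csv")
    ap <- paste0(pfx, "_activations.csv")
    write_kinematics_csv(res, kp, meta)
    write_activations_csv(res, ap, meta)
    return(invisible(list(kinematics = kp, activations = ap)))
  }

  if (action == "rate") {
    if (is.null(sim_path)) sim_path <- paste0(pfx, "_kinematics.csv")
    if (!file.exists(sim_path))
      stop("no simulated kinematics at ", sim_path,
           "; run the simulate action first")
    sim <- read_kinematics_csv(sim_path)
    if (is.null(corridor_paths)) {
      corridor_paths <- Sys.glob(paste0(pfx, "_corridor_*.csv"))
      if (length(corridor_paths) == 0) {
        rp <- run_pipeline(cfg, "fixtures")
        corridor_paths <- unlist(rp[grepl("^corridor_", names(rp))])
      }
    }
    rt <- cfg$rating
    settings <- cora_settings(corridor_mode = rt$corridor_mode,
                              inner_sd = rt$inner_sd,
                              outer_sd = rt$outer_sd,
                              inner_frac = rt$inner_frac,
                              outer_frac = rt$outer_frac)
    rows <- list()
    for (cp in corridor_paths) {
      corr <- read_corridor_csv(cp)
      ch <- corr$channel[1]
      sc <- cora_score(sim$time, sim[[ch]], corr, settings)
      rows[[ch]] <- data.frame(channel = ch,
                               family = if (grepl("_t", ch)) "translation"
                               else "rotation",
                               score = sc$score,
                               peak = max(abs(corr$mean)))
    }
    report <- overall_score(do.call(rbind, rows),
                            thresholds = rt$thresholds)
    rp <- paste0(pfx, "_report.csv")
    write_report_csv(report, rp)
    return(invisible(list(report = rp, result = report)))
  }

  # action == "tune"
  corr <- generate_corridor_fixture(seed = cfg$seed,
                                    maneuver = cfg$maneuver$type)
  refs <- stats::setNames(list(corr), cfg$maneuver$type)
  pulses <- stats::setNames(list(pulse), cfg$maneuver$type)
  tn <- cfg$tuning
  fit <- tune_controller(refs, pulses, plant, stps, config,
                         objective = tn$objective,
                         metric = tn$metric,
                         constraint_ceiling = tn$constraint_ceiling,
                         seed = cfg$seed, n_designs = tn$n_designs,
                         max_iter = tn$max_iter, tol = tn$tol,
                         zoom = tn$zoom)
  hp <- paste0(pfx, "_tuning_history.csv")
  .write_table_csv(fit$optimizer$history, hp,
                   units = c("", "1/rad", "1/(rad ms)", "ms/rad", "", ""),
                   meta)
  gp <- paste0(pfx, "_tuned_gains.yaml")
  yaml::write_yaml(list(gains = as.list(coef(fit)),
                        objective = tn$objective,
                        constraint_violated = fit$optimizer$constraint_violated),
                   gp)
  invisible(list(history = hp, gains = gp, fit = fit))
}
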