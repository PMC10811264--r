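# tune_controller(): the package's fitting function. It estimates PID
# gains for a chosen controller mode by SRSM optimization of the
# curve-mapping discrepancy between simulated and reference head
# displacement histories, under the saturation-duration-penalized
# activity constraint, and returns a classed object with the usual model
# methods.

#' Objective channels per maneuver
#'
#' The tuning objective set: `"T"` uses the loading-direction
#' translation (head x translation in braking, head y translation in
#' lane change), `"R"` the principal rotation (head y rotation in
#' braking, head x rotation in lane change), `"TR"` both. Each maneuver
#' thus contributes one or two objectives, giving two or four in total.
#'
#' @param objective `"T"`, `"R"` or `"TR"`.
#' @return named list mapping maneuver type to channel names.
#' @export
objective_channels <- function(objective = c("T", "R", "TR")) {
  objective <- match.arg(objective)
  ch <- list(braking = c(T = "head_tx", R = "head_ry"),
             lane_change = c(T = "head_ty", R = "head_rx"))
  sel <- switch(objective, T = "T", R = "R", TR = c("T", "R"))
  lapply(ch, function(x) unname(x[sel]))
}

#' Tune controller gains against reference displacement histories
#'
#' Fits the parallel-form PID gains (Kp, Ki, Kd) of a neck-muscle
#' controller by sequential response surface optimization: for every
#' candidate design the head-neck plant is simulated through each
#' maneuver, the curve-mapping discrepancy between the simulated and
#' reference time histories of the objective channels is scalarized with
#' equal weights, and the maximum-activity constraint (0.99, saturation
#' duration added) must hold across maneuvers.
#'
#' @param references named list: for each maneuver type present in
#'   `pulses`, a named list of reference series per channel, each a list
#'   with `t` (s) and `y`. Reference corridors ([reference_corridor()])
#'   are also accepted (their mean is used).
#' @param pulses list of [braking_pulse()] / [lane_change_pulse()]
#'   objects; names must match `references`.
#' @param plant a [head_neck_plant()].
#' @param stps normalized `stp_set`.
#' @param config a [controller_config()] fixing the mode and chain
#'   constants.
#' @param objective `"T"`, `"R"` or `"TR"`.
#' @param space a [default_design_space()].
#' @param metric `"curve_mapping"` (default) or `"rms"`.
#' @param constraint_ceiling maximum allowed activity (default 0.99).
#' @param dt_ms simulation step, ms.
#' @param seed integer seed for the SRSM candidate pools.
#' @param ... passed to [srsm_optimize()] (`n_designs`, `max_iter`,
#'   `tol`, `zoom`).
#' @return object of class `neck_tune` with methods [coef()], [print()],
#'   [summary()], [plot()], [simulate()], [residuals()] and [fitted()].
#' @export
tune_controller <- function(references, pulses, plant, stps, config,
                            objective = c("T", "R", "TR"),
                            space = default_design_space(),
                            metric = c("curve_mapping", "rms"),
                            constraint_ceiling = 0.99, dt_ms = 1,
                            seed = 1, ...) {
  objective <- match.arg(objective)
  metric <- match.arg(metric)
  stopifnot(length(pulses) >= 1, !is.null(names(pulses)),
            all(names(pulses) %in% names(references)))
  chmap <- objective_channels(objective)
  distfun <- if (metric == "curve_mapping") curve_mapping_distance else
    rms_distance

  get_ref <- function(mnv, ch) {
    r <- references[[mnv]][[ch]]
    if (is.null(r)) stop("no reference for channel ", ch, " in ", mnv)
    if (inherits(r, "reference_corridor")) list(t = r$time, y = r$mean) else r
  }

  n_obj <- sum(lengths(chmap[vapply(pulses, `[[`, "", "type")]))

  simulate_design <- function(design) {
    g <- controller_gains(design[["Kp"]], design[["Ki"]], design[["Kd"]])
    objs <- c(); cons <- -Inf
    sims <- list()
    for (mnv in names(pulses)) {
      type <- pulses[[mnv]]$type
      sim <- tryCatch(simulate_plant(plant, pulses[[mnv]], g, stps,
                                     config, dt_ms = dt_ms),
                      error = function(e) {
                        if (!grepl("instability", conditionMessage(e)))
                          stop(e)
                        NULL
                      })
      if (is.null(sim)) {
        # a diverged design is maximally bad on every response
        return(list(objectives = rep(1e3, n_obj), constraint = 1e3,
                    sims = NULL))
      }
      sims[[mnv]] <- sim
      for (ch in chmap[[type]]) {
        ref <- get_ref(mnv, ch)
        objs <- c(objs, distfun(sim$time_s, sim$channels[, ch],
                                ref$t, ref$y))
      }
      cons <- max(cons, saturation_penalized_activity(sim,
                                                      constraint_ceiling))
    }
    list(objectives = objs, constraint = cons, sims = sims)
  }

  opt <- srsm_optimize(function(d) simulate_design(d)[c("objectives",
                                                        "constraint")],
                       space = space, ceiling = constraint_ceiling,
                       seed = seed, ...)
  best <- simulate_design(opt$best_design)
  gains <- controller_gains(opt$best_design[["Kp"]],
                            opt$best_design[["Ki"]],
                            opt$best_design[["Kd"]])
  structure(list(gains = gains, optimizer = opt, objective = objective,
                 metric = metric, mode = config$mode,
                 constraint_ceiling = constraint_ceiling,
                 references = references, pulses = pulses, plant = plant,
                 stps = stps, config = config, dt_ms = dt_ms, seed = seed,
                 sims = best$sims, objectives = best$objectives,
                 chmap = chmap, call = match.call()),
            class = "neck_tune")
}

#' @export
coef.neck_tune <- function(object, ...) {
  unlist(object$gains[c("Kp", "Ki", "Kd")])
}

#' @export
print.neck_tune <- function(x, ...) {
  cat(sprintf("Tuned %s neck controller (objective %s, metric %s)\n",
              x$mode, x$objective, x$metric))
  cat(sprintf("  Kp = %.4g 1/rad, Ki = %.4g 1/(rad ms), Kd = %.4g ms/rad\n",
              x$gains$Kp, x$gains$Ki, x$gains$Kd))
  cat(sprintf("  scalarized objective %.4g, constraint %.4g (ceiling %.2f)%s\n",
              x$optimizer$best_objective, x$optimizer$best_constraint,
              x$constraint_ceiling,
              if (x$optimizer$constraint_violated)
                " [constraint violated at optimum]" else ""))
  cat(sprintf("  %d iterations, %s\n", x$optimizer$iterations,
              if (x$optimizer$converged) "converged on change tolerance"
              else "stopped at iteration limit"))
  invisible(x)
}

#' @export
summary.neck_tune <- function(object, ...) {
  h <- object$optimizer$history
  per_it <- stats::aggregate(h$objective, list(iteration = h$iteration),
                             min)
  names(per_it)[2] <- "best_objective"
  out <- list(gains = coef(object), objective = object$objective,
              mode = object$mode,
              iterations = object$optimizer$iterations,
              converged = object$optimizer$converged,
              constraint_violated = object$optimizer$constraint_violated,
              per_iteration = per_it,
              objectives = object$objectives)
  class(out) <- "summary.neck_tune"
  out
}

#' @export
print.summary.neck_tune <- function(x, ...) {
  cat(sprintf("SRSM gain tuning (%s controller, objective set %s)\n",
              x$mode, x$objective))
  cat("Gains:\n"); print(x$gains)
  cat("Best simulated objective per iteration:\n")
  print(x$per_iteration, row.names = FALSE)
  if (x$constraint_violated)
    cat("NOTE: activity constraint violated at the reported optimum\n")
  invisible(x)
}

#' Convergence plot of a tuned controller
#'
#' Best simulated objective and region ranges per iteration.
#'
#' @param x a `neck_tune` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.neck_tune <- function(x, ...) {
  reg <- x$optimizer$regions
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(reg$iteration, reg$best_objective, type = "b",
                 xlab = "iteration", ylab = "best objective",
                 main = "SRSM convergence", ...)
  rng <- as.matrix(reg[, grepl("^range_", names(reg))])
  graphics::matplot(reg$iteration, sweep(rng, 2, rng[1, ], "/"),
                    type = "b", pch = 1:3, lty = 1:3, col = 1,
                    xlab = "iteration", ylab = "region range (relative)")
  graphics::legend("topright", legend = sub("range_", "", colnames(rng)),
                   pch = 1:3, lty = 1:3, bty = "n", cex = 0.8)
  invisible(x)
}

#' Simulate the plant at the tuned gains
#'
#' @param object a `neck_tune`.
#' @param nsim number of maneuvers to run (all by default).
#' @param seed ignored (the plant is deterministic).
#' @param ... unused.
#' @return named list of `simulation_result`s, one per maneuver.
#' @export
simulate.neck_tune <- function(object, nsim = length(object$pulses),
                               seed = NULL, ...) {
  lapply(object$pulses[seq_len(nsim)], function(p)
    simulate_plant(object$plant, p, object$gains, object$stps,
                   object$config, dt_ms = object$dt_ms))
}

#' @export
fitted.neck_tune <- function(object, ...) {
  out <- list()
  for (mnv in names(object$sims)) {
    type <- object$pulses[[mnv]]$type
    for (ch in object$chmap[[type]]) {
      sim <- object$sims[[mnv]]
      out[[paste(mnv, ch, sep = ".")]] <-
        list(t = sim$time_s, y = sim$channels[, ch])
    }
  }
  out
}

#' @export
residuals.neck_tune <- function(object, ...) {
  ft <- fitted(object)
  out <- list()
  for (nm in names(ft)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ref <- object$references[[parts[1]]][[parts[2]]]
    if (inherits(ref, "reference_corridor")) ref <- list(t = ref$time,
                                                         y = ref$mean)
    yref <- stats::approx(ref$t, ref$y, ft[[nm]]$t, rule = 2)$y
    out[[nm]] <- ft[[nm]]$y - yref
  }
  out
}
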