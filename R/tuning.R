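# Gain tuning: curve comparison metrics, the saturation-duration-modified
# activity constraint, and the sequential response surface method (SRSM)
# with domain reduction -- per iteration a small number of designs (7) are
# selected D-optimally in the current trust region, a linear metamodel is
# fitted per response, its constrained optimum is found, and the region is
# panned to that optimum and zoomed.

#' Curve-mapping discrepancy between two time series
#'
#' A partial-curve-mapping style metric: both curves are normalized by
#' the reference peak magnitude (values) and the common duration (time),
#' parameterized by normalized arc length, resampled at matching
#' arc-length fractions, and the mean pointwise Euclidean distance in the
#' normalized (t, y) plane is returned. Zero iff the curves are
#' identical; anchored on the reference (not symmetric in its
#' arguments). The exact mapping algorithm is the package's documented
#' choice; a plain RMS-after-resampling alternative is available via
#' [rms_distance()] for sensitivity checks.
#'
#' @param sim_t,sim_y simulated series (time s, value).
#' @param ref_t,ref_y reference series.
#' @param n_map number of arc-length sample points (default 200).
#' @return non-negative scalar discrepancy (units: fraction of the
#'   reference peak).
#' @export
curve_mapping_distance <- function(sim_t, sim_y, ref_t, ref_y, n_map = 200) {
  stopifnot(length(sim_t) == length(sim_y), length(ref_t) == length(ref_y))
  peak <- max(abs(ref_y))
  if (peak <= 0) stop("undefined normalization: reference is identically zero")
  t0 <- max(min(sim_t), min(ref_t)); t1 <- min(max(sim_t), max(ref_t))
  if (t1 <= t0) stop("series do not overlap in time")
  tt <- seq(t0, t1, length.out = n_map)
  ys <- stats::approx(sim_t, sim_y, tt, rule = 2)$y / peak
  yr <- stats::approx(ref_t, ref_y, tt, rule = 2)$y / peak
  tn <- (tt - t0) / (t1 - t0)
  arc_param <- function(y) {
    s <- c(0, cumsum(sqrt(diff(tn)^2 + diff(y)^2)))
    if (s[n_map] <= 0) return(list(s = seq(0, 1, length.out = n_map), tot = 0))
    list(s = s / s[n_map], tot = s[n_map])
  }
  ps <- arc_param(ys); pr <- arc_param(yr)
  sfrac <- seq(0, 1, length.out = n_map)
  ix_s <- stats::approx(ps$s, seq_len(n_map), sfrac, rule = 2, ties = "ordered")$y
  ix_r <- stats::approx(pr$s, seq_len(n_map), sfrac, rule = 2, ties = "ordered")$y
  interp_at <- function(vals, ix) {
    j <- pmin(n_map - 1, pmax(1, floor(ix))); fr <- ix - j
    vals[j] * (1 - fr) + vals[j + 1] * fr
  }
  dxt <- interp_at(tn, ix_s) - interp_at(tn, ix_r)
  dyy <- interp_at(ys, ix_s) - interp_at(yr, ix_r)
  mean(sqrt(dxt^2 + dyy^2))
}

#' RMS distance after resampling to a common time base
#'
#' @inheritParams curve_mapping_distance
#' @param normalize divide by the reference peak magnitude (default TRUE).
#' @return non-negative scalar.
#' @export
rms_distance <- function(sim_t, sim_y, ref_t, ref_y, n_map = 200,
                         normalize = TRUE) {
  peak <- max(abs(ref_y))
  if (normalize && peak <= 0)
    stop("undefined normalization: reference is identically zero")
  t0 <- max(min(sim_t), min(ref_t)); t1 <- min(max(sim_t), max(ref_t))
  tt <- seq(t0, t1, length.out = n_map)
  ys <- stats::approx(sim_t, sim_y, tt, rule = 2)$y
  yr <- stats::approx(ref_t, ref_y, tt, rule = 2)$y
  d <- sqrt(mean((ys - yr)^2))
  if (normalize) d / peak else d
}

#' Saturation-duration-penalized activity constraint response
#'
#' The tuning constraint reads the controller's common activity signal
#' (the saturated PID response by default, configurable to the
#' post-dynamics activation). Below the ceiling the response is simply
#' the maximum activity; at or above it, the total saturated duration is
#' added to the ceiling so the optimizer can distinguish brief from
#' sustained saturation. The response is strictly increasing in the
#' saturated duration.
#'
#' @param result a `simulation_result`.
#' @param ceiling constraint ceiling (default 0.99).
#' @param duration_scale seconds of saturation are added after
#'   multiplication by this factor (default 1 per second; the scale is a
#'   package choice).
#' @return scalar constraint response.
#' @export
saturation_penalized_activity <- function(result, ceiling = 0.99,
                                          duration_scale = 1) {
  stopifnot(inherits(result, "simulation_result"))
  sig <- if (result$config$constraint_signal == "activation" &&
             ncol(result$activations) > 0)
    apply(result$activations, 1, max) else result$u_sat
  mx <- max(sig)
  if (mx < ceiling) return(mx)
  sat_s <- sum(sig >= ceiling) * result$dt_ms / 1000
  ceiling + duration_scale * sat_s
}

#' Design space for gain tuning
#'
#' Per-gain start, minimum and maximum. Defaults are the published
#' optimization settings: start (0.1, 1e-6, 100), bounds Kp in [0, 2],
#' Ki in [0, 0.1] (the Ziegler-Nichols ceiling, see
#' [ki_tuning_ceiling()]), Kd in [0, 1000]. Starting values sit at the
#' low end of the ranges so the very first design is feasible under the
#' activity constraint.
#'
#' @param start,min,max named numeric vectors over (Kp, Ki, Kd).
#' @return object of class `design_space`.
#' @export
default_design_space <- function(start = c(Kp = 0.1, Ki = 1e-6, Kd = 100),
                                 min = c(Kp = 0, Ki = 0, Kd = 0),
                                 max = c(Kp = 2, Ki = 0.1, Kd = 1000)) {
  stopifnot(all(min <= start), all(start <= max))
  structure(list(start = start, min = min, max = max,
                 names = names(start)),
            class = "design_space")
}

# greedy D-optimal selection of n rows from candidate matrix X (with
# intercept column added), maximizing det(X'X) incrementally
.d_optimal_select <- function(cand, n) {
  p <- ncol(cand) + 1L
  X <- cbind(1, cand)
  chosen <- integer(0)
  avail <- seq_len(nrow(X))
  M <- diag(1e-8, p)
  for (k in seq_len(n)) {
    best <- avail[1]; bestdet <- -Inf
    for (i in avail) {
      d <- det(M + tcrossprod(X[i, ]))
      if (d > bestdet) { bestdet <- d; best <- i }
    }
    chosen <- c(chosen, best)
    M <- M + tcrossprod(X[best, ])
    avail <- setdiff(avail, best)
  }
  chosen
}

#' Sequential response surface optimization with domain reduction
#'
#' Per iteration: a candidate pool (Latin hypercube, 200 points) is drawn
#' in the current region, `n_designs` designs are selected by greedy
#' D-optimal determinant maximization for the linear model matrix, the
#' simulator is evaluated at each, a linear polynomial metamodel is
#' fitted per objective and for the constraint, and the scalarized
#' metamodel objective is minimized subject to the metamodel constraint
#' `<= ceiling` within the region. The region is then panned to the
#' predicted optimum (clipped to the global bounds) and zoomed by the
#' contraction factor. Termination on relative design change and
#' objective change below `tol`, or `max_iter` iterations. The reported
#' optimum is the best simulated feasible design; if no simulated design
#' is feasible the best (lowest-constraint) design is reported with
#' `constraint_violated = TRUE`.
#'
#' @param simulator function(design named vector) returning a list with
#'   `objectives` (numeric vector) and `constraint` (scalar).
#' @param space a [default_design_space()].
#' @param n_designs simulations per iteration (default 7).
#' @param max_iter maximum iterations (default 10).
#' @param tol relative design- and objective-change tolerance
#'   (default 0.01; relative is the documented reading).
#' @param zoom base region contraction factor per iteration (default
#'   0.6). The per-axis contraction interpolates between `zoom` (interior
#'   predicted optimum) and 1 (optimum at the region edge, pure
#'   panning); `zoom = 1` disables domain reduction entirely, reducing
#'   the method to repeated single-stage RSM.
#' @param osc_damp additional range damping applied to an axis whose
#'   pan direction flips sign between iterations (default 0.7).
#' @param init_range_frac the first trust region spans this fraction of
#'   each variable's global range, centered on the starting design
#'   (default 0.45, the conventional subregion size for this method);
#'   panning can still reach the whole space.
#' @param ceiling constraint ceiling (default 0.99).
#' @param weights scalarization weights for the objectives (equal by
#'   default).
#' @param pool_size candidate pool size (default 200).
#' @param seed integer seed; the pool is the only stochastic element, so
#'   the optimizer is deterministic given the seed.
#' @return list with `best_design`, `best_objective`, `best_constraint`,
#'   `feasible`, `constraint_violated`, `converged`, `iterations`,
#'   `history` (one row per simulated design) and `regions` (one row per
#'   iteration).
#' @export
srsm_optimize <- function(simulator, space = default_design_space(),
                          n_designs = 7, max_iter = 10, tol = 0.01,
                          zoom = 0.6, osc_damp = 0.7,
                          init_range_frac = 0.45, ceiling = 0.99,
                          weights = NULL, pool_size = 200, seed = 1) {
  stopifnot(inherits(space, "design_space"))
  nm <- space$names
  d <- length(nm)
  lo_g <- space$min; hi_g <- space$max
  center <- space$start
  range_ <- init_range_frac * (hi_g - lo_g) / 2

  history <- list(); regions <- list()
  prev_center <- NULL; prev_best_pred <- NULL; prev_move <- NULL
  best_sim <- NULL
  converged <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    lo <- pmax(lo_g, center - range_)
    hi <- pmin(hi_g, center + range_)
    set.seed(seed + it)
    pool <- lhs::randomLHS(pool_size, d)
    pool <- sweep(sweep(pool, 2, hi - lo, "*"), 2, lo, "+")
    # scale to [0,1] on the region for a well-conditioned model matrix
    span <- pmax(hi - lo, 1e-12)
    pool_s <- sweep(sweep(pool, 2, lo, "-"), 2, span, "/")
    # the region center (the start design in iteration 1, the previous
    # predicted optimum afterwards) is always simulated, plus n-1
    # D-optimally selected pool designs
    ctr <- if (it == 1) space$start else center
    ctr_s <- (ctr - lo) / span
    pool_s <- rbind(ctr_s, pool_s)
    pool <- rbind(ctr, pool)
    sel <- c(1L, .d_optimal_select(pool_s[-1, , drop = FALSE],
                                   n_designs - 1) + 1L)
    X <- pool[sel, , drop = FALSE]
    colnames(X) <- nm
    resp <- lapply(seq_len(nrow(X)), function(i) {
      simulator(stats::setNames(X[i, ], nm))
    })
    objm <- do.call(rbind, lapply(resp, function(r) r$objectives))
    cons <- vapply(resp, function(r) r$constraint, numeric(1))
    if (is.null(weights)) weights <- rep(1 / ncol(objm), ncol(objm))
    scal <- as.numeric(objm %*% weights)

    if (it == 1 && !any(cons <= ceiling))
      stop("infeasible start: no feasible design in the first iteration")

    for (i in seq_len(nrow(X)))
      history[[length(history) + 1]] <-
        data.frame(iteration = it, t(X[i, ]), objective = scal[i],
                   constraint = cons[i])

    # track best simulated feasible design
    feas <- cons <= ceiling
    cand_idx <- if (any(feas)) which(feas)[which.min(scal[feas])] else
      which.min(cons)
    cand <- list(design = stats::setNames(X[cand_idx, ], nm),
                 objective = scal[cand_idx], constraint = cons[cand_idx],
                 feasible = feas[cand_idx])
    if (is.null(best_sim) ||
        (cand$feasible && (!best_sim$feasible ||
                           cand$objective < best_sim$objective)) ||
        (!best_sim$feasible && !cand$feasible &&
         cand$constraint < best_sim$constraint))
      best_sim <- cand

    # linear metamodels on region-scaled coordinates
    Xs <- sweep(sweep(X, 2, lo, "-"), 2, span, "/")
    fit <- function(y) stats::lm.fit(cbind(1, Xs), y)$coefficients
    b_obj <- fit(scal)
    b_con <- fit(cons)
    pred_pool <- cbind(1, pool_s)
    p_obj <- as.numeric(pred_pool %*% b_obj)
    p_con <- as.numeric(pred_pool %*% b_con)
    ok <- p_con <= ceiling
    opt_idx <- if (any(ok)) which(ok)[which.min(p_obj[ok])] else
      which.min(p_con)
    # refine: linear objective over the box attains its optimum at a
    # vertex; include the box vertices among the predictions
    verts <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    pv_obj <- as.numeric(cbind(1, verts) %*% b_obj)
    pv_con <- as.numeric(cbind(1, verts) %*% b_con)
    okv <- pv_con <= ceiling
    use_vert <- any(okv) && (!any(ok) || min(pv_obj[okv]) < p_obj[opt_idx])
    opt_s <- if (use_vert) verts[which(okv)[which.min(pv_obj[okv])], ] else
      pool_s[opt_idx, ]
    opt <- lo + opt_s * span
    pred_obj <- sum(c(1, opt_s) * b_obj)

    regions[[it]] <- data.frame(iteration = it, t(stats::setNames(center, paste0("center_", nm))),
                                t(stats::setNames(range_, paste0("range_", nm))),
                                best_objective = best_sim$objective,
                                predicted_objective = pred_obj)

    # termination: relative design and objective change
    if (!is.null(prev_center)) {
      dchange <- max(abs(opt - prev_center) / pmax(hi_g - lo_g, 1e-12))
      ochange <- abs(pred_obj - prev_best_pred) /
        max(abs(prev_best_pred), 1e-12)
      if (dchange < tol && ochange < tol) {
        center <- stats::setNames(opt, nm)
        converged <- TRUE
        break
      }
    }
    # incumbent safeguard: this iteration's simulated center is the
    # previous prediction; if it underperformed the best simulated
    # feasible design, re-anchor the next region on the incumbent
    if (it > 1 && best_sim$feasible &&
        (!(feas[1]) || scal[1] > best_sim$objective)) {
      opt <- best_sim$design
      opt_s <- (opt - lo) / span
      pred_obj <- best_sim$objective
    }
    move <- (opt - center) / pmax(range_, 1e-15)
    move <- pmin(1, pmax(-1, move))
    # domain reduction: an axis whose predicted optimum sits at the
    # region edge pans at (nearly) full range, an interior optimum
    # contracts toward `zoom`; a sign flip of the move direction
    # (oscillation) damps the range further
    lam <- zoom + abs(move) * (1 - zoom)
    if (!is.null(prev_move)) lam <- lam * ifelse(move * prev_move < 0,
                                                 osc_damp, 1)
    prev_move <- move
    prev_center <- opt; prev_best_pred <- pred_obj
    center <- stats::setNames(pmin(hi_g, pmax(lo_g, opt)), nm)
    range_ <- range_ * lam
  }

  list(best_design = best_sim$design,
       best_objective = best_sim$objective,
       best_constraint = best_sim$constraint,
       feasible = best_sim$feasible,
       constraint_violated = !best_sim$feasible,
       converged = converged, iterations = it,
       history = do.call(rbind, history),
       regions = do.call(rbind, regions))
}
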