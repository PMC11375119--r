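# Behavioural metrics computed from trial logs: motion efficiency, correction
# counting, force RMS, null-space reaching range, CTR motion-concurrency
# phases, success rates and latency summaries.

#' Motion efficiency of a successful reach
#'
#' The ratio of the straight-line distance from the start position to the
#' target over the total path length travelled, with the trajectory truncated
#' at the success time.
#'
#' @param traj_null T x 2 null-space trajectory.
#' @param start 2-vector start position (defaults to the first sample).
#' @param target 2-vector target position.
#' @param success_time time of success in seconds (trajectory truncated
#'   here); `NULL` uses the full trajectory.
#' @param fs sampling rate in Hz.
#' @return Efficiency in (0, 1]; `NA` (with a warning) for a zero path length.
#' @export
motion_efficiency <- function(traj_null, start = NULL, target, success_time = NULL,
                              fs = 1000) {
  traj_null <- as.matrix(traj_null)
  if (!is.null(success_time)) {
    n_keep <- min(nrow(traj_null), as.integer(ceiling(success_time * fs)))
    traj_null <- traj_null[seq_len(n_keep), , drop = FALSE]
  }
  if (is.null(start)) start <- traj_null[1, ]
  path <- sum(row_norms(diff(traj_null)))
  if (path <= 0) {
    warning("zero path length: motion efficiency undefined")
    return(NA_real_)
  }
  vnorm(target - start) / path
}

#' Count movement corrections in a trajectory
#'
#' Low-pass filters the 2-D trajectory (second-order Butterworth, 3 Hz),
#' differentiates to a speed profile and counts its local maxima. Peaks must
#' exceed `min_height_frac` of the trial's maximum speed and be separated by
#' at least `min_separation` seconds (suppressing numerical micro-peaks).
#' For successful trials pass the success time as `end_time` so counting
#' stops when the target is reached.
#'
#' @param traj_null T x 2 null-space trajectory.
#' @param fs sampling rate in Hz.
#' @param end_time truncate the trajectory here (seconds); `NULL` for none.
#' @param cutoff smoothing cut-off in Hz (default 3).
#' @param min_height_frac peak height threshold as a fraction of the maximum
#'   speed (default 0.05).
#' @param min_separation minimum peak separation in seconds (default 0.1).
#' @return Integer count of speed peaks.
#' @export
count_corrections <- function(traj_null, fs, end_time = NULL, cutoff = 3,
                              min_height_frac = 0.05, min_separation = 0.1) {
  traj_null <- as.matrix(traj_null)
  if (!is.null(end_time)) {
    n_keep <- min(nrow(traj_null), as.integer(ceiling(end_time * fs)))
    traj_null <- traj_null[seq_len(n_keep), , drop = FALSE]
  }
  if (nrow(traj_null) < 0.5 * fs)
    stop("trajectory shorter than 0.5 s: correction counting rejected",
         call. = FALSE)
  sm <- smooth_trajectory(traj_null, fs, cutoff)
  speed <- row_norms(diff(sm)) * fs
  vmax <- max(speed)
  if (vmax <= 0) return(0L)
  pk <- pracma::findpeaks(speed, minpeakheight = min_height_frac * vmax,
                          minpeakdistance = max(1L, as.integer(min_separation * fs)))
  if (is.null(pk)) 0L else nrow(pk)
}

#' Root-mean-square force over a trial
#'
#' `sqrt(mean(||f||^2))` over the samples of the force trajectory.
#'
#' @param traj_force T x 2 force trajectory in newtons.
#' @return RMS force in newtons.
#' @export
force_rms <- function(traj_force) {
  traj_force <- as.matrix(traj_force)
  if (nrow(traj_force) == 0L) stop("empty force trajectory", call. = FALSE)
  sqrt(mean(rowSums(traj_force^2)))
}

#' Angular reaching range in the null-space
#'
#' Collects the angles `atan2(n_y, n_x)` of trajectory samples whose null
#' magnitude lies within `tol` of the target radius, and (when the force
#' constraint is applied) whose force magnitude stays below
#' `force_frac * sMVF` — the distinction drawn between constraint-respecting
#' and constraint-violating reached angles. The range is the circular span of
#' the collected angle set: 360 minus the largest angular gap between sorted
#' reached angles (well defined for wrap-around sets).
#'
#' @param traj_null T x 2 rotated null trajectory (concatenate stages as
#'   needed; see [session_reaching_range()]).
#' @param traj_force T x 2 force trajectory (required with the constraint).
#' @param smvf scaling MVF in newtons (required with the constraint).
#' @param target_radius radius of the target ring in null units (default 2).
#' @param tol magnitude band half-width (default 0.4, the target tolerance).
#' @param constraint `"with"` (default) applies the force-magnitude
#'   constraint, `"without"` ignores it.
#' @param force_frac force threshold fraction (default 0.04).
#' @param bin_deg angular resolution in degrees used when spanning the
#'   collected set (default 1).
#' @return Object of class `reaching_range`: list with `angles` (sorted
#'   unique binned angles, degrees), `range` (degrees in \[0, 360\]) and
#'   `empty` flag.
#' @export
reaching_range <- function(traj_null, traj_force = NULL, smvf = NULL,
                           target_radius = 2, tol = 0.4,
                           constraint = c("with", "without"),
                           force_frac = 0.04, bin_deg = 1) {
  constraint <- match.arg(constraint)
  traj_null <- as.matrix(traj_null)
  keep <- abs(row_norms(traj_null) - target_radius) <= tol
  if (constraint == "with") {
    if (is.null(traj_force) || is.null(smvf))
      stop("force constraint requires traj_force and smvf", call. = FALSE)
    keep <- keep & (row_norms(as.matrix(traj_force)) < force_frac * smvf)
  }
  ang <- wrap360(rad2deg(atan2(traj_null[keep, 2], traj_null[keep, 1])))
  ang <- sort(unique(round(ang / bin_deg) * bin_deg))
  if (!length(ang)) {
    return(structure(list(angles = numeric(0), range = 0, empty = TRUE),
                     class = "reaching_range"))
  }
  if (length(ang) == 1L) {
    return(structure(list(angles = ang, range = 0, empty = FALSE),
                     class = "reaching_range"))
  }
  gaps <- diff(c(ang, ang[1] + 360))
  structure(list(angles = ang, range = 360 - max(gaps), empty = FALSE),
            class = "reaching_range")
}

#' @export
print.reaching_range <- function(x, ...) {
  cat(sprintf("<reaching_range> %d angles, span %.1f deg%s\n",
              length(x$angles), x$range, if (x$empty) " (empty set)" else ""))
  invisible(x)
}

#' Reaching range of an NSTR session
#'
#' Applies [reaching_range()] to the exploration stage, the target-reaching
#' stage, or their union.
#'
#' @param session an NSTR `session_log` with stored trajectories (and an
#'   `exploration` element for the exploration stages).
#' @param stage `"exploration"`, `"reaching"` or `"union"`.
#' @param constraint passed to [reaching_range()].
#' @param ... further arguments passed to [reaching_range()].
#' @return A `reaching_range` object.
#' @export
session_reaching_range <- function(session,
                                   stage = c("union", "exploration", "reaching"),
                                   constraint = "with", ...) {
  stopifnot(inherits(session, "session_log"))
  stage <- match.arg(stage)
  nul <- list(); frc <- list()
  if (stage %in% c("exploration", "union")) {
    if (is.null(session$exploration))
      stop("session has no exploration trace", call. = FALSE)
    nul <- c(nul, list(session$exploration$traj_null))
    frc <- c(frc, list(session$exploration$traj_force))
  }
  if (stage %in% c("reaching", "union")) {
    nul <- c(nul, lapply(session$trials, `[[`, "traj_null"))
    frc <- c(frc, lapply(session$trials, `[[`, "traj_force"))
    if (any(vapply(nul, is.null, logical(1))))
      stop("session was run without stored trajectories", call. = FALSE)
  }
  reaching_range(do.call(rbind, nul), do.call(rbind, frc),
                 smvf = session$smvf, constraint = constraint, ...)
}

#' Motion-concurrency phase decomposition of a CTR trial
#'
#' The required null movement is `D = target_size - baseline`, where the
#' baseline is the unintentional null activity predicted for the matching
#' task-space target from calibration. Phase 1 covers movement onset until
#' the task-space target is reached; Phase 2 the remainder until the
#' null-space target reach. `phase1 = (||n~|| at task reach - baseline)/D`,
#' `phase2 = (target_size - ||n~|| at task reach)/D`, so the shares sum to 1
#' and Phase 2 may be negative after a Phase-1 overshoot. Trials whose
#' required movement is below 15% of the target size are excluded as too
#' small for robust measurement.
#'
#' @param trial a successful CTR `trial_result` (needs
#'   `ntilde_at_task_reach`), or a bare numeric `||n~||` value at task reach.
#' @param baseline baseline null magnitude for the matching target position.
#' @param target_size the trial's null-space target size.
#' @param exclusion_frac exclusion threshold as a fraction of the target size
#'   (default 0.15).
#' @return List with `phase1`, `phase2`, `excluded` (logical) and `reason`.
#' @export
concurrency_phases <- function(trial, baseline, target_size,
                               exclusion_frac = 0.15) {
  if (is.null(baseline) || !is.finite(baseline))
    stop("missing baseline for this target position", call. = FALSE)
  nt <- if (inherits(trial, "trial_result")) {
    if (!isTRUE(trial$success))
      stop("concurrency phases are defined for successful trials", call. = FALSE)
    trial$ntilde_at_task_reach
  } else as.numeric(trial)
  D <- target_size - baseline
  if (D < exclusion_frac * target_size) {
    return(list(phase1 = NA_real_, phase2 = NA_real_, excluded = TRUE,
                reason = sprintf(
                  "required null movement %.3f below %.0f%% of target size",
                  D, 100 * exclusion_frac)))
  }
  phase1 <- (nt - baseline) / D
  list(phase1 = phase1, phase2 = 1 - phase1, excluded = FALSE, reason = NA_character_)
}

#' Baseline null activity per CTR target position
#'
#' For positions T1-T8 the baseline is the mean unrotated null magnitude
#' `||n~||` over the matching calibration target's final 2-s hold; for the
#' origin target T9 it is the offset-corrected rest level
#' `mean ||N~ alpha_rest - n0||` (approximately zero).
#'
#' @param calibration list as produced by [simulate_calibration_session()]
#'   (fields `targets`, a list of labelled hold recordings, and `rest`).
#' @param model a [nullspace_model()].
#' @param config a [ctr_config()] giving the task positions.
#' @param smvf scaling MVF in newtons.
#' @return Numeric vector of 9 baselines, one per position `T1..T9`.
#' @export
ctr_baselines <- function(calibration, model, config, smvf) {
  stopifnot(inherits(model, "nullspace_model"), inherits(config, "ctr_config"))
  cal_targets <- t(vapply(calibration$targets, function(r) r$target_force,
                          numeric(2)))
  out <- numeric(9)
  for (p in 1:8) {
    want <- config$positions[p, ] * smvf
    d <- row_norms(sweep(cal_targets, 2, want))
    hit <- which(d <= 1e-6 * max(1, smvf))
    if (!length(hit)) hit <- which(d == min(d) & d < 0.05 * smvf)
    if (!length(hit))
      stop(sprintf("no calibration target matches CTR position T%d", p),
           call. = FALSE)
    out[p] <- mean(vapply(calibration$targets[hit], function(r) {
      idx <- hold_indices(r, 2)
      mean(row_norms(r$envelope[idx, , drop = FALSE] %*% t(model$N_scaled)))
    }, numeric(1)))
  }
  rest <- calibration$rest
  idx <- hold_indices(rest, 2)
  nt <- rest$envelope[idx, , drop = FALSE] %*% t(model$N_scaled)
  out[9] <- mean(row_norms(sweep(nt, 2, model$n0)))
  names(out) <- paste0("T", 1:9)
  out
}

#' Success rates by target group
#'
#' @param session a `session_log`.
#' @param group_by for CTR sessions: any of `"position"`, `"size"`; for NSTR
#'   the grouping is always by target id.
#' @return Data frame with one row per group: `n`, `successes`, `rate`.
#' @export
success_rate <- function(session, group_by = c("position", "size")) {
  stopifnot(inherits(session, "session_log"))
  succ <- vapply(session$trials, `[[`, logical(1), "success")
  if (session$paradigm == "nstr") {
    g <- vapply(session$trials, `[[`, integer(1), "target_id")
    key <- data.frame(target_id = g)
  } else {
    key <- data.frame(row.names = seq_along(succ))
    if ("position" %in% group_by)
      key$position_id <- vapply(session$trials, `[[`, integer(1), "position_id")
    if ("size" %in% group_by)
      key$size_id <- vapply(session$trials, `[[`, integer(1), "size_id")
    if (!ncol(key)) stop("group_by must name at least one factor", call. = FALSE)
  }
  agg <- stats::aggregate(succ, by = as.list(key), FUN = function(s)
    c(n = length(s), successes = sum(s)))
  out <- cbind(agg[, setdiff(names(agg), "x"), drop = FALSE],
               as.data.frame(agg$x))
  out$rate <- out$successes / out$n
  out
}

#' Per-target latency summaries
#'
#' Medians and interquartile ranges of the time to success, grouped per
#' target; CTR sessions additionally report the separate task-space and
#' null-space latencies.
#'
#' @param session a `session_log` with at least one successful trial.
#' @return Data frame, one row per target group.
#' @export
time_to_success_summary <- function(session) {
  stopifnot(inherits(session, "session_log"))
  succ <- vapply(session$trials, `[[`, logical(1), "success")
  med_iqr <- function(x) c(median = stats::median(x),
                           iqr = unname(stats::IQR(x)))
  if (session$paradigm == "nstr") {
    g <- vapply(session$trials, `[[`, integer(1), "target_id")[succ]
    tts <- vapply(session$trials, `[[`, numeric(1), "time_to_success")[succ]
    if (!length(tts)) return(data.frame(target_id = integer(0),
                                        median = numeric(0), iqr = numeric(0)))
    agg <- stats::aggregate(tts, by = list(target_id = g), FUN = med_iqr)
    cbind(agg["target_id"], as.data.frame(agg$x))
  } else {
    pid <- vapply(session$trials, `[[`, integer(1), "position_id")[succ]
    sid <- vapply(session$trials, `[[`, integer(1), "size_id")[succ]
    df <- data.frame(
      position_id = pid, size_id = sid,
      tts = vapply(session$trials, `[[`, numeric(1), "time_to_success")[succ],
      task = vapply(session$trials, `[[`, numeric(1), "task_latency")[succ],
      null = vapply(session$trials, `[[`, numeric(1), "null_latency")[succ])
    if (!nrow(df)) return(df[0, ])
    agg <- stats::aggregate(df[c("tts", "task", "null")],
                            by = df[c("position_id", "size_id")], FUN = med_iqr)
    out <- agg[c("position_id", "size_id")]
    for (v in c("tts", "task", "null")) {
      m <- as.data.frame(agg[[v]])
      names(m) <- paste0(v, c("_median", "_iqr"))
      out <- cbind(out, m)
    }
    out
  }
}
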