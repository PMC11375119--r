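# Deterministic simulation of the two reaching paradigms.
#
# NSTR (null-space target reaching): the cursor is the negative of the
# rotated null coordinate n; a trial succeeds when n stays within the target
# tolerance for the hold duration while the force magnitude stays below the
# threshold fraction of sMVF.  Targets progress by a 5-degree anticlockwise
# rotation once at least 80% of the last ten trials at the current target
# succeeded.
#
# CTR (concurrent target reaching): the cursor position is the sMVF-scaled
# force and its radius the unrotated null magnitude ||n~||; a trial succeeds
# when position and size conditions hold jointly for the hold duration.

#' NSTR session configuration
#'
#' @param n_trials number of target reaches (default 80).
#' @param trial_duration trial length in seconds (default 7).
#' @param hold_duration required in-target hold in seconds (default 1).
#' @param null_tolerance target tolerance in rotated null units (default 0.4).
#' @param force_threshold_frac force threshold as a fraction of sMVF
#'   (default 0.04).
#' @param initial_target first target location in rotated null units
#'   (default `c(2, 0)`, the natural co-contraction coordinate at radius 2).
#' @param rotation_step anticlockwise progression step in degrees (default 5).
#' @param window moving-window length in trials for the progression rule
#'   (default 10).
#' @param success_frac required success fraction within the window
#'   (default 0.8).
#' @param exploration_duration free-exploration time in seconds before the
#'   trials (default 120).
#' @param fs sampling/evaluation rate in Hz (default 1000).
#' @return Object of class `nstr_config`.
#' @export
nstr_config <- function(n_trials = 80L, trial_duration = 7, hold_duration = 1,
                        null_tolerance = 0.4, force_threshold_frac = 0.04,
                        initial_target = c(2, 0), rotation_step = 5,
                        window = 10L, success_frac = 0.8,
                        exploration_duration = 120, fs = 1000) {
  cfg <- list(n_trials = as.integer(n_trials), trial_duration = trial_duration,
              hold_duration = hold_duration, null_tolerance = null_tolerance,
              force_threshold_frac = force_threshold_frac,
              initial_target = as.numeric(initial_target),
              rotation_step = rotation_step, window = as.integer(window),
              success_frac = success_frac,
              exploration_duration = exploration_duration, fs = fs)
  vals <- c(cfg$n_trials, cfg$trial_duration, cfg$hold_duration,
            cfg$null_tolerance, cfg$force_threshold_frac, cfg$rotation_step,
            cfg$window, cfg$fs)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all NSTR config scalars must be positive", call. = FALSE)
  if (cfg$success_frac <= 0 || cfg$success_frac > 1)
    stop("success_frac must lie in (0, 1]", call. = FALSE)
  structure(cfg, class = "nstr_config")
}

#' CTR session configuration
#'
#' Nine task-space target positions (origin plus eight points at a radius of
#' 0.2 in sMVF-fraction units) crossed with two null-space sizes
#' (`||n~|| = 3` and `6`). Position and size tolerances are not printed in
#' the study protocol; the defaults reuse the NSTR force-threshold fraction
#' and null tolerance and are config-overridable.
#'
#' @param n_trials number of reaches (default 90).
#' @param radius_frac task-target radius as a fraction of sMVF (default 0.2).
#' @param sizes the two null-space target sizes (default `c(3, 6)`).
#' @param trial_duration,hold_duration as in [nstr_config()].
#' @param position_tolerance tolerance on `||f/sMVF - position||`
#'   (default 0.04).
#' @param size_tolerance tolerance on `| ||n~|| - size |` in null units
#'   (default 0.4).
#' @param fs sampling/evaluation rate in Hz (default 1000).
#' @return Object of class `ctr_config` with a `positions` matrix (9 x 2,
#'   sMVF-fraction units; row 9 is the origin target T9).
#' @export
ctr_config <- function(n_trials = 90L, radius_frac = 0.2, sizes = c(3, 6),
                       trial_duration = 7, hold_duration = 1,
                       position_tolerance = 0.04, size_tolerance = 0.4,
                       fs = 1000) {
  ang <- deg2rad(45 * (0:7))
  positions <- rbind(radius_frac * cbind(cos(ang), sin(ang)), c(0, 0))
  rownames(positions) <- paste0("T", 1:9)
  if (length(sizes) != 2L) stop("exactly 2 target sizes are required", call. = FALSE)
  cfg <- list(n_trials = as.integer(n_trials), positions = positions,
              sizes = as.numeric(sizes), trial_duration = trial_duration,
              hold_duration = hold_duration,
              position_tolerance = position_tolerance,
              size_tolerance = size_tolerance, fs = fs)
  structure(cfg, class = "ctr_config")
}

#' Evaluate one NSTR trial
#'
#' Success requires a contiguous window of `hold_duration` in which every
#' sample satisfies `||n - target|| <= null_tolerance` and
#' `||f|| < force_threshold_frac * sMVF`. `time_to_success` is the end of the
#' first such window. The displayed cursor is the negative of `n`; evaluation
#' is in n-space.
#'
#' @param traj_null T x 2 matrix of rotated null coordinates `n`.
#' @param traj_force T x 2 matrix of force (N), time-aligned with `traj_null`.
#' @param target 2-vector target in rotated null units.
#' @param config an [nstr_config()].
#' @param smvf scaling MVF in newtons.
#' @return Object of class `trial_result`: `success`, `time_to_success`
#'   (s, `NA` on failure), `hold_start` (s), per-sample `in_target` and
#'   `force_ok` flags, and the trajectories.
#' @export
evaluate_nstr_trial <- function(traj_null, traj_force, target, config, smvf) {
  stopifnot(inherits(config, "nstr_config"))
  if (missing(smvf) || is.null(smvf) || !is.finite(smvf))
    stop("sMVF is required to evaluate the force threshold", call. = FALSE)
  traj_null <- as.matrix(traj_null); traj_force <- as.matrix(traj_force)
  stopifnot(nrow(traj_null) == nrow(traj_force))
  fs <- config$fs
  if (nrow(traj_null) > config$trial_duration * fs + 1)
    stop("trajectory longer than the trial duration", call. = FALSE)
  in_target <- row_norms(sweep(traj_null, 2, target)) <= config$null_tolerance
  force_ok <- row_norms(traj_force) < config$force_threshold_frac * smvf
  win <- first_true_window(in_target & force_ok,
                           as.integer(round(config$hold_duration * fs)))
  success <- !is.null(win)
  structure(list(paradigm = "nstr", target = as.numeric(target),
                 success = success,
                 time_to_success = if (success) win[2] / fs else NA_real_,
                 hold_start = if (success) (win[1] - 1) / fs else NA_real_,
                 in_target = in_target, force_ok = force_ok,
                 traj_null = traj_null, traj_force = traj_force, fs = fs),
            class = "trial_result")
}

#' Adaptive target progression for NSTR
#'
#' If the number of successful trials at the current target within the last
#' `window` trials reaches `success_frac * window`, the next target is the
#' current one rotated anticlockwise by `rotation_step` degrees about the
#' origin (magnitude preserved); otherwise the target is unchanged. Only
#' trials at the current target count, evaluated from the first trial at that
#' target, so with the defaults eight consecutive successes suffice.
#'
#' @param history data frame with columns `target_id` (integer) and `success`
#'   (logical), one row per completed trial in order.
#' @param current_target 2-vector, the current target location.
#' @param config an [nstr_config()].
#' @return List with `target` (2-vector for the next trial) and `progressed`
#'   (logical).
#' @export
progression_update <- function(history, current_target, config) {
  stopifnot(inherits(config, "nstr_config"), nrow(history) >= 1L)
  cur_id <- history$target_id[nrow(history)]
  recent <- utils::tail(history, config$window)
  n_ok <- sum(recent$success & recent$target_id == cur_id)
  need <- ceiling(config$success_frac * config$window - 1e-9)
  if (n_ok >= need) {
    list(target = as.numeric(rot2(config$rotation_step) %*% current_target),
         progressed = TRUE)
  } else {
    list(target = as.numeric(current_target), progressed = FALSE)
  }
}

#' Run an NSTR session
#'
#' Executes `n_trials` trials: the controller produces an activation
#' trajectory for the current target, the engine projects it through the
#' null-space model, evaluates the trial and applies the progression rule.
#'
#' @param controller function `(target, trial_index)` returning a T x 4
#'   matrix of non-negative activations sampled at `config$fs`
#'   (T = `trial_duration * fs`).
#' @param model a [nullspace_model()].
#' @param config an [nstr_config()].
#' @param smvf scaling MVF in newtons.
#' @param store_trajectories keep per-trial trajectories in the log
#'   (default `TRUE`).
#' @return Object of class `session_log` with per-trial results, target ids
#'   and the set of distinct targets attempted.
#' @export
run_nstr_session <- function(controller, model, config, smvf,
                             store_trajectories = TRUE) {
  stopifnot(inherits(config, "nstr_config"), inherits(model, "nullspace_model"))
  target <- config$initial_target
  target_id <- 1L
  targets <- list(target)
  trials <- vector("list", config$n_trials)
  history <- data.frame(target_id = integer(0), success = logical(0))
  for (k in seq_len(config$n_trials)) {
    alpha <- controller(target, k)
    alpha <- as.matrix(alpha)
    if (any(alpha < 0))
      stop("controller emitted negative activations", call. = FALSE)
    pr <- project(alpha, model)
    tr <- evaluate_nstr_trial(pr$null, pr$force, target, config, smvf)
    tr$trial <- k
    tr$target_id <- target_id
    if (!store_trajectories) {
      tr$traj_null <- NULL; tr$traj_force <- NULL
      tr$in_target <- NULL; tr$force_ok <- NULL
    }
    trials[[k]] <- tr
    history <- rbind(history,
                     data.frame(target_id = target_id, success = tr$success))
    up <- progression_update(history, target, config)
    if (up$progressed && k < config$n_trials) {
      target <- up$target
      target_id <- target_id + 1L
      targets[[target_id]] <- target
    }
  }
  new_session_log("nstr", config, smvf, trials, targets, history)
}

#' Randomised CTR target schedule
#'
#' Draws `n_trials` (position, size) pairs uniformly over the 9 positions and
#' 2 sizes, reproducibly for a fixed seed.
#'
#' @param config a [ctr_config()].
#' @param seed integer seed.
#' @return Data frame with columns `position_id` (1-9), `size_id` (1-2) and
#'   `size` (null units).
#' @export
generate_ctr_schedule <- function(config, seed) {
  stopifnot(inherits(config, "ctr_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  pos <- sample.int(nrow(config$positions), config$n_trials, replace = TRUE)
  sz <- sample.int(length(config$sizes), config$n_trials, replace = TRUE)
  data.frame(position_id = pos, size_id = sz, size = config$sizes[sz])
}

#' Evaluate one CTR trial
#'
#' Success requires a contiguous hold in which, at every sample,
#' `||f/sMVF - position|| <= position_tolerance` and
#' `| ||n~|| - size | <= size_tolerance`, where `||n~||` is the unrotated
#' null magnitude driving the cursor radius. With `require_hold = FALSE` the
#' hold shrinks to a single sample (reach-only success). Task- and null-space
#' latencies are the entry times of the continuous condition runs leading
#' into the successful hold.
#'
#' @param traj_ntilde T x 2 matrix of unrotated null coordinates `n~`.
#' @param traj_force T x 2 matrix of force (N).
#' @param position 2-vector task target in sMVF-fraction units.
#' @param size target null magnitude.
#' @param config a [ctr_config()].
#' @param smvf scaling MVF in newtons.
#' @param require_hold logical, default `TRUE`.
#' @return Object of class `trial_result` with `success`, `time_to_success`,
#'   `task_latency`, `null_latency`, `ntilde_at_task_reach` and trajectories.
#' @export
evaluate_ctr_trial <- function(traj_ntilde, traj_force, position, size,
                               config, smvf, require_hold = TRUE) {
  stopifnot(inherits(config, "ctr_config"))
  if (missing(smvf) || is.null(smvf) || !is.finite(smvf))
    stop("sMVF is required to scale the task-space cursor", call. = FALSE)
  traj_ntilde <- as.matrix(traj_ntilde); traj_force <- as.matrix(traj_force)
  stopifnot(nrow(traj_ntilde) == nrow(traj_force))
  fs <- config$fs
  pos_ok <- row_norms(sweep(traj_force / smvf, 2, position)) <=
    config$position_tolerance
  nt_mag <- row_norms(traj_ntilde)
  size_ok <- abs(nt_mag - size) <= config$size_tolerance
  hold_n <- if (require_hold) as.integer(round(config$hold_duration * fs)) else 1L
  win <- first_true_window(pos_ok & size_ok, hold_n)
  success <- !is.null(win)
  task_latency <- null_latency <- nt_at_reach <- NA_real_
  if (success) {
    task_i <- run_entry(pos_ok, win[1])
    null_i <- run_entry(size_ok, win[1])
    task_latency <- task_i / fs
    null_latency <- null_i / fs
    nt_at_reach <- nt_mag[task_i]
  }
  structure(list(paradigm = "ctr", position = as.numeric(position),
                 size = size, success = success,
                 time_to_success = if (success) win[2] / fs else NA_real_,
                 hold_start = if (success) (win[1] - 1) / fs else NA_real_,
                 task_latency = task_latency, null_latency = null_latency,
                 ntilde_at_task_reach = nt_at_reach,
                 pos_ok = pos_ok, size_ok = size_ok,
                 traj_ntilde = traj_ntilde, traj_force = traj_force, fs = fs),
            class = "trial_result")
}

## first index of the maximal run of TRUEs in `ok` that contains index `at`
run_entry <- function(ok, at) {
  i <- at
  while (i > 1L && ok[i - 1L]) i <- i - 1L
  i
}

#' Run a CTR session
#'
#' Draws the randomised schedule and evaluates one controller-generated trial
#' per (position, size) pair.
#'
#' @param controller function `(position, size, trial_index)` returning a
#'   T x 4 matrix of non-negative activations at `config$fs`.
#' @param model a [nullspace_model()].
#' @param config a [ctr_config()].
#' @param smvf scaling MVF in newtons.
#' @param seed integer seed for the target schedule.
#' @param store_trajectories keep per-trial trajectories (default `TRUE`).
#' @return A `session_log`.
#' @export
run_ctr_session <- function(controller, model, config, smvf, seed,
                            store_trajectories = TRUE) {
  stopifnot(inherits(config, "ctr_config"), inherits(model, "nullspace_model"))
  sched <- generate_ctr_schedule(config, seed)
  trials <- vector("list", config$n_trials)
  for (k in seq_len(config$n_trials)) {
    position <- config$positions[sched$position_id[k], ]
    size <- sched$size[k]
    alpha <- as.matrix(controller(position, size, k))
    if (any(alpha < 0))
      stop("controller emitted negative activations", call. = FALSE)
    pr <- project(alpha, model)
    tr <- evaluate_ctr_trial(pr$null_tilde, pr$force, position, size,
                             config, smvf)
    tr$trial <- k
    tr$position_id <- sched$position_id[k]
    tr$size_id <- sched$size_id[k]
    if (!store_trajectories) {
      tr$traj_ntilde <- NULL; tr$traj_force <- NULL
      tr$pos_ok <- NULL; tr$size_ok <- NULL
    }
    trials[[k]] <- tr
  }
  new_session_log("ctr", config, smvf, trials,
                  targets = list(positions = config$positions,
                                 sizes = config$sizes),
                  history = sched)
}

new_session_log <- function(paradigm, config, smvf, trials, targets, history) {
  structure(list(paradigm = paradigm, config = config, smvf = smvf,
                 trials = trials, targets = targets, history = history),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  ns <- sum(vapply(x$trials, `[[`, logical(1), "success"))
  cat(sprintf("<session_log> %s: %d trials, %d successes\n",
              toupper(x$paradigm), length(x$trials), ns))
  invisible(x)
}

#' Distinct NSTR targets attempted in a session
#'
#' @param session an NSTR `session_log`.
#' @return Matrix of the distinct target locations (one per row), in order of
#'   first attempt.
#' @export
session_targets <- function(session) {
  stopifnot(inherits(session, "session_log"), session$paradigm == "nstr")
  do.call(rbind, session$targets)
}

## save/restore .Random.seed so schedule generation does not disturb the
## caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
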