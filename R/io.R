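# File formats: CSV for time series, JSON for models and logs.
# Channel order is fixed and recorded in every header: fcr, fcu, ecrl, ecu.
# Angles are serialized in degrees; null coordinates are in the rotated
# frame unless a frame tag says otherwise.

recording_header <- c("time_s", "emg_fcr", "emg_fcu", "emg_ecrl", "emg_ecu",
                      "force_x_n", "force_y_n")

#' Read a raw recording from CSV
#'
#' Expects the documented header `time_s, emg_fcr, emg_fcu, emg_ecrl,
#' emg_ecu, force_x_n, force_y_n`; validates the uniform time grid and
#' rejects missing columns, non-monotone time and non-finite samples with
#' row numbers.
#'
#' @param path CSV file path.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(recording_header, names(df))
  if (length(miss))
    stop(sprintf("missing columns in %s: %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  bad <- which(!stats::complete.cases(df[recording_header]) |
                 !apply(sapply(df[recording_header], is.finite), 1, all))
  if (length(bad))
    stop(sprintf("non-finite samples in %s at rows: %s", path,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    r <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(sprintf("non-monotone time in %s at row %d", path, r), call. = FALSE)
  }
  emg_recording(df$time_s,
                as.matrix(df[c("emg_fcr", "emg_fcu", "emg_ecrl", "emg_ecu")]),
                as.matrix(df[c("force_x_n", "force_y_n")]))
}

#' Write a raw recording to CSV
#'
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(rec$time, rec$emg, rec$force)
  names(df) <- recording_header
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a pulling matrix to JSON
#'
#' Stores the matrix row-major with its per-axis R-squared, the channel
#' order and (optionally) the sMVF.
#'
#' @param pm a `pulling_matrix`.
#' @param path output path.
#' @param smvf optional scaling MVF to record alongside.
#' @return The path, invisibly.
#' @export
write_pulling_matrix <- function(pm, path, smvf = NULL) {
  stopifnot(inherits(pm, "pulling_matrix"))
  obj <- list(H = as.numeric(t(pm$H)), shape = c(2L, 4L), order = "row-major",
              r_squared = as.numeric(pm$r_squared), n_points = pm$n_points,
              channels = emg_channels())
  if (!is.null(smvf)) obj$smvf <- smvf
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pulling matrix from JSON
#'
#' @param path file written by [write_pulling_matrix()].
#' @return List with `H` (2x4), `r_squared` and, when present, `smvf`.
#' @export
read_pulling_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(obj$H, 2, 4, byrow = TRUE,
              dimnames = list(c("x", "y"), obj$channels))
  list(H = H, r_squared = obj$r_squared, smvf = obj$smvf)
}

#' Serialize a null-space model to JSON
#'
#' Matrices are written row-major with the channel order recorded.
#'
#' @param model a [nullspace_model()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_nullspace_model <- function(model, path) {
  stopifnot(inherits(model, "nullspace_model"))
  obj <- list(H = as.numeric(t(model$H)), N = as.numeric(t(model$N)),
              kappa = model$kappa, n0 = model$n0, n_c = model$n_c,
              R_c = as.numeric(t(model$R_c)), order = "row-major",
              channels = model$channels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a null-space model from JSON
#'
#' @param path file written by [write_nullspace_model()].
#' @return A validated [nullspace_model()].
#' @export
read_nullspace_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- matrix(obj$H, 2, 4, byrow = TRUE)
  N <- matrix(obj$N, 2, 4, byrow = TRUE)
  new_nullspace_model(H, N, obj$kappa, obj$kappa * N, obj$n0, obj$n_c)
}

#' Write a session log to a directory
#'
#' Emits `trials.jsonl` (one JSON record per trial), per-trial trajectory
#' CSVs under `trajectories/`, and a `manifest.json` run manifest naming the
#' configuration, seeds and files.
#'
#' @param log a `session_log`.
#' @param dir output directory (created if needed).
#' @param seed seed to record in the manifest (optional).
#' @return The directory, invisibly.
#' @export
write_session_log <- function(log, dir, seed = NULL) {
  stopifnot(inherits(log, "session_log"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj_dir <- file.path(dir, "trajectories")
  records <- vector("character", length(log$trials))
  has_traj <- length(log$trials) > 0 && !is.null(log$trials[[1]]$traj_force)
  if (has_traj) dir.create(traj_dir, showWarnings = FALSE)
  for (k in seq_along(log$trials)) {
    tr <- log$trials[[k]]
    rec <- list(trial = tr$trial, paradigm = tr$paradigm,
                success = tr$success, time_to_success = tr$time_to_success,
                hold_start = tr$hold_start)
    if (tr$paradigm == "nstr") {
      rec$target_id <- tr$target_id
      rec$target <- tr$target
    } else {
      rec$position_id <- tr$position_id
      rec$size_id <- tr$size_id
      rec$position <- tr$position
      rec$size <- tr$size
      rec$task_latency <- tr$task_latency
      rec$null_latency <- tr$null_latency
      rec$ntilde_at_task_reach <- tr$ntilde_at_task_reach
    }
    if (has_traj) {
      f <- file.path("trajectories", sprintf("trial_%03d.csv", k))
      nul <- if (tr$paradigm == "nstr") tr$traj_null else tr$traj_ntilde
      df <- data.frame(time_s = seq_len(nrow(nul)) / tr$fs,
                       null_x = nul[, 1], null_y = nul[, 2],
                       force_x_n = tr$traj_force[, 1],
                       force_y_n = tr$traj_force[, 2])
      utils::write.csv(df, file.path(dir, f), row.names = FALSE)
      rec$trajectory_file <- f
      rec$null_frame <- if (tr$paradigm == "nstr") "rotated" else "unrotated"
    }
    records[k] <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                   null = "null", na = "null")
  }
  writeLines(records, file.path(dir, "trials.jsonl"))
  manifest <- list(paradigm = log$paradigm, n_trials = length(log$trials),
                   smvf = log$smvf, seed = seed,
                   config = unclass_config(log$config),
                   files = c("trials.jsonl",
                             if (has_traj) sprintf("trajectories/trial_%03d.csv",
                                                   seq_along(log$trials))),
                   package_version = as.character(utils::packageVersion("nullreach")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

unclass_config <- function(cfg) {
  x <- unclass(cfg)
  if (!is.null(x$positions)) x$positions <- as.numeric(t(x$positions))
  x
}

#' Read a session log directory
#'
#' Reconstructs a `session_log` from the files written by
#' [write_session_log()] (trajectories included when present).
#'
#' @param dir directory containing `manifest.json` and `trials.jsonl`.
#' @return A `session_log`.
#' @export
read_session_log <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop(sprintf("missing manifest: %s", man_path), call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "trials.jsonl"))
  trials <- lapply(lines, function(l) {
    tr <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    if (!is.null(tr$trajectory_file)) {
      fp <- file.path(dir, tr$trajectory_file)
      if (!file.exists(fp))
        stop(sprintf("session log names a missing trajectory file: %s", fp),
             call. = FALSE)
      df <- utils::read.csv(fp)
      nul <- as.matrix(df[c("null_x", "null_y")])
      if (identical(tr$paradigm, "nstr")) tr$traj_null <- nul
      else tr$traj_ntilde <- nul
      tr$traj_force <- as.matrix(df[c("force_x_n", "force_y_n")])
      tr$fs <- 1 / mean(diff(df$time_s))
    }
    tr$time_to_success <- tr$time_to_success %||% NA_real_
    tr$hold_start <- tr$hold_start %||% NA_real_
    class(tr) <- "trial_result"
    tr
  })
  cfg <- as.list(manifest$config)
  if (!is.null(cfg$positions))
    cfg$positions <- matrix(cfg$positions, ncol = 2, byrow = TRUE,
                            dimnames = list(paste0("T", 1:9), NULL))
  class(cfg) <- paste0(manifest$paradigm, "_config")
  structure(list(paradigm = manifest$paradigm, config = cfg,
                 smvf = manifest$smvf, trials = trials,
                 targets = NULL, history = NULL, manifest = manifest),
            class = "session_log")
}
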