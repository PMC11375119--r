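#' Multichannel EMG + force recording
#'
#' Container for a synchronized raw recording: four surface-EMG channels from
#' the wrist muscles (FCR, FCU, ECRL, ECU) and the two planar force axes
#' (X = flexion--extension, Y = radial--ulnar deviation), sampled on a uniform
#' time grid.
#'
#' @param time numeric vector of sample times in seconds (uniform grid).
#' @param emg numeric matrix, one column per EMG channel in the order
#'   FCR, FCU, ECRL, ECU (arbitrary units).
#' @param force numeric matrix with two columns, force in newtons.
#' @param fs sampling rate in Hz; inferred from `time` when `NULL`.
#'
#' @return An object of class `emg_recording` with fields `time`, `emg`,
#'   `force`, `fs` and `channels`.
#' @export
emg_recording <- function(time, emg, force, fs = NULL) {
  emg <- as.matrix(emg)
  force <- as.matrix(force)
  n <- length(time)
  if (nrow(emg) != n || nrow(force) != n)
    stop("time, emg and force must share the same number of samples", call. = FALSE)
  if (ncol(emg) != 4L)
    stop("emg must have 4 channels (FCR, FCU, ECRL, ECU)", call. = FALSE)
  if (ncol(force) != 2L)
    stop("force must have 2 channels (X, Y)", call. = FALSE)
  stop_if_not_finite(time, "time")
  stop_if_not_finite(emg, "emg")
  stop_if_not_finite(force, "force")
  if (n >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0))
      stop("time grid must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("time grid must be uniform", call. = FALSE)
    if (is.null(fs)) fs <- 1 / mean(dt)
  }
  if (is.null(fs)) stop("fs must be given for single-sample recordings", call. = FALSE)
  colnames(emg) <- emg_channels()
  colnames(force) <- c("x", "y")
  structure(list(time = as.numeric(time), emg = emg, force = force,
                 fs = as.numeric(fs), channels = emg_channels()),
            class = "emg_recording")
}

#' Canonical EMG channel order
#'
#' @return Character vector `c("fcr", "fcu", "ecrl", "ecu")`.
#' @export
emg_channels <- function() c("fcr", "fcu", "ecrl", "ecu")

#' Envelope recording
#'
#' A processed recording holding the non-negative EMG envelope alpha(t) per
#' channel together with the (unfiltered) force trace. Produced by
#' [emg_envelope()] or synthesized directly at envelope level.
#'
#' @param time numeric sample times in seconds.
#' @param envelope numeric matrix, 4 non-negative envelope channels.
#' @param force numeric matrix, 2 force channels in newtons.
#' @param fs sampling rate in Hz; inferred from `time` when `NULL`.
#' @param warmup filter warm-up duration in seconds flagged at the start of the
#'   recording; excluded from calibration averages.
#'
#' @return An object of class `envelope_recording`.
#' @export
envelope_recording <- function(time, envelope, force, fs = NULL, warmup = 0) {
  envelope <- as.matrix(envelope)
  force <- as.matrix(force)
  n <- length(time)
  if (nrow(envelope) != n || nrow(force) != n)
    stop("time, envelope and force must share the same number of samples", call. = FALSE)
  if (ncol(envelope) != 4L) stop("envelope must have 4 channels", call. = FALSE)
  if (ncol(force) != 2L) stop("force must have 2 channels", call. = FALSE)
  stop_if_not_finite(envelope, "envelope")
  if (any(envelope < 0))
    stop("envelope values must be non-negative", call. = FALSE)
  if (is.null(fs)) {
    if (n < 2L) stop("fs must be given for single-sample recordings", call. = FALSE)
    fs <- 1 / mean(diff(time))
  }
  colnames(envelope) <- emg_channels()
  colnames(force) <- c("x", "y")
  structure(list(time = as.numeric(time), envelope = envelope, force = force,
                 fs = as.numeric(fs), warmup = warmup, channels = emg_channels()),
            class = "envelope_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples @ %g Hz (%.2f s), channels: %s\n",
              length(x$time), x$fs, length(x$time) / x$fs,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
print.envelope_recording <- function(x, ...) {
  cat(sprintf("<envelope_recording> %d samples @ %g Hz (%.2f s), warm-up %g s\n",
              length(x$time), x$fs, length(x$time) / x$fs, x$warmup))
  invisible(x)
}

## Mean envelope (4-vector) over a recording's final `window` seconds.
## The warm-up flag is respected: samples before `warmup` never contribute.
mean_envelope_hold <- function(rec, window = 2) {
  idx <- hold_indices(rec, window)
  colMeans(rec$envelope[idx, , drop = FALSE])
}

mean_force_hold <- function(rec, window = 2) {
  idx <- hold_indices(rec, window)
  colMeans(rec$force[idx, , drop = FALSE])
}

hold_indices <- function(rec, window) {
  t_end <- rec$time[length(rec$time)]
  keep <- rec$time >= max(t_end - window, rec$warmup %||% 0)
  if (!any(keep)) stop("hold window is empty", call. = FALSE)
  which(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
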