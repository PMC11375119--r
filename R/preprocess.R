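# EMG envelope extraction and trajectory smoothing.
#
# The envelope chain is: second-order Butterworth high-pass at 20 Hz,
# full-wave rectification, second-order Butterworth low-pass at 5 Hz,
# applied per channel. Filtering is causal by default (single pass,
# zero initial state), matching an online visual-feedback context; a
# zero-phase option (forward-backward pass) is available for offline use.

#' Extract EMG envelopes from a raw recording
#'
#' Applies, per EMG channel, a second-order Butterworth high-pass at
#' `highpass` Hz, full-wave rectification, and a second-order Butterworth
#' low-pass at `lowpass` Hz. Small negative ringing after the low-pass is
#' clipped to zero so the envelope is non-negative at every sample (the
#' non-negativity is load-bearing for the reachable-cone computation).
#' Force channels pass through unchanged.
#'
#' @param raw an [emg_recording()].
#' @param highpass high-pass cut-off in Hz (default 20).
#' @param lowpass low-pass cut-off in Hz (default 5).
#' @param zero_phase logical; if `TRUE` use zero-phase (forward-backward)
#'   filtering for offline analysis. Default `FALSE` (causal).
#' @param warmup duration in seconds flagged as filter warm-up and excluded
#'   from calibration averages (default 0.5).
#'
#' @return An [envelope_recording()] of the same length.
#' @export
emg_envelope <- function(raw, highpass = 20, lowpass = 5, zero_phase = FALSE,
                         warmup = 0.5) {
  stopifnot(inherits(raw, "emg_recording"))
  if (raw$fs < 100)
    stop("sampling rate below 100 Hz: envelope extraction rejected", call. = FALSE)
  if (length(raw$time) < raw$fs)
    stop("recording shorter than 1 s: envelope extraction rejected", call. = FALSE)
  if (raw$fs <= 2 * max(highpass, lowpass))
    stop("sampling rate violates the Nyquist requirement for the filter cut-offs",
         call. = FALSE)
  stop_if_not_finite(raw$emg, "emg")
  hp <- signal::butter(2, highpass / (raw$fs / 2), type = "high")
  lp <- signal::butter(2, lowpass / (raw$fs / 2), type = "low")
  apply_filt <- function(filt, x) {
    if (zero_phase) as.numeric(signal::filtfilt(filt, x))
    else as.numeric(signal::filter(filt, x))
  }
  env <- apply(raw$emg, 2, function(x) {
    y <- abs(apply_filt(hp, x))
    pmax(apply_filt(lp, y), 0)
  })
  envelope_recording(raw$time, env, raw$force, fs = raw$fs, warmup = warmup)
}

#' Low-pass smooth a planar trajectory
#'
#' Filters each coordinate of a 2-D time series with a second-order
#' Butterworth low-pass (causal). Used before correction counting.
#'
#' @param trace numeric matrix with 2 columns (one sample per row).
#' @param fs sampling rate in Hz.
#' @param cutoff low-pass cut-off in Hz (default 3).
#'
#' @return Matrix of the same dimensions.
#' @export
smooth_trajectory <- function(trace, fs, cutoff = 3) {
  trace <- as.matrix(trace)
  if (cutoff >= fs / 2) stop("cutoff must be below fs/2", call. = FALSE)
  if (nrow(trace) < 12L)
    stop("trace shorter than the filter warm-up: smoothing rejected", call. = FALSE)
  lp <- signal::butter(2, cutoff / (fs / 2), type = "low")
  ## seed the filter state at the first sample to avoid a step transient
  apply(trace, 2, function(x) {
    x0 <- x[1L]
    x0 + as.numeric(signal::filter(lp, x - x0))
  })
}
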