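# Force/EMG calibration: maximum voluntary force, the sMVF scaling, and
# ordinary-least-squares estimation of the 2x4 pulling matrix H in f = H alpha.

#' MVF direction schedule
#'
#' The 16 instructed maximum-voluntary-force directions, every 22.5 degrees.
#' The schedule starts from leftward (flexion, 180 degrees in the
#' X = extension-positive frame) and progresses anticlockwise.
#'
#' @return Numeric vector of 16 angles in degrees, wrapped to \[0, 360).
#' @export
mvf_directions <- function() {
  wrap360(180 + 22.5 * (0:15))
}

#' Per-direction maximum voluntary force
#'
#' The MVF for a direction is the maximum of the force-magnitude signal over
#' the final 2 s of a (at least) 4-s exertion.
#'
#' @param force_trace numeric matrix, 2 columns (X, Y force in N).
#' @param fs sampling rate in Hz.
#' @param window length in seconds of the final analysis window (default 2).
#' @param direction optional instructed direction in degrees; when
#'   `projection = TRUE` the force is projected onto it instead of taking the
#'   planar magnitude.
#' @param projection logical, default `FALSE` (use the 2-D magnitude).
#'
#' @return Maximum force in newtons.
#' @export
compute_mvf <- function(force_trace, fs, window = 2, direction = NULL,
                        projection = FALSE) {
  force_trace <- as.matrix(force_trace)
  n <- nrow(force_trace)
  if (n / fs < 2 * window)
    stop("force trace shorter than 4 s: MVF rejected", call. = FALSE)
  idx <- which(seq_len(n) / fs >= n / fs - window)
  seg <- force_trace[idx, , drop = FALSE]
  if (projection) {
    if (is.null(direction)) stop("projection = TRUE requires a direction", call. = FALSE)
    u <- c(cos(deg2rad(direction)), sin(deg2rad(direction)))
    max(seg %*% u)
  } else {
    max(row_norms(seg))
  }
}

#' Scaling MVF
#'
#' The participant-specific scaling MVF (sMVF) is the minimum of the 16
#' per-direction MVF values; all force thresholds and target radii in the
#' tasks are expressed as fractions of it.
#'
#' @param mvf_by_direction numeric vector of 16 positive MVF values.
#' @return The minimum, a scalar in newtons.
#' @export
compute_smvf <- function(mvf_by_direction) {
  if (length(mvf_by_direction) != 16L)
    stop("expected 16 per-direction MVF values", call. = FALSE)
  if (any(!is.finite(mvf_by_direction)) || any(mvf_by_direction <= 0))
    stop("MVF values must be positive and finite", call. = FALSE)
  min(mvf_by_direction)
}

#' Calibration target set
#'
#' The 17 force targets used to fit the pulling matrix: one rest target at
#' \[0, 0\] N plus 16 targets evenly spaced on the circle of radius
#' `0.2 * smvf`, ordered anticlockwise starting from +X (extension).
#'
#' @param smvf scaling MVF in newtons.
#' @param radius_frac fraction of sMVF for the circle radius (default 0.2).
#' @return A 17 x 2 matrix of target forces in newtons; the first row is rest.
#' @export
make_calibration_targets <- function(smvf, radius_frac = 0.2) {
  if (!is.finite(smvf) || smvf <= 0) stop("smvf must be positive", call. = FALSE)
  ang <- deg2rad(22.5 * (0:15))
  rbind(c(0, 0), radius_frac * smvf * cbind(cos(ang), sin(ang)))
}

#' Calibration points
#'
#' A set of per-target calibration observations: the commanded target force,
#' the mean measured force over the final 2-s hold, and the mean EMG envelope
#' over the same window.
#'
#' @param target_force n x 2 matrix of commanded forces (N).
#' @param mean_force n x 2 matrix of held mean forces (N).
#' @param mean_envelope n x 4 matrix of held mean envelopes.
#' @return An object of class `calibration_points`.
#' @export
calibration_points <- function(target_force, mean_force, mean_envelope) {
  target_force <- as.matrix(target_force)
  mean_force <- as.matrix(mean_force)
  mean_envelope <- as.matrix(mean_envelope)
  n <- nrow(target_force)
  stopifnot(nrow(mean_force) == n, nrow(mean_envelope) == n,
            ncol(target_force) == 2L, ncol(mean_force) == 2L,
            ncol(mean_envelope) == 4L)
  stop_if_not_finite(mean_envelope, "mean_envelope")
  stop_if_not_finite(mean_force, "mean_force")
  structure(list(target_force = target_force, mean_force = mean_force,
                 mean_envelope = mean_envelope),
            class = "calibration_points")
}

#' @export
print.calibration_points <- function(x, ...) {
  cat(sprintf("<calibration_points> %d points\n", nrow(x$mean_force)))
  invisible(x)
}

#' Fit the pulling matrix by ordinary least squares
#'
#' Estimates the 2x4 pulling matrix H in the linear model f = H alpha by OLS
#' over calibration points, with no intercept: the rest target anchors the
#' origin, and any rest-level envelope bias is handled downstream by the
#' null-space offset.
#'
#' @param points a [calibration_points()] object with at least 17 points.
#' @return An object of class `pulling_matrix` with fields `H` (2x4),
#'   `r_squared` (per force axis), `residuals` (n x 2) and `n_points`.
#' @export
fit_pulling_matrix <- function(points) {
  stopifnot(inherits(points, "calibration_points"))
  X <- points$mean_envelope
  Y <- points$mean_force
  if (nrow(X) < 17L)
    stop("need at least 17 calibration points", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    dep <- sort(qrX$pivot[seq.int(qrX$rank + 1L, 4L)])
    stop(sprintf("envelope design is rank-deficient; collinear channels: %s",
                 paste(emg_channels()[dep], collapse = ", ")), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)             # 4 x 2
  H <- t(B)
  dimnames(H) <- list(c("x", "y"), emg_channels())
  res <- Y - X %*% B
  q <- rsq_from_residuals(Y, res)
  structure(list(H = H, r_squared = q$r_squared, residuals = res,
                 n_points = nrow(X)),
            class = "pulling_matrix")
}

#' @export
print.pulling_matrix <- function(x, ...) {
  cat(sprintf("<pulling_matrix> fitted on %d points; R^2 x = %.4f, y = %.4f\n",
              x$n_points, x$r_squared[1], x$r_squared[2]))
  print(round(x$H, 4))
  invisible(x)
}

#' Goodness of fit of a pulling matrix
#'
#' Recomputes per-axis R-squared (about the axis mean) and per-point residual
#' norms of a pulling matrix on a set of calibration points.
#'
#' @param pm a [fit_pulling_matrix()] result, or a bare 2x4 matrix.
#' @param points a [calibration_points()] object.
#' @return List with `r_squared` (length 2, `NA` and a flag where an axis has
#'   zero variance) and `residual_norms` (length n).
#' @export
fit_quality <- function(pm, points) {
  H <- if (inherits(pm, "pulling_matrix")) pm$H else as.matrix(pm)
  stopifnot(inherits(points, "calibration_points"), all(dim(H) == c(2, 4)))
  if (nrow(points$mean_force) == 0L) stop("points must be non-empty", call. = FALSE)
  res <- points$mean_force - points$mean_envelope %*% t(H)
  q <- rsq_from_residuals(points$mean_force, res)
  list(r_squared = q$r_squared, zero_variance_axis = q$zero_variance,
       residual_norms = row_norms(res))
}

rsq_from_residuals <- function(Y, res) {
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  ssr <- colSums(res^2)
  zero <- sst <= .Machine$double.eps * nrow(Y)
  r2 <- ifelse(zero, NA_real_, 1 - ssr / sst)
  names(r2) <- c("x", "y")
  list(r_squared = r2, zero_variance = zero)
}
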