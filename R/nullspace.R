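# Construction of the scaled, offset, co-contraction-aligned null-space
# coordinate system and the non-negative reachable cone.
#
# With pulling matrix H (2x4), the null-space basis N (2x4) has orthonormal
# rows orthogonal to the rows of H.  The scaling kappa = max(||h1||, ||h2||)
# makes null-space coordinates n~ = kappa N alpha magnitude-comparable to
# force: ||n~|| = beta demands a muscle activity level similar to producing
# beta N of force.  The displayed coordinate is n = R_c (N~ alpha - n0) where
# n0 is the rest offset and R_c rotates the natural co-contraction coordinate
# n_c onto the +X axis.

#' Orthonormal null-space basis of a pulling matrix
#'
#' Returns the 2x4 matrix whose rows are orthonormal basis vectors of the
#' kernel of H (the muscle-activation directions producing zero force).
#' The rows come from the SVD of H; each row's sign is fixed so that its
#' largest-magnitude entry is positive, making serialized models reproducible.
#'
#' @param H 2x4 pulling matrix (or a `pulling_matrix` object).
#' @return 2x4 matrix `N` with `N %*% t(N) = I` and `N %*% t(H) = 0`.
#' @export
nullspace_basis <- function(H) {
  H <- as_H(H)
  sv <- svd(H, nu = 2, nv = 4)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("pulling matrix is not full row rank: null-space undefined", call. = FALSE)
  N <- t(sv$v[, 3:4, drop = FALSE])
  ## deterministic sign convention per row
  for (i in 1:2) {
    j <- which.max(abs(N[i, ]))
    if (N[i, j] < 0) N[i, ] <- -N[i, ]
  }
  N
}

#' Scale the null-space basis to force-comparable units
#'
#' `kappa = max(||h1||, ||h2||)`, the larger of the two row norms of H
#' (the EMG-to-force gains of the two principal force directions); the scaled
#' basis is `kappa * N`.
#'
#' @param N 2x4 orthonormal null-space basis.
#' @param H 2x4 pulling matrix (or `pulling_matrix`).
#' @return List with `kappa` (scalar) and `N_scaled` (2x4).
#' @export
scale_basis <- function(N, H) {
  H <- as_H(H)
  kappa <- max(vnorm(H[1, ]), vnorm(H[2, ]))
  list(kappa = kappa, N_scaled = kappa * N)
}

#' Rest offset of the null-space coordinates
#'
#' The offset `n0 = N_scaled %*% mean(alpha_rest)`, with the mean envelope
#' taken over the rest recording's analysis window (after filter warm-up).
#'
#' @param rest_recording an [envelope_recording()] of the rest trial,
#'   at least 2 s after warm-up.
#' @param N_scaled scaled null-space basis (2x4).
#' @return Numeric 2-vector `n0`.
#' @export
estimate_offset <- function(rest_recording, N_scaled) {
  stopifnot(inherits(rest_recording, "envelope_recording"))
  dur <- rest_recording$time[length(rest_recording$time)] -
    (rest_recording$warmup %||% 0)
  if (dur < 2)
    stop("rest recording must provide at least 2 s after warm-up", call. = FALSE)
  a <- mean_envelope_hold(rest_recording, window = dur)
  as.numeric(N_scaled %*% a)
}

#' Natural co-contraction coordinate
#'
#' Averages the null-space activity over the six co-contraction calibration
#' repetitions: for each repetition the mean envelope over its final 2-s hold
#' is projected through the scaled basis, and `n_c` is the mean of those
#' projections minus the rest offset. Both magnitude and direction are kept.
#'
#' @param repetitions list of exactly 6 [envelope_recording()]s.
#' @param N_scaled scaled null-space basis (2x4).
#' @param n0 rest offset 2-vector.
#' @param tol rejection threshold on `||n_c||` (the aligning rotation is
#'   undefined for a vanishing co-contraction coordinate).
#' @return Numeric 2-vector `n_c`.
#' @export
estimate_cocontraction <- function(repetitions, N_scaled, n0, tol = 1e-8) {
  if (length(repetitions) != 6L)
    stop("expected exactly 6 co-contraction repetitions", call. = FALSE)
  proj <- vapply(repetitions, function(rec) {
    stopifnot(inherits(rec, "envelope_recording"))
    as.numeric(N_scaled %*% mean_envelope_hold(rec, window = 2))
  }, numeric(2))
  n_c <- rowMeans(proj) - n0
  if (vnorm(n_c) < tol)
    stop("co-contraction coordinate has vanishing magnitude: rotation undefined",
         call. = FALSE)
  n_c
}

#' Rotation aligning the co-contraction direction with +X
#'
#' Builds the proper rotation `R_c` with `R_c %*% n_c = c(||n_c||, 0)`.
#'
#' @param n_c non-zero 2-vector.
#' @return 2x2 rotation matrix with determinant 1.
#' @export
make_rotation <- function(n_c) {
  if (vnorm(n_c) <= 0 || !all(is.finite(n_c)))
    stop("n_c must be a non-zero finite 2-vector", call. = FALSE)
  rot2(-rad2deg(atan2(n_c[2], n_c[1])))
}

#' Assemble a null-space model
#'
#' Runs the full null-space calibration: basis, scaling, rest offset,
#' co-contraction coordinate and aligning rotation. The basis orientation is
#' fixed so that the pre-rotation co-contraction coordinate has a non-negative
#' first component (the SVD rows are sign-ambiguous; this convention makes
#' models reproducible across runs), with `R_c` absorbing the remaining
#' alignment.
#'
#' @param H 2x4 pulling matrix (or `pulling_matrix`).
#' @param rest_recording rest-trial [envelope_recording()].
#' @param cocontraction_reps list of 6 co-contraction [envelope_recording()]s.
#' @return Object of class `nullspace_model` with fields `H`, `N`, `kappa`,
#'   `N_scaled`, `n0`, `n_c`, `R_c` and `channels`.
#' @export
nullspace_model <- function(H, rest_recording, cocontraction_reps) {
  H <- as_H(H)
  N <- nullspace_basis(H)
  sc <- scale_basis(N, H)
  n0 <- estimate_offset(rest_recording, sc$N_scaled)
  n_c <- estimate_cocontraction(cocontraction_reps, sc$N_scaled, n0)
  if (n_c[1] < 0) {           # orientation convention (see description)
    N[1, ] <- -N[1, ]
    sc$N_scaled[1, ] <- -sc$N_scaled[1, ]
    n0[1] <- -n0[1]
    n_c[1] <- -n_c[1]
  }
  new_nullspace_model(H, N, sc$kappa, sc$N_scaled, n0, n_c)
}

## low-level constructor + validity
new_nullspace_model <- function(H, N, kappa, N_scaled, n0, n_c) {
  R_c <- make_rotation(n_c)
  m <- structure(list(H = H, N = N, kappa = kappa, N_scaled = N_scaled,
                      n0 = as.numeric(n0), n_c = as.numeric(n_c), R_c = R_c,
                      channels = emg_channels()),
                 class = "nullspace_model")
  validate_nullspace_model(m)
  m
}

validate_nullspace_model <- function(m, tol = 1e-8) {
  stopifnot(all(dim(m$N) == c(2, 4)), all(dim(m$H) == c(2, 4)))
  if (max(abs(m$N %*% t(m$N) - diag(2))) > tol)
    stop("null-space basis rows are not orthonormal", call. = FALSE)
  if (max(abs(m$N %*% t(m$H))) > tol * max(1, max(abs(m$H))))
    stop("null-space basis is not orthogonal to the pulling matrix", call. = FALSE)
  if (abs(det(m$R_c) - 1) > tol || max(abs(t(m$R_c) %*% m$R_c - diag(2))) > tol)
    stop("R_c is not a proper rotation", call. = FALSE)
  aligned <- as.numeric(m$R_c %*% m$n_c)
  if (aligned[1] <= 0 || abs(aligned[2]) > tol * max(1, vnorm(m$n_c)))
    stop("R_c does not align n_c with +X", call. = FALSE)
  invisible(m)
}

#' @export
print.nullspace_model <- function(x, ...) {
  cat(sprintf(paste0("<nullspace_model> kappa = %.4f, ||n_c|| = %.4f, ",
                     "n0 = [%.4f, %.4f]\n"),
              x$kappa, vnorm(x$n_c), x$n0[1], x$n0[2]))
  invisible(x)
}

#' Project an activation into force and null-space coordinates
#'
#' `force = H alpha`; `null = R_c (N_scaled alpha - n0)` (the rotated,
#' offset-corrected null coordinate). The on-screen NSTR cursor is the
#' negative of the null coordinate; evaluation is always in n-space.
#'
#' @param alpha non-negative 4-vector (or an n x 4 matrix of activations).
#' @param model a [nullspace_model()].
#' @return For a vector input, list with `force` (2-vector), `null`
#'   (2-vector) and `null_tilde` (unrotated `N_scaled alpha`, driving the CTR
#'   cursor radius). For a matrix input, the fields are n x 2 matrices.
#' @export
project <- function(alpha, model) {
  stopifnot(inherits(model, "nullspace_model"))
  vec <- is.null(dim(alpha))
  A <- if (vec) matrix(alpha, 1) else as.matrix(alpha)
  if (ncol(A) != 4L) stop("alpha must have 4 channels", call. = FALSE)
  stop_if_not_finite(A, "alpha")
  if (any(A < 0)) stop("alpha entries must be non-negative", call. = FALSE)
  f <- A %*% t(model$H)
  nt <- A %*% t(model$N_scaled)
  nn <- sweep(nt, 2, model$n0) %*% t(model$R_c)
  if (vec) list(force = as.numeric(f[1, ]), null = as.numeric(nn[1, ]),
                null_tilde = as.numeric(nt[1, ]))
  else list(force = f, null = nn, null_tilde = nt)
}

#' Reachable-cone membership of a null-space target
#'
#' Decides whether a target in rotated null coordinates is reachable by a
#' non-negative activation that simultaneously produces the required force:
#' is there `alpha >= 0` with `R_c (N_scaled alpha - n0) = target` and
#' `H alpha = required_force`?  With the default fixed force the stacked
#' equality system has four independent rows for four unknowns, so
#' feasibility reduces to a unique linear solve plus the non-negativity
#' check; with `required_force = NULL` (force unconstrained) feasibility is
#' decided by non-negative least squares on the null-coordinate equations.
#'
#' @param target 2-vector in rotated null units.
#' @param model a [nullspace_model()].
#' @param required_force 2-vector of force (N) that must be produced
#'   simultaneously (default `c(0, 0)`, the NSTR feasibility case), or
#'   `NULL` to leave force unconstrained.
#' @param tol equality-constraint tolerance in scaled units (default 1e-7);
#'   non-negativity is checked to the same tolerance.
#' @return Logical; attribute `"alpha"` carries the feasibility witness when
#'   membership holds.
#' @export
cone_membership <- function(target, model, required_force = c(0, 0),
                            tol = 1e-7) {
  stopifnot(inherits(model, "nullspace_model"), length(target) == 2L)
  b_null <- as.numeric(t(model$R_c) %*% target + model$n0)   # N_scaled alpha
  scale <- max(1, vnorm(b_null), abs(model$kappa))
  if (!is.null(required_force)) {
    M <- rbind(model$H, model$N_scaled)
    b <- c(required_force, b_null)
    alpha <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(alpha)) return(FALSE)
    ok <- all(alpha >= -tol * scale) &&
      vnorm(M %*% pmax(alpha, 0) - b) <= tol * scale * 10
    res <- ok
    if (ok) attr(res, "alpha") <- pmax(alpha, 0)
    return(res)
  }
  fit <- pracma::lsqnonneg(model$N_scaled, b_null)
  alpha <- fit$x
  ok <- vnorm(model$N_scaled %*% alpha - b_null) <= tol * scale * 10
  res <- ok
  if (ok) attr(res, "alpha") <- alpha
  res
}

#' Extreme rays of the reachable cone
#'
#' The set of null coordinates reachable by non-negative activation is an
#' affine cone with apex `-R_c n0` (the image of `alpha = 0`): its directions
#' are the conical hull of the four column images `R_c N_scaled e_j`. Returns
#' the two boundary rays (unit vectors, rotated null coordinates) or flags
#' that the columns positively span the whole plane.
#'
#' @param model a [nullspace_model()].
#' @return Object of class `reachable_cone`: list with `rays` (2x2 matrix,
#'   one unit ray per row, or `NULL` when the plane is covered), `apex`,
#'   `contains_full_plane`, `degenerate` (all columns collinear) and
#'   `angles_deg` of the column images.
#' @export
cone_extreme_rays <- function(model) {
  stopifnot(inherits(model, "nullspace_model"))
  C <- model$R_c %*% model$N_scaled         # 2 x 4 column images
  len <- sqrt(colSums(C^2))
  keep <- len > 1e-12 * max(len, 1)
  ang <- sort(wrap360(rad2deg(atan2(C[2, keep], C[1, keep]))))
  apex <- as.numeric(-model$R_c %*% model$n0)
  if (length(unique(round(wrap360(ang * 2), 6))) == 1L && length(ang) > 0) {
    ## all collinear (possibly opposite): single-ray / line, degenerate
    a <- ang[1]
    return(structure(list(rays = rbind(c(cos(deg2rad(a)), sin(deg2rad(a)))),
                          apex = apex, contains_full_plane = FALSE,
                          degenerate = TRUE, angles_deg = ang),
                     class = "reachable_cone"))
  }
  gaps <- diff(c(ang, ang[1] + 360))
  if (max(gaps) < 180) {
    return(structure(list(rays = NULL, apex = apex,
                          contains_full_plane = TRUE, degenerate = FALSE,
                          angles_deg = ang),
                     class = "reachable_cone"))
  }
  ## the cone is the sector complementary to the largest angular gap
  k <- which.max(gaps)
  lo <- ang[(k %% length(ang)) + 1L]        # ray after the gap
  hi <- ang[k]                              # ray before the gap
  rays <- rbind(c(cos(deg2rad(lo)), sin(deg2rad(lo))),
                c(cos(deg2rad(hi)), sin(deg2rad(hi))))
  structure(list(rays = rays, apex = apex, contains_full_plane = FALSE,
                 degenerate = FALSE, angles_deg = ang,
                 sector_deg = c(lo, if (hi < lo) hi + 360 else hi)),
            class = "reachable_cone")
}

#' @export
print.reachable_cone <- function(x, ...) {
  if (x$contains_full_plane) cat("<reachable_cone> full plane\n")
  else if (x$degenerate) cat("<reachable_cone> degenerate (single ray)\n")
  else cat(sprintf("<reachable_cone> sector [%.2f, %.2f] deg, apex [%.3f, %.3f]\n",
                   x$sector_deg[1], x$sector_deg[2], x$apex[1], x$apex[2]))
  invisible(x)
}

as_H <- function(H) {
  if (inherits(H, "pulling_matrix")) H <- H$H
  H <- as.matrix(H)
  if (!all(dim(H) == c(2, 4))) stop("H must be 2x4", call. = FALSE)
  stop_if_not_finite(H, "H")
  H
}
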