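# Small internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Euclidean norm of a vector
vnorm <- function(x) sqrt(sum(x^2))

## Row-wise Euclidean norms of an n x 2 (or n x k) matrix
row_norms <- function(m) sqrt(rowSums(m^2))

## 2x2 anticlockwise rotation by `deg` degrees
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## Wrap angles (degrees) into [0, 360)
wrap360 <- function(a) ((a %% 360) + 360) %% 360

## First run of at least `len` consecutive TRUEs; returns c(start, end) indices
## (1-based, inclusive) of the first window of exactly `len` samples inside that
## run, or NULL if none exists.
first_true_window <- function(ok, len) {
  stopifnot(len >= 1L)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NULL)
  s <- starts[hit[1L]]
  c(s, s + len - 1L)
}

## Minimum-jerk position profile s(tau) for tau in [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    if (is.matrix(x)) {
      bad <- which(!apply(is.finite(x), 2, all))
      stop(sprintf("non-finite samples in %s (channel %s)", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

## Derive a 32-bit sub-seed from a base seed and a stream label
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 31L) %% 2147483562L
}
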