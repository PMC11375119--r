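# Shared fixtures, built in code. The noiseless model fixture is memoised per
# test file to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

## ground-truth geometry + noiseless calibration + fitted model
noiseless_fixture <- function(seed = 1L) {
  key <- paste0("fix", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  geom <- make_wrist_geometry(seed)
  cal <- simulate_calibration_session(geom, rounds = 6L, noise = 0, seed = seed)
  pm <- fit_pulling_matrix(calibration_points_from_session(cal))
  model <- nullspace_model(pm, cal$rest, cal$cocontraction)
  fix <- list(geometry = geom, calibration = cal, pm = pm, model = model,
              smvf = cal$smvf)
  .fixture_cache[[key]] <- fix
  fix
}

## constant-envelope recording helper
const_envelope_rec <- function(alpha, duration = 3, fs = 1000,
                               force = c(0, 0)) {
  n <- as.integer(duration * fs)
  envelope_recording(seq_len(n) / fs,
                     matrix(alpha, n, 4, byrow = TRUE),
                     matrix(force, n, 2, byrow = TRUE), fs = fs)
}

## random full-row-rank pulling matrix
random_H <- function() {
  repeat {
    H <- matrix(stats::rnorm(8, sd = 5), 2, 4)
    if (svd(H)$d[2] > 0.5) return(H)
  }
}

## bare nullspace_model carcass for geometry-only cone tests (columns of
## N_scaled placed at prescribed angles; bypasses calibration)
cone_stub <- function(angles_deg, lengths = rep(1, length(angles_deg)),
                      n0 = c(0, 0)) {
  C <- rbind(cos(angles_deg * pi / 180), sin(angles_deg * pi / 180))
  C <- sweep(C, 2, lengths, `*`)
  m <- list(H = matrix(0, 2, 4), N = C, kappa = 1, N_scaled = C,
            n0 = n0, n_c = c(1, 0), R_c = diag(2),
            channels = emg_channels())
  class(m) <- "nullspace_model"
  m
}

## analytic magnitude response of an order-n Butterworth filter
butter_gain <- function(f, fc, n = 2, type = c("low", "high")) {
  type <- match.arg(type)
  r <- (f / fc)^n
  if (type == "low") 1 / sqrt(1 + r^2) else r / sqrt(1 + r^2)
}
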