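# Behavioural metrics: efficiency, corrections, force RMS, reaching range,
# concurrency phases and summaries.

test_that("motion efficiency is path-length-normalised and capped at one", {
  fs <- 100
  t <- seq(0, 1, by = 1 / fs)
  ## straight line start -> target
  straight <- cbind(2 * t, 0 * t)
  expect_equal(motion_efficiency(straight, target = c(2, 0), fs = fs), 1)
  ## out-and-back detour travelling twice the direct distance
  half <- cbind(seq(0, 2, length.out = 51), 0)
  detour <- rbind(cbind(seq(0, 1, length.out = 26), 0),
                  cbind(seq(1, 0, length.out = 26), 0)[-1, ],
                  half)
  expect_equal(motion_efficiency(detour, target = c(2, 0), fs = fs), 0.5,
               tolerance = 1e-10)
  ## random walks: segment-sum oracle, always <= 1 toward the realised endpoint
  set.seed(51)
  for (i in 1:25) {
    w <- cbind(cumsum(rnorm(200, sd = 0.1)), cumsum(rnorm(200, sd = 0.1)))
    tgt <- w[nrow(w), ]
    oracle <- sqrt(sum((tgt - w[1, ])^2)) /
      sum(sqrt(rowSums(diff(w)^2)))
    eff <- motion_efficiency(w, target = tgt, fs = fs)
    expect_equal(eff, oracle, tolerance = 1e-12)
    expect_lte(eff, 1 + 1e-12)
  }
  ## truncation at the success time discards the post-success tail
  tail_junk <- rbind(straight, matrix(rnorm(400), ncol = 2))
  expect_equal(motion_efficiency(tail_junk, target = c(2, 0),
                                 success_time = length(t) / fs, fs = fs),
               1, tolerance = 1e-6)
  expect_warning(motion_efficiency(matrix(1, 10, 2), target = c(1, 1), fs = fs),
                 "zero path")
})

test_that("correction counting finds speed-profile peaks after 3 Hz smoothing", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  mj <- function(tt) ifelse(tt < 0 | tt > 1, as.numeric(tt > 1),
                            10 * tt^3 - 15 * tt^4 + 6 * tt^5)
  ## one smooth bell-shaped reach
  one <- cbind(2 * mj(t / 1.5), 0)
  expect_equal(count_corrections(one, fs), 1L)
  ## three separated bells
  three <- cbind(mj(t / 0.6) + mj((t - 1.1) / 0.6) + mj((t - 2.2) / 0.6), 0)
  expect_equal(count_corrections(three, fs), 3L)
  ## constant position: no peaks
  expect_equal(count_corrections(matrix(5, 2 * fs, 2), fs), 0L)
  ## oracle: sign changes of the filtered speed derivative (above threshold)
  sm <- smooth_trajectory(three, fs, 3)
  speed <- sqrt(rowSums(diff(sm)^2)) * fs
  dsp <- diff(speed)
  cand <- which(dsp[-length(dsp)] > 0 & dsp[-1] <= 0) + 1
  cand <- cand[speed[cand] > 0.05 * max(speed)]
  ## collapse candidates closer than 100 ms
  n_oracle <- sum(diff(c(-Inf, cand)) > 0.1 * fs)
  expect_equal(count_corrections(three, fs), n_oracle)
  ## invariance to rigid motions
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(three %*% t(R), 2, c(5, -3), `+`)
  expect_equal(count_corrections(moved, fs), count_corrections(three, fs))
  expect_error(count_corrections(one[1:100, ], fs), "0.5 s")
})

test_that("force RMS is the quadratic mean of the force magnitude", {
  n <- 500
  expect_equal(force_rms(matrix(c(2, 0), n, 2, byrow = TRUE)), 2)
  alt <- matrix(c(3, 0), n, 2, byrow = TRUE) * rep(c(1, -1), length.out = n)
  expect_equal(force_rms(alt), 3)
  set.seed(52)
  f <- matrix(rnorm(2 * n), n, 2)
  expect_equal(force_rms(f), sqrt(sum(f^2) / n), tolerance = 1e-12)
})

test_that("reaching range spans the angle set within the magnitude band", {
  fs <- 100
  ang <- seq(0, 90, length.out = 500)
  sweep_traj <- 2 * cbind(cos(ang * pi / 180), sin(ang * pi / 180))
  zero_f <- matrix(0, nrow(sweep_traj), 2)
  rr <- reaching_range(sweep_traj, zero_f, smvf = 10)
  expect_equal(rr$range, 90, tolerance = 1.5)
  ## force violation on the 45-90 arc shrinks the constrained range to 45
  f_viol <- zero_f
  f_viol[ang > 45, 1] <- 0.05 * 10
  rr_with <- reaching_range(sweep_traj, f_viol, smvf = 10)
  expect_equal(rr_with$range, 45, tolerance = 1.5)
  rr_without <- reaching_range(sweep_traj, f_viol, smvf = 10,
                               constraint = "without")
  expect_equal(rr_without$range, 90, tolerance = 1.5)
  ## constrained angles are a subset of unconstrained ones
  expect_true(all(rr_with$angles %in% rr_without$angles))
  ## wrap-around sets are handled circularly
  wrap_ang <- c(seq(350, 360, length.out = 100), seq(0, 10, length.out = 100))
  wrap_traj <- 2 * cbind(cos(wrap_ang * pi / 180), sin(wrap_ang * pi / 180))
  rr_wrap <- reaching_range(wrap_traj, matrix(0, 200, 2), smvf = 10)
  expect_equal(rr_wrap$range, 20, tolerance = 1.5)
  ## samples off the magnitude band are ignored; empty set flagged
  off_band <- 5 * cbind(cos(ang * pi / 180), sin(ang * pi / 180))
  rr_off <- reaching_range(off_band, matrix(0, 500, 2), smvf = 10)
  expect_true(rr_off$empty)
  expect_equal(rr_off$range, 0)
  ## random sessions: per-sample filter oracle for the collected set
  set.seed(53)
  for (i in 1:10) {
    traj <- matrix(rnorm(400, sd = 2), 200, 2)
    frc <- matrix(rnorm(400, sd = 0.3), 200, 2)
    rr_r <- reaching_range(traj, frc, smvf = 10, bin_deg = 1)
    keep <- abs(sqrt(rowSums(traj^2)) - 2) <= 0.4 &
      sqrt(rowSums(frc^2)) < 0.4
    a_or <- sort(unique(round(((atan2(traj[keep, 2], traj[keep, 1]) *
                                  180 / pi) %% 360))))
    expect_equal(rr_r$angles, a_or)
  }
})

test_that("concurrency phases split the required null movement and sum to one", {
  ## linear rise reaching the size exactly at task reach
  ph <- concurrency_phases(3, baseline = 1, target_size = 3)
  expect_equal(ph$phase1, 1)
  expect_equal(ph$phase2, 0)
  expect_false(ph$excluded)
  ## no null movement before task reach
  ph2 <- concurrency_phases(1, baseline = 1, target_size = 3)
  expect_equal(ph2$phase1, 0)
  expect_equal(ph2$phase2, 1)
  ## overshoot in phase 1 makes phase 2 negative
  ph3 <- concurrency_phases(3.6, baseline = 1, target_size = 3)
  expect_gt(ph3$phase1, 1)
  expect_lt(ph3$phase2, 0)
  expect_equal(ph3$phase1 + ph3$phase2, 1)
  ## below 15% of target size: excluded
  ph4 <- concurrency_phases(2.9, baseline = 2.8, target_size = 3)
  expect_true(ph4$excluded)
  expect_match(ph4$reason, "15")
  ## boundary: D exactly at the threshold is kept
  ph5 <- concurrency_phases(3, baseline = 3 - 0.15 * 3, target_size = 3)
  expect_false(ph5$excluded)
  ## property: shares always sum to one when not excluded
  set.seed(54)
  for (i in 1:50) {
    size <- sample(c(3, 6), 1)
    base <- runif(1, 0, size * 0.8)
    ntr <- runif(1, base, size * 1.3)
    ph_i <- concurrency_phases(ntr, base, size)
    if (!ph_i$excluded) expect_equal(ph_i$phase1 + ph_i$phase2, 1)
  }
  expect_error(concurrency_phases(3, NULL, 3), "baseline")
})

test_that("CTR baselines come from matching calibration holds, with near-zero rest baseline", {
  fix <- noiseless_fixture(1)
  cfg <- ctr_config()
  b <- ctr_baselines(fix$calibration, fix$model, cfg, fix$smvf)
  expect_length(b, 9)
  expect_lt(b[9], 0.05)
  ## direct recomputation for position T1
  want <- cfg$positions[1, ] * fix$smvf
  hits <- Filter(function(r)
    sqrt(sum((r$target_force - want)^2)) < 1e-6, fix$calibration$targets)
  oracle <- mean(sapply(hits, function(r) {
    idx <- which(r$time >= max(r$time) - 2)
    mean(sqrt(rowSums((r$envelope[idx, ] %*% t(fix$model$N_scaled))^2)))
  }))
  expect_equal(unname(b[1]), oracle, tolerance = 1e-10)
  expect_true(all(b[1:8] > 0))
})

test_that("success rates and latency summaries match counting and quantile oracles", {
  fix <- noiseless_fixture(1)
  cfg <- ctr_config(fs = 100, n_trials = 40, trial_duration = 3)
  sched <- generate_ctr_schedule(cfg, seed = 5)
  n <- cfg$trial_duration * cfg$fs
  set.seed(55)
  trials <- lapply(seq_len(cfg$n_trials), function(k) {
    succ <- runif(1) < 0.6
    structure(list(paradigm = "ctr", trial = k,
                   position_id = sched$position_id[k],
                   size_id = sched$size_id[k], size = sched$size[k],
                   success = succ,
                   time_to_success = if (succ) runif(1, 1, 3) else NA_real_,
                   task_latency = if (succ) runif(1, 0.5, 2) else NA_real_,
                   null_latency = if (succ) runif(1, 0.5, 3) else NA_real_),
              class = "trial_result")
  })
  log <- structure(list(paradigm = "ctr", config = cfg, smvf = fix$smvf,
                        trials = trials, history = sched),
                   class = "session_log")
  sr <- success_rate(log, group_by = "size")
  succ <- sapply(trials, `[[`, "success")
  sid <- sapply(trials, `[[`, "size_id")
  for (s in unique(sid))
    expect_equal(sr$rate[sr$size_id == s], mean(succ[sid == s]))
  expect_true(all(sr$rate >= 0 & sr$rate <= 1))
  ## per-(position, size) rates match table-based counting
  sr2 <- success_rate(log)
  pid <- sapply(trials, `[[`, "position_id")
  for (r in seq_len(nrow(sr2))) {
    sel <- pid == sr2$position_id[r] & sid == sr2$size_id[r]
    expect_equal(sr2$n[r], sum(sel))
    expect_equal(sr2$successes[r], sum(succ[sel]))
  }
  tls <- time_to_success_summary(log)
  tts <- sapply(trials, `[[`, "time_to_success")
  for (r in seq_len(nrow(tls))) {
    sel <- succ & pid == tls$position_id[r] & sid == tls$size_id[r]
    expect_equal(tls$tts_median[r], median(tts[sel]))
    expect_equal(tls$tts_iqr[r], IQR(tts[sel]))
  }
})

test_that("latency medians follow the sort-based quantile oracle", {
  mk_trial <- function(k, tts) structure(
    list(paradigm = "nstr", trial = k, target_id = 1L, success = !is.na(tts),
         time_to_success = tts), class = "trial_result")
  log <- structure(list(paradigm = "nstr", config = nstr_config(),
                        smvf = 10, trials = lapply(seq_along(c(2, 3, 4)),
                                                   function(i) mk_trial(i, c(2, 3, 4)[i]))),
                   class = "session_log")
  s <- time_to_success_summary(log)
  expect_equal(s$median, 3)
  log1 <- structure(list(paradigm = "nstr", config = nstr_config(), smvf = 10,
                         trials = list(mk_trial(1, 2.5))), class = "session_log")
  s1 <- time_to_success_summary(log1)
  expect_equal(s1$iqr, 0)
})
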