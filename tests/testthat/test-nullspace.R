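# Null-space basis, scaling, offsets, rotation, projection and the
# non-negative reachable cone.

test_that("null-space basis is orthonormal, annihilates H, and matches an independent kernel", {
  ## coordinate subspace: kernel of [e1; e2] is span{e3, e4}
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  N <- nullspace_basis(H)
  expect_equal(abs(N[, 3:4]) %*% c(1, 1), cbind(c(1, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(N[, 1:2], matrix(0, 2, 2), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    H <- random_H()
    N <- nullspace_basis(H)
    expect_lt(max(abs(N %*% t(H))), 1e-10)
    expect_lt(max(abs(N %*% t(N) - diag(2))), 1e-10)
    ## independent kernel via MASS::Null; compare projectors
    K <- MASS::Null(t(H))
    P_or <- K %*% solve(t(K) %*% K, t(K))
    expect_equal(t(N) %*% N, P_or, tolerance = 1e-9)
  }
  expect_error(nullspace_basis(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))), "rank")
})

test_that("basis signs are deterministic across repeated computation", {
  set.seed(32)
  H <- random_H()
  expect_identical(nullspace_basis(H), nullspace_basis(H))
})

test_that("kappa is the larger pulling-row norm and scales the basis", {
  H <- rbind(c(3, 0, 0, 0), c(0, 4, 0, 0))
  N <- nullspace_basis(H)
  sc <- scale_basis(N, H)
  expect_equal(sc$kappa, 4)
  expect_equal(sc$N_scaled, 4 * N)
  ## equal row norms
  He <- rbind(c(2, 1, 0, 0), c(0, 0, 2, 1))
  expect_equal(scale_basis(nullspace_basis(He), He)$kappa, sqrt(5))
  set.seed(33)
  for (i in 1:10) {
    H <- random_H()
    expect_equal(scale_basis(nullspace_basis(H), H)$kappa,
                 max(sqrt(sum(H[1, ]^2)), sqrt(sum(H[2, ]^2))))
  }
})

test_that("rest offset is the projected mean envelope over the rest window", {
  set.seed(34)
  H <- random_H()
  Ns <- scale_basis(nullspace_basis(H), H)$N_scaled
  expect_equal(estimate_offset(const_envelope_rec(c(0, 0, 0, 0)), Ns), c(0, 0))
  a <- c(0.2, 0.1, 0.3, 0.05)
  expect_equal(estimate_offset(const_envelope_rec(a), Ns),
               as.numeric(Ns %*% a), tolerance = 1e-12)
  ## noisy rest: matches a two-pass mean oracle
  n <- 3000
  E <- pmax(matrix(rep(a, each = n), n) + matrix(rnorm(4 * n, sd = 0.03), n), 0)
  rec <- envelope_recording(seq_len(n) / 1000, E, matrix(0, n, 2))
  expect_equal(estimate_offset(rec, Ns), as.numeric(Ns %*% colMeans(E)),
               tolerance = 1e-12)
  short <- const_envelope_rec(a, duration = 1)
  expect_error(estimate_offset(short, Ns), "2 s")
})

test_that("co-contraction coordinate averages six repetitions after offset removal", {
  set.seed(35)
  H <- random_H()
  Ns <- scale_basis(nullspace_basis(H), H)$N_scaled
  a <- c(0.3, 0.25, 0.2, 0.35)
  reps <- replicate(6, const_envelope_rec(a), simplify = FALSE)
  n0 <- c(0.05, -0.02)
  expect_equal(estimate_cocontraction(reps, Ns, n0),
               as.numeric(Ns %*% a) - n0, tolerance = 1e-12)
  ## repetitions symmetric about a mean give the mean
  d <- runif(4, 0, 0.05)
  reps_sym <- c(replicate(3, const_envelope_rec(a + d), simplify = FALSE),
                replicate(3, const_envelope_rec(a - d), simplify = FALSE))
  expect_equal(estimate_cocontraction(reps_sym, Ns, c(0, 0)),
               as.numeric(Ns %*% a), tolerance = 1e-12)
  ## random repetitions: arithmetic-mean oracle
  reps_r <- replicate(6, const_envelope_rec(runif(4, 0.1, 0.5)), simplify = FALSE)
  oracle <- rowMeans(vapply(reps_r, function(r)
    as.numeric(Ns %*% r$envelope[1, ]), numeric(2)))
  expect_equal(estimate_cocontraction(reps_r, Ns, c(0, 0)), oracle,
               tolerance = 1e-12)
  expect_error(estimate_cocontraction(reps[1:5], Ns, c(0, 0)), "6")
  zero_reps <- replicate(6, const_envelope_rec(c(0, 0, 0, 0)), simplify = FALSE)
  expect_error(estimate_cocontraction(zero_reps, Ns, c(0, 0)), "vanishing")
})

test_that("the aligning rotation is proper and sends n_c to [||n_c||, 0]", {
  expect_equal(make_rotation(c(5, 0)), diag(2), tolerance = 1e-14)
  R <- make_rotation(c(0, 2))
  expect_equal(as.numeric(R %*% c(0, 2)), c(2, 0), tolerance = 1e-12)
  set.seed(36)
  for (i in 1:25) {
    v <- rnorm(2)
    R <- make_rotation(v)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_lt(max(abs(as.numeric(R %*% v) - c(sqrt(sum(v^2)), 0))), 1e-12)
  }
  expect_error(make_rotation(c(0, 0)), "non-zero")
})

test_that("projection splits activation into force and offset-corrected null coordinates", {
  fix <- noiseless_fixture(1)
  m <- fix$model
  g <- fix$geometry
  ## rest maps to the null origin
  rest_mean <- colMeans(fix$calibration$rest$envelope)
  pr <- project(rest_mean, m)
  expect_equal(pr$null, c(0, 0), tolerance = 1e-8)
  ## rest + co-contraction lands on the +X half-axis
  pr2 <- project(rest_mean + 0.4 * g$cocontraction_pattern, m)
  expect_gt(pr2$null[1], 0)
  expect_equal(pr2$null[2], 0, tolerance = 1e-8)
  expect_equal(pr2$force, pr$force, tolerance = 1e-8)
  ## random activations: elementwise matrix-product oracle
  set.seed(37)
  for (i in 1:20) {
    a <- runif(4)
    pr3 <- project(a, m)
    expect_equal(pr3$force, as.numeric(m$H %*% a), tolerance = 1e-12)
    expect_equal(pr3$null,
                 as.numeric(m$R_c %*% (m$N_scaled %*% a - m$n0)),
                 tolerance = 1e-12)
    expect_equal(pr3$null_tilde, as.numeric(m$N_scaled %*% a), tolerance = 1e-12)
  }
  expect_error(project(c(-0.1, 0, 0, 0), m), "non-negative")
  ## joint linearity up to the fixed offset: n(a1+a2) = n(a1) + n(a2) + R_c n0
  a1 <- runif(4); a2 <- runif(4)
  p1 <- project(a1, m); p2 <- project(a2, m); ps <- project(a1 + a2, m)
  expect_equal(ps$force, p1$force + p2$force, tolerance = 1e-10)
  expect_equal(ps$null,
               p1$null + p2$null + as.numeric(m$R_c %*% m$n0),
               tolerance = 1e-10)
})

test_that("kappa scaling equates null magnitude with dominant-axis force capacity", {
  set.seed(38)
  for (i in 1:10) {
    H <- random_H()
    N <- nullspace_basis(H)
    sc <- scale_basis(N, H)
    dom <- which.max(c(sqrt(sum(H[1, ]^2)), sqrt(sum(H[2, ]^2))))
    beta <- runif(1, 0.5, 4)
    ## activation along the dominant row's normalized direction producing
    ## beta N along that axis
    a_f <- beta * H[dom, ] / sum(H[dom, ]^2)
    expect_equal(as.numeric(H %*% a_f)[dom], beta, tolerance = 1e-12)
    ## kernel activation of the same Euclidean norm has ||n~|| = beta exactly
    k_hat <- N[1, ]
    a_n <- sqrt(sum(a_f^2)) * k_hat
    expect_equal(sqrt(sum((sc$N_scaled %*% a_n)^2)), beta, tolerance = 1e-10)
  }
})

test_that("cone membership accepts constructive witnesses and honours the force constraint", {
  fix <- noiseless_fixture(1)
  m <- fix$model
  set.seed(39)
  ## constructive witnesses: alpha in the kernel, non-negative
  n_checked <- 0
  while (n_checked < 25) {
    cc <- rnorm(2)
    a <- as.numeric(t(m$N) %*% cc)
    if (any(a < 0)) next
    n_checked <- n_checked + 1
    target <- as.numeric(m$R_c %*% (m$N_scaled %*% a - m$n0))
    res <- cone_membership(target, m)
    expect_true(isTRUE(res))
    ## round trip: witness projects back onto the target
    w <- attr(res, "alpha")
    expect_equal(project(w, m)$null, target, tolerance = 1e-8)
    expect_lt(sqrt(sum((m$H %*% w)^2)), 1e-6)
  }
  ## the rotated co-contraction coordinate is reachable at zero force
  expect_true(isTRUE(cone_membership(c(sqrt(sum(m$n_c^2)), 0), m)))
  ## force-unconstrained membership is a superset of zero-force membership
  for (i in 1:20) {
    tgt <- rnorm(2, sd = 2)
    if (isTRUE(cone_membership(tgt, m)))
      expect_true(isTRUE(cone_membership(tgt, m, required_force = NULL)))
  }
})

test_that("cone membership agrees with a dense non-negative grid search", {
  fix <- noiseless_fixture(1)
  m <- fix$model
  ## decision rule under zero force: unique alpha = N' c / kappa must be >= 0.
  ## Oracle: dense grid over kernel coefficients, image set comparison.
  set.seed(310)
  cg <- as.matrix(expand.grid(seq(-8, 8, length.out = 161),
                              seq(-8, 8, length.out = 161)))
  keep <- cg %*% m$N >= 0                    # alpha = t(N) %*% c per row
  cg <- cg[rowSums(keep) == 4, , drop = FALSE]
  images <- sweep(cg, 2, m$n0) %*% t(m$R_c)  # R_c (kappa N alpha - n0), kappa N t(N) c = c
  n_cases <- 0
  mism <- 0
  while (n_cases < 2000) {
    cc <- runif(2, -7, 7)
    a <- as.numeric(t(m$N) %*% cc) / m$kappa
    margin <- min(a) * m$kappa
    if (abs(margin) < 0.2) next              # skip grid-resolution boundary band
    n_cases <- n_cases + 1
    target <- as.numeric(m$R_c %*% (cc - m$n0))
    mine <- isTRUE(cone_membership(target, m))
    d2 <- colSums((t(images) - target)^2)
    oracle <- min(d2) < 0.15^2
    if (mine != oracle) mism <- mism + 1
  }
  expect_equal(mism, 0)
})

test_that("extreme rays bound the reachable directions", {
  ## prescribed column angles within a half-plane
  stub <- cone_stub(c(10, 40, 80, 100))
  cone <- cone_extreme_rays(stub)
  expect_false(cone$contains_full_plane)
  expect_equal(sort(cone$sector_deg %% 360), c(10, 100))
  ## columns positively spanning the plane
  stub2 <- cone_stub(c(0, 90, 180, 270))
  expect_true(cone_extreme_rays(stub2)$contains_full_plane)
  ## collinear columns: degenerate single ray
  stub3 <- cone_stub(c(30, 30, 30, 210))
  expect_true(cone_extreme_rays(stub3)$degenerate)
  ## cross-check against relaxed membership on the fitted model
  fix <- noiseless_fixture(1)
  m <- fix$model
  cone_m <- cone_extreme_rays(m)
  set.seed(311)
  if (!cone_m$contains_full_plane) {
    lo <- cone_m$sector_deg[1]; hi <- cone_m$sector_deg[2]
    for (i in 1:200) {
      tgt <- rnorm(2, sd = 3)
      if (isTRUE(cone_membership(tgt, m, required_force = NULL))) {
        v <- tgt - cone_m$apex
        ang <- (atan2(v[2], v[1]) * 180 / pi) %% 360
        in_sector <- (ang >= lo - 1e-6 & ang <= hi + 1e-6) |
          (ang + 360 >= lo - 1e-6 & ang + 360 <= hi + 1e-6)
        expect_true(in_sector)
      }
    }
  }
})

test_that("nullspace model validity and serialization invariants hold for fitted models", {
  for (s in 1:3) {
    fix <- noiseless_fixture(s)
    m <- fix$model
    expect_lt(max(abs(m$N %*% t(m$N) - diag(2))), 1e-10)
    expect_lt(max(abs(m$N %*% t(m$H))), 1e-10)
    expect_equal(det(m$R_c), 1, tolerance = 1e-12)
    aligned <- as.numeric(m$R_c %*% m$n_c)
    expect_gt(aligned[1], 0)
    expect_equal(aligned[2], 0, tolerance = 1e-10)
    expect_equal(m$kappa, max(sqrt(rowSums(m$H^2))))
    expect_equal(m$N_scaled, m$kappa * m$N)
  }
})
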