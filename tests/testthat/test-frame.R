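test_that("sliding mean: constants, identity window, and a naive loop oracle", {
  x <- matrix(c(0, 9.81, 0), 100, 3, byrow = TRUE)
  expect_equal(sliding_mean(x, fs = 20, window_s = 5), x)

  set.seed(1)
  y <- matrix(rnorm(30), 10, 3)
  expect_equal(sliding_mean(y, fs = 10, window_s = 0.1), y)  # 1-sample window

  # naive per-sample loop oracle on random input
  z <- matrix(rnorm(120), 40, 3)
  L <- 7L; left <- 3L; right <- 3L
  oracle <- z * 0
  for (i in 1:40) {
    w <- max(1, i - left):min(40, i + right)
    oracle[i, ] <- colMeans(z[w, , drop = FALSE])
  }
  expect_equal(sliding_mean(z, fs = 1, window_s = 7), oracle, tolerance = 1e-12)

  # zero-mean sinusoid, window an integer number of periods: interior ~ 0
  fs <- 50; f0 <- 2; n <- 1000
  s <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  sm <- sliding_mean(cbind(s, s, s), fs, window_s = 1)  # 50 samples = 2 periods
  interior <- 26:(n - 26)
  expect_lt(max(abs(sm[interior, ])), 1e-9)

  expect_error(sliding_mean(z, fs = 1, window_s = 0), "positive")
  expect_error(sliding_mean(z, fs = 10, window_s = 0.01), "one sample")
})

test_that("gravity estimation recovers truth on static and gait signals", {
  rec <- static_recording(n = 300, fs = 50, g = c(1.2, 9.6, -0.8))
  expect_equal(estimate_gravity(rec), rec$samples, ignore_attr = TRUE)

  # synthetic walk: interior gravity direction within 2 degrees of truth
  cfg <- noise_free_config()
  fr <- generate_movement(cfg, "S01", "walk")
  g <- estimate_gravity(fr$x, cfg$fs)
  interior <- (5 * cfg$fs):(nrow(g) - 5 * cfg$fs)
  expect_lt(max(angle_to(g[interior, ], fr$truth$gravity)), 2)

  # filter length has little effect: 3 s vs 7 s within 5 degrees
  g3 <- estimate_gravity(fr$x, cfg$fs, window_s = 3)
  g7 <- estimate_gravity(fr$x, cfg$fs, window_s = 7)
  cosang <- rowSums(g3 * g7) / (sqrt(rowSums(g3^2)) * sqrt(rowSums(g7^2)))
  expect_lt(max(acos(pmin(1, cosang[interior])) * 180 / pi), 5)
})

test_that("horizontal component projects off gravity exactly", {
  g <- matrix(c(0, 9.81, 0), 50, 3, byrow = TRUE)

  a_par <- g * 0.7                       # parallel to gravity -> zero
  hc <- horizontal_component(a_par, g)
  expect_lt(max(abs(hc$h)), 1e-12)

  a_orth <- matrix(c(1.5, 0, -2), 50, 3, byrow = TRUE)  # orthogonal -> identity
  expect_equal(horizontal_component(a_orth, g)$h, a_orth, ignore_attr = TRUE)

  # reconstruction a = h + (a.g^)g^ on random vectors
  set.seed(2)
  a <- matrix(rnorm(150, sd = 4), 50, 3)
  gr <- matrix(rnorm(150), 50, 3) + matrix(c(0, 9.81, 0), 50, 3, byrow = TRUE)
  hc2 <- horizontal_component(a, gr)
  ghat <- gr / sqrt(rowSums(gr^2))
  recon <- hc2$h + rowSums(a * ghat) * ghat
  expect_lt(max(abs(recon - a)), 1e-12)
  expect_lt(max(abs(rowSums(hc2$h * ghat))), 1e-9)   # orthogonality

  # degenerate gravity flags samples invalid
  g0 <- gr; g0[7, ] <- 1e-9
  hc3 <- horizontal_component(a, g0)
  expect_false(hc3$valid[7])
  expect_true(all(is.na(hc3$h[7, ])))
})

test_that("forward estimation: constant mean, degenerate postures, axis recovery", {
  h <- matrix(c(0.5, 0, 0), 200, 3, byrow = TRUE)
  fw <- estimate_forward(h, fs = 20)
  expect_true(all(fw$valid))
  expect_equal(fw$f / sqrt(rowSums(fw$f^2)),
               matrix(c(1, 0, 0), 200, 3, byrow = TRUE), ignore_attr = TRUE)

  # zero horizontal signal (idealised posture): every sample invalid
  fw0 <- estimate_forward(matrix(0, 200, 3), fs = 20)
  expect_false(any(fw0$valid))

  # gait signal: the estimated forward AXIS aligns with truth where the
  # smoothed magnitude is meaningful (the sign alternates with pace)
  cfg <- noise_free_config()
  fr <- generate_movement(cfg, "S02", "walk")
  g <- estimate_gravity(fr$x, cfg$fs)
  hc <- horizontal_component(fr$x, g)
  fw2 <- estimate_forward(hc$h, cfg$fs, eps_f = 1e-6, valid = hc$valid)
  interior <- (5 * cfg$fs):(nrow(g) - 5 * cfg$fs)
  fn <- sqrt(rowSums(fw2$f^2))
  strong <- intersect(interior, which(fn > 0.5 * median(fn[interior])))
  expect_lt(median(axis_angle_to(fw2$f[strong, ], fr$truth$forward)), 5)
  expect_lt(max(axis_angle_to(fw2$f[strong, ], fr$truth$forward)), 10)
})

test_that("frame construction is orthonormal, right-handed and rotation-covariant", {
  # fixed example: normalisation plus cross product, right-handed order
  fr <- build_frame(matrix(c(0, -9.81, 0), 1, 3), matrix(c(2, 0, 0), 1, 3))
  expect_equal(fr$fwd[1, ], c(1, 0, 0))
  expect_equal(fr$grav[1, ], c(0, -1, 0))
  expect_equal(fr$cross[1, ], c(0, 0, -1))   # u_fwd x u_grav

  set.seed(3)
  g <- matrix(rnorm(300), 100, 3) * 2 + matrix(c(0, 9.81, 0), 100, 3,
                                               byrow = TRUE)
  f <- matrix(rnorm(300), 100, 3)
  fr2 <- build_frame(g, f)
  for (i in c(1, 50, 100)) {
    M <- rbind(fr2$fwd[i, ], fr2$grav[i, ], fr2$cross[i, ])
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)       # orthonormal triad
    expect_equal(det(M), 1, tolerance = 1e-9)              # right-handed
  }

  # covariance: rotating g and f jointly rotates the frame vectors
  for (rep in 1:5) {
    R <- random_rotation()
    fr3 <- build_frame(g %*% t(R), f %*% t(R))
    expect_equal(fr3$fwd, fr2$fwd %*% t(R), tolerance = 1e-9)
    expect_equal(fr3$grav, fr2$grav %*% t(R), tolerance = 1e-9)
    expect_equal(fr3$cross, fr2$cross %*% t(R), tolerance = 1e-9)
  }
})

test_that("frame transform is the identity on sensor axes, maps the basis, and inverts", {
  n <- 60
  id <- build_frame(matrix(c(0, 1, 0), n, 3, byrow = TRUE) * 9.81,
                    matrix(c(1, 0, 0), n, 3, byrow = TRUE))
  set.seed(4)
  a <- matrix(rnorm(3 * n, sd = 3), n, 3)
  # identity triad: fwd = x, grav = y, cross = x cross y = z
  tr <- transform_to_frame(a, id)
  expect_equal(tr$x, a, ignore_attr = TRUE, tolerance = 1e-12)

  g <- matrix(rnorm(3 * n), n, 3) + matrix(c(0, 9.81, 0), n, 3, byrow = TRUE)
  f <- matrix(rnorm(3 * n), n, 3)
  frm <- build_frame(g, f)
  # the gravity unit vector maps to (0, 1, 0)
  tg <- transform_to_frame(frm$grav, frm)
  expect_equal(tg$x, matrix(c(0, 1, 0), n, 3, byrow = TRUE),
               ignore_attr = TRUE, tolerance = 1e-9)
  # norm conservation and inversion by the transpose
  tr2 <- transform_to_frame(a, frm)
  expect_equal(sqrt(rowSums(tr2$x^2)), sqrt(rowSums(a^2)), tolerance = 1e-9)
  for (i in c(1, n %/% 2, n)) {
    M <- rbind(frm$fwd[i, ], frm$grav[i, ], frm$cross[i, ])
    expect_lt(max(abs(t(M) %*% tr2$x[i, ] - a[i, ])), 1e-12)
  }
})

test_that("gravity subtraction kills static signals and is rotation-invariant in norm", {
  rec <- static_recording(n = 400, fs = 50, g = c(3, 9, -1))
  g <- estimate_gravity(rec)
  out <- subtract_gravity(rec, g)
  expect_lt(max(abs(out$x)), 1e-9)

  set.seed(5)
  noisy <- static_recording(n = 400, fs = 50, noise_sd = 0.2)
  gn <- estimate_gravity(noisy)
  outn <- subtract_gravity(noisy, gn)
  expect_lt(sqrt(mean(outn$x^2)), 3 * 0.2)   # residual on the noise scale

  # rotated static recording: identical residual norms
  R <- rotation_matrix("z", 57)
  rotated <- noisy
  rotated$samples <- noisy$samples %*% t(R)
  outr <- subtract_gravity(rotated, estimate_gravity(rotated))
  expect_equal(sqrt(rowSums(outr$x^2)), sqrt(rowSums(outn$x^2)),
               tolerance = 1e-9)
})

test_that("per-stage estimates are exactly equivariant under rotation", {
  set.seed(6)
  cfg <- synth_config(seed = 8)
  fr <- generate_movement(cfg, "S03", "jog")
  R <- random_rotation()
  a <- fr$x; aR <- a %*% t(R)

  g <- estimate_gravity(a, cfg$fs)
  gR <- estimate_gravity(aR, cfg$fs)
  expect_equal(gR, g %*% t(R), tolerance = 1e-12)   # linearity

  h <- horizontal_component(a, g)$h
  hR <- horizontal_component(aR, gR)$h
  expect_equal(hR, h %*% t(R), tolerance = 1e-9)

  f <- estimate_forward(h, cfg$fs)$f
  fR <- estimate_forward(hR, cfg$fs)$f
  expect_equal(fR, f %*% t(R), tolerance = 1e-9)
})

test_that("segment preprocessing routes postures, movements and fallbacks", {
  cfg <- synth_config(seed = 12)
  post <- generate_posture(cfg, "S01", "sit")
  pp <- preprocess_segment(post$x, cfg$fs, "posture")
  expect_true(all(pp$provenance == "gravity_subtracted"))

  mov <- generate_movement(cfg, "S01", "walk")
  pm <- preprocess_segment(mov$x, cfg$fs, "movement")
  expect_gte(mean(pm$provenance == "frame"), 0.95)
  expect_true(all(is.finite(pm$x)))

  expect_error(preprocess_segment(mov$x[0, , drop = FALSE], cfg$fs,
                                  "movement"), "at least one sample|empty")
})

test_that("end-to-end preprocessing is invariant to a fixed sensor rotation", {
  cfg <- synth_config(seed = 21)
  for (act in c("walk", "stairs")) {
    fr <- generate_movement(cfg, "S04", act)
    p1 <- preprocess_segment(fr$x, cfg$fs, "movement")
    R <- random_rotation()
    p2 <- preprocess_segment(fr$x %*% t(R), cfg$fs, "movement")
    both <- p1$provenance == "frame" & p2$provenance == "frame"
    expect_gte(mean(both), 0.95)
    expect_lt(max(abs(p1$x[both, ] - p2$x[both, ])), 1e-6)
    # gravity-subtracted samples agree in norm
    gs <- p1$provenance == "gravity_subtracted" &
      p2$provenance == "gravity_subtracted"
    if (any(gs))
      expect_lt(max(abs(sqrt(rowSums(p1$x[gs, , drop = FALSE]^2)) -
                        sqrt(rowSums(p2$x[gs, , drop = FALSE]^2)))), 1e-6)
  }
})

test_that("recording-level preprocessing reproduces segment boundaries", {
  cfg <- synth_config(n_subjects = 1, duration_s = 20, seed = 30)
  ds <- generate_dataset(cfg)
  rec <- ds$recordings[[1]]
  segs <- preprocess_recording(rec, ds$type_map, mode = "per_type")
  expect_length(segs, 5L)
  expect_equal(sum(vapply(segs, function(s) nrow(s$x), 0L)),
               nrow(rec$samples))
  types <- vapply(segs, `[[`, "", "type")
  provs <- vapply(segs, function(s) as.character(s$provenance[1]), "")
  expect_true(all(provs[types == "posture"] == "gravity_subtracted"))
  # raw mode leaves the samples untouched
  raw <- preprocess_recording(rec, ds$type_map, mode = "raw")
  expect_equal(do.call(rbind, lapply(raw, `[[`, "x")), rec$samples,
               ignore_attr = TRUE)
})
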