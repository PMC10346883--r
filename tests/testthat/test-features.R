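test_that("window counts match floor((N - L) / S) + 1 by enumeration", {
  # 20 Hz, 10 s series, 5 s window, 1 s step: 6 windows starting every 20
  w <- window_signal(matrix(1, 200, 3), fs = 20)
  expect_length(w$windows, 6L)
  expect_equal(w$starts, seq(1L, 101L, by = 20L))

  # exactly one window when N = L
  w1 <- window_signal(matrix(1, 100, 3), fs = 20)
  expect_length(w1$windows, 1L)

  # exhaustive enumeration over N in [L, L + 200]
  L <- 100L; S <- 20L
  for (n in seq(L, L + 200L, by = 7L)) {
    got <- length(window_signal(matrix(0, n, 1), fs = 20)$windows)
    expect_identical(got, as.integer(floor((n - L) / S) + 1L))
  }

  expect_warning(w0 <- window_signal(matrix(1, 50, 3), fs = 20), "shorter")
  expect_length(w0$windows, 0L)
})

test_that("windows carry the Hanning taper", {
  w <- window_signal(matrix(2, 100, 1), fs = 20)$windows[[1]]
  expect_equal(as.numeric(w), 2 * signal::hanning(100))
  # rectangular option
  wr <- window_signal(matrix(2, 100, 1), fs = 20, taper = FALSE)$windows[[1]]
  expect_equal(as.numeric(wr), rep(2, 100))
})

test_that("spectra locate sinusoid peaks at the DFT-arithmetic bin", {
  fs <- 20; L <- 100
  t <- (0:(L - 1)) / fs
  w <- window_signal(cbind(sin(2 * pi * 2 * t)), fs)$windows[[1]]
  sp <- window_spectrum(w, fs, f_max = 10)
  expect_equal(nrow(sp), 51L)                       # M = floor(10*100/20) + 1
  expect_equal(which.max(sp[, 1]) - 1L, 10L)        # 2 Hz / 0.2 Hz spacing

  # zero signal gives all-zero bins; M formula at another rate
  expect_true(all(window_spectrum(matrix(0, 500, 3), 100, 20) == 0))
  expect_equal(nrow(window_spectrum(matrix(0, 500, 3), 100, 20)), 101L)

  expect_error(window_spectrum(matrix(0, 100, 3), 20, f_max = 11), "Nyquist")
})

test_that("full-band spectral energy matches the tapered window energy", {
  set.seed(1)
  fs <- 20; L <- 100
  x <- rnorm(L)
  w <- window_signal(cbind(x), fs)$windows[[1]]
  sp <- window_spectrum(w, fs, f_max = fs / 2)      # up to Nyquist: L/2 + 1 bins
  # Parseval: sum |X_k|^2 over all L bins equals L * sum x^2; fold the
  # one-sided spectrum (interior bins appear twice)
  e_spec <- sp[1, 1]^2 + sp[L / 2 + 1, 1]^2 + 2 * sum(sp[2:(L / 2), 1]^2)
  expect_equal(as.numeric(e_spec), as.numeric(L * sum(w^2)),
               tolerance = 1e-9)
})

test_that("feature assembly counts windows per segment and orders rows", {
  segs <- list(list(x = matrix(rnorm(600), 200, 3), subject = "a",
                    label = "walk", type = "movement"),
               list(x = matrix(rnorm(300), 100, 3), subject = "a",
                    label = "sit", type = "posture"))
  fsft <- build_features(segs, fs = 20)
  expect_s3_class(fsft, "feature_set")
  expect_equal(nrow(fsft$x), 7L)                    # 6 + 1 windows
  expect_equal(ncol(fsft$x), 3L * 51L)
  expect_true(all(fsft$x >= 0))

  # empty input gives an empty feature set
  empty <- build_features(list(), fs = 20)
  expect_equal(nrow(empty$x), 0L)

  # relabelled copy: identical matrix, different labels
  segs2 <- segs
  segs2[[1]]$label <- "jog"
  f2 <- build_features(segs2, fs = 20)
  expect_equal(f2$x, fsft$x)
  expect_equal(unique(f2$meta$label), c("jog", "sit"))

  # f_max auto rule: 10 Hz at 20 Hz sampling, else 20 Hz
  expect_equal(default_f_max(20), 10)
  expect_equal(default_f_max(50), 20)
  expect_equal(default_f_max(30), 15)               # capped at Nyquist
})

test_that("orientation invariance propagates into the feature matrix", {
  cfg <- synth_config(seed = 17)
  fr <- generate_movement(cfg, "S05", "walk")
  R <- random_rotation()
  p1 <- preprocess_segment(fr$x, cfg$fs, "movement")
  p2 <- preprocess_segment(fr$x %*% t(R), cfg$fs, "movement")
  mk <- function(p) build_features(list(list(x = p$x, subject = "s",
                                             label = "walk",
                                             type = "movement")), cfg$fs)
  f1 <- mk(p1); f2 <- mk(p2)
  # interior windows fully covered by frame-valid samples on both sides
  both <- p1$provenance == "frame" & p2$provenance == "frame"
  L <- 5 * cfg$fs
  covered <- vapply(f1$meta$start, function(s) all(both[s:(s + L - 1)]), TRUE)
  expect_gt(sum(covered), 0)
  expect_lt(max(abs(f1$x[covered, ] - f2$x[covered, ])), 1e-5)
})

test_that("feature sets round-trip through the CSV + sidecar serialisation", {
  segs <- list(list(x = matrix(rnorm(450), 150, 3), subject = "a",
                    label = "walk", type = "movement"))
  fsft <- build_features(segs, fs = 20)
  path <- tempfile(fileext = ".csv")
  write_features(fsft, path)
  back <- read_features(path)
  expect_equal(back$x, fsft$x, tolerance = 1e-12)
  expect_equal(back$meta$label, fsft$meta$label)
  expect_equal(back$M, fsft$M)
  expect_equal(back$f_max, fsft$f_max)
})
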