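# Linearly separable synthetic spectra: class k gets an energy bump in a
# class-specific bin range.
separable_spectra <- function(n, M = 40, classes = c("a", "b"), seed = 1) {
  set.seed(seed)
  y <- sample(classes, n, replace = TRUE)
  X <- matrix(abs(rnorm(n * 3 * M)), n)
  for (k in seq_along(classes)) {
    sel <- y == classes[k]
    X[sel, (k - 1) * 12 + (3:8)] <- X[sel, (k - 1) * 12 + (3:8)] + 6
  }
  list(X = X, y = y)
}

test_that("configuration validation catches impossible architectures", {
  expect_error(cnn_config(M = 6, C = 3), "too small")
  expect_error(cnn_config(M = 50, C = 1), "at least 2")
  expect_error(cnn_config(M = 50, C = 3, dropout = c(0.5, 0.5)), "dropout")
  cfg <- cnn_config(M = 50, C = 6)
  expect_s3_class(cfg, "cnn_config")
})

test_that("an untrained network outputs a valid C-way probability simplex", {
  cfg <- cnn_config(M = 30, C = 6, seed = 4)
  m <- build_cnn(cfg, classes = letters[1:6])
  p <- predict(m, matrix(0, 5, 90), type = "prob")
  expect_equal(dim(p), c(5L, 6L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  cls <- predict(m, matrix(rnorm(90 * 4), 4), type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), letters[1:6])
})

test_that("parameter count matches an independent layer-arithmetic oracle", {
  cfg <- cnn_config(M = 101, C = 5)
  # hand-computed: conv1 5*3*16+16, conv2 5*16*32+32, L1=97, L1p=48, L2=44,
  # L2p=22, flat=704, dense 704*128+128, out 128*5+5
  oracle <- (5 * 3 * 16 + 16) + (5 * 16 * 32 + 32) +
    (704 * 128 + 128) + (128 * 5 + 5)
  expect_equal(cnn_n_params(cfg), oracle)
  # and the initialised weights really hold that many numbers
  m <- build_cnn(cfg)
  expect_equal(sum(lengths(m$weights)), oracle)
})

test_that("analytic gradients match central finite differences", {
  cfg <- cnn_config(M = 14, C = 3, n_axes = 2, conv1_filters = 4,
                    conv1_kernel = 3, pool1 = 2, conv2_filters = 5,
                    conv2_kernel = 3, pool2 = 2, dense = 6, seed = 11)
  m <- build_cnn(cfg)
  set.seed(11)
  X <- matrix(rnorm(7 * 28), 7)
  y <- sample(0:2, 7, replace = TRUE)
  lg <- orientfree:::cnn_loss_grad_cpp(m$weights, X, y, unclass(cfg))
  set.seed(12)
  for (nm in names(m$weights)) {
    for (i in sample(length(m$weights[[nm]]),
                     min(4, length(m$weights[[nm]])))) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + 1e-5
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - 1e-5
      fd <- (orientfree:::cnn_loss_grad_cpp(wp, X, y, unclass(cfg))$loss -
             orientfree:::cnn_loss_grad_cpp(wm, X, y, unclass(cfg))$loss) / 2e-5
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-5)
    }
  }
})

test_that("training separates linearly separable spectra quickly", {
  d <- separable_spectra(400, seed = 2)
  cfg <- cnn_config(M = 40, C = 2, conv1_filters = 8, conv2_filters = 8,
                    dense = 32, epochs = 30, patience = 0, batch = 64,
                    seed = 5)
  m <- build_cnn(cfg)
  m <- train_cnn(m, d$X, d$y)
  acc <- mean(as.character(predict(m, d$X)) == d$y)
  expect_gt(acc, 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- separable_spectra(150, seed = 3)
  cfg <- cnn_config(M = 40, C = 2, conv1_filters = 4, conv2_filters = 6,
                    dense = 16, epochs = 4, patience = 0, seed = 21)
  m1 <- train_cnn(build_cnn(cfg), d$X[1:120, ], d$y[1:120],
                  d$X[121:150, ], d$y[121:150])
  m2 <- train_cnn(build_cnn(cfg), d$X[1:120, ], d$y[1:120],
                  d$X[121:150, ], d$y[121:150])
  expect_identical(m1$log$train_loss, m2$log$train_loss)
  expect_identical(m1$log$val_loss, m2$log$val_loss)
  expect_identical(m1$weights, m2$weights)
})

test_that("training on structureless data stays at chance on fresh data", {
  # null benchmark: features carry no class information at all
  set.seed(7)
  X <- matrix(abs(rnorm(600 * 120)), 600)
  y <- sample(c("a", "b"), 600, replace = TRUE)
  cfg <- cnn_config(M = 40, C = 2, conv1_filters = 4, conv2_filters = 6,
                    dense = 16, epochs = 8, patience = 0, seed = 8)
  m <- train_cnn(build_cnn(cfg), X[1:400, ], y[1:400])
  acc <- 100 * mean(as.character(predict(m, X[401:600, ])) == y[401:600])
  expect_lt(abs(acc - 50), 10)
})

test_that("predictions are independent of batch order and argmax-consistent", {
  d <- separable_spectra(100, seed = 9)
  cfg <- cnn_config(M = 40, C = 2, conv1_filters = 4, conv2_filters = 6,
                    dense = 16, epochs = 3, patience = 0, seed = 10)
  m <- train_cnn(build_cnn(cfg), d$X, d$y)
  p <- predict(m, d$X, type = "prob")
  set.seed(10)
  perm <- sample(100)
  p2 <- predict(m, d$X[perm, ], type = "prob")
  expect_equal(p2, p[perm, ], tolerance = 1e-12)
  cls <- predict(m, d$X, type = "class")
  expect_identical(as.integer(cls), max.col(p, ties.method = "first"))
})

test_that("the movement/posture pre-classifier is the same net with C = 2", {
  cfg <- cnn_config(M = 40, C = 5, conv1_filters = 4, conv2_filters = 6,
                    dense = 16, seed = 13)
  tm <- build_type_classifier(cfg)
  expect_equal(tm$cfg$C, 2L)
  expect_identical(tm$classes, c("movement", "posture"))
  p <- predict(tm, matrix(0, 2, 120), type = "prob")
  expect_equal(dim(p), c(2L, 2L))

  # on synthetic spectra, movement vs posture is essentially solved
  cfg2 <- synth_config(n_subjects = 3, duration_s = 30, seed = 14)
  ds <- generate_dataset(cfg2)
  segs <- unlist(lapply(ds$recordings, preprocess_recording,
                        type_map = ds$type_map, mode = "raw"),
                 recursive = FALSE)
  ft <- build_features(segs, cfg2$fs)
  tcfg <- cnn_config(M = ft$M, C = 2, conv1_filters = 8, conv2_filters = 8,
                     dense = 32, epochs = 8, patience = 0, seed = 15)
  tm2 <- train_cnn(build_type_classifier(tcfg), ft, ft$meta$type)
  acc <- mean(as.character(predict(tm2, ft)) == ft$meta$type)
  expect_gt(acc, 0.95)
})

test_that("training warns on absent classes and rejects unknown labels", {
  d <- separable_spectra(60, seed = 16)
  cfg <- cnn_config(M = 40, C = 3, conv1_filters = 4, conv2_filters = 4,
                    dense = 8, epochs = 1, patience = 0, seed = 17)
  m <- build_cnn(cfg, classes = c("a", "b", "zz"))
  expect_warning(train_cnn(m, d$X, d$y), "absent")
  m2 <- build_cnn(cfg, classes = c("a", "q", "r"))
  expect_error(suppressWarnings(train_cnn(m2, d$X, d$y)), "outside")
})
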