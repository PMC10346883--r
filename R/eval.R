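#' Subject-wise fold assignment
#'
#' Subjects are shuffled by `seed` and dealt round-robin into `k` folds, so
#' every recording of a subject lives in exactly one fold.  In iteration
#' `i` (0-based) the test set is fold `i`, the validation set fold
#' `(i + 1) mod k`, and the remaining folds train the model, so train,
#' validation and test subjects never overlap.
#'
#' @param subjects character vector of subject identifiers (duplicates
#'   collapsed).
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return An object of class `fold_assignment`: named integer vector
#'   `fold` (values in `0:(k-1)`), and `k`.
#' @export
subject_folds <- function(subjects, k = 10, seed = 1) {
  subjects <- unique(as.character(subjects))
  if (k < 2) stop("`k` must be at least 2")
  if (length(subjects) < 3)
    stop("need at least 3 subjects to separate train/validation/test")
  set.seed(seed)
  sh <- sample(subjects)
  structure(list(fold = setNames((seq_along(sh) - 1L) %% as.integer(k), sh),
                 k = as.integer(k)), class = "fold_assignment")
}

#' Train/validation/test subjects for one CV iteration
#' @param fa a `fold_assignment`.
#' @param i iteration index in `0:(k-1)`.
#' @return A list of character vectors `train`, `val`, `test`.
#' @export
fold_split <- function(fa, i) {
  stopifnot(inherits(fa, "fold_assignment"), i >= 0, i < fa$k)
  test <- names(fa$fold)[fa$fold == i]
  val <- names(fa$fold)[fa$fold == (i + 1L) %% fa$k]
  train <- setdiff(names(fa$fold), c(test, val))
  list(train = train, val = val, test = test)
}

#' Classification accuracy from a confusion matrix
#'
#' The percentage of correctly classified windows:
#' `100 * sum(diag(confusion)) / N` with `N` the total count.
#'
#' @param confusion C x C count matrix, rows = true classes,
#'   columns = predicted.
#' @return Accuracy in percent.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix holds no observations")
  100 * sum(diag(confusion)) / n
}

#' 95% confidence half-width for an accuracy
#'
#' Binomial normal-approximation interval on the percentage scale:
#' `1.96 * sqrt(acc * (100 - acc) / N)`.
#'
#' @param accuracy_pct accuracy in percent, in `[0, 100]`.
#' @param n number of evaluated windows (>= 1).
#' @return Half-width in percentage points (`accuracy_pct` is read as
#'   plus/minus this value).
#' @export
ci95 <- function(accuracy_pct, n) {
  if (!is.numeric(accuracy_pct) || accuracy_pct < 0 || accuracy_pct > 100)
    stop("`accuracy_pct` must lie in [0, 100]")
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1")
  1.96 * sqrt(accuracy_pct * (100 - accuracy_pct) / n)
}

#' Per-class precision and recall
#'
#' `precision_c = diag_c / colsum_c` and `recall_c = diag_c / rowsum_c`;
#' zero denominators yield `NA` (undefined), not 0.  Confidence intervals
#' use the same binomial half-width as [ci95()] with the per-class counts.
#'
#' @param confusion C x C count matrix, rows = true, columns = predicted.
#' @return A data frame with one row per class: `class`, `precision`,
#'   `precision_ci`, `recall`, `recall_ci`, `n_true`, `n_pred`.
#' @export
precision_recall <- function(confusion) {
  confusion <- as.matrix(confusion)
  cls <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))
  d <- diag(confusion)
  npred <- colSums(confusion)
  ntrue <- rowSums(confusion)
  prec <- ifelse(npred > 0, 100 * d / npred, NA_real_)
  rec <- ifelse(ntrue > 0, 100 * d / ntrue, NA_real_)
  data.frame(class = cls,
             precision = prec,
             precision_ci = ifelse(npred > 0,
                                   1.96 * sqrt(prec * (100 - prec) / npred),
                                   NA_real_),
             recall = rec,
             recall_ci = ifelse(ntrue > 0,
                                1.96 * sqrt(rec * (100 - rec) / ntrue),
                                NA_real_),
             n_true = as.numeric(ntrue), n_pred = as.numeric(npred),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Summarise a pooled confusion matrix (plus optional per-fold accuracies)
## into one setup report.
summarise_setup <- function(confusion, type_of_label, fold_acc = NULL,
                            pool = c("pooled", "per_fold")) {
  pool <- match.arg(pool)
  n <- sum(confusion)
  acc <- if (pool == "pooled" || is.null(fold_acc)) accuracy(confusion)
         else mean(fold_acc)
  by_type <- lapply(c(movement = "movement", posture = "posture"), function(tp) {
    rows <- names(type_of_label)[type_of_label == tp]
    rows <- intersect(rows, rownames(confusion))
    if (length(rows) == 0) return(NULL)
    sub <- confusion[rows, , drop = FALSE]
    nn <- sum(sub)
    a <- if (nn > 0) 100 * sum(diag(confusion)[rows]) / nn else NA_real_
    list(accuracy = a, ci95 = if (nn > 0) ci95(a, nn) else NA_real_, n = nn)
  })
  list(accuracy = acc, ci95 = ci95(acc, n), n = n, confusion = confusion,
       per_class = precision_recall(confusion), by_type = by_type,
       fold_accuracy = fold_acc)
}

#' Run the four orientation-robustness experimental setups
#'
#' Executes, under one shared fold assignment and rotation draw:
#' \enumerate{
#'   \item \strong{baseline} - original recordings, no preprocessing;
#'   \item \strong{rotated} - every subject's recording perturbed by a
#'     fixed rotation of `theta_deg` about one randomly selected sensor
#'     axis;
#'   \item \strong{rotated_algorithm} - rotated data with the consistent
#'     reference frame applied to every segment, postures included;
#'   \item \strong{rotated_per_type} - rotated data with the frame
#'     transform for movements and gravity subtraction for postures,
#'     routed by a 2-class movement/posture CNN trained on the rotated
#'     spectra (its errors propagate into the reported accuracy).
#' }
#' Every setup uses subject-wise `k`-fold cross-validation with the same
#' folds; windows from all test folds are pooled before computing accuracy
#' and its 95% interval (set `pool = "per_fold"` to average per-fold
#' accuracies instead).
#'
#' @param recordings list of [triaxial_recording()]s (one per subject).
#' @param type_map named character vector mapping every activity label to
#'   `"movement"`/`"posture"`.
#' @param k folds (default 10).
#' @param theta_deg rotation angle for the perturbation (default 45).
#' @param seed master seed: folds, rotation axes and all training runs
#'   derive from it.
#' @param win_s,step_s,f_max spectral windowing parameters
#'   (see [build_features()]).
#' @param window_s sliding-mean length for the frame algorithm, seconds.
#' @param cnn named list of [cnn_config()] overrides for the activity
#'   classifier (e.g. `list(epochs = 15, dense = 64)`).
#' @param type_cnn overrides for the movement/posture pre-classifier
#'   (defaults to `cnn`).
#' @param pool `"pooled"` or `"per_fold"` accuracy aggregation.
#' @param verbose print per-fold progress.
#' @return An object of class `eval_report`: per-setup summaries
#'   (accuracy, ci95, confusion, per-class precision/recall, by-type
#'   accuracies), the type-classifier accuracy under setup 4, the fold
#'   assignment and the rotation specs.
#' @export
run_setups <- function(recordings, type_map, k = 10, theta_deg = 45, seed = 1,
                       win_s = 5, step_s = 1, f_max = NULL, window_s = 5,
                       cnn = list(), type_cnn = cnn,
                       pool = c("pooled", "per_fold"), verbose = FALSE) {
  pool <- match.arg(pool)
  fs <- unique(vapply(recordings, function(r) r$fs, 0))
  if (length(fs) != 1L) stop("all recordings must share one sampling rate")
  if (is.null(f_max)) f_max <- default_f_max(fs)
  subjects <- vapply(recordings, function(r) r$subject_id, "")
  if (anyDuplicated(subjects)) stop("expected one recording per subject")

  folds <- subject_folds(subjects, k, seed)
  specs <- random_subject_rotations(subjects, theta_deg, seed)
  rotated <- lapply(recordings, function(r) {
    apply_rotation(r, specs[specs$subject == r$subject_id, ])
  })

  feat <- function(recs, mode) {
    segs <- lapply(recs, preprocess_recording, type_map = type_map,
                   mode = mode, window_s = window_s)
    build_features(segs, fs, win_s, step_s, f_max)
  }
  if (verbose) message("building features for the four setups ...")
  fs_base <- feat(recordings, "raw")
  fs_rot <- feat(rotated, "raw")
  fs_alg <- feat(rotated, "frame_all")
  fs_grav <- feat(rotated, "gravity_all")
  ## oracle-routed training features: frame for true movements,
  ## gravity subtraction for true postures
  mov_rows <- fs_alg$meta$type == "movement"
  x_type_true <- fs_alg$x
  x_type_true[!mov_rows, ] <- fs_grav$x[!mov_rows, , drop = FALSE]

  classes <- sort(unique(unlist(lapply(recordings, function(r) r$labels))))
  meta <- fs_base$meta           # identical across variants by construction
  seg_key <- paste(meta$subject, meta$segment)

  cnn_cfg <- function(overrides, C, seed) {
    do.call(cnn_config, c(list(M = fs_base$M, C = C, n_axes = 3L, seed = seed),
                          overrides))
  }
  fit_and_score <- function(x, labels, classes, tr, va, te, seed,
                            overrides, x_test = NULL) {
    cfg <- cnn_cfg(overrides, length(classes), seed)
    m <- build_cnn(cfg, classes = classes)
    m <- train_cnn(m, x[tr, , drop = FALSE], labels[tr],
                   x[va, , drop = FALSE], labels[va])
    xt <- if (is.null(x_test)) x[te, , drop = FALSE] else x_test
    predict(m, xt, type = "class")
  }

  setups <- c("baseline", "rotated", "rotated_algorithm", "rotated_per_type")
  conf <- lapply(setNames(setups, setups), function(s)
    matrix(0, length(classes), length(classes),
           dimnames = list(classes, classes)))
  conf_type <- matrix(0, 2, 2, dimnames = list(c("movement", "posture"),
                                               c("movement", "posture")))
  fold_acc <- lapply(setNames(setups, setups), function(s) numeric(0))

  xs <- list(baseline = fs_base$x, rotated = fs_rot$x,
             rotated_algorithm = fs_alg$x)
  for (i in seq_len(folds$k) - 1L) {
    sp <- fold_split(folds, i)
    tr <- meta$subject %in% sp$train
    va <- meta$subject %in% sp$val
    te <- meta$subject %in% sp$test
    if (!any(te)) next
    if (verbose) message("fold ", i + 1, "/", folds$k)
    ## one shared training seed per fold, so setups are compared with
    ## identical initialisation and shuffling (paired comparison)
    for (s in names(xs)) {
      pred <- fit_and_score(xs[[s]], meta$label, classes, tr, va, te,
                            derive_seed(seed, "fold", i), cnn)
      cm <- table(factor(meta$label[te], classes), factor(pred, classes))
      conf[[s]] <- conf[[s]] + as.matrix(cm)
      fold_acc[[s]] <- c(fold_acc[[s]], accuracy(cm))
    }
    ## setup 4: movement/posture router trained on the rotated spectra
    tcfg <- cnn_cfg(type_cnn, 2L, derive_seed(seed, "type", i))
    tm <- build_type_classifier(tcfg)
    tm <- train_cnn(tm, fs_rot$x[tr, , drop = FALSE], meta$type[tr],
                    fs_rot$x[va, , drop = FALSE], meta$type[va])
    tpred <- as.character(predict(tm, fs_rot$x[te, , drop = FALSE]))
    conf_type <- conf_type +
      as.matrix(table(factor(meta$type[te], rownames(conf_type)),
                      factor(tpred, rownames(conf_type))))
    ## route each test segment by the majority window vote
    routed <- tapply(tpred, seg_key[te], function(v)
      if (mean(v == "movement") >= 0.5) "movement" else "posture")
    seg_route <- routed[seg_key[te]]
    x_test <- fs_alg$x[te, , drop = FALSE]
    gr <- seg_route == "posture"
    x_test[gr, ] <- fs_grav$x[te, , drop = FALSE][gr, , drop = FALSE]
    pred <- fit_and_score(x_type_true, meta$label, classes, tr, va, te,
                          derive_seed(seed, "fold", i), cnn,
                          x_test = x_test)
    cm <- table(factor(meta$label[te], classes), factor(pred, classes))
    conf[["rotated_per_type"]] <- conf[["rotated_per_type"]] + as.matrix(cm)
    fold_acc[["rotated_per_type"]] <- c(fold_acc[["rotated_per_type"]],
                                        accuracy(cm))
  }

  type_of_label <- setNames(unname(type_map[classes]), classes)
  out <- lapply(setNames(setups, setups), function(s)
    summarise_setup(conf[[s]], type_of_label, fold_acc[[s]], pool))
  structure(list(setups = out,
                 type_classifier = list(accuracy = accuracy(conf_type),
                                        ci95 = ci95(accuracy(conf_type),
                                                    sum(conf_type)),
                                        confusion = conf_type),
                 classes = classes, folds = folds, rotations = specs,
                 n_windows = nrow(meta), pool = pool,
                 params = list(k = k, theta_deg = theta_deg, seed = seed,
                               win_s = win_s, step_s = step_s, f_max = f_max,
                               window_s = window_s)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> subject-wise", x$folds$k, "fold CV,",
      x$n_windows, "windows,", length(x$classes), "classes\n")
  for (s in names(x$setups)) {
    st <- x$setups[[s]]
    cat(sprintf("  %-18s %6.2f +- %.2f %%", s, st$accuracy, st$ci95))
    bt <- st$by_type
    if (!is.null(bt$movement) && !is.null(bt$posture))
      cat(sprintf("   (movements %.2f, postures %.2f)",
                  bt$movement$accuracy, bt$posture$accuracy))
    cat("\n")
  }
  cat(sprintf("  type classifier    %6.2f +- %.2f %%\n",
              x$type_classifier$accuracy, x$type_classifier$ci95))
  invisible(x)
}

#' Run the synthetic orientation-robustness benchmark
#'
#' Generates the default synthetic dataset (20 subjects, 50 Hz, five
#' activities of 120 s each) and executes the four experimental setups
#' under subject-wise 10-fold cross-validation.  The classifier uses a
#' reduced architecture (8/16 filters, 64 dense units, batch 64, learning
#' rate 5e-3, at most 12 epochs with early stopping), which is ample for
#' the synthetic spectra and keeps the full benchmark inside roughly a
#' quarter of an hour on one CPU.
#'
#' @param seed master seed for generation, folds, rotations and training.
#' @param n_subjects,duration_s benchmark size overrides.
#' @param theta_deg rotation perturbation angle in degrees.
#' @param verbose print progress.
#' @return An `eval_report`, see [run_setups()].
#' @export
run_benchmark <- function(seed = 1, n_subjects = 20, duration_s = 120,
                          theta_deg = 45, verbose = FALSE) {
  cfg <- synth_config(n_subjects = n_subjects, duration_s = duration_s,
                      seed = derive_seed(seed, "synth"))
  ds <- generate_dataset(cfg)
  run_setups(ds$recordings, ds$type_map, k = 10, theta_deg = theta_deg,
             seed = seed,
             cnn = list(conv1_filters = 8L, conv2_filters = 16L,
                        dense = 64L, batch = 64L, epochs = 12L,
                        patience = 3L, lr = 5e-3),
             type_cnn = list(conv1_filters = 8L, conv2_filters = 16L,
                             dense = 64L, batch = 128L, epochs = 4L,
                             patience = 0L, lr = 5e-3),
             verbose = verbose)
}
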