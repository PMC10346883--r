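#' Configuration for the spectral CNN classifier
#'
#' The classifier is a compact 1-D convolutional network over the per-axis
#' spectral magnitudes: a feature-learning subnet of two convolutional
#' layers with intermediate max-pooling, then a classification subnet of
#' fully connected layers ending in a `C`-way softmax; ReLU activations in
#' between, dropout after each pooling and dense layer to control
#' overfitting, categorical cross-entropy loss and the RMSprop optimizer.
#' Filter counts, kernel and pooling sizes, dense width, dropout rates and
#' the training schedule are all set here; the defaults are conventional
#' small-CNN values for spectra of roughly 50-100 bins per axis.
#'
#' @param M spectral bins per axis.
#' @param C number of classes (>= 2).
#' @param n_axes input channels (3 axis spectra by default; set to 1 and
#'   `M` to the full concatenated length for a flat layout).
#' @param conv1_filters,conv1_kernel,pool1 first convolution block.
#' @param conv2_filters,conv2_kernel,pool2 second convolution block.
#' @param dense width of the fully connected hidden layer.
#' @param dropout dropout rates after pool 1, pool 2 and the dense layer.
#' @param lr,rho,eps RMSprop learning rate, decay and stabiliser.
#' @param batch minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (0 disables).
#' @param min_delta minimum validation-loss improvement that resets
#'   patience.
#' @param class_weights optional per-class loss weights (length `C`).
#' @param standardize z-score each input feature using training-set
#'   statistics (stored in the model and reapplied at prediction).
#'   Spectral magnitudes span orders of magnitude between the DC bin and
#'   the high-frequency tail; standardisation is what makes RMSprop
#'   converge quickly on them.
#' @param seed integer seed controlling weight initialisation, shuffling
#'   and dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(M, C, n_axes = 3L,
                       conv1_filters = 16L, conv1_kernel = 5L, pool1 = 2L,
                       conv2_filters = 32L, conv2_kernel = 5L, pool2 = 2L,
                       dense = 128L, dropout = c(0.25, 0.25, 0.5),
                       lr = 1e-3, rho = 0.9, eps = 1e-8,
                       batch = 64L, epochs = 50L, patience = 10L,
                       min_delta = 0, class_weights = NULL,
                       standardize = TRUE, seed = 1L) {
  cfg <- list(M = as.integer(M), C = as.integer(C),
              n_axes = as.integer(n_axes),
              conv1_filters = as.integer(conv1_filters),
              conv1_kernel = as.integer(conv1_kernel), pool1 = as.integer(pool1),
              conv2_filters = as.integer(conv2_filters),
              conv2_kernel = as.integer(conv2_kernel), pool2 = as.integer(pool2),
              dense = as.integer(dense), dropout = as.numeric(dropout),
              lr = lr, rho = rho, eps = eps, batch = as.integer(batch),
              epochs = as.integer(epochs), patience = as.integer(patience),
              min_delta = min_delta, class_weights = class_weights,
              standardize = isTRUE(standardize), seed = as.integer(seed))
  if (cfg$C < 2L) stop("`C` must be at least 2")
  if (any(unlist(cfg[c("M", "n_axes", "conv1_filters", "conv1_kernel", "pool1",
                       "conv2_filters", "conv2_kernel", "pool2", "dense",
                       "batch", "epochs")]) < 1L))
    stop("all size and schedule parameters must be positive")
  if (length(cfg$dropout) != 3L || any(cfg$dropout < 0) || any(cfg$dropout >= 1))
    stop("`dropout` must be three rates in [0, 1)")
  L1 <- cfg$M - cfg$conv1_kernel + 1L
  L1p <- L1 %/% cfg$pool1
  L2 <- L1p - cfg$conv2_kernel + 1L
  L2p <- L2 %/% cfg$pool2
  if (L1 < 1L || L1p < 1L || L2 < 1L || L2p < 1L)
    stop("`M` is too small for the configured kernels and pooling")
  structure(cfg, class = "cnn_config")
}

#' Number of trainable parameters implied by a configuration
#' @param cfg a [cnn_config()].
#' @return Integer parameter count.
#' @export
cnn_n_params <- function(cfg) {
  L1 <- cfg$M - cfg$conv1_kernel + 1L
  L1p <- L1 %/% cfg$pool1
  L2 <- L1p - cfg$conv2_kernel + 1L
  flat <- (L2 %/% cfg$pool2) * cfg$conv2_filters
  cfg$conv1_kernel * cfg$n_axes * cfg$conv1_filters + cfg$conv1_filters +
    cfg$conv2_kernel * cfg$conv1_filters * cfg$conv2_filters + cfg$conv2_filters +
    flat * cfg$dense + cfg$dense +
    cfg$dense * cfg$C + cfg$C
}

#' Build an untrained CNN
#'
#' Initialises the weights (He-scaled normal draws, seeded by
#' `cfg$seed`) for the architecture described in [cnn_config()].
#'
#' @param cfg a [cnn_config()].
#' @param classes optional character vector of class labels, length
#'   `cfg$C`; fixed at training time when `NULL`.
#' @return An object of class `orientfree_cnn`.
#' @export
build_cnn <- function(cfg, classes = NULL) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (!is.null(classes) && length(classes) != cfg$C)
    stop("`classes` must have length C")
  set.seed(cfg$seed)
  structure(list(cfg = cfg, weights = cnn_init_weights(unclass(cfg)),
                 classes = classes, scaling = NULL, log = NULL,
                 trained = FALSE),
            class = "orientfree_cnn")
}

#' Build the 2-class movement/posture pre-classifier
#'
#' The same architecture as the activity classifier with a softmax over
#' two classes, used to route each analysis window to the appropriate
#' preprocessing branch.
#'
#' @param cfg a [cnn_config()]; its `C` is forced to 2.
#' @return An untrained `orientfree_cnn` with classes
#'   `c("movement", "posture")`.
#' @export
build_type_classifier <- function(cfg) {
  cfg$C <- 2L
  build_cnn(cfg, classes = c("movement", "posture"))
}

feature_matrix <- function(features) {
  if (inherits(features, "feature_set")) features$x else as.matrix(features)
}

apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  sweep(sweep(x, 2L, scaling$mu, "-"), 2L, scaling$sd, "/")
}

#' Train a CNN on a feature set
#'
#' Minimises the categorical cross-entropy with RMSprop; training is
#' deterministic given `cfg$seed` (all randomness is drawn from R's RNG).
#' When a validation set is supplied, training stops early once the
#' validation loss has not improved for `patience` epochs and the
#' best-validation weights are restored.  Classes named in `model$classes`
#' but absent from the training labels trigger a warning, not an error.
#'
#' @param model an `orientfree_cnn` from [build_cnn()].
#' @param features a `feature_set` (or bare matrix) of training windows.
#' @param labels training labels; defaults to `features$meta$label`.
#' @param val_features,val_labels optional validation windows and labels
#'   (for subject-wise evaluation, pass a different subjects' fold).
#' @param verbose print per-epoch losses.
#' @return The trained model, with a `log` holding per-epoch training and
#'   validation losses, validation accuracy, the best epoch and the seed.
#' @export
train_cnn <- function(model, features, labels = NULL,
                      val_features = NULL, val_labels = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "orientfree_cnn"))
  cfg <- model$cfg
  x <- feature_matrix(features)
  if (is.null(labels)) labels <- features$meta$label
  labels <- as.character(labels)
  if (nrow(x) == 0L) stop("no training windows")
  if (ncol(x) != cfg$n_axes * cfg$M)
    stop("feature dimension does not match the model")
  classes <- model$classes %||% sort(unique(labels))
  if (length(classes) != cfg$C)
    stop("number of classes (", length(classes),
         ") does not match the model's C (", cfg$C, ")")
  unknown <- setdiff(unique(labels), classes)
  if (length(unknown) > 0)
    stop("labels outside the model's classes: ", paste(unknown, collapse = ", "))
  absent <- setdiff(classes, unique(labels))
  if (length(absent) > 0)
    warning("class(es) absent from training data: ",
            paste(absent, collapse = ", "))
  y <- match(labels, classes) - 1L

  if (is.null(val_features)) {
    xv <- matrix(numeric(0), 0L, ncol(x))
    yv <- integer(0)
  } else {
    xv <- feature_matrix(val_features)
    vl <- as.character(val_labels %||% val_features$meta$label)
    keep <- vl %in% classes
    xv <- xv[keep, , drop = FALSE]
    yv <- match(vl[keep], classes) - 1L
  }

  if (isTRUE(cfg$standardize)) {
    model$scaling <- list(mu = colMeans(x),
                          sd = pmax(apply(x, 2L, stats::sd), 1e-8))
    x <- apply_scaling(x, model$scaling)
    xv <- apply_scaling(xv, model$scaling)
  }

  opt <- list(lr = cfg$lr, rho = cfg$rho, eps = cfg$eps, batch = cfg$batch,
              epochs = cfg$epochs, patience = cfg$patience,
              min_delta = cfg$min_delta, class_weights = cfg$class_weights,
              verbose = isTRUE(verbose))
  set.seed(cfg$seed)
  fit <- cnn_train_cpp(x, y, xv, yv, model$weights, unclass(cfg), opt)
  model$weights <- fit$weights
  model$classes <- classes
  model$log <- list(train_loss = fit$train_loss, val_loss = fit$val_loss,
                    val_acc = fit$val_acc, best_epoch = fit$best_epoch,
                    epochs_run = fit$epochs_run, seed = cfg$seed)
  model$trained <- TRUE
  model
}

#' Predict activity classes for a feature set
#'
#' @param object a trained `orientfree_cnn`.
#' @param newdata a `feature_set` or bare feature matrix.
#' @param type `"class"` for the argmax labels (ties broken by lowest
#'   class index), `"prob"` for the per-window probability matrix.
#' @param ... unused.
#' @return A factor of predicted labels, or a windows x classes
#'   probability matrix whose rows sum to 1.
#' @export
predict.orientfree_cnn <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$classes))
    stop("model has no class labels; train it or supply `classes`")
  x <- apply_scaling(feature_matrix(newdata), object$scaling)
  p <- cnn_predict_cpp(object$weights, x, unclass(object$cfg))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.orientfree_cnn <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<orientfree_cnn> %d-way, %d x %d bins, %d parameters%s\n",
              cfg$C, cfg$n_axes, cfg$M, cnn_n_params(cfg),
              if (x$trained) sprintf(" (trained, best epoch %d)",
                                     x$log$best_epoch) else " (untrained)"))
  invisible(x)
}
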