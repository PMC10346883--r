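#' Split a signal into overlapped Hanning-tapered analysis windows
#'
#' Windows of `round(win_s * fs)` samples are taken every
#' `round(step_s * fs)` samples (5 s windows with a 1 s step by default)
#' and multiplied pointwise by a Hanning taper; the trailing partial window
#' is dropped.
#'
#' @param x numeric vector or N x k matrix (one column per axis).
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param step_s hop between consecutive window starts in seconds.
#' @param taper apply the Hanning taper (`TRUE`, the default) or return
#'   rectangular windows.
#' @return A list with `windows` (list of L x k tapered matrices, empty
#'   with a warning when the signal is shorter than one window) and
#'   `starts` (1-based start indices).
#' @export
window_signal <- function(x, fs, win_s = 5, step_s = 1, taper = TRUE) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  L <- as.integer(round(win_s * fs))
  S <- as.integer(round(step_s * fs))
  if (L < 1L || S < 1L) stop("`win_s` and `step_s` must span >= 1 sample")
  n <- nrow(x)
  if (n < L) {
    warning("signal shorter than one analysis window; no windows produced")
    return(list(windows = list(), starts = integer(0), L = L, S = S))
  }
  starts <- seq.int(1L, n - L + 1L, by = S)
  w <- if (taper) signal::hanning(L) else rep(1, L)
  list(windows = lapply(starts, function(s) x[s:(s + L - 1L), , drop = FALSE] * w),
       starts = starts, L = L, S = S)
}

#' Magnitude spectrum of an analysis window
#'
#' Discrete-Fourier magnitude of each axis, restricted to the band
#' `[0, f_max]`: bins `0 .. M-1` with `M = floor(f_max * L / fs) + 1`,
#' where `L` is the window length in samples.  The DC bin is included.
#'
#' @param w L x k (tapered) window matrix, one column per axis.
#' @param fs sampling rate in Hz.
#' @param f_max upper band edge in Hz; must not exceed the Nyquist
#'   frequency `fs / 2`.
#' @return M x k matrix of non-negative spectral magnitudes.
#' @export
window_spectrum <- function(w, fs, f_max) {
  w <- if (is.matrix(w)) w else matrix(as.numeric(w), ncol = 1L)
  if (f_max > fs / 2 + 1e-9) stop("`f_max` exceeds the Nyquist frequency fs/2")
  if (f_max < 0) stop("`f_max` must be non-negative")
  L <- nrow(w)
  M <- floor(f_max * L / fs) + 1L
  abs(mvfft(w))[seq_len(M), , drop = FALSE]
}

#' Default spectral band edge for a sampling rate
#'
#' 10 Hz for 20 Hz recordings (the Nyquist limit) and 20 Hz otherwise,
#' always capped at Nyquist.
#' @param fs sampling rate in Hz.
#' @return Band edge in Hz.
#' @export
default_f_max <- function(fs) min(if (fs <= 20) 10 else 20, fs / 2)

#' Build a spectral feature set from preprocessed segments
#'
#' Windows each single-activity segment (windows never span an activity
#' boundary, so every window carries a single label), computes per-axis
#' magnitude spectra and stacks them into a feature matrix of
#' W windows x (3 axes x M bins), with the three axis spectra laid out
#' side by side (axis-major) and treated as 3 channels of length M by the
#' classifier.  Rows are ordered deterministically by (subject, segment,
#' start).
#'
#' @param segments list of preprocessed segments as produced by
#'   [preprocess_recording()] (elements with `x`, `subject`, `label`,
#'   `type`), or a list of such lists (one per recording).
#' @param fs sampling rate in Hz, consistent across segments.
#' @param win_s,step_s analysis window length and step in seconds.
#' @param f_max spectral band edge in Hz; `NULL` uses [default_f_max()].
#' @param include_dc keep the 0 Hz bin (default `TRUE`).
#' @param normalize `"none"` (default) or `"max"` for per-window
#'   max-normalisation of the magnitudes.
#' @return An object of class `feature_set`: list with matrix `x`, data
#'   frame `meta` (`subject`, `label`, `type`, `segment`, `start`,
#'   `time_s`), and fields `M`, `n_axes`, `f_max`, `fs`, `win_s`,
#'   `step_s`, `include_dc`.
#' @export
build_features <- function(segments, fs, win_s = 5, step_s = 1, f_max = NULL,
                           include_dc = TRUE,
                           normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  if (is.null(f_max)) f_max <- default_f_max(fs)
  if (f_max > fs / 2 + 1e-9) stop("`f_max` exceeds the Nyquist frequency fs/2")
  ## accept a list of per-recording segment lists and flatten it
  if (length(segments) > 0 && is.null(segments[[1]]$x))
    segments <- unlist(segments, recursive = FALSE)
  L <- as.integer(round(win_s * fs))
  S <- as.integer(round(step_s * fs))
  M_full <- floor(f_max * L / fs) + 1L
  keep <- if (include_dc) seq_len(M_full) else seq.int(2L, M_full)
  M <- length(keep)
  taper <- signal::hanning(L)

  mats <- list()
  metas <- list()
  seg_id <- 0L
  for (seg in segments) {
    seg_id <- seg_id + 1L
    x <- as.matrix(seg$x)
    n <- nrow(x)
    if (n < L) next
    starts <- seq.int(1L, n - L + 1L, by = S)
    idx <- outer(seq_len(L) - 1L, starts, `+`) + 0L   # L x W sample indices
    feats <- lapply(seq_len(ncol(x)), function(ax) {
      Xw <- matrix(x[idx, ax], nrow = L) * taper      # L x W tapered windows
      t(abs(mvfft(Xw))[keep, , drop = FALSE])          # W x M magnitudes
    })
    fm <- do.call(cbind, feats)
    if (normalize == "max") {
      mx <- pmax(apply(fm, 1L, max), .Machine$double.xmin)
      fm <- fm / mx
    }
    mats[[length(mats) + 1L]] <- fm
    metas[[length(metas) + 1L]] <- data.frame(
      subject = seg$subject %||% NA_character_,
      label = seg$label %||% NA_character_,
      type = seg$type %||% NA_character_,
      segment = seg_id, start = starts, time_s = (starts - 1L) / fs,
      stringsAsFactors = FALSE)
  }
  if (length(mats) == 0L) {
    x <- matrix(numeric(0), nrow = 0L, ncol = 3L * M)
    meta <- data.frame(subject = character(0), label = character(0),
                       type = character(0), segment = integer(0),
                       start = integer(0), time_s = numeric(0))
  } else {
    x <- do.call(rbind, mats)
    meta <- do.call(rbind, metas)
    o <- order(meta$subject, meta$segment, meta$start)
    x <- x[o, , drop = FALSE]
    meta <- meta[o, , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(x = x, meta = meta, M = M, n_axes = 3L, f_max = f_max,
                 fs = fs, win_s = win_s, step_s = step_s,
                 include_dc = include_dc),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set> %d windows x (%d axes x %d bins), band [0, %g] Hz\n",
    nrow(x$x), x$n_axes, x$M, x$f_max))
  if (nrow(x$meta) > 0)
    cat("  subjects:", length(unique(x$meta$subject)),
        " labels:", paste(unique(x$meta$label), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a feature set to a delimited table with a JSON sidecar
#'
#' The matrix and window metadata go into one CSV; dimensions, band and
#' windowing parameters go into `<path>.json`.
#'
#' @param features a `feature_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  dt <- data.table::data.table(features$meta,
                               data.table::as.data.table(features$x))
  data.table::fwrite(dt, path)
  side <- features[c("M", "n_axes", "f_max", "fs", "win_s", "step_s",
                     "include_dc")]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature set written by [write_features()]
#' @param path CSV path given to [write_features()].
#' @return A `feature_set`.
#' @export
read_features <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(path, showProgress = FALSE)
  meta_cols <- c("subject", "label", "type", "segment", "start", "time_s")
  meta <- as.data.frame(dt[, meta_cols, with = FALSE])
  meta$subject <- as.character(meta$subject)
  x <- as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE])
  dimnames(x) <- NULL
  structure(c(list(x = x, meta = meta), side), class = "feature_set")
}
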