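#' Centered sliding mean with truncated edges
#'
#' Mean filter over a centered window of `round(window_s * fs)` samples,
#' applied independently to each column.  At the edges the mean is taken
#' over the samples actually available (truncation), rather than
#' zero-padding, which would bias the gravity magnitude near the ends of a
#' segment.  Implemented with cumulative sums, which is algebraically the
#' stated boxcar convolution.
#'
#' @param x numeric vector or N x k matrix.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 5, the value used for
#'   both the gravity and the forward sliding means).
#' @return A matrix of the same dimension as `x` (vectors become one-column
#'   matrices).
#' @export
sliding_mean <- function(x, fs, window_s = 5) {
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0)
    stop("`window_s` must be a positive number of seconds")
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  L <- as.integer(round(window_s * fs))
  if (L < 1L) stop("window must span at least one sample (window_s * fs >= 1)")
  n <- nrow(x)
  if (L == 1L || n == 1L) return(x)
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  cs <- rbind(0, apply(x, 2L, cumsum))
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Estimate the gravity vector at each sample
#'
#' The quasi-constant gravity reaction is recovered by a long sliding mean
#' of the total acceleration, per coordinate: body movements are
#' (approximately) zero-mean over a multi-second window and average away,
#' leaving gravity.  The returned vector points along the measured mean
#' acceleration, i.e. the reaction to gravity as seen by an accelerometer;
#' no sign flip is applied (any consistent convention preserves the
#' orientation-invariance property).
#'
#' @param rec a [triaxial_recording()] or N x 3 matrix.
#' @param fs sampling rate in Hz; taken from `rec` when it is a recording.
#' @param window_s sliding-mean length in seconds (default 5).
#' @return N x 3 matrix of per-sample gravity estimates in sensor
#'   coordinates, same units as the input.
#' @export
estimate_gravity <- function(rec, fs = NULL, window_s = 5) {
  if (inherits(rec, "triaxial_recording")) fs <- rec$fs
  if (is.null(fs)) stop("`fs` is required when `rec` is a bare matrix")
  sliding_mean(as_samples(rec), fs, window_s)
}

#' Horizontal (gravity-orthogonal) component of the acceleration
#'
#' Subtracts the component along the estimated gravity direction:
#' `h(t) = a(t) - (a(t) . g^(t)) g^(t)`.  Samples whose gravity estimate is
#' too small to define a direction (`|g| <= eps_g`) are marked invalid and
#' returned as `NA`.
#'
#' @param rec a [triaxial_recording()] or N x 3 matrix.
#' @param g N x 3 gravity series from [estimate_gravity()].
#' @param eps_g degeneracy threshold on `|g|`; default
#'   `0.1 * median(|g|)`, a unit-agnostic relative rule.
#' @return A list with `h` (N x 3, `NA` where invalid), logical `valid`,
#'   and the `eps_g` used.
#' @export
horizontal_component <- function(rec, g, eps_g = NULL) {
  a <- as_samples(rec)
  g <- as.matrix(g)
  stopifnot(nrow(a) == nrow(g), ncol(g) == 3L)
  gn <- row_norms(g)
  if (is.null(eps_g)) eps_g <- 0.1 * median(gn)
  valid <- gn > eps_g
  ghat <- g / pmax(gn, .Machine$double.xmin)
  h <- a - rowSums(a * ghat) * ghat
  h[!valid, ] <- NA_real_
  list(h = h, valid = valid, eps_g = eps_g)
}

#' Estimate the forward movement direction at each sample
#'
#' The forward direction is the sliding mean of the horizontal
#' acceleration: locomotion carries a non-zero-mean forward component,
#' while vertical impacts and lateral sway average towards zero.  Samples
#' where the smoothed magnitude does not exceed `eps_f` have no usable
#' forward direction (the degenerate case of static postures) and are
#' flagged invalid rather than raising an error.
#'
#' @param h N x 3 horizontal acceleration (from [horizontal_component()]);
#'   rows may be `NA` where gravity was degenerate.
#' @param fs sampling rate in Hz.
#' @param window_s sliding-mean length in seconds (default 5, shared with
#'   the gravity filter).
#' @param eps_f magnitude threshold in signal units below which a sample
#'   has no forward direction (default `1e-6`; [preprocess_segment()]
#'   passes the relative rule `0.05 * median(|a| - |g|)`).
#' @param valid optional logical mask of rows usable as input (defaults to
#'   complete rows of `h`).
#' @return A list with `f` (N x 3 smoothed horizontal acceleration) and
#'   logical `valid`.
#' @export
estimate_forward <- function(h, fs, window_s = 5, eps_f = 1e-6, valid = NULL) {
  h <- as.matrix(h)
  if (is.null(valid)) valid <- stats::complete.cases(h)
  hv <- h
  hv[!valid, ] <- 0
  L <- as.integer(round(window_s * fs))
  if (L < 1L) stop("window must span at least one sample (window_s * fs >= 1)")
  n <- nrow(h)
  left <- (L - 1L) %/% 2L
  right <- L - 1L - left
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  cs <- rbind(0, apply(hv, 2L, cumsum))
  cnt <- c(0, cumsum(as.numeric(valid)))
  m <- cnt[hi + 1L] - cnt[lo]
  f <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / pmax(m, 1)
  ok <- m > 0 & row_norms(f) > eps_f
  list(f = f, valid = ok)
}

#' Build the consistent reference frame
#'
#' Assembles the per-sample orthonormal triad: gravity unit vector
#' `u_grav = g/|g|`, forward unit vector `u_fwd` (the forward estimate with
#' its gravity-direction component removed, then normalised - identical to
#' `f/|f|` when gravity is constant, and guaranteeing exact orthogonality
#' when it is not), and `u_cross = u_fwd x u_grav`, making the triad
#' (forward, gravity, cross) right-handed.  Samples where either direction
#' is degenerate are marked invalid; no error is raised.
#'
#' @param g N x 3 gravity series.
#' @param f N x 3 forward series.
#' @param valid optional logical mask of samples with a usable forward
#'   direction (from [estimate_forward()]).
#' @param sign_continuity keep the forward axis temporally continuous: the
#'   smoothed horizontal acceleration is a zero-DC quantity whose sign
#'   alternates with the pace fluctuation, so consecutive valid samples
#'   whose forward vectors point into opposite half-spaces have the later
#'   one (and the cross axis with it) negated.  The decision uses inner
#'   products only, so it is exactly rotation-equivariant; it removes the
#'   spectral artefacts that axis flips would inject into analysis
#'   windows.  The overall sign per segment remains arbitrary (magnitude
#'   spectra are insensitive to it).
#' @return An object of class `reference_frame`: list of N x 3 matrices
#'   `fwd`, `grav`, `cross` (rows `NA` where invalid) and logical `valid`.
#' @export
build_frame <- function(g, f, valid = NULL, sign_continuity = TRUE) {
  g <- as.matrix(g); f <- as.matrix(f)
  stopifnot(nrow(g) == nrow(f), ncol(g) == 3L, ncol(f) == 3L)
  n <- nrow(g)
  if (is.null(valid)) valid <- rep(TRUE, n)
  gn <- row_norms(g)
  okg <- is.finite(gn) & gn > 0
  ug <- g / pmax(gn, .Machine$double.xmin)
  f0 <- f
  f0[!is.finite(f0)] <- 0
  fperp <- f0 - rowSums(f0 * ug) * ug
  fn <- row_norms(fperp)
  ok <- valid & okg & is.finite(fn) & fn > 0
  uf <- fperp / pmax(fn, .Machine$double.xmin)
  if (sign_continuity && sum(ok) > 1L) {
    v <- which(ok)
    d <- rowSums(uf[v[-1L], , drop = FALSE] * uf[v[-length(v)], , drop = FALSE])
    flip <- cumprod(ifelse(d < 0, -1, 1))
    uf[v[-1L], ] <- uf[v[-1L], , drop = FALSE] * flip
  }
  uc <- cross3(uf, ug)
  ug[!ok, ] <- NA_real_
  uf[!ok, ] <- NA_real_
  uc[!ok, ] <- NA_real_
  structure(list(fwd = uf, grav = ug, cross = uc, valid = ok),
            class = "reference_frame")
}

#' Transform acceleration into the consistent reference frame
#'
#' At each valid sample the transformation matrix has the frame unit
#' vectors (expressed in sensor coordinates) as its rows, ordered forward,
#' gravity, cross, so the new coordinates are the projections
#' `(a . u_fwd, a . u_grav, a . u_cross)`.  The matrix is orthonormal, so
#' the transform preserves norms and is inverted by its transpose.
#'
#' @param rec a [triaxial_recording()] or N x 3 matrix.
#' @param frame a `reference_frame` from [build_frame()].
#' @return A list with `x` (N x 3 transformed series, `NA` at invalid
#'   samples), logical `valid`, and per-sample `provenance`
#'   (`"frame"` where transformed, `NA` elsewhere).
#' @export
transform_to_frame <- function(rec, frame) {
  a <- as_samples(rec)
  stopifnot(inherits(frame, "reference_frame"), nrow(a) == nrow(frame$fwd))
  v <- cbind(rowSums(a * frame$fwd),
             rowSums(a * frame$grav),
             rowSums(a * frame$cross))
  v[!frame$valid, ] <- NA_real_
  colnames(v) <- c("fwd", "grav", "cross")
  list(x = v, valid = frame$valid,
       provenance = ifelse(frame$valid, "frame", NA_character_))
}

#' Subtract the gravity-direction component (posture treatment)
#'
#' Postures carry no forward motion, so no consistent frame exists; the
#' orientation nuisance is instead reduced by removing the component along
#' the estimated gravity direction.  The three residual coordinates are
#' kept in sensor axes; the residual norm is rotation-invariant.
#'
#' @inheritParams horizontal_component
#' @return A list with `x` (N x 3 residual), logical `valid`, per-sample
#'   `provenance` (`"gravity_subtracted"`), and `eps_g`.
#' @export
subtract_gravity <- function(rec, g, eps_g = NULL) {
  hc <- horizontal_component(rec, g, eps_g)
  list(x = hc$h, valid = hc$valid,
       provenance = ifelse(hc$valid, "gravity_subtracted", NA_character_),
       eps_g = hc$eps_g)
}

#' Preprocess one single-activity segment
#'
#' The full preprocessing branch of the pipeline.  Movements: estimate
#' gravity, take the horizontal component, estimate the forward direction,
#' build the frame and transform; samples with no usable forward direction
#' fall back to gravity subtraction instead of being dropped, so window
#' grids stay aligned across experimental setups.  Postures: estimate
#' gravity and subtract its component.  Degeneracy thresholds are relative
#' to the segment: `eps_g = eps_g_rel * median(|g|)` and
#' `eps_f = max(1e-6, eps_f_rel * median(|a| - |g|))`.
#'
#' @param x a [triaxial_recording()] or N x 3 matrix holding one
#'   single-activity segment.
#' @param fs sampling rate in Hz (taken from the recording if given one).
#' @param mode `"movement"` or `"posture"`.
#' @param window_s sliding-mean length in seconds for both the gravity and
#'   forward filters (default 5).
#' @param eps_g_rel,eps_f_rel relative degeneracy thresholds.
#' @param g optional precomputed N x 3 gravity series for this segment
#'   (used when gravity is estimated over a whole recording instead of per
#'   segment).
#' @return A list with `x` (N x 3 preprocessed series, always finite),
#'   per-sample `provenance` factor with levels `frame`,
#'   `gravity_subtracted`, `unprocessed`, logical `valid_frame`, and the
#'   thresholds `eps_g`, `eps_f`.
#' @export
preprocess_segment <- function(x, fs = NULL, mode = c("movement", "posture"),
                               window_s = 5, eps_g_rel = 0.1,
                               eps_f_rel = 0.05, g = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "triaxial_recording")) fs <- x$fs
  if (is.null(fs)) stop("`fs` is required when `x` is a bare matrix")
  a <- as_samples(x)
  if (nrow(a) < 1L) stop("empty segment")
  if (is.null(g)) g <- sliding_mean(a, fs, window_s)
  gn <- row_norms(g)
  an <- row_norms(a)
  eps_g <- eps_g_rel * median(gn)
  eps_f <- max(1e-6, eps_f_rel * median(an - gn))
  hc <- horizontal_component(a, g, eps_g)
  prov <- rep("unprocessed", nrow(a))
  if (mode == "posture") {
    out <- hc$h
    prov[hc$valid] <- "gravity_subtracted"
    valid_frame <- rep(FALSE, nrow(a))
  } else {
    fw <- estimate_forward(hc$h, fs, window_s, eps_f, hc$valid)
    fr <- build_frame(g, fw$f, fw$valid)
    tr <- transform_to_frame(a, fr)
    out <- tr$x
    prov[fr$valid] <- "frame"
    fb <- !fr$valid & hc$valid            # forward degenerate: fall back
    out[fb, ] <- hc$h[fb, ]
    prov[fb] <- "gravity_subtracted"
    valid_frame <- fr$valid
  }
  bad <- !stats::complete.cases(out)      # unusable gravity estimate
  out[bad, ] <- a[bad, , drop = FALSE]
  prov[bad] <- "unprocessed"
  list(x = unname(out),
       provenance = factor(prov, levels = c("frame", "gravity_subtracted",
                                            "unprocessed")),
       valid_frame = valid_frame, eps_g = eps_g, eps_f = eps_f)
}

#' Preprocess a labelled recording segment by segment
#'
#' Splits the recording into maximal single-activity segments and routes
#' each through the branch selected by `mode`: `"per_type"` uses the frame
#' transform for movements and gravity subtraction for postures (the
#' complete solution), `"frame_all"` applies the frame transform to every
#' segment, `"gravity_all"` subtracts gravity everywhere, `"raw"` leaves
#' the signal untouched (baseline).
#'
#' @param rec a [triaxial_recording()].
#' @param type_map named character vector mapping labels to
#'   `"movement"`/`"posture"`.
#' @param mode preprocessing policy, see above.
#' @param window_s sliding-mean length in seconds.
#' @param gravity_source `"segment"` estimates gravity within each segment;
#'   `"recording"` estimates it once over the whole recording (so posture
#'   segments inherit a gravity direction influenced by the surrounding
#'   movements).
#' @param eps_g_rel,eps_f_rel relative degeneracy thresholds, passed on.
#' @return A list with one element per segment: `x` (preprocessed series),
#'   `subject`, `label`, `type`, `start`, `end`, `provenance`.
#' @export
preprocess_recording <- function(rec, type_map,
                                 mode = c("per_type", "frame_all",
                                          "gravity_all", "raw"),
                                 window_s = 5,
                                 gravity_source = c("segment", "recording"),
                                 eps_g_rel = 0.1, eps_f_rel = 0.05) {
  mode <- match.arg(mode)
  gravity_source <- match.arg(gravity_source)
  segs <- segment_activities(rec, type_map)
  g_full <- if (gravity_source == "recording")
    sliding_mean(rec$samples, rec$fs, window_s) else NULL
  lapply(seq_len(nrow(segs)), function(i) {
    idx <- segs$start[i]:segs$end[i]
    a <- rec$samples[idx, , drop = FALSE]
    if (mode == "raw") {
      x <- a
      prov <- factor(rep("unprocessed", length(idx)),
                     levels = c("frame", "gravity_subtracted", "unprocessed"))
    } else {
      seg_mode <- switch(mode,
                         per_type = if (segs$type[i] == "movement")
                           "movement" else "posture",
                         frame_all = "movement",
                         gravity_all = "posture")
      p <- preprocess_segment(a, rec$fs, seg_mode, window_s,
                              eps_g_rel, eps_f_rel,
                              g = if (is.null(g_full)) NULL else
                                g_full[idx, , drop = FALSE])
      x <- p$x
      prov <- p$provenance
    }
    list(x = x, subject = rec$subject_id, label = segs$label[i],
         type = segs$type[i], start = segs$start[i], end = segs$end[i],
         provenance = prov)
  })
}
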