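#' Construct a tri-axial accelerometer recording
#'
#' The basic container of the package: an N x 3 matrix of acceleration
#' samples (sensor axes x, y, z) with a per-sample activity label, a
#' sampling rate and free-form metadata.  Units (m/s^2 or g) are recorded in
#' `meta$unit` and must be uniform within a recording; every operation in
#' the package is linear or direction-based, so no unit conversion is
#' forced.
#'
#' @param samples numeric N x 3 matrix, acceleration in sensor coordinates.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id opaque subject identifier (coerced to character).
#' @param labels per-sample activity labels, length N (default all `NA`).
#' @param meta named list of annotations (device, location, unit, ...).
#' @return An object of class `triaxial_recording`.
#' @examples
#' rec <- triaxial_recording(cbind(0, 9.81, 0)[rep(1, 10), ], fs = 20,
#'                           subject_id = "s1", labels = rep("stand", 10))
#' rec
#' @export
triaxial_recording <- function(samples, fs, subject_id, labels = NULL,
                               meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) != 3L)
    stop("`samples` must have exactly 3 acceleration channels")
  n <- nrow(samples)
  if (n < 1L) stop("a recording must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("all acceleration values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` must have exactly one entry per sample")
  dimnames(samples) <- list(NULL, c("x", "y", "z"))
  structure(list(subject_id = as.character(subject_id), fs = as.numeric(fs),
                 samples = samples, labels = labels, meta = meta),
            class = "triaxial_recording")
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> subject %s: %d samples at %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  labs <- unique(x$labels)
  cat("  labels:", paste(head(labs, 8), collapse = ", "),
      if (length(labs) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read recordings in the WISDM raw line format
#'
#' Parses `user,activity,timestamp,x,y,z;` records (trailing semicolons and
#' several records per physical line are tolerated).  Malformed records are
#' counted, skipped and reported with a warning.  Rows are grouped by
#' subject; within a subject, a timestamp gap larger than `gap_factor`
#' nominal sample periods starts a new recording, so sliding-mean filters
#' never bridge a discontinuity in the data collection.  The timestamp unit
#' is not assumed: the nominal period in timestamp units is estimated as the
#' median positive timestamp increment.
#'
#' @param path path to a WISDM-style raw text file.
#' @param fs nominal sampling rate in Hz (the classic WISDM phones sampled
#'   at 20 Hz).
#' @param gap_factor session split threshold, in nominal sample periods.
#' @return A list of [triaxial_recording()] objects, one per
#'   (subject, contiguous session), with attribute `skipped_lines` giving
#'   the number of malformed records.
#' @export
read_wisdm <- function(path, fs = 20, gap_factor = 10) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- unlist(strsplit(lines, ";", fixed = TRUE), use.names = FALSE)
  recs <- trimws(recs)
  recs <- recs[nzchar(recs)]
  parts <- strsplit(recs, ",", fixed = TRUE)
  n6 <- lengths(parts) == 6L
  parts6 <- parts[n6]
  num <- function(i) suppressWarnings(as.numeric(vapply(parts6, `[`, "", i)))
  ts <- num(3); ax <- num(4); ay <- num(5); az <- num(6)
  ok6 <- is.finite(ts) & is.finite(ax) & is.finite(ay) & is.finite(az)
  skipped <- sum(!n6) + sum(!ok6)
  if (skipped > 0)
    warning(sprintf("skipped %d malformed record(s) in %s", skipped, path))
  if (!any(ok6)) stop("no parseable records in ", path)
  df <- data.frame(
    subject = vapply(parts6, `[`, "", 1)[ok6],
    label   = trimws(vapply(parts6, `[`, "", 2)[ok6]),
    ts = ts[ok6], x = ax[ok6], y = ay[ok6], z = az[ok6],
    stringsAsFactors = FALSE)

  out <- list()
  for (s in unique(df$subject)) {
    d <- df[df$subject == s, , drop = FALSE]
    dts <- diff(d$ts)
    pos <- dts[dts > 0]
    if (length(pos) > 0) {
      period <- median(pos)              # nominal sample period, timestamp units
      new_session <- c(FALSE, dts > gap_factor * period)
    } else {
      new_session <- rep(FALSE, nrow(d))
    }
    sess <- cumsum(new_session)
    for (k in unique(sess)) {
      dd <- d[sess == k, , drop = FALSE]
      out[[length(out) + 1L]] <- triaxial_recording(
        as.matrix(dd[, c("x", "y", "z")]), fs = fs, subject_id = s,
        labels = dd$label,
        meta = list(source = path, session = k + 1L, unit = "m/s^2"))
    }
  }
  attr(out, "skipped_lines") <- skipped
  out
}

#' Read recordings from a generic delimited file
#'
#' Covers dataset layouts such as MotionSense, USC-HAD, PAMAP2 or HARTH via
#' a column mapping.  Rows are grouped by subject identifier (file order is
#' preserved inside each subject); one recording per subject is returned.
#'
#' @param path path to a delimited text file with a header.
#' @param colmap named character vector mapping the roles `subject`,
#'   `label`, `x`, `y`, `z` to column names in the file.
#' @param fs sampling rate in Hz to assign to the recordings.
#' @return A list of [triaxial_recording()] objects.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("s,act,ax,ay,az", "1,walk,0.1,9.8,0.2", "1,walk,0.2,9.7,0.1"), f)
#' recs <- read_generic_csv(f, c(subject = "s", label = "act",
#'                               x = "ax", y = "ay", z = "az"), fs = 50)
#' @export
read_generic_csv <- function(path,
                             colmap = c(subject = "subject", label = "label",
                                        x = "x", y = "y", z = "z"),
                             fs) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  need <- c("subject", "label", "x", "y", "z")
  if (!all(need %in% names(colmap)))
    stop("`colmap` must name the columns: ", paste(need, collapse = ", "))
  dt <- data.table::fread(path, showProgress = FALSE)
  miss <- setdiff(unname(colmap[need]), names(dt))
  if (length(miss) > 0)
    stop("mapped column(s) absent from file: ", paste(miss, collapse = ", "))
  df <- data.frame(subject = as.character(dt[[colmap[["subject"]]]]),
                   label = as.character(dt[[colmap[["label"]]]]),
                   x = as.numeric(dt[[colmap[["x"]]]]),
                   y = as.numeric(dt[[colmap[["y"]]]]),
                   z = as.numeric(dt[[colmap[["z"]]]]),
                   stringsAsFactors = FALSE)
  lapply(unique(df$subject), function(s) {
    d <- df[df$subject == s, , drop = FALSE]
    triaxial_recording(as.matrix(d[, c("x", "y", "z")]), fs = fs,
                       subject_id = s, labels = d$label,
                       meta = list(source = path))
  })
}

#' Write recordings to a delimited file
#'
#' Writes one row per sample with columns `subject,label,x,y,z`.  Floats are
#' written at full precision (shortest representation that round-trips a
#' double), so [read_generic_csv()] recovers the samples bitwise and the
#' labels exactly.
#'
#' @param recs a [triaxial_recording()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recs, path) {
  if (inherits(recs, "triaxial_recording")) recs <- list(recs)
  tabs <- lapply(recs, function(r) {
    ## %.17g guarantees the shortest exact decimal for a double, so the
    ## reader recovers the samples bitwise
    data.table::data.table(subject = r$subject_id, label = r$labels,
                           x = sprintf("%.17g", r$samples[, 1]),
                           y = sprintf("%.17g", r$samples[, 2]),
                           z = sprintf("%.17g", r$samples[, 3]))
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Split a recording into maximal single-activity segments
#'
#' Run-length encodes the per-sample labels into maximal runs of constant
#' label and attaches the activity type (movement or posture) needed to
#' route each segment to the appropriate preprocessing branch.  Segment
#' indices are 1-based and inclusive; concatenating the segments
#' reconstructs the recording.
#'
#' @param rec a [triaxial_recording()].
#' @param type_map named character vector mapping every activity label to
#'   `"movement"` or `"posture"`.
#' @return A data frame with one row per segment: `subject`, `label`,
#'   `type`, `start`, `end`, `n`.
#' @export
segment_activities <- function(rec, type_map) {
  stopifnot(inherits(rec, "triaxial_recording"))
  labs <- rec$labels
  unmapped <- setdiff(unique(labs), names(type_map))
  if (length(unmapped) > 0)
    stop("labels missing from `type_map`: ", paste(unmapped, collapse = ", "))
  bad <- setdiff(unique(unname(type_map)), c("movement", "posture"))
  if (length(bad) > 0)
    stop("`type_map` values must be 'movement' or 'posture'")
  r <- rle(labs)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(subject = rec$subject_id, label = r$values,
             type = unname(type_map[r$values]),
             start = start, end = end, n = r$lengths,
             stringsAsFactors = FALSE)
}
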