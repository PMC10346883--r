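#' Default synthetic activity presets
#'
#' Five activities — three repetitive movements and two postures — whose
#' body-frame signal structure mirrors what the frame algorithm exploits:
#' movements carry a non-zero-mean forward component, zero-mean vertical
#' impacts (with a second harmonic) and a small lateral sway at a
#' class-specific gait frequency; postures are gravity (optionally tilted)
#' plus a small sway oscillation.  Walking and stair climbing share the
#' same fundamental frequency and similar total energy, so telling them
#' apart requires the forward/vertical amplitude ratio — exactly the
#' directional cue a mounting rotation destroys and the frame transform
#' restores.  Amplitudes are in m/s^2, frequencies in Hz, tilt in degrees.
#'
#' @return A data frame with columns `activity`, `type`, `f0`, `amp_fwd`,
#'   `amp_vert`, `amp_lat`, `tilt_deg`.
#' @export
default_activity_presets <- function() {
  data.frame(
    activity = c("walk", "jog", "stairs", "sit", "stand"),
    type = c("movement", "movement", "movement", "posture", "posture"),
    f0 = c(1.8, 2.6, 1.8, 0.4, 0.8),
    amp_fwd = c(1.2, 1.15, 1.05, 0, 0),
    amp_vert = c(2.2, 3.4, 2.45, 0, 0),
    amp_lat = c(0.15, 0.2, 0.2, 0.25, 0.35),
    tilt_deg = c(0, 0, 0, 30, 0),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions of the synthetic benchmark: per-subject
#' tri-axial recordings with known gravity, forward direction and mounting
#' rotation.  Defaults give 20 subjects at 50 Hz performing five
#' activities (three movements, two postures) for 120 s each.
#'
#' @param n_subjects number of subjects.
#' @param fs sampling rate in Hz.
#' @param duration_s duration of each activity segment in seconds.
#' @param activities preset table, see [default_activity_presets()].
#' @param noise_sd white sensor noise standard deviation, m/s^2.
#' @param asym forward-acceleration asymmetry: the constant mean offset of
#'   the forward component as a fraction of its oscillation amplitude.
#'   A non-zero mean is what makes the forward axis identifiable.
#' @param amp_jitter per-subject multiplicative amplitude jitter
#'   (uniform in `1 +- amp_jitter`), shared across that subject's
#'   activities.
#' @param f0_jitter per-subject cadence variability in Hz, quantised to
#'   the 0.2 Hz grid commensurate with the 5 s analysis windows (a shift
#'   is drawn uniformly from the grid points in `+- f0_jitter`); applied
#'   to movements only.
#' @param speed_mod_amp,speed_mod_f slow forward speed modulation
#'   (m/s^2, Hz): people do not walk at perfectly constant pace, and this
#'   sub-window-band component is what makes the forward axis observable
#'   to the sliding-mean estimator.
#' @param tilt_jitter per-subject posture tilt jitter in degrees.
#' @param harmonic relative amplitude of the second harmonic on the
#'   vertical component.
#' @param rotation `"none"` (sensor aligned with the body) or `"random"`
#'   (one fixed, uniformly random mounting rotation per subject).
#' @param g0 gravity magnitude, m/s^2.
#' @param seed integer master seed; all draws derive from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20, fs = 50, duration_s = 120,
                         activities = default_activity_presets(),
                         noise_sd = 0.3, asym = 0.2, amp_jitter = 0.1,
                         f0_jitter = 0.2, tilt_jitter = 5, harmonic = 0.3,
                         speed_mod_amp = 0.6, speed_mod_f = 0.22,
                         rotation = c("none", "random"), g0 = 9.81,
                         seed = 1) {
  rotation <- match.arg(rotation)
  stopifnot(n_subjects >= 1, fs > 0, duration_s > 0, noise_sd >= 0,
            asym >= 0, amp_jitter >= 0, f0_jitter >= 0, g0 > 0,
            all(c("activity", "type", "f0", "amp_fwd", "amp_vert",
                  "amp_lat", "tilt_deg") %in% names(activities)))
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 duration_s = duration_s, activities = activities,
                 noise_sd = noise_sd, asym = asym, amp_jitter = amp_jitter,
                 f0_jitter = f0_jitter, tilt_jitter = tilt_jitter,
                 harmonic = harmonic, speed_mod_amp = speed_mod_amp,
                 speed_mod_f = speed_mod_f, rotation = rotation, g0 = g0,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## Uniformly random 3-D rotation matrix (QR of a Gaussian matrix with a
## sign fix; det forced to +1).
random_rotation_matrix <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Per-subject generation profile
#'
#' Draws the subject-level nuisances once (amplitude scale, mounting
#' rotation, gait-frequency and tilt jitters), deterministically from the
#' config seed and the subject id.
#'
#' @param cfg a [synth_config()].
#' @param subject subject identifier.
#' @return A list with `scale`, `rotation` (3 x 3), `f0_shift`,
#'   `tilt_shift`.
#' @export
subject_profile <- function(cfg, subject) {
  set.seed(derive_seed(cfg$seed, "profile", subject))
  ## cadence shifts live on the 0.2 Hz grid so gait harmonics stay
  ## commensurate with the 5 s windows
  grid <- seq(-0.2 * floor(cfg$f0_jitter / 0.2 + 1e-9),
              0.2 * floor(cfg$f0_jitter / 0.2 + 1e-9), by = 0.2)
  list(scale = runif(1, 1 - cfg$amp_jitter, 1 + cfg$amp_jitter),
       rotation = if (cfg$rotation == "random") random_rotation_matrix()
                  else diag(3),
       f0_shift = if (length(grid) > 1) sample(grid, 1) else 0,
       tilt_shift = runif(1, -cfg$tilt_jitter, cfg$tilt_jitter))
}

synth_fragment <- function(cfg, subject, activity, profile) {
  p <- cfg$activities[cfg$activities$activity == activity, ]
  if (nrow(p) != 1L) stop("unknown activity: ", activity)
  set.seed(derive_seed(cfg$seed, "fragment", subject, activity))
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  s <- profile$scale
  f0 <- p$f0 + profile$f0_shift * (p$type == "movement")
  ph <- runif(3, 0, 2 * pi)

  if (p$type == "movement") {
    grav_dir <- c(0, 1, 0)
    phm <- runif(1, 0, 2 * pi)
    fwd <- s * p$amp_fwd * (sin(2 * pi * f0 * t + ph[1]) + cfg$asym) +
      s * cfg$speed_mod_amp * sin(2 * pi * cfg$speed_mod_f * t + phm)
    vert <- s * p$amp_vert * (sin(2 * pi * f0 * t + ph[2]) +
                              cfg$harmonic * sin(4 * pi * f0 * t + 2 * ph[2]))
    lat <- s * p$amp_lat * sin(2 * pi * f0 * t + ph[3])
    body <- cbind(fwd, cfg$g0 * grav_dir[2] + vert, lat)
    truth_fwd <- c(1, 0, 0)
  } else {
    tilt <- (p$tilt_deg + profile$tilt_shift) * pi / 180
    grav_dir <- c(sin(tilt), cos(tilt), 0)
    ## sway along a random horizontal direction (orthogonal to gravity)
    az <- runif(1, 0, 2 * pi)
    e1 <- c(cos(tilt), -sin(tilt), 0)        # in-plane, orthogonal to gravity
    e2 <- c(0, 0, 1)
    sway_dir <- cos(az) * e1 + sin(az) * e2
    sway <- s * p$amp_lat * sin(2 * pi * f0 * t + ph[1])
    body <- cfg$g0 * matrix(grav_dir, n, 3, byrow = TRUE) +
      outer(sway, sway_dir)
    truth_fwd <- NULL
  }
  if (cfg$noise_sd > 0)
    body <- body + matrix(rnorm(3 * n, sd = cfg$noise_sd), n, 3)
  R <- profile$rotation
  list(x = body %*% t(R),
       truth = list(gravity = as.numeric(R %*% (cfg$g0 * grav_dir)),
                    forward = if (is.null(truth_fwd)) NULL
                              else as.numeric(R %*% truth_fwd),
                    rotation = R, f0 = f0, scale = s, type = p$type))
}

#' Generate one movement fragment with ground truth
#'
#' Body-frame construction: gravity reaction along +y, a forward component
#' with strictly positive mean (`amp_fwd * (sin + asym)`), zero-mean
#' vertical impacts with a second harmonic, zero-mean lateral sway, white
#' noise; the whole signal is then rotated by the subject's mounting
#' rotation.  Deterministic given the config seed, subject and activity.
#'
#' @param cfg a [synth_config()].
#' @param subject subject identifier.
#' @param activity a movement-typed activity from `cfg$activities`.
#' @param profile optional precomputed [subject_profile()].
#' @return A list with `x` (N x 3 sensor-frame samples) and `truth`
#'   (`gravity`, `forward`, `rotation`, `f0`, `scale`).
#' @export
generate_movement <- function(cfg, subject, activity, profile = NULL) {
  p <- cfg$activities[cfg$activities$activity == activity, ]
  if (nrow(p) != 1L || p$type != "movement")
    stop("`activity` must name a movement-typed preset")
  if (is.null(profile)) profile <- subject_profile(cfg, subject)
  synth_fragment(cfg, subject, activity, profile)
}

#' Generate one posture fragment with ground truth
#'
#' Gravity (tilted per activity), a small sway oscillation along a random
#' horizontal direction, white noise, rotated by the mounting rotation.
#' No forward motion exists by construction, so the frame module flags
#' these samples forward-invalid.
#'
#' @inheritParams generate_movement
#' @param activity a posture-typed activity from `cfg$activities`.
#' @return As [generate_movement()], with `truth$forward = NULL`.
#' @export
generate_posture <- function(cfg, subject, activity, profile = NULL) {
  p <- cfg$activities[cfg$activities$activity == activity, ]
  if (nrow(p) != 1L || p$type != "posture")
    stop("`activity` must name a posture-typed preset")
  if (is.null(profile)) profile <- subject_profile(cfg, subject)
  synth_fragment(cfg, subject, activity, profile)
}

#' Generate the full synthetic benchmark dataset
#'
#' One recording per subject: the configured activities in a
#' subject-specific random order, concatenated, with per-sample labels.
#' The manifest records every ground truth (mounting rotation, gravity and
#' forward vectors in sensor coordinates, realised frequencies and
#' scales).  Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return A list with `recordings` (list of [triaxial_recording()]),
#'   `manifest` (per subject: `rotation`, `scale`, per-activity truths),
#'   `type_map` (label to movement/posture), and `cfg`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  type_map <- setNames(cfg$activities$type, cfg$activities$activity)
  recordings <- vector("list", cfg$n_subjects)
  manifest <- vector("list", cfg$n_subjects)
  names(manifest) <- subjects
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    profile <- subject_profile(cfg, s)
    set.seed(derive_seed(cfg$seed, "order", s))
    acts <- sample(cfg$activities$activity)
    frs <- lapply(acts, function(a) synth_fragment(cfg, s, a, profile))
    x <- do.call(rbind, lapply(frs, `[[`, "x"))
    labels <- rep(acts, each = as.integer(round(cfg$duration_s * cfg$fs)))
    recordings[[i]] <- triaxial_recording(
      x, fs = cfg$fs, subject_id = s, labels = labels,
      meta = list(unit = "m/s^2", synthetic = TRUE))
    manifest[[s]] <- list(rotation = profile$rotation,
                          scale = profile$scale, order = acts,
                          truth = setNames(lapply(frs, `[[`, "truth"), acts))
  }
  list(recordings = recordings, manifest = manifest, type_map = type_map,
       cfg = cfg)
}
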