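# Shared fixtures: tiny recordings, WISDM toy files and angle helpers.

# Signed angle (degrees) between the rows of u and a fixed vector v.
angle_to <- function(u, v) {
  v <- v / sqrt(sum(v^2))
  cv <- rowSums(u * matrix(v, nrow(u), 3, byrow = TRUE)) / sqrt(rowSums(u^2))
  acos(pmin(1, pmax(-1, cv))) * 180 / pi
}

# Axis-wise angle: sign of u is ignored.
axis_angle_to <- function(u, v) {
  a <- angle_to(u, v)
  pmin(a, 180 - a)
}

# A uniformly random rotation matrix (QR-based, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# Static recording: pure gravity reaction plus optional noise.
static_recording <- function(n = 200, fs = 20, g = c(0, 9.81, 0),
                             noise_sd = 0, subject = "s1", label = "stand") {
  x <- matrix(g, n, 3, byrow = TRUE)
  if (noise_sd > 0) x <- x + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  triaxial_recording(x, fs = fs, subject_id = subject,
                     labels = rep(label, n))
}

# Write a toy WISDM-format file; `lines` is a character vector of records.
write_wisdm_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# Sample WISDM records for one subject at 20 Hz (timestamps in ms).
wisdm_lines <- function(subject = "1", activity = "Walking", n = 3,
                        t0 = 0, dt = 50) {
  sprintf("%s,%s,%d,%.2f,%.2f,%.2f;", subject, activity,
          t0 + (seq_len(n) - 1) * dt,
          runif(n, -1, 1), 9.8 + runif(n, -0.5, 0.5), runif(n, -1, 1))
}

# Noise-free synthetic config shared by recoverability tests.
noise_free_config <- function(seed = 7, rotation = "random") {
  synth_config(noise_sd = 0, rotation = rotation, seed = seed)
}
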