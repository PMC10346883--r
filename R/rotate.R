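#' Axis rotation matrix
#'
#' The elementary rotation matrices about the sensor x, y and z axes used
#' to simulate sensor mis-orientation:
#' \deqn{R_x = \begin{pmatrix}1&0&0\\0&c&-s\\0&s&c\end{pmatrix},\;
#'       R_y = \begin{pmatrix}c&0&s\\0&1&0\\-s&0&c\end{pmatrix},\;
#'       R_z = \begin{pmatrix}c&-s&0\\s&c&0\\0&0&1\end{pmatrix}}
#' with \eqn{c = \cos\theta}, \eqn{s = \sin\theta}.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param theta_deg rotation angle in degrees.
#' @return A 3 x 3 orthonormal matrix with determinant 1.
#' @examples
#' rotation_matrix("z", 90)
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), theta_deg) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1L,
            is.finite(theta_deg))
  th <- theta_deg * pi / 180
  cth <- cos(th); sth <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0,   0, cth, sth,   0, -sth, cth), 3, 3),
         y = matrix(c(cth, 0, -sth,   0, 1, 0,   sth, 0, cth), 3, 3),
         z = matrix(c(cth, sth, 0,   -sth, cth, 0,   0, 0, 1), 3, 3))
}

#' Apply a rotation perturbation to a recording
#'
#' Replaces every sample `a` by `R a`, simulating the same sensor worn in a
#' different orientation.  Labels, sampling rate and metadata are
#' unchanged; per-sample norms are preserved.
#'
#' @param rec a [triaxial_recording()].
#' @param spec one row of a rotation specification (list or data frame row
#'   with `subject`, `axis`, `theta_deg`), typically from
#'   [random_subject_rotations()].
#' @return The rotated [triaxial_recording()]; the applied rotation is
#'   recorded in `meta$rotation`.
#' @export
apply_rotation <- function(rec, spec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  spec <- as.list(spec)
  if (!identical(as.character(spec$subject), rec$subject_id))
    stop("rotation spec is for subject ", spec$subject,
         " but recording belongs to subject ", rec$subject_id)
  R <- rotation_matrix(spec$axis, spec$theta_deg)
  out <- rec
  out$samples <- rec$samples %*% t(R)
  colnames(out$samples) <- c("x", "y", "z")
  out$meta$rotation <- list(axis = spec$axis, theta_deg = spec$theta_deg)
  out
}

#' Draw one random-axis rotation per subject
#'
#' The mis-orientation protocol: for each subject one of the three sensor
#' axes is selected uniformly at random and a fixed rotation of
#' `theta_deg` (default 45 degrees) about it is assigned; the remaining
#' axes are kept fixed.  The draw is fully determined by `seed`.
#'
#' @param subjects character vector of subject identifiers (duplicates are
#'   collapsed; one spec per subject).
#' @param theta_deg rotation angle in degrees applied to every subject.
#' @param seed integer seed (required; reproducibility contract).
#' @return A data frame with columns `subject`, `axis`, `theta_deg` and
#'   attribute `seed`.
#' @export
random_subject_rotations <- function(subjects, theta_deg = 45, seed) {
  if (missing(seed)) stop("`seed` is required")
  subjects <- unique(as.character(subjects))
  if (length(subjects) == 0L) stop("`subjects` must be non-empty")
  set.seed(seed)
  out <- data.frame(subject = subjects,
                    axis = sample(c("x", "y", "z"), length(subjects),
                                  replace = TRUE),
                    theta_deg = theta_deg, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}
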