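`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise Euclidean norms of an N x k matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

## Row-wise cross product of two N x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Small deterministic seed derived from a base seed and string tags,
## kept inside the 32-bit integer range R's RNG accepts.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(tags) * seq_along(utf8ToInt(tags)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## Accept either a triaxial_recording or a bare N x 3 matrix.
as_samples <- function(x) {
  if (inherits(x, "triaxial_recording")) x$samples else {
    m <- as.matrix(x)
    if (ncol(m) != 3L) stop("expected a triaxial recording or an N x 3 matrix")
    m
  }
}
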