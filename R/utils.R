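## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  x / n
}

## Rows of `m` normalized to unit length; zero rows left untouched.
unitize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Row-wise cross product of two n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Rotation matrix taking unit vector `from` onto unit vector `to`
## (Rodrigues; stable at the antipodal case).
rotation_between <- function(from, to) {
  from <- unitize(from); to <- unitize(to)
  v <- cross3(from, to)
  c_ <- sum(from * to)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## 180 degrees: rotate about any axis orthogonal to `from`
    axis <- if (abs(from[1]) < 0.9) cross3(from, c(1, 0, 0)) else cross3(from, c(0, 1, 0))
    axis <- unitize(axis)
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

rotation_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

## Stratified k-fold assignment: returns integer fold id per observation.
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
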