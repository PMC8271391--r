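#' Quaternion algebra (Hamilton convention, scalar first)
#'
#' Quaternions are represented as numeric vectors `c(w, x, y, z)` or as
#' n-by-4 matrices (one quaternion per row) for whole time series. All
#' rotation quaternions encode body-to-global rotations in the Hamilton
#' convention: composing `q1 %q% q2` applies `q2` first, then `q1`.
#'
#' @param w,x,y,z real components (scalar part first)
#' @return a numeric vector of length 4 with class attribute preserved as a
#'   plain vector; helper functions accept both vectors and row matrices.
#' @examples
#' q <- quat(1, 0, 0, 0)
#' quat_rotate(q, c(1, 0, 0))
#' @export
quat <- function(w, x, y, z) c(w, x, y, z)

# Coerce vector input to a 1x4 matrix; returns list(q = matrix, vec = TRUE/FALSE)
.quat_mat <- function(q) {
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 4L)
    list(q = q, vec = FALSE)
  } else {
    stopifnot(length(q) == 4L)
    list(q = matrix(q, 1L, 4L), vec = TRUE)
  }
}

.quat_out <- function(m, vec) if (vec) drop(m) else m

#' Quaternion norm
#' @param q quaternion vector or n-by-4 matrix
#' @return numeric scalar or vector of norms
#' @export
quat_norm <- function(q) {
  qm <- .quat_mat(q)
  sqrt(rowSums(qm$q^2))
}

#' Normalize quaternion(s) to unit norm
#' @param q quaternion vector or n-by-4 matrix
#' @return unit quaternion(s), same shape as input
#' @export
quat_normalize <- function(q) {
  qm <- .quat_mat(q)
  n <- sqrt(rowSums(qm$q^2))
  if (any(n < 1e-12)) stop("cannot normalize a (near-)zero quaternion")
  .quat_out(qm$q / n, qm$vec)
}

#' Quaternion conjugate
#' @param q quaternion vector or n-by-4 matrix
#' @return conjugate quaternion(s)
#' @export
quat_conjugate <- function(q) {
  qm <- .quat_mat(q)
  .quat_out(qm$q * rep(c(1, -1, -1, -1), each = nrow(qm$q)), qm$vec)
}

#' Hamilton product of two quaternions (vectorized over rows)
#'
#' @param a,b quaternion vectors or n-by-4 matrices (recycled row-wise if one
#'   argument is a single quaternion)
#' @return product quaternion(s)
#' @export
quat_multiply <- function(a, b) {
  am <- .quat_mat(a); bm <- .quat_mat(b)
  na <- nrow(am$q); nb <- nrow(bm$q)
  if (na != nb) {
    if (na == 1L) am$q <- am$q[rep(1L, nb), , drop = FALSE]
    else if (nb == 1L) bm$q <- bm$q[rep(1L, na), , drop = FALSE]
    else stop("incompatible quaternion counts")
  }
  A <- am$q; B <- bm$q
  out <- cbind(
    A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
    A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
    A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
    A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  )
  .quat_out(out, am$vec && bm$vec)
}

#' @rdname quat_multiply
#' @export
`%q%` <- function(a, b) quat_multiply(a, b)

#' Rotate 3-vectors by quaternion(s)
#'
#' Applies the rotation encoded by `q` (body-to-global) to `v`.
#'
#' @param q unit quaternion vector or n-by-4 matrix
#' @param v 3-vector or n-by-3 matrix
#' @return rotated vector(s), same shape as `v`
#' @export
quat_rotate <- function(q, v) {
  qm <- .quat_mat(q)
  vm <- if (is.matrix(v)) v else matrix(v, 1L, 3L)
  n <- max(nrow(qm$q), nrow(vm))
  Q <- if (nrow(qm$q) == n) qm$q else qm$q[rep(1L, n), , drop = FALSE]
  V <- if (nrow(vm) == n) vm else vm[rep(1L, n), , drop = FALSE]
  w <- Q[, 1]; u <- Q[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  uv <- .cross3(u, V)
  uuv <- .cross3(u, uv)
  out <- V + 2 * w * uv + 2 * uuv
  if (is.matrix(v)) out else drop(out)
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rotation matrix from a unit quaternion
#' @param q unit quaternion (length-4 vector)
#' @return 3x3 rotation matrix mapping body coordinates to global coordinates
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4L)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix (Shepperd's method)
#' @param R 3x3 rotation matrix
#' @return unit quaternion with non-negative scalar part
#' @export
quat_from_matrix <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Unit quaternion for a rotation about an axis
#' @param axis 3-vector rotation axis (normalized internally)
#' @param angle rotation angle, radians
#' @return unit quaternion
#' @export
quat_from_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * a)
}

#' Canonicalize sign: q and -q encode the same rotation; pick w >= 0
#' @param q quaternion vector or n-by-4 matrix
#' @return sign-canonicalized quaternion(s)
#' @export
quat_canonical <- function(q) {
  qm <- .quat_mat(q)
  s <- ifelse(qm$q[, 1] < 0, -1, 1)
  .quat_out(qm$q * s, qm$vec)
}

#' Hemisphere correction for a quaternion time series
#'
#' Flips the sign of individual quaternions so consecutive rows have a
#' non-negative dot product, making the series continuous in R^4.
#'
#' @param Q n-by-4 matrix of unit quaternions
#' @return n-by-4 matrix with consecutive dot products >= 0
#' @export
quat_hemisphere <- function(Q) {
  stopifnot(is.matrix(Q), ncol(Q) == 4L)
  if (nrow(Q) < 2L) return(Q)
  d <- rowSums(Q[-1L, , drop = FALSE] * Q[-nrow(Q), , drop = FALSE])
  # cumulative sign flips: a negative dot flips everything downstream
  flips <- cumprod(ifelse(d < 0, -1, 1))
  Q[-1L, ] <- Q[-1L, , drop = FALSE] * flips
  Q
}

#' Rotation vector (axis * angle) to quaternion and back
#' @param rv 3-vector, radians
#' @return unit quaternion
#' @export
quat_from_rotvec <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(quat_normalize(c(1, rv / 2)))
  c(cos(th / 2), sin(th / 2) * rv / th)
}

#' @rdname quat_from_rotvec
#' @param q unit quaternion
#' @export
quat_to_rotvec <- function(q) {
  q <- quat_canonical(quat_normalize(q))
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(c(0, 0, 0))
  th <- 2 * atan2(s, q[1])
  th * v / s
}
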