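#' Cardan (Tait-Bryan) angle decomposition of joint rotations
#'
#' Joint rotations are decomposed into three sequential rotations about
#' moving axes. The default order `"zxy"` follows lower-limb joint
#' coordinate practice: flexion-extension about z, ab-adduction about the
#' floating x axis, internal-external rotation about the long (y) axis.
#' The order is a configuration constant, not hard-coded anatomy.
#'
#' @name cardan
NULL

.axis_index <- c(x = 1L, y = 2L, z = 3L)

.parse_order <- function(order) {
  ax <- .axis_index[strsplit(order, "")[[1]]]
  if (length(ax) != 3L || anyNA(ax) || length(unique(ax)) != 3L)
    stop("order must be a permutation of 'x', 'y', 'z', e.g. 'zxy'")
  unname(ax)
}

# +1 for cyclic (xyz, yzx, zxy), -1 for anticyclic orders
.order_sign <- function(ax) {
  if (all(ax == c(1, 2, 3)) || all(ax == c(2, 3, 1)) || all(ax == c(3, 1, 2))) 1 else -1
}

# rotation-matrix elements, vectorized over quaternion rows: returns list of
# closures indexing R[i, j] as an n-vector
.rot_elements <- function(Q) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  R <- array(0, dim = c(nrow(Q), 3L, 3L))
  R[, 1, 1] <- 1 - 2 * (y^2 + z^2); R[, 1, 2] <- 2 * (x * y - w * z); R[, 1, 3] <- 2 * (x * z + w * y)
  R[, 2, 1] <- 2 * (x * y + w * z); R[, 2, 2] <- 1 - 2 * (x^2 + z^2); R[, 2, 3] <- 2 * (y * z - w * x)
  R[, 3, 1] <- 2 * (x * z - w * y); R[, 3, 2] <- 2 * (y * z + w * x); R[, 3, 3] <- 1 - 2 * (x^2 + y^2)
  R
}

.unwrap <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Extract Cardan angles from a quaternion series
#'
#' Intrinsic Tait-Bryan decomposition of each rotation in the configured
#' axis order. Angles are unwrapped to be continuous across frames. Frames
#' whose middle angle lies within 1 degree of +/-90 degrees are flagged as
#' gimbal-proximal in the `"gimbal"` attribute; at exact gimbal lock the
#' degenerate-case formula (third angle set to zero) is used.
#'
#' @param q_rel n-by-4 matrix of unit quaternions (or a single quaternion)
#' @param order three-letter intrinsic axis order, default `"zxy"`
#' @return n-by-3 matrix of angles in degrees, columns named by axis, with
#'   a logical `"gimbal"` attribute of length n
#' @export
cardan_angles <- function(q_rel, order = "zxy") {
  qm <- .quat_mat(q_rel)
  Q <- qm$q / sqrt(rowSums(qm$q^2))
  ax <- .parse_order(order)
  eps <- .order_sign(ax)
  i <- ax[1]; j <- ax[2]; k <- ax[3]
  R <- .rot_elements(Q)
  sb <- pmin(1, pmax(-1, eps * R[, i, k]))
  b <- asin(sb)
  a <- atan2(-eps * R[, j, k], R[, k, k])
  cc <- atan2(-eps * R[, i, j], R[, i, i])
  gimbal <- abs(sb) >= sin(89 * pi / 180)
  locked <- abs(sb) >= 1 - 1e-12
  if (any(locked)) {
    a[locked] <- atan2(R[locked, k, j], R[locked, j, j])
    cc[locked] <- 0
  }
  out <- cbind(.unwrap(a), .unwrap(b), .unwrap(cc)) * 180 / pi
  colnames(out) <- strsplit(order, "")[[1]]
  attr(out, "gimbal") <- gimbal
  if (qm$vec) {
    out <- structure(drop(out), gimbal = gimbal[1])
  }
  out
}

#' Compose a quaternion from Cardan angles
#'
#' Inverse of [cardan_angles()]: builds the intrinsic rotation
#' `R_i(a) R_j(b) R_k(c)` in the configured order.
#'
#' @param angles n-by-3 matrix (or length-3 vector) of angles, degrees,
#'   in the order of the axis string
#' @param order three-letter intrinsic axis order, default `"zxy"`
#' @return n-by-4 matrix of unit quaternions (or a single quaternion)
#' @export
cardan_quaternion <- function(angles, order = "zxy") {
  vec <- !is.matrix(angles)
  A <- if (vec) matrix(angles, 1L, 3L) else as.matrix(angles)
  stopifnot(ncol(A) == 3L)
  ax <- .parse_order(order)
  rad <- A * pi / 180
  q <- matrix(rep(c(1, 0, 0, 0), each = nrow(A)), nrow(A), 4L)
  for (s in 1:3) {
    e <- c(0, 0, 0); e[ax[s]] <- 1
    half <- rad[, s] / 2
    qs <- cbind(cos(half), outer(sin(half), e))
    q <- quat_multiply(q, qs)
  }
  if (vec) drop(q) else q
}
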