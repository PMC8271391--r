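#' Virtual inertial sensor simulation
#'
#' Signals a real IMU would record are derived from a rigid-body pose
#' trajectory: the gyroscope from the quaternion derivative, the
#' accelerometer from the second derivative of the sensor origin expressed
#' as specific force (gravity included, so a static sensor reads +g).
#'
#' @name virtual-imu
NULL

# time derivative by central differences, second-order one-sided stencils at
# the ends; X is an n-by-k matrix sampled at dt
.diff1 <- function(X, dt) {
  n <- nrow(X)
  D <- matrix(0, n, ncol(X))
  D[2:(n - 1), ] <- (X[3:n, , drop = FALSE] - X[1:(n - 2), , drop = FALSE]) / (2 * dt)
  D[1, ] <- (-3 * X[1, ] + 4 * X[2, ] - X[3, ]) / (2 * dt)
  D[n, ] <- (3 * X[n, ] - 4 * X[n - 1, ] + X[n - 2, ]) / (2 * dt)
  D
}

# second time derivative, central; second-order one-sided at the ends
.diff2 <- function(X, dt) {
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 frames for endpoint second derivatives")
  D <- matrix(0, n, ncol(X))
  D[2:(n - 1), ] <- (X[3:n, , drop = FALSE] - 2 * X[2:(n - 1), , drop = FALSE] +
                       X[1:(n - 2), , drop = FALSE]) / dt^2
  D[1, ] <- (2 * X[1, ] - 5 * X[2, ] + 4 * X[3, ] - X[4, ]) / dt^2
  D[n, ] <- (2 * X[n, ] - 5 * X[n - 1, ] + 4 * X[n - 2, ] - X[n - 3, ]) / dt^2
  D
}

#' Body-frame angular rate from a pose sequence
#'
#' Differentiates the orientation quaternions (central differences,
#' one-sided second-order stencils at the endpoints) and maps the
#' derivative to angular velocity via `omega = 2 * vec(q* x dq/dt)`,
#' giving the rate in the body (sensor) frame — what a gyroscope measures.
#'
#' @param pose a [pose_sequence()]
#' @return n-by-3 matrix of angular velocity, rad/s, body frame
#' @export
angular_rate <- function(pose) {
  stopifnot(inherits(pose, "pose_sequence"))
  Q <- pose$orientations
  dQ <- .diff1(Q, 1 / pose$rate)
  w <- quat_multiply(quat_conjugate(Q), dQ)
  2 * w[, 2:4, drop = FALSE]
}

#' Pose of a sensor rigidly attached to a segment
#'
#' Composes the segment pose with a sensor placement: the sensor
#' orientation is `q_seg x offset_q` and its origin is the segment origin
#' plus the placement translation rotated into the global frame.
#'
#' @param segment a [pose_sequence()] for the host segment
#' @param placement a [sensor_placement()]
#' @return a [pose_sequence()] for the sensor
#' @export
sensor_pose <- function(segment, placement) {
  stopifnot(inherits(segment, "pose_sequence"),
            inherits(placement, "sensor_placement"))
  q_s <- quat_multiply(segment$orientations, placement$offset_q)
  p_s <- segment$origins + quat_rotate(segment$orientations, placement$offset_t)
  pose_sequence(q_s, p_s, segment$rate)
}

#' Specific force measured by an accelerometer on a moving pose
#'
#' The sensor origin is differentiated twice (central differences) and the
#' specific force `f = R(q)^T (p'' - g)` is expressed in the sensor frame.
#' With the default gravity vector a stationary, level sensor reads
#' `(0, 0, 9.81)` and a free-falling one reads zero.
#'
#' @param sensor a [pose_sequence()] for the sensor
#' @param g_vec gravity vector in the global frame, m/s^2
#' @return n-by-3 matrix of specific force, m/s^2, sensor frame
#' @export
simulate_accel <- function(sensor, g_vec = c(0, 0, -9.81)) {
  stopifnot(inherits(sensor, "pose_sequence"), length(g_vec) == 3L)
  pdd <- .diff2(sensor$origins, 1 / sensor$rate)
  f_glob <- sweep(pdd, 2L, g_vec)          # p'' - g
  quat_rotate(quat_conjugate(sensor$orientations), f_glob)
}

#' Simulate a virtual IMU on a body segment
#'
#' Moves the sensor to its placement on the segment, then derives the
#' gyroscope from the quaternion derivative and the accelerometer from the
#' second derivative of the sensor origin (specific-force convention).
#'
#' @inheritParams sensor_pose
#' @param g_vec gravity vector in the global frame, m/s^2
#' @return an [imu_signal()]
#' @export
simulate_imu <- function(segment, placement, g_vec = c(0, 0, -9.81)) {
  sp <- sensor_pose(segment, placement)
  imu_signal(accel = simulate_accel(sp, g_vec),
             gyro = angular_rate(sp),
             rate = segment$rate)
}

#' Frame-by-frame relative orientation between two segments
#'
#' `q_rel = q_parent* x q_child` per frame, hemisphere-corrected across
#' frames; this is the joint rotation used for Cardan angle extraction.
#'
#' @param parent,child [pose_sequence()] objects of equal length and rate
#' @return n-by-4 matrix of unit quaternions (parent-to-child)
#' @export
relative_orientation <- function(parent, child) {
  stopifnot(inherits(parent, "pose_sequence"), inherits(child, "pose_sequence"))
  if (n_frames(parent) != n_frames(child))
    stop("parent and child must have the same number of frames")
  if (abs(parent$rate - child$rate) > 1e-9)
    stop("parent and child must share a sampling rate")
  q <- quat_multiply(quat_conjugate(parent$orientations), child$orientations)
  quat_hemisphere(q)
}
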