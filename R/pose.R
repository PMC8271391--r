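#' Body-segment pose time series
#'
#' A `pose_sequence` holds a uniformly sampled rigid-body trajectory: one
#' unit quaternion (body-to-global) and one origin position per frame.
#' Quaternions are hemisphere-corrected on construction so the series is
#' continuous; non-unit input quaternions are normalized with a warning.
#'
#' @param orientations n-by-4 matrix of quaternions (scalar first,
#'   body-to-global, Hamilton convention)
#' @param origins n-by-3 matrix of origin positions, metres, global frame
#' @param rate sampling rate, Hz
#' @return an object of class `pose_sequence`
#' @export
pose_sequence <- function(orientations, origins, rate) {
  orientations <- as.matrix(orientations)
  origins <- as.matrix(origins)
  stopifnot(ncol(orientations) == 4L, ncol(origins) == 3L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  if (nrow(orientations) != nrow(origins))
    stop("orientations and origins must have the same number of frames")
  if (nrow(orientations) < 3L)
    stop("a pose_sequence needs at least 3 frames")
  if (!all(is.finite(orientations)) || !all(is.finite(origins)))
    stop("pose_sequence values must be finite")
  n <- sqrt(rowSums(orientations^2))
  if (any(abs(n - 1) > 1e-9)) {
    warning("non-unit quaternions normalized")
    orientations <- orientations / n
  }
  orientations <- quat_hemisphere(orientations)
  structure(list(orientations = orientations, origins = origins, rate = rate),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence: %d frames @ %g Hz>\n", nrow(x$orientations), x$rate))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param pose a `pose_sequence`
#' @return integer frame count
#' @export
n_frames <- function(pose) nrow(pose$orientations)

#' Segment identifiers of the five-sensor lower-limb set
#' @return character vector of segment ids in canonical order
#' @export
segment_ids <- function() c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R")

#' Sensor-to-segment placement
#'
#' The rigid offset of a sensor relative to its host segment frame: a
#' translation (metres, segment frame) and a rotation (segment-to-sensor).
#'
#' @param segment_id one of [segment_ids()]
#' @param offset_t 3-vector translation, metres, |offset_t| <= 0.5
#' @param offset_q unit quaternion rotating segment coordinates into sensor
#'   coordinates
#' @return an object of class `sensor_placement`
#' @export
sensor_placement <- function(segment_id,
                             offset_t = c(0, 0, 0),
                             offset_q = c(1, 0, 0, 0)) {
  segment_id <- match.arg(segment_id, segment_ids())
  stopifnot(length(offset_t) == 3L, all(is.finite(offset_t)))
  if (sqrt(sum(offset_t^2)) > 0.5)
    stop("|offset_t| must be <= 0.5 m")
  offset_q <- quat_canonical(quat_normalize(offset_q))
  structure(list(segment_id = segment_id, offset_t = as.numeric(offset_t),
                 offset_q = offset_q),
            class = "sensor_placement")
}

#' @export
print.sensor_placement <- function(x, ...) {
  rv <- quat_to_rotvec(x$offset_q)
  cat(sprintf("<sensor_placement on %s: t = [%s] m, rot = %.2f deg>\n",
              x$segment_id, paste(sprintf("%.3f", x$offset_t), collapse = ", "),
              sqrt(sum(rv^2)) * 180 / pi))
  invisible(x)
}

#' Tri-axial inertial sensor signal
#'
#' Specific force (what an accelerometer reads: coordinate acceleration
#' minus gravity, in the sensor frame) and angular rate, both per frame.
#'
#' @param accel n-by-3 matrix, m/s^2, sensor frame
#' @param gyro n-by-3 matrix, rad/s, sensor frame
#' @param rate sampling rate, Hz
#' @return an object of class `imu_signal`
#' @export
imu_signal <- function(accel, gyro, rate) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  stopifnot(ncol(accel) == 3L, ncol(gyro) == 3L, rate > 0)
  if (nrow(accel) != nrow(gyro))
    stop("accel and gyro must have the same length")
  if (!all(is.finite(accel)) || !all(is.finite(gyro)))
    stop("imu_signal values must be finite")
  structure(list(accel = accel, gyro = gyro, rate = rate), class = "imu_signal")
}

#' @export
print.imu_signal <- function(x, ...) {
  cat(sprintf("<imu_signal: %d frames @ %g Hz>\n", nrow(x$accel), x$rate))
  invisible(x)
}
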