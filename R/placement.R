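#' Fit a sensor placement to measured IMU data
#'
#' Optimises the rigid sensor-to-segment offset (translation + rotation)
#' so the virtual IMU simulated from the segment pose reproduces a measured
#' signal. The objective is the mean squared discrepancy summed over
#' accelerometer channels plus `gyro_weight` times the gyroscope channels;
#' it is minimised by bounded local least squares (L-BFGS-B) from the
#' initial guess, optionally preceded by a coarse grid over rotation
#' offsets. Deterministic given the initial guess.
#'
#' @param segment a [pose_sequence()], time-aligned with `measured`
#' @param measured an [imu_signal()] at the same rate
#' @param init a [sensor_placement()] initial guess
#' @param gyro_weight weight of the gyroscope term in the objective
#' @param g_vec gravity vector, m/s^2, global frame
#' @param coarse_rot_grid if `TRUE`, seed the local optimiser from the best
#'   of a coarse grid of rotation offsets around the initial guess
#' @param control passed to [stats::optim()]
#' @return a [sensor_placement()] with attributes `residual` (final
#'   objective value), `converged` (logical) and `counts`
#' @export
fit_placement <- function(segment, measured, init,
                          gyro_weight = 1,
                          g_vec = c(0, 0, -9.81),
                          coarse_rot_grid = FALSE,
                          control = list(maxit = 500)) {
  stopifnot(inherits(segment, "pose_sequence"), inherits(measured, "imu_signal"),
            inherits(init, "sensor_placement"))
  if (nrow(measured$accel) != n_frames(segment))
    stop("segment and measured signal must be time-aligned (equal lengths)")
  if (abs(measured$rate - segment$rate) > 1e-9)
    stop("segment and measured signal must share a sampling rate")

  obj <- function(p) {
    # bypass constructor validation: optimiser iterates stay in the box
    pl <- structure(list(segment_id = init$segment_id, offset_t = p[1:3],
                         offset_q = quat_from_rotvec(p[4:6])),
                    class = "sensor_placement")
    sim <- simulate_imu(segment, pl, g_vec)
    mean((sim$accel - measured$accel)^2) +
      gyro_weight * mean((sim$gyro - measured$gyro)^2)
  }

  p0 <- c(init$offset_t, quat_to_rotvec(init$offset_q))
  if (coarse_rot_grid) {
    grid <- expand.grid(a = seq(-pi, pi, length.out = 5)[-5],
                        b = c(-pi / 2, 0, pi / 2),
                        c = seq(-pi, pi, length.out = 5)[-5])
    cand <- rbind(p0, t(apply(grid, 1L, function(g) {
      q <- cardan_quaternion(c(g) * 180 / pi, order = "zxy")
      c(init$offset_t, quat_to_rotvec(q))
    })))
    vals <- apply(cand, 1L, obj)
    p0 <- cand[which.min(vals), ]
  }

  # box of half-width 0.28 m per axis keeps |offset_t| inside the 0.5 m ball
  fit <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = c(rep(-0.28, 3), rep(-pi, 3)),
                      upper = c(rep(0.28, 3), rep(pi, 3)),
                      control = control)
  out <- sensor_placement(init$segment_id, fit$par[1:3],
                          quat_from_rotvec(fit$par[4:6]))
  attr(out, "residual") <- fit$value
  attr(out, "converged") <- fit$convergence == 0L
  attr(out, "counts") <- fit$counts
  out
}

#' Augment one motion trial across a sensor-placement library
#'
#' Simulates the full five-sensor IMU trial once per placement set in the
#' library, widening the sensor-to-segment alignment distribution of the
#' training data. With a library of 23 placement sets each source trial
#' yields 23 simulated trials.
#'
#' @param trial_segments named list mapping each of [segment_ids()] to a
#'   [pose_sequence()]
#' @param library list of placement sets; each set is a named list of
#'   [sensor_placement()] covering all five segments
#' @param g_vec gravity vector, m/s^2
#' @return a list with one element per library entry (in library order);
#'   each element is a named list of [imu_signal()] per segment
#' @export
augment_trial <- function(trial_segments, library, g_vec = c(0, 0, -9.81)) {
  if (length(library) == 0L) stop("placement library must be non-empty")
  segs <- segment_ids()
  if (!all(segs %in% names(trial_segments)))
    stop("trial_segments must cover all five segments")
  lapply(library, function(set) {
    if (!all(segs %in% names(set)))
      stop("placement set missing a segment: need all of ",
           paste(segs, collapse = ", "))
    out <- lapply(segs, function(s) simulate_imu(trial_segments[[s]], set[[s]], g_vec))
    names(out) <- segs
    out
  })
}
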