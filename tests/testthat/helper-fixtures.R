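# Fixtures are generated in code; nothing is read from disk.

# smooth random orientation/position path built from low-frequency sinusoids
random_smooth_pose <- function(n = 200, rate = 200, seed = 1,
                               ang_amp = 30, pos_amp = 0.3) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  mk <- function(amp) {
    a <- stats::runif(3, 0.3, 1) * amp
    f <- stats::runif(3, 0.3, 1.5)
    ph <- stats::runif(3, 0, 2 * pi)
    sapply(1:3, function(k) a[k] * sin(2 * pi * f[k] * t + ph[k]))
  }
  angles <- mk(ang_amp)
  origins <- mk(pos_amp)
  pose_sequence(cardan_quaternion(angles, "zxy"), origins, rate)
}

# independent gyroscope oracle: body angular rate from the skew-symmetric
# part of the rotation-matrix finite difference (interior frames only)
rotmat_gyro_oracle <- function(pose) {
  Q <- pose$orientations
  n <- nrow(Q)
  dt <- 1 / pose$rate
  out <- matrix(NA_real_, n, 3)
  Rs <- lapply(seq_len(n), function(i) quat_to_matrix(Q[i, ]))
  for (i in 2:(n - 1)) {
    Rdot <- (Rs[[i + 1]] - Rs[[i - 1]]) / (2 * dt)
    S <- t(Rs[[i]]) %*% Rdot            # body-frame angular velocity skew
    out[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
  }
  out
}

# constant-rate rotation about a global axis, origin fixed
spin_pose <- function(axis, omega, n = 201, rate = 100) {
  t <- (seq_len(n) - 1) / rate
  Q <- t(sapply(t, function(tt) quat_from_axis_angle(axis, omega * tt)))
  pose_sequence(Q, matrix(0, n, 3), rate)
}

static_pose <- function(q = c(1, 0, 0, 0), p = c(0, 0, 0), n = 20, rate = 100) {
  pose_sequence(matrix(q, n, 4, byrow = TRUE), matrix(p, n, 3, byrow = TRUE),
                rate)
}

# horizontal circular motion of the origin, fixed orientation
circle_pose <- function(radius, omega, n = 401, rate = 100, q = c(1, 0, 0, 0)) {
  t <- (seq_len(n) - 1) / rate
  p <- cbind(radius * cos(omega * t), radius * sin(omega * t), 0)
  pose_sequence(matrix(q, n, 4, byrow = TRUE), p, rate)
}

noiseless_config <- function()
  list(accel_sd = 0, gyro_sd = 0, accel_bias_sd = 0, gyro_bias_sd = 0)

tiny_study <- function(n_subjects = 4, n_flagged = 2, trials = 2, seed = 7,
                       noise = noiseless_config()) {
  cohort <- sample_cohort(n_subjects, n_flagged, seed = seed)
  make_dataset(cohort, trials_per_subject = trials, noise_config = noise,
               seed = seed)
}

random_placement <- function(seed, t_sd = 0.03, rot_sd_deg = 10,
                             segment = "thigh_L") {
  set.seed(seed)
  sensor_placement(segment, stats::rnorm(3, 0, t_sd),
                   quat_from_rotvec(stats::rnorm(3, 0, rot_sd_deg * pi / 180)))
}
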