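test_that("angular rate is zero for a constant orientation", {
  pose <- static_pose(n = 30)
  expect_lt(max(abs(angular_rate(pose))), 1e-12)
})

test_that("angular rate recovers a constant-rate rotation about z", {
  pose <- spin_pose(c(0, 0, 1), omega = 1, n = 201, rate = 100)
  w <- angular_rate(pose)
  expect_lt(max(abs(sweep(w, 2, c(0, 0, 1)))), 1e-4)  # O(dt^2) at dt = 0.01
})

test_that("angular rate matches the rotation-matrix oracle on smooth paths", {
  for (seed in 1:3) {
    pose <- random_smooth_pose(n = 150, rate = 2000, seed = seed, ang_amp = 10)
    w <- angular_rate(pose)
    w_oracle <- rotmat_gyro_oracle(pose)
    interior <- 2:(n_frames(pose) - 1)
    expect_lt(max(abs(w[interior, ] - w_oracle[interior, ])), 1e-6)
  }
})

test_that("differentiation converges at second order", {
  err_at <- function(rate) {
    pose <- spin_pose(c(0, 0, 1), omega = 2, n = 2 * rate + 1, rate = rate)
    e_gyro <- max(abs(sweep(angular_rate(pose), 2, c(0, 0, 2))))
    circ <- circle_pose(0.5, 2, n = 2 * rate + 1, rate = rate)
    f <- simulate_accel(circ)
    # analytic: centripetal 0.5 * 4 = 2 m/s^2 horizontal, 9.81 vertical
    t <- (seq_len(n_frames(circ)) - 1) / rate
    f_true <- cbind(-2 * cos(2 * t), -2 * sin(2 * t), 9.81)
    interior <- 3:(n_frames(circ) - 2)
    e_acc <- max(abs(f[interior, ] - f_true[interior, ]))
    c(e_gyro, e_acc)
  }
  e1 <- err_at(100); e2 <- err_at(200)
  ratio <- e1 / e2
  expect_gt(ratio[1], 3); expect_lt(ratio[1], 5)
  expect_gt(ratio[2], 3); expect_lt(ratio[2], 5)
})

test_that("accelerometer reads gravity reaction when static", {
  pose <- static_pose(q = c(1, 0, 0, 0), p = c(1, 2, 3), n = 20)
  f <- simulate_accel(pose)
  expect_lt(max(abs(sweep(f, 2, c(0, 0, 9.81)))), 1e-9)
  # rotated sensor sees gravity in its own frame
  q <- quat_from_axis_angle(c(0, 1, 0), pi / 2)
  f_rot <- simulate_accel(static_pose(q = q, n = 20))
  g_body <- quat_rotate(quat_conjugate(q), c(0, 0, 9.81))
  expect_lt(max(abs(sweep(f_rot, 2, g_body))), 1e-9)
})

test_that("specific force vanishes in free fall", {
  rate <- 100
  t <- (0:100) / rate
  g <- c(0, 0, -9.81)
  p <- cbind(0.1 + 0 * t, 0.2 + 0 * t, 0.5 * -9.81 * t^2)
  q <- quat_from_axis_angle(c(1, 1, 0), 0.7)
  pose <- pose_sequence(matrix(q, length(t), 4, byrow = TRUE), p, rate)
  expect_lt(max(abs(simulate_accel(pose, g))), 1e-6)
})

test_that("circular motion gives the centripetal specific force", {
  circ <- circle_pose(0.5, 2, n = 401, rate = 100)
  f <- simulate_accel(circ)
  interior <- 5:395
  horiz <- sqrt(f[interior, 1]^2 + f[interior, 2]^2)
  expect_equal(mean(horiz), 2.0, tolerance = 1e-3)   # r * omega^2
  expect_equal(mean(f[interior, 3]), 9.81, tolerance = 1e-9)
})

test_that("sensor_pose applies the rigid offset", {
  seg <- random_smooth_pose(60, 100, seed = 41)
  ident <- sensor_placement("pelvis")
  same <- sensor_pose(seg, ident)
  expect_equal(same$orientations, seg$orientations)
  expect_equal(same$origins, seg$origins)
  shift <- sensor_placement("pelvis", offset_t = c(0.1, 0, 0))
  shifted <- sensor_pose(static_pose(n = 10), shift)
  expect_equal(shifted$origins[, 1], rep(0.1, 10))
})

test_that("offset sensor on a spinning segment sees the centripetal force", {
  omega <- 2; r <- 0.2
  seg <- spin_pose(c(0, 0, 1), omega, n = 401, rate = 100)
  pl <- sensor_placement("pelvis", offset_t = c(r, 0, 0))
  sp <- sensor_pose(seg, pl)
  rad <- sqrt(rowSums(sp$origins[, 1:2]^2))
  expect_lt(max(abs(rad - r)), 1e-12)                 # circle of radius r
  imu <- simulate_imu(seg, pl)
  interior <- 5:395
  horiz <- sqrt(imu$accel[interior, 1]^2 + imu$accel[interior, 2]^2)
  expect_equal(mean(horiz), r * omega^2, tolerance = 1e-3)
  expect_lt(max(abs(sweep(imu$gyro[interior, , drop = FALSE], 2, c(0, 0, omega)))),
            1e-4)
})

test_that("static segment gives zero gyro and |accel| = g for any placement", {
  pose <- static_pose(n = 20)
  pl <- random_placement(seed = 42)
  imu <- simulate_imu(pose, pl)
  expect_lt(max(abs(imu$gyro)), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(imu$accel^2)) - 9.81)), 1e-9)
})

test_that("gyro signals of two rotation-offset placements differ by that rotation", {
  seg <- random_smooth_pose(80, 100, seed = 43)
  q_a <- quat_from_rotvec(c(0.2, -0.1, 0.3))
  q_b <- quat_from_rotvec(c(-0.3, 0.2, 0.1))
  imu_a <- simulate_imu(seg, sensor_placement("thigh_L", offset_q = q_a))
  imu_b <- simulate_imu(seg, sensor_placement("thigh_L", offset_q = q_b))
  # frame change: w_b = R(q_b^* x q_a) w_a
  q_ab <- quat_multiply(quat_conjugate(q_b), q_a)
  expect_lt(max(abs(quat_rotate(q_ab, imu_a$gyro) - imu_b$gyro)), 1e-9)
})

test_that("body-frame signals are invariant under a global rotation", {
  seg <- random_smooth_pose(80, 100, seed = 44)
  pl <- random_placement(seed = 45)
  g <- c(0, 0, -9.81)
  q_glob <- quat_normalize(c(0.8, 0.1, -0.5, 0.3))
  seg_rot <- pose_sequence(
    quat_multiply(matrix(q_glob, 1), seg$orientations),
    quat_rotate(matrix(q_glob, nrow = n_frames(seg), ncol = 4, byrow = TRUE),
                seg$origins),
    seg$rate)
  imu <- simulate_imu(seg, pl, g)
  imu_rot <- simulate_imu(seg_rot, pl, quat_rotate(q_glob, g))
  expect_lt(max(abs(imu$gyro - imu_rot$gyro)), 1e-9)
  expect_lt(max(abs(imu$accel - imu_rot$accel)), 1e-8)
})

test_that("pose validation rejects bad input and normalizes with a warning", {
  expect_error(pose_sequence(matrix(c(1, 0, 0, 0), 2, 4, byrow = TRUE),
                             matrix(0, 2, 3), 100), "at least 3 frames")
  expect_warning(pose_sequence(matrix(c(2, 0, 0, 0), 5, 4, byrow = TRUE),
                               matrix(0, 5, 3), 100), "normalized")
  expect_error(sensor_placement("pelvis", offset_t = c(1, 0, 0)), "0.5 m")
  expect_error(imu_signal(matrix(0, 5, 3), matrix(0, 4, 3), 100), "same length")
})
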