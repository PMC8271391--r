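test_that("cohort sampling matches requested composition and is deterministic", {
  cohort <- sample_cohort(12, 5, seed = 71)
  expect_length(cohort, 12)
  expect_equal(sum(vapply(cohort, `[[`, logical(1), "has_ground_truth_sensors")), 5)
  masses <- vapply(cohort, `[[`, numeric(1), "mass")
  heights <- vapply(cohort, `[[`, numeric(1), "height")
  expect_true(all(masses >= 40 & masses <= 120))
  expect_true(all(heights >= 1.4 & heights <= 2.1))
  single <- sample_cohort(1, 0, seed = 72)
  expect_false(single[[1]]$has_ground_truth_sensors)
  expect_identical(sample_cohort(6, 2, seed = 73), sample_cohort(6, 2, seed = 73))
  expect_error(sample_cohort(3, 4, seed = 74), "<=")
})

test_that("joint-angle curves are periodic with the stride period", {
  sub <- sample_cohort(1, 0, seed = 75)[[1]]
  # speed chosen so the stride period is an integer number of frames
  ja <- synth_joint_angles(sub, speed = 0.48 / 0.42, n_strides = 3)
  stride_frames <- round(ja$period * ja$rate)
  expect_equal(stride_frames, 125)
  n <- nrow(ja$angles)
  a <- ja$angles[1:(n - stride_frames), ]
  b <- ja$angles[(stride_frames + 1):n, ]
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("stride period decreases monotonically with speed", {
  sub <- sample_cohort(1, 0, seed = 76)[[1]]
  p_slow <- synth_joint_angles(sub, 0.8)$period
  p_fast <- synth_joint_angles(sub, 2.0)$period
  expect_gt(p_slow, p_fast)
  expect_error(synth_joint_angles(sub, 3.0), "outside")
})

test_that("channel ranges order sagittal > frontal > transverse at hip and knee", {
  cohort <- sample_cohort(5, 0, seed = 77)
  for (sub in cohort) {
    ja <- synth_joint_angles(sub, 1.4)
    rng <- apply(ja$angles, 2, function(v) diff(range(v)))
    for (j in c("hip", "knee")) for (s in c("L", "R")) {
      expect_gt(rng[paste(j, s, "flex", sep = "_")], rng[paste(j, s, "abd", sep = "_")])
      expect_gt(rng[paste(j, s, "abd", sep = "_")], rng[paste(j, s, "rot", sep = "_")])
    }
  }
})

test_that("forward kinematics closes the loop with the angle extraction", {
  sub <- sample_cohort(1, 0, seed = 78)[[1]]
  ja <- synth_joint_angles(sub, 1.3)
  pelvis <- make_pelvis_path(sub, 1.3, nrow(ja$angles))
  poses <- forward_kinematics(ja$angles, sub, pelvis)
  for (side in c("L", "R")) {
    hip <- cardan_angles(relative_orientation(poses$pelvis,
                                              poses[[paste0("thigh_", side)]]))
    knee <- cardan_angles(relative_orientation(poses[[paste0("thigh_", side)]],
                                               poses[[paste0("shank_", side)]]))
    expect_lt(max(abs(hip - ja$angles[, paste("hip", side, c("flex", "abd", "rot"),
                                              sep = "_")])), 1e-6)
    expect_lt(max(abs(knee - ja$angles[, paste("knee", side, c("flex", "abd", "rot"),
                                               sep = "_")])), 1e-6)
  }
  expect_error(forward_kinematics(ja$angles[-1, ], sub, pelvis), "same number")
})

test_that("zero angles keep the chain parallel to the pelvis at full length", {
  sub <- sample_cohort(1, 0, seed = 79)[[1]]
  n <- 10
  zeros <- matrix(0, n, 18, dimnames = list(NULL, channel_names()))
  pelvis <- static_pose(q = quat_from_axis_angle(c(1, 0, 0), pi / 2),
                        p = c(0, 0, 1), n = n)
  poses <- forward_kinematics(zeros, sub, pelvis)
  expect_equal(poses$thigh_L$orientations, pelvis$orientations)
  expect_equal(poses$shank_R$orientations, pelvis$orientations)
  # hip-to-ankle span equals thigh + shank length
  ankle <- poses$shank_L$origins[1, ] +
    quat_rotate(poses$shank_L$orientations[1, ],
                c(0, -sub$segment_lengths[["shank"]], 0))
  hip <- poses$thigh_L$origins[1, ]
  expect_equal(sqrt(sum((ankle - hip)^2)),
               sub$segment_lengths[["thigh"]] + sub$segment_lengths[["shank"]],
               tolerance = 1e-12)
})

test_that("moments vanish at foot contact and scale with body size", {
  sub <- sample_cohort(1, 0, seed = 80)[[1]]
  ja <- synth_joint_angles(sub, 1.1)
  mom <- synth_moments(sub, ja$angles, ja$events)
  for (side in c("L", "R")) {
    ct <- ja$events[[paste0("contact_", side)]]
    cols <- grep(paste0("_", side, "_"), colnames(mom))
    expect_true(all(abs(mom[ct, cols]) < 1e-12))
  }
  # normalized curves are independent of mass/height; unnormalized scale as m*h
  big <- sub; big$mass <- 2 * sub$mass; big$height <- sub$height
  mom_big <- synth_moments(big, ja$angles, ja$events)
  expect_equal(mom_big, mom)
  unnorm <- moment_denormalize(mom, sub$mass, sub$height)
  unnorm2 <- moment_denormalize(mom, 2 * sub$mass, 2 * sub$height)
  expect_equal(unnorm2, 4 * unnorm)
  expect_identical(synth_moments(sub, ja$angles, ja$events), mom)
})

test_that("dataset assembly counts and reproducibility", {
  study <- tiny_study(n_subjects = 4, n_flagged = 2, trials = 3, seed = 81)
  expect_length(study$trials, 12)
  expect_length(study$simulated, 24)     # 12 trials x 2 placement sets
  expect_length(study$measured, 6)       # 2 flagged subjects x 3 trials
  study2 <- tiny_study(n_subjects = 4, n_flagged = 2, trials = 3, seed = 81)
  expect_identical(study$simulated[[7]]$imus$thigh_R$gyro,
                   study2$simulated[[7]]$imus$thigh_R$gyro)
  # noiseless config: measured equals the direct simulation
  key <- names(study$measured)[1]
  ti <- as.integer(key)
  sub <- study$cohort[[study$trials[[ti]]$subject_index]]
  direct <- simulate_imu(study$trials[[ti]]$segment_poses$pelvis,
                         sub$placements$pelvis)
  expect_equal(study$measured[[key]]$pelvis$accel, direct$accel, tolerance = 1e-12)
  # generated poses satisfy the type invariants (finite, hemisphere-aligned)
  Q <- study$trials[[1]]$segment_poses$shank_L$orientations
  expect_true(all(rowSums(Q[-1, ] * Q[-nrow(Q), ]) >= 0))
})
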