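#' Synthetic gait cohort generation
#'
#' A parametric stand-in for a treadmill/overground walking dataset: subject
#' anthropometrics are drawn from population statistics (mass 72.5 +/- 11.9
#' kg, height 1.73 +/- 0.09 m), joint-angle curves are truncated Fourier
#' series over the stride cycle with subject-specific coefficients, segment
#' poses follow from forward kinematics, and joint moments are stance-phase
#' templates scaled by body weight and height. A subset of subjects carries
#' "ground-truth" sensors with subject-specific placements, mirroring a
#' cohort in which only some participants wore real IMUs.
#'
#' @name syngait
NULL

#' Joint-angle/moment channel names (18 channels)
#' @return character vector: joints (hip, knee, ankle) x sides (L, R) x
#'   components (flex, abd, rot); left side first, flexion first
#' @export
channel_names <- function() {
  joints <- c("hip", "knee", "ankle")
  comps <- c("flex", "abd", "rot")
  unlist(lapply(c("L", "R"), function(s)
    unlist(lapply(joints, function(j) paste(j, s, comps, sep = "_")))))
}

# population-mean Fourier templates per joint/component channel (degrees):
# a0 = mean offset, amp/phase for harmonics 1..4 of the stride cycle.
# Amplitudes give physiologic ranges (hip flexion ~40 deg, knee ~60 deg)
# with sagittal > frontal > transverse.
.gait_templates <- function() {
  list(
    hip_flex   = list(a0 = 10, amp = c(20, 4, 1.5, 0.5),  ph = c(0.3, 1.2, 0.4, 2.1)),
    hip_abd    = list(a0 = 0,  amp = c(4, 2, 0.8, 0.3),   ph = c(1.1, 2.3, 0.7, 1.9)),
    hip_rot    = list(a0 = 0,  amp = c(2, 1, 0.4, 0.2),   ph = c(2.0, 0.5, 1.4, 0.3)),
    knee_flex  = list(a0 = 25, amp = c(25, 12, 4, 1.5),   ph = c(1.8, 4.4, 1.1, 0.8)),
    knee_abd   = list(a0 = 0,  amp = c(2.5, 1.2, 0.5, 0.2), ph = c(0.9, 1.7, 2.6, 1.2)),
    knee_rot   = list(a0 = 0,  amp = c(1.5, 0.8, 0.3, 0.1), ph = c(2.4, 0.2, 1.0, 2.8)),
    ankle_flex = list(a0 = 0,  amp = c(10, 6, 2, 0.8),    ph = c(2.9, 1.5, 0.6, 1.3)),
    ankle_abd  = list(a0 = 0,  amp = c(3, 1.5, 0.6, 0.2), ph = c(0.4, 2.2, 1.8, 0.9)),
    ankle_rot  = list(a0 = 0,  amp = c(1.8, 0.9, 0.3, 0.1), ph = c(1.6, 0.8, 2.5, 0.5))
  )
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

# nominal sensor mounting points per segment (segment frame: x anterior,
# y superior along the segment, z right), metres
.nominal_mounts <- function() {
  list(pelvis  = c(-0.10, 0.02, 0),
       thigh_L = c(0.05, -0.15, -0.04), thigh_R = c(0.05, -0.15, 0.04),
       shank_L = c(0.04, -0.12, -0.03), shank_R = c(0.04, -0.12, 0.03))
}

.sample_placement_set <- function(t_sd = 0.015, rot_sd_deg = 5) {
  mounts <- .nominal_mounts()
  out <- lapply(names(mounts), function(s) {
    t_off <- mounts[[s]] + pmax(-0.08, pmin(0.08, stats::rnorm(3, 0, t_sd)))
    rv <- stats::rnorm(3, 0, rot_sd_deg * pi / 180)
    sensor_placement(s, t_off, quat_from_rotvec(rv))
  })
  names(out) <- names(mounts)
  out
}

#' Sample a synthetic walking cohort
#'
#' Draws subject anthropometrics from Gaussians truncated to physiologic
#' bounds, subject-specific gait Fourier coefficients around the population
#' templates, and subject-specific sensor placements. Exactly
#' `n_ground_truth` subjects are flagged as carrying measured IMUs.
#'
#' @param n_subjects number of subjects
#' @param n_ground_truth number of subjects with measured ("ground-truth")
#'   IMU data; must not exceed `n_subjects`
#' @param seed RNG seed (the function seeds the RNG; same seed, same cohort)
#' @param speed_range self-selected walking speed range, m/s
#' @return list of `subject_spec` objects
#' @export
sample_cohort <- function(n_subjects, n_ground_truth, seed = 1,
                          speed_range = c(0.8, 2.0)) {
  if (n_ground_truth > n_subjects)
    stop("n_ground_truth must be <= n_subjects")
  set.seed(seed)
  mass <- .rtrunc_norm(n_subjects, 72.5, 11.9, 40, 120)
  height <- .rtrunc_norm(n_subjects, 1.73, 0.09, 1.4, 2.1)
  flagged <- rep(FALSE, n_subjects)
  if (n_ground_truth > 0)
    flagged[sample.int(n_subjects, n_ground_truth)] <- TRUE
  templates <- .gait_templates()
  lapply(seq_len(n_subjects), function(i) {
    coeffs <- lapply(templates, function(tm) {
      list(a0 = tm$a0 + stats::rnorm(1, 0, 1.5),
           amp = tm$amp * (1 + stats::rnorm(4, 0, 0.08)),
           ph = tm$ph + stats::rnorm(4, 0, 0.08))
    })
    # moment amplitudes track the subject's angular excursions (amplitude
    # ratio vs the population template, weighted by harmonic size), so the
    # kinetics are predictable from the same kinematics that drive the IMU
    amp_ratio <- vapply(names(templates), function(b)
      sum(coeffs[[b]]$amp) / sum(templates[[b]]$amp), numeric(1))
    mcoef <- vapply(channel_names(), function(ch)
      amp_ratio[[sub("_(L|R)_", "_", ch)]], numeric(1))
    structure(list(
      subject_id = sprintf("S%03d", i),
      mass = mass[i], height = height[i],
      segment_lengths = c(pelvis_width = 0.13 * height[i],
                          thigh = 0.245 * height[i],
                          shank = 0.246 * height[i]),
      gait_coeffs = coeffs,
      moment_coeffs = mcoef,
      speed_range = speed_range,
      has_ground_truth_sensors = flagged[i],
      placements = .sample_placement_set(),
      seed = seed + i
    ), class = "subject_spec")
  })
}

# stride period (s) and stance fraction as monotone functions of speed
.stride_period <- function(speed) 1.73 - 0.42 * speed
.stance_fraction <- function(speed) 0.63 - 0.033 * (speed - 0.8)

#' Synthesize joint-angle curves and gait events for one trial
#'
#' Each of the 18 channels is a truncated Fourier series (4 harmonics) over
#' the stride cycle with the subject's coefficients; right-side channels are
#' the left templates shifted by half a stride. Stride period decreases
#' monotonically with speed and non-sagittal amplitudes are smallest by
#' construction.
#'
#' @param subject a `subject_spec`
#' @param speed walking speed, m/s, within the subject's configured range
#' @param n_strides number of strides to generate
#' @param rate sampling rate, Hz
#' @return list with `angles` (n-by-18 matrix, degrees, [channel_names()]),
#'   `events` (frame indices of foot contact and toe-off per side),
#'   `rate`, `speed`, `period` (stride period, s)
#' @export
synth_joint_angles <- function(subject, speed, n_strides = 2, rate = 100) {
  stopifnot(inherits(subject, "subject_spec"))
  rng <- subject$speed_range
  if (speed < rng[1] - 1e-9 || speed > rng[2] + 1e-9)
    stop(sprintf("speed %.2f outside configured range [%.2f, %.2f]",
                 speed, rng[1], rng[2]))
  period <- .stride_period(speed)
  n <- round(n_strides * period * rate) + 1L
  phase <- (seq_len(n) - 1L) / (period * rate)   # stride cycles
  amp_scale <- 1 + 0.25 * (speed - 1.4)          # faster gait, larger excursions
  eval_chan <- function(cf, shift) {
    v <- rep(cf$a0, n)
    for (k in 1:4)
      v <- v + amp_scale * cf$amp[k] * cos(2 * pi * k * (phase + shift) + cf$ph[k])
    v
  }
  base <- names(.gait_templates())
  angles <- matrix(0, n, 18L, dimnames = list(NULL, channel_names()))
  for (side in c("L", "R")) {
    shift <- if (side == "L") 0 else 0.5
    for (b in base) {
      jn <- sub("_(flex|abd|rot)$", "", b)
      comp <- sub("^.*_", "", b)
      angles[, paste(jn, side, comp, sep = "_")] <-
        eval_chan(subject$gait_coeffs[[b]], shift)
    }
  }
  stance <- .stance_fraction(speed)
  frames_at <- function(cycles) {
    f <- round(cycles * period * rate) + 1L
    f[f >= 1L & f <= n]
  }
  events <- list(
    contact_L = frames_at(0:n_strides),
    toeoff_L = frames_at(0:(n_strides - 1) + stance),
    contact_R = frames_at(0:(n_strides - 1) + 0.5),
    toeoff_R = frames_at(0:(n_strides - 1) + 0.5 + stance)
  )
  list(angles = angles, events = events, rate = rate, speed = speed,
       period = period)
}

#' Pelvis trajectory for a walking trial
#'
#' Straight-line progression at the trial speed with small stride-locked
#' vertical and lateral oscillations and gentle pelvic tilt/obliquity/
#' rotation excursions. Global frame: x forward, y left, z up; the upright
#' reference orientation maps the segment's superior (y) axis to global z.
#'
#' @param subject a `subject_spec`
#' @param speed walking speed, m/s
#' @param n number of frames
#' @param rate sampling rate, Hz
#' @return a [pose_sequence()]
#' @export
make_pelvis_path <- function(subject, speed, n, rate = 100) {
  period <- .stride_period(speed)
  t <- (seq_len(n) - 1L) / rate
  phase <- t / period
  x <- speed * t
  y <- 0.02 * sin(2 * pi * phase)
  z <- 0.53 * subject$height + 0.015 * cos(4 * pi * phase)
  q_up <- quat_from_axis_angle(c(1, 0, 0), pi / 2)  # body y (superior) -> global z
  osc <- cbind(3 * sin(2 * pi * phase),             # about z: axial rotation
               2 * sin(2 * pi * phase + 1),         # about x: obliquity
               1.5 * sin(4 * pi * phase + 0.5))     # about y: tilt wobble
  q_osc <- cardan_quaternion(osc, order = "zxy")
  pose_sequence(quat_multiply(matrix(q_up, 1), q_osc), cbind(x, y, z), rate)
}

#' Forward kinematics: segment poses from joint-angle curves
#'
#' Composes the kinematic chain pelvis -> thigh -> shank per side: the
#' thigh orientation is the pelvis orientation composed with the hip
#' rotation (intrinsic Cardan order), the shank adds the knee rotation;
#' origins follow segment lengths along the distal (negative y) axis.
#'
#' @param angles n-by-18 matrix of joint angles, degrees ([channel_names()])
#' @param subject a `subject_spec` (segment lengths)
#' @param pelvis_path a [pose_sequence()] with the same number of frames
#' @param order intrinsic Cardan order used to build joint rotations
#' @return named list of [pose_sequence()]: pelvis, thigh_L, thigh_R,
#'   shank_L, shank_R
#' @export
forward_kinematics <- function(angles, subject, pelvis_path, order = "zxy") {
  stopifnot(inherits(subject, "subject_spec"),
            inherits(pelvis_path, "pose_sequence"))
  n <- nrow(angles)
  if (n != n_frames(pelvis_path))
    stop("angles and pelvis_path must have the same number of frames")
  sl <- subject$segment_lengths
  rate <- pelvis_path$rate
  out <- list(pelvis = pelvis_path)
  for (side in c("L", "R")) {
    zsign <- if (side == "L") -1 else 1
    hip_cols <- paste("hip", side, c("flex", "abd", "rot"), sep = "_")
    knee_cols <- paste("knee", side, c("flex", "abd", "rot"), sep = "_")
    q_hip <- cardan_quaternion(angles[, hip_cols, drop = FALSE], order)
    q_thigh <- quat_multiply(pelvis_path$orientations, q_hip)
    hip_ctr <- pelvis_path$origins +
      quat_rotate(pelvis_path$orientations, c(0, 0, zsign * sl[["pelvis_width"]] / 2))
    out[[paste0("thigh_", side)]] <- pose_sequence(q_thigh, hip_ctr, rate)
    q_knee <- cardan_quaternion(angles[, knee_cols, drop = FALSE], order)
    q_shank <- quat_multiply(q_thigh, q_knee)
    knee_ctr <- hip_ctr + quat_rotate(q_thigh, c(0, -sl[["thigh"]], 0))
    out[[paste0("shank_", side)]] <- pose_sequence(q_shank, knee_ctr, rate)
  }
  out
}

# stance-phase moment template: zero at contact and toe-off, double hump
# for sagittal channels; s in [0, 1] over stance
.moment_template <- function(s, c1, c2, ph) 4 * s * (1 - s) * (c1 + c2 * sin(2 * pi * s + ph))

# per-channel normalized template coefficients (units of M / (m g h))
.moment_coeff_table <- function() {
  list(hip_flex = c(0.06, 0.035, 0.6), hip_abd = c(0.05, 0.015, 2.1),
       hip_rot = c(0.010, 0.004, 1.2), knee_flex = c(0.04, 0.025, 2.8),
       knee_abd = c(0.025, 0.010, 1.6), knee_rot = c(0.008, 0.003, 0.4),
       ankle_flex = c(0.08, 0.030, 4.1), ankle_abd = c(0.012, 0.005, 0.9),
       ankle_rot = c(0.006, 0.002, 2.3))
}

#' Synthesize normalized joint-moment curves for one trial
#'
#' Per-channel stance templates (zero at foot contact and toe-off,
#' double-humped sagittal shapes) modulated by the subject's moment
#' coefficients. Curves are returned normalized to body weight times height
#' (dimensionless M / (m g h)); multiply by `mass * 9.81 * height` for
#' newton-metres. Values are identically zero outside stance.
#'
#' @param subject a `subject_spec`
#' @param angles n-by-18 angle matrix (defines the trial length)
#' @param events gait events as returned by [synth_joint_angles()]
#' @return n-by-18 matrix of normalized moments ([channel_names()])
#' @export
synth_moments <- function(subject, angles, events) {
  stopifnot(inherits(subject, "subject_spec"))
  n <- nrow(angles)
  tab <- .moment_coeff_table()
  mom <- matrix(0, n, 18L, dimnames = list(NULL, channel_names()))
  cn <- channel_names()
  for (side in c("L", "R")) {
    contacts <- events[[paste0("contact_", side)]]
    toeoffs <- events[[paste0("toeoff_", side)]]
    for (ct in contacts) {
      to <- toeoffs[toeoffs > ct]
      if (length(to) == 0L) next
      to <- to[1]
      idx <- ct:to
      s <- (idx - ct) / (to - ct)
      for (b in names(tab)) {
        jn <- sub("_(flex|abd|rot)$", "", b)
        comp <- sub("^.*_", "", b)
        ch <- paste(jn, side, comp, sep = "_")
        k <- subject$moment_coeffs[match(ch, cn)]
        cf <- tab[[b]]
        mom[idx, ch] <- k * .moment_template(s, cf[1], cf[2], cf[3])
      }
    }
  }
  mom
}

#' Assemble a synthetic gait study bundle
#'
#' Generates, for every subject and trial: segment poses, joint angles and
#' normalized moments; for flagged subjects additionally a "measured" IMU
#' trial (the subject's own placements plus additive Gaussian noise and a
#' per-trial constant bias); and the placement-augmented simulated IMU
#' trials (every flagged subject's placement set applied to every trial, so
#' the augmentation factor equals the number of flagged subjects).
#'
#' @param cohort list of `subject_spec` from [sample_cohort()]
#' @param trials_per_subject trials generated per subject
#' @param noise_config list with `accel_sd` (m/s^2), `gyro_sd` (rad/s),
#'   `accel_bias_sd`, `gyro_bias_sd`
#' @param seed RNG seed (function seeds the RNG)
#' @param n_strides strides per trial
#' @param rate sampling rate, Hz
#' @return a `gait_study` list: `cohort`, `trials`, `measured` (keyed by
#'   trial index, flagged subjects only), `simulated` (augmented virtual-IMU
#'   trials with `trial` and `placement_subject` indices)
#' @export
make_dataset <- function(cohort, trials_per_subject = 3,
                         noise_config = list(accel_sd = 0.2, gyro_sd = 0.02,
                                             accel_bias_sd = 0.1,
                                             gyro_bias_sd = 0.01),
                         seed = 1, n_strides = 2, rate = 100) {
  set.seed(seed)
  flagged <- which(vapply(cohort, `[[`, logical(1), "has_ground_truth_sensors"))
  trials <- list()
  measured <- list()
  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    speeds <- stats::runif(trials_per_subject, sub$speed_range[1], sub$speed_range[2])
    for (tr in seq_len(trials_per_subject)) {
      ja <- synth_joint_angles(sub, speeds[tr], n_strides, rate)
      pelvis <- make_pelvis_path(sub, speeds[tr], nrow(ja$angles), rate)
      poses <- forward_kinematics(ja$angles, sub, pelvis)
      mom <- synth_moments(sub, ja$angles, ja$events)
      trial <- structure(list(
        subject_id = sub$subject_id, subject_index = si, speed = speeds[tr],
        rate = rate, joint_angles = ja$angles, joint_moments = mom,
        events = ja$events, segment_poses = poses
      ), class = "gait_trial")
      trials[[length(trials) + 1L]] <- trial
      if (sub$has_ground_truth_sensors) {
        imus <- lapply(segment_ids(), function(s) {
          sim <- simulate_imu(poses[[s]], sub$placements[[s]])
          nfr <- nrow(sim$accel)
          a_bias <- stats::rnorm(3, 0, noise_config$accel_bias_sd)
          g_bias <- stats::rnorm(3, 0, noise_config$gyro_bias_sd)
          imu_signal(
            sim$accel + matrix(stats::rnorm(nfr * 3, 0, noise_config$accel_sd), nfr) +
              rep(a_bias, each = nfr),
            sim$gyro + matrix(stats::rnorm(nfr * 3, 0, noise_config$gyro_sd), nfr) +
              rep(g_bias, each = nfr),
            rate)
        })
        names(imus) <- segment_ids()
        measured[[as.character(length(trials))]] <- imus
      }
    }
  }
  library_sets <- lapply(cohort[flagged], `[[`, "placements")
  simulated <- list()
  for (ti in seq_along(trials)) {
    sims <- augment_trial(trials[[ti]]$segment_poses, library_sets)
    for (li in seq_along(sims)) {
      simulated[[length(simulated) + 1L]] <- list(
        trial = ti,
        placement_subject = cohort[[flagged[li]]]$subject_id,
        imus = sims[[li]])
    }
  }
  structure(list(cohort = cohort, trials = trials, measured = measured,
                 simulated = simulated, noise_config = noise_config,
                 seed = seed, rate = rate),
            class = "gait_study")
}

#' @export
print.gait_study <- function(x, ...) {
  cat(sprintf("<gait_study: %d subjects, %d trials, %d measured, %d simulated>\n",
              length(x$cohort), length(x$trials), length(x$measured),
              length(x$simulated)))
  invisible(x)
}
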