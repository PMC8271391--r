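#' Study-bundle persistence
#'
#' A `gait_study` is written as a directory tree of plain-text artifacts:
#' one wide CSV per trial for segment poses (`t`, then per-segment
#' `q_w..q_z, p_x..p_z` columns), one CSV for the 36 target channels
#' (angles in degrees, normalized moments), one 30-column CSV per IMU
#' trial, and a `study.json` manifest carrying the cohort, events, noise
#' configuration, seed and a content hash.
#'
#' @name study-io
NULL

.pose_wide <- function(poses, rate) {
  n <- n_frames(poses[[1L]])
  out <- data.frame(t = (seq_len(n) - 1L) / rate)
  for (s in names(poses)) {
    p <- poses[[s]]
    q <- p$orientations; o <- p$origins
    df <- data.frame(q[, 1], q[, 2], q[, 3], q[, 4], o[, 1], o[, 2], o[, 3])
    names(df) <- paste(s, c("q_w", "q_x", "q_y", "q_z", "p_x", "p_y", "p_z"),
                       sep = "_")
    out <- cbind(out, df)
  }
  out
}

.pose_from_wide <- function(df, rate) {
  segs <- unique(sub("_(q_[wxyz]|p_[xyz])$", "", setdiff(names(df), "t")))
  out <- lapply(segs, function(s) {
    q <- as.matrix(df[paste(s, c("q_w", "q_x", "q_y", "q_z"), sep = "_")])
    o <- as.matrix(df[paste(s, c("p_x", "p_y", "p_z"), sep = "_")])
    pose_sequence(q, o, rate)
  })
  names(out) <- segs
  out
}

.imu_wide <- function(imus, rate) {
  n <- nrow(imus[[1L]]$accel)
  out <- data.frame(t = (seq_len(n) - 1L) / rate)
  for (s in names(imus)) {
    df <- data.frame(imus[[s]]$accel, imus[[s]]$gyro)
    names(df) <- paste(s, c("ax", "ay", "az", "gx", "gy", "gz"), sep = "_")
    out <- cbind(out, df)
  }
  out
}

.imu_from_wide <- function(df, rate) {
  segs <- unique(sub("_(a|g)[xyz]$", "", setdiff(names(df), "t")))
  out <- lapply(segs, function(s)
    imu_signal(as.matrix(df[paste(s, c("ax", "ay", "az"), sep = "_")]),
               as.matrix(df[paste(s, c("gx", "gy", "gz"), sep = "_")]), rate))
  names(out) <- segs
  out
}

.cohort_json <- function(cohort) {
  lapply(cohort, function(s) {
    pl <- lapply(s$placements, function(p)
      list(segment_id = p$segment_id, offset_t = p$offset_t,
           offset_q = p$offset_q))
    list(subject_id = s$subject_id, mass = s$mass, height = s$height,
         segment_lengths = as.list(s$segment_lengths),
         gait_coeffs = s$gait_coeffs, moment_coeffs = s$moment_coeffs,
         speed_range = s$speed_range,
         has_ground_truth_sensors = s$has_ground_truth_sensors,
         placements = pl, seed = s$seed)
  })
}

.cohort_from_json <- function(lst) {
  lapply(lst, function(s) {
    pl <- lapply(s$placements, function(p)
      sensor_placement(p$segment_id, unlist(p$offset_t), unlist(p$offset_q)))
    names(pl) <- vapply(pl, `[[`, character(1), "segment_id")
    structure(list(
      subject_id = s$subject_id, mass = s$mass, height = s$height,
      segment_lengths = unlist(s$segment_lengths),
      gait_coeffs = lapply(s$gait_coeffs, function(g)
        list(a0 = g$a0, amp = unlist(g$amp), ph = unlist(g$ph))),
      moment_coeffs = unlist(s$moment_coeffs),
      speed_range = unlist(s$speed_range),
      has_ground_truth_sensors = isTRUE(s$has_ground_truth_sensors),
      placements = pl, seed = s$seed), class = "subject_spec")
  })
}

#' Write a study bundle to disk
#'
#' @param study a `gait_study`
#' @param dir output directory (created; must not exist unless `force`)
#' @param force overwrite an existing directory
#' @return the manifest (invisibly), including the content hash
#' @export
write_study <- function(study, dir, force = FALSE) {
  stopifnot(inherits(study, "gait_study"))
  if (dir.exists(dir)) {
    if (!force) stop("output directory exists; use force = TRUE to overwrite")
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  dir.create(file.path(dir, "trials"))
  trials_meta <- list()
  for (ti in seq_along(study$trials)) {
    tr <- study$trials[[ti]]
    base <- sprintf("trial_%03d", ti)
    utils::write.csv(.pose_wide(tr$segment_poses, tr$rate),
                     file.path(dir, "trials", paste0(base, "_poses.csv")),
                     row.names = FALSE)
    targets <- data.frame(tr$joint_angles, tr$joint_moments)
    names(targets) <- c(paste0("angle_", channel_names()),
                        paste0("moment_", channel_names()))
    utils::write.csv(targets,
                     file.path(dir, "trials", paste0(base, "_targets.csv")),
                     row.names = FALSE)
    trials_meta[[ti]] <- list(index = ti, subject_id = tr$subject_id,
                              subject_index = tr$subject_index,
                              speed = tr$speed, rate = tr$rate,
                              events = tr$events)
  }
  for (key in names(study$measured)) {
    utils::write.csv(.imu_wide(study$measured[[key]], study$rate),
                     file.path(dir, "trials",
                               sprintf("measured_%03d.csv", as.integer(key))),
                     row.names = FALSE)
  }
  dir.create(file.path(dir, "simulated"))
  sim_meta <- list()
  for (si in seq_along(study$simulated)) {
    e <- study$simulated[[si]]
    utils::write.csv(.imu_wide(e$imus, study$rate),
                     file.path(dir, "simulated", sprintf("sim_%05d.csv", si)),
                     row.names = FALSE)
    sim_meta[[si]] <- list(index = si, trial = e$trial,
                           placement_subject = e$placement_subject)
  }
  manifest <- list(format = "imugait-study-1", rate = study$rate,
                   seed = study$seed, noise_config = study$noise_config,
                   n_trials = length(study$trials),
                   measured_trials = as.integer(names(study$measured)),
                   cohort = .cohort_json(study$cohort),
                   trials = trials_meta, simulated = sim_meta)
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  hash <- dir_hash(dir)
  manifest$content_hash <- hash
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Content hash of a directory of text artifacts
#' @param dir directory path
#' @return md5 hash over the sorted per-file md5 sums (excluding the
#'   study.json and run.json metadata, which embed hashes and run paths)
#' @export
dir_hash <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!basename(files) %in% c("study.json", "run.json")]
  sums <- tools::md5sum(files)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(basename(names(sums)), unname(sums)), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a study bundle from disk
#' @param dir directory written by [write_study()]
#' @return a `gait_study`
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "study.json"))
  if (!identical(manifest$format, "imugait-study-1"))
    stop("not an imugait study bundle: ", dir)
  rate <- manifest$rate
  cohort <- .cohort_from_json(manifest$cohort)
  trials <- lapply(manifest$trials, function(tm) {
    base <- sprintf("trial_%03d", tm$index)
    poses <- .pose_from_wide(
      utils::read.csv(file.path(dir, "trials", paste0(base, "_poses.csv"))), rate)
    targets <- utils::read.csv(file.path(dir, "trials", paste0(base, "_targets.csv")))
    ang <- as.matrix(targets[paste0("angle_", channel_names())])
    mom <- as.matrix(targets[paste0("moment_", channel_names())])
    colnames(ang) <- colnames(mom) <- channel_names()
    structure(list(subject_id = tm$subject_id, subject_index = tm$subject_index,
                   speed = tm$speed, rate = rate, joint_angles = ang,
                   joint_moments = mom,
                   events = lapply(tm$events, function(v) as.integer(unlist(v))),
                   segment_poses = poses), class = "gait_trial")
  })
  measured <- list()
  for (ti in unlist(manifest$measured_trials)) {
    measured[[as.character(ti)]] <- .imu_from_wide(
      utils::read.csv(file.path(dir, "trials", sprintf("measured_%03d.csv", ti))),
      rate)
  }
  simulated <- lapply(manifest$simulated, function(sm)
    list(trial = sm$trial, placement_subject = sm$placement_subject,
         imus = .imu_from_wide(
           utils::read.csv(file.path(dir, "simulated",
                                     sprintf("sim_%05d.csv", sm$index))), rate)))
  structure(list(cohort = cohort, trials = trials, measured = measured,
                 simulated = simulated,
                 noise_config = manifest$noise_config, seed = manifest$seed,
                 rate = rate),
            class = "gait_study")
}
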