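#' Signal preprocessing for the gait-regression pipeline
#'
#' Zero-lag Butterworth filtering, cross-correlation synchronisation, time
#' normalisation to 101-point phases, body-weight-and-height moment
#' normalisation, and confidence-based sample exclusion.
#'
#' @name preprocess
NULL

#' Zero-lag (forward-backward) Butterworth low-pass filter
#'
#' Designs a low-pass Butterworth filter of the requested order and applies
#' it forward and backward so the net phase shift is zero (the effective
#' attenuation is the squared magnitude response). Edge transients are
#' suppressed by odd-reflection padding with steady-state initial
#' conditions, so constant signals pass through unchanged.
#'
#' @param x numeric vector or n-by-k matrix (channels in columns)
#' @param order filter order (as designed; applied twice)
#' @param cutoff_hz cut-off frequency, Hz; must be below Nyquist
#' @param rate_hz sampling rate, Hz
#' @return filtered signal, same shape as `x`
#' @export
zero_lag_butter <- function(x, order, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2)
    stop("cutoff frequency must be below the Nyquist frequency")
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(X)
  if (n <= 3L * order)
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order, 2 * cutoff_hz / rate_hz, type = "low")
  b <- bf$b; a <- bf$a
  pole_r <- max(Mod(polyroot(rev(a))))
  pad <- min(n - 1L, max(3L * order,
                         if (pole_r < 1) ceiling(log(1e-12) / log(pole_r)) else n - 1L))
  one_pass <- function(v) {
    vp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    y <- signal::filter(b, a, vp,
                        init.x = rep(vp[1], length(b) - 1L),
                        init.y = rep(vp[1], length(a) - 1L))
    y[(pad + 1):(pad + n)]
  }
  out <- apply(X, 2L, function(v) rev(one_pass(rev(one_pass(v)))))
  if (vec) drop(out) else out
}

#' Synchronisation lag between two series by cross-correlation
#'
#' Finds the integer lag maximising the normalised cross-correlation
#' between `a` and `b` (positive lag: `b` is delayed relative to `a`).
#' Ties are broken toward the smallest absolute lag.
#'
#' @param a,b numeric vectors (e.g. gyroscope magnitude channels)
#' @param max_lag maximum |lag| searched, samples; both series must be at
#'   least twice as long
#' @return integer lag in samples
#' @export
sync_lag <- function(a, b, max_lag) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L * max_lag || length(b) < 2L * max_lag)
    stop("series must be at least twice max_lag long")
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("cannot synchronise flat (zero-variance) input")
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]    # smallest |lag| first for tie-break
  best <- -Inf; best_lag <- 0L
  for (L in lags) {
    if (L >= 0) { ai <- seq_len(length(a) - L); bi <- ai + L }
    else { bi <- seq_len(length(b) + L); ai <- bi - L }
    if (length(ai) < 3L) next
    sa <- a[ai]; sb <- b[bi]
    if (stats::sd(sa) < 1e-12 || stats::sd(sb) < 1e-12) next
    r <- stats::cor(sa, sb)
    if (r > best + 1e-12) { best <- r; best_lag <- L }
  }
  as.integer(best_lag)
}

#' Time-normalise a signal window to a fixed number of points
#'
#' Linearly interpolates the frames in `[start, end]` onto `n_points`
#' equally spaced samples spanning the window inclusively, so the first and
#' last output samples equal the boundary frames. Used to normalise
#' kinematics to the step phase and kinetics to the stance phase (101
#' points by default).
#'
#' @param x numeric vector or n-by-k matrix
#' @param start,end window boundaries, frame indices (start < end)
#' @param n_points output length (>= 2), default 101
#' @return `n_points`-row matrix (or vector)
#' @export
time_normalize <- function(x, start, end, n_points = 101L) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1L) else x
  if (n_points < 2L) stop("n_points must be >= 2")
  if (start < 1L || end > nrow(X) || start >= end)
    stop("degenerate or out-of-range window")
  at <- seq(start, end, length.out = n_points)
  out <- apply(X, 2L, function(v) stats::approx(seq_len(nrow(X)), v, xout = at)$y)
  if (vec) drop(out) else out
}

#' Normalise joint moments to body weight and height
#'
#' Divides moments (N m) by `mass * 9.81 * height`, yielding the
#' dimensionless representation used for between-subject comparison.
#'
#' @param moments numeric vector/matrix of moments
#' @param mass body mass, kg (> 0)
#' @param height body height, m (> 0)
#' @return normalised moments, same shape
#' @export
moment_normalize <- function(moments, mass, height) {
  if (mass <= 0 || height <= 0) stop("mass and height must be positive")
  moments / (mass * 9.81 * height)
}

#' @rdname moment_normalize
#' @export
moment_denormalize <- function(moments, mass, height) {
  if (mass <= 0 || height <= 0) stop("mass and height must be positive")
  moments * (mass * 9.81 * height)
}

#' Confidence-based exclusion of deviant samples
#'
#' Given an ensemble of fixed-length multichannel samples, computes the
#' pointwise ensemble mean and SD per (channel, time) and scores each
#' sample by the mean absolute z-deviation over all points with non-zero
#' SD. Under independent Gaussian deviations the score of a clean sample
#' is a mean of `K` folded-normal deviates, so its null distribution is
#' `Normal(sqrt(2/pi), sqrt(1 - 2/pi) / sqrt(K))`. A sample is excluded
#' when its score, expressed relative to the ensemble's 10th-percentile
#' score (a truncation-insensitive anchor), exceeds the `level`-quantile
#' of that null expressed relative to the null's own 10th percentile.
#' This keeps the exclusion rate at `1 - level` under the null while
#' making the filter idempotent: refiltering the kept set excludes
#' (almost) nothing, because the low-quantile anchor barely moves when
#' the upper tail is removed.
#'
#' @param samples a list of equally sized channel-by-time matrices, or a
#'   3-D array `[sample, channel, time]`; at least 10 samples
#' @param level confidence level, default 0.95
#' @param effective_points effective number of independent points per
#'   sample used in the null; defaults to the count of non-degenerate
#'   (channel, time) points, which assumes independent deviations —
#'   supply a smaller value for strongly correlated deviation patterns
#' @return list with `kept` (indices), `excluded` (data.frame of `id` and
#'   `score`), `scores`, `threshold` (on the score scale)
#' @export
ci_filter <- function(samples, level = 0.95, effective_points = NULL) {
  A <- if (is.array(samples) && length(dim(samples)) == 3L) samples
  else {
    stopifnot(is.list(samples), length(samples) >= 1L)
    d <- dim(samples[[1L]])
    arr <- array(NA_real_, c(length(samples), d))
    for (i in seq_along(samples)) arr[i, , ] <- samples[[i]]
    arr
  }
  ns <- dim(A)[1L]
  if (ns < 10L) stop("ci_filter needs at least 10 samples")
  mu <- apply(A, c(2L, 3L), mean)
  sdv <- apply(A, c(2L, 3L), stats::sd)
  valid <- sdv > 1e-12
  if (!any(valid)) {
    warning("zero ensemble SD everywhere; no exclusions")
    return(list(kept = seq_len(ns),
                excluded = data.frame(id = integer(), score = numeric()),
                scores = rep(0, ns), threshold = Inf))
  }
  K <- effective_points %||% sum(valid)
  scores <- vapply(seq_len(ns), function(i) {
    z <- abs(A[i, , ] - mu) / ifelse(valid, sdv, 1)
    mean(z[valid])
  }, numeric(1))
  mu0 <- sqrt(2 / pi)
  s0 <- sqrt(1 - 2 / pi) / sqrt(K)
  anchor_null <- mu0 + stats::qnorm(0.10) * s0
  cut_null <- mu0 + stats::qnorm(level) * s0
  anchor <- stats::quantile(scores, 0.10, type = 7, names = FALSE)
  threshold <- anchor * cut_null / anchor_null
  out <- which(scores > threshold)
  list(kept = setdiff(seq_len(ns), out),
       excluded = data.frame(id = out, score = scores[out]),
       scores = scores, threshold = threshold)
}

#' Input-channel names of the five-sensor signal matrix (30 channels)
#' @return character vector, sensor-major, accelerometer before gyroscope,
#'   axes x, y, z innermost
#' @export
imu_channel_names <- function() {
  unlist(lapply(segment_ids(), function(s)
    paste(s, rep(c("accel", "gyro"), each = 3L), c("x", "y", "z"), sep = "_")))
}

# stack a named list of per-segment imu_signal objects into the canonical
# 30-by-n channel matrix
.stack_imus <- function(imus) {
  do.call(rbind, lapply(segment_ids(), function(s)
    rbind(t(imus[[s]]$accel), t(imus[[s]]$gyro))))
}

#' Build time-normalised training samples from a study bundle
#'
#' The pipeline glue between the synthetic study and the tensor layouts:
#' every augmented simulated IMU trial (and, optionally, every measured IMU
#' trial) is filtered (zero-lag first-order low pass for the IMU channels,
#' zero-lag fourth-order low pass for the target joint angles) and linearly
#' time-normalised to `n_points` samples. Kinematics are normalised to the
#' step phase (left foot contact to the next left contact), together with
#' the inputs. Kinetics are normalised to the stance phase of each
#' channel's own side (left channels over the left stance, right channels
#' over the right stance within the same stride), with the inputs spanning
#' the full stride so both stances are covered.
#'
#' @param study a `gait_study` from [make_dataset()]
#' @param target `"angles"` or `"moments"`
#' @param n_points normalised series length, default 101
#' @param imu_cutoff_hz,imu_order IMU low-pass settings (5 Hz, order 1)
#' @param target_cutoff_hz,target_order target-curve low-pass settings
#'   (6 Hz, order 4; applied to angles only)
#' @param include_simulated,include_measured which sample sources to emit
#' @return list of samples; each has `X` (30-by-`n_points`), `Y`
#'   (18-by-`n_points`), `subject_id`, `trial`, `placement`, `kind`
#' @export
study_samples <- function(study, target = c("angles", "moments"),
                          n_points = 101L,
                          imu_cutoff_hz = 5, imu_order = 1L,
                          target_cutoff_hz = 6, target_order = 4L,
                          include_simulated = TRUE, include_measured = TRUE) {
  target <- match.arg(target)
  stopifnot(inherits(study, "gait_study"))
  rate <- study$rate
  trial_cache <- new.env(parent = emptyenv())
  prep_target <- function(ti) {
    key <- as.character(ti)
    if (!is.null(trial_cache[[key]])) return(trial_cache[[key]])
    trial <- study$trials[[ti]]
    ev <- trial$events
    win <- c(ev$contact_L[1L], ev$contact_L[2L])     # one full stride
    if (target == "angles") {
      Yr <- zero_lag_butter(trial$joint_angles, target_order, target_cutoff_hz, rate)
      Y <- t(time_normalize(Yr, win[1L], win[2L], n_points))
    } else {
      Yr <- trial$joint_moments
      Y <- matrix(0, 18L, n_points, dimnames = list(channel_names(), NULL))
      for (side in c("L", "R")) {
        ct <- ev[[paste0("contact_", side)]][1L]
        to <- ev[[paste0("toeoff_", side)]]
        to <- to[to > ct][1L]
        cols <- grep(paste0("_", side, "_"), channel_names())
        Y[cols, ] <- t(time_normalize(Yr[, cols, drop = FALSE], ct, to, n_points))
      }
    }
    res <- list(Y = Y, win = win, subject_id = trial$subject_id)
    trial_cache[[key]] <- res
    res
  }
  prep_x <- function(imus, win) {
    Xr <- t(zero_lag_butter(t(.stack_imus(imus)), imu_order, imu_cutoff_hz, rate))
    t(time_normalize(t(Xr), win[1L], win[2L], n_points))
  }
  samples <- list()
  if (include_simulated) {
    for (entry in study$simulated) {
      tgt <- prep_target(entry$trial)
      samples[[length(samples) + 1L]] <- list(
        X = prep_x(entry$imus, tgt$win), Y = tgt$Y,
        subject_id = tgt$subject_id, trial = entry$trial,
        placement = entry$placement_subject, kind = "simulated")
    }
  }
  if (include_measured) {
    for (key in names(study$measured)) {
      ti <- as.integer(key)
      tgt <- prep_target(ti)
      samples[[length(samples) + 1L]] <- list(
        X = prep_x(study$measured[[key]], tgt$win), Y = tgt$Y,
        subject_id = tgt$subject_id, trial = ti,
        placement = "own", kind = "measured")
    }
  }
  samples
}
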