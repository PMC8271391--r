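#' Network-specific tensor layouts
#'
#' The same time-normalised samples are assembled into three layouts: a
#' flat matrix for the MLP (`[n, 30 * n_points]` inputs, `[n, 18 *
#' n_points]` outputs), a rank-3 sequence tensor for the LSTM (`[n, 30,
#' n_points]` / `[n, 18, n_points]`), and an RGB image tensor for the CNN
#' (`[n, side, side, 3]` with flat outputs). The channel order is a frozen
#' contract: sensors pelvis, thigh_L, thigh_R, shank_L, shank_R;
#' accelerometer before gyroscope; axes x, y, z; time fastest-varying when
#' flattened.
#'
#' @name tensors
NULL

.new_dataset_tensors <- function(layout, X, Y, sample_index, n_points,
                                 side = NULL) {
  structure(list(layout = layout, X = X, Y = Y, sample_index = sample_index,
                 n_points = n_points, side = side,
                 channels_in = imu_channel_names(),
                 channels_out = channel_names(),
                 scalers = NULL),
            class = "dataset_tensors")
}

#' @export
print.dataset_tensors <- function(x, ...) {
  cat(sprintf("<dataset_tensors[%s]: X %s, Y %s%s>\n", x$layout,
              paste(dim(x$X), collapse = "x"), paste(dim(x$Y), collapse = "x"),
              if (is.null(x$scalers)) "" else ", scaled"))
  invisible(x)
}

.sample_index_df <- function(samples) {
  data.frame(subject_id = vapply(samples, `[[`, character(1), "subject_id"),
             trial = vapply(samples, `[[`, numeric(1), "trial"),
             placement = vapply(samples, `[[`, character(1), "placement"),
             kind = vapply(samples, `[[`, character(1), "kind"),
             stringsAsFactors = FALSE)
}

.check_samples <- function(samples) {
  if (length(samples) == 0L) stop("no samples to assemble")
  d <- dim(samples[[1L]]$X)
  for (s in samples)
    if (!identical(dim(s$X), d) || nrow(s$Y) != 18L || ncol(s$Y) != d[2L])
      stop("inconsistent sample dimensions; time-normalise all trials first")
  d[2L]
}

# channel-by-time matrix -> flat row, time fastest-varying within channel
.flatten_mat <- function(M) as.vector(t(M))
.unflatten_mat <- function(v, n_channels, n_points)
  matrix(v, n_channels, n_points, byrow = TRUE)

#' Assemble the flat (MLP) layout
#' @param samples list of samples from [study_samples()]
#' @return a `dataset_tensors` with `X [n, 30 * n_points]`,
#'   `Y [n, 18 * n_points]`
#' @export
assemble_flat <- function(samples) {
  npts <- .check_samples(samples)
  X <- t(vapply(samples, function(s) .flatten_mat(s$X), numeric(30L * npts)))
  Y <- t(vapply(samples, function(s) .flatten_mat(s$Y), numeric(18L * npts)))
  .new_dataset_tensors("flat", X, Y, .sample_index_df(samples), npts)
}

#' Assemble the sequence (LSTM) layout
#' @inheritParams assemble_flat
#' @return a `dataset_tensors` with `X [n, 30, n_points]`,
#'   `Y [n, 18, n_points]`
#' @export
assemble_sequence <- function(samples) {
  npts <- .check_samples(samples)
  n <- length(samples)
  X <- array(0, c(n, 30L, npts)); Y <- array(0, c(n, 18L, npts))
  for (i in seq_len(n)) { X[i, , ] <- samples[[i]]$X; Y[i, , ] <- samples[[i]]$Y }
  .new_dataset_tensors("sequence", X, Y, .sample_index_df(samples), npts)
}

#' Native image encoding of one 30-channel signal matrix
#'
#' Ten rows (5 sensors x accelerometer/gyroscope), `n_points` columns
#' (time), three colour channels (x/y/z axes). This is the image before
#' interpolation to the network input side.
#'
#' @param X 30-by-`n_points` channel matrix
#' @return array `[10, n_points, 3]`
#' @export
signal_image_native <- function(X) {
  npts <- ncol(X)
  img <- array(0, c(10L, npts, 3L))
  for (s in 1:5) for (ty in 1:2) for (ax in 1:3)
    img[(s - 1L) * 2L + ty, , ax] <- X[(s - 1L) * 6L + (ty - 1L) * 3L + ax, ]
  img
}

#' @rdname signal_image_native
#' @param img array `[10, n_points, 3]`
#' @export
signal_image_to_channels <- function(img) {
  npts <- dim(img)[2L]
  X <- matrix(0, 30L, npts)
  for (s in 1:5) for (ty in 1:2) for (ax in 1:3)
    X[(s - 1L) * 6L + (ty - 1L) * 3L + ax, ] <- img[(s - 1L) * 2L + ty, , ax]
  X
}

# bilinear resize of a matrix via separable linear interpolation
.resize_bilinear <- function(M, out_r, out_c) {
  r <- nrow(M); cc <- ncol(M)
  rows_at <- seq(1, r, length.out = out_r)
  cols_at <- seq(1, cc, length.out = out_c)
  tmp <- apply(M, 1L, function(v) stats::approx(seq_len(cc), v, xout = cols_at)$y)
  # tmp is out_c x r; interpolate across original rows
  out <- apply(tmp, 1L, function(v) stats::approx(seq_len(r), v, xout = rows_at)$y)
  # out is out_r x out_c
  out
}

#' Assemble the image (CNN) layout
#'
#' Each sample's 30-channel matrix is packed into a 10-row native RGB image
#' ([signal_image_native()]) and bilinearly interpolated to
#' `side x side x 3`. Pixel scaling to `[0, 1]` is applied by the min-max
#' scalers fitted on the training partition ([fit_scalers()]).
#'
#' @inheritParams assemble_flat
#' @param side image side length, default 224
#' @return a `dataset_tensors` with `X [n, side, side, 3]` and flat
#'   `Y [n, 18 * n_points]`
#' @export
assemble_image <- function(samples, side = 224L) {
  npts <- .check_samples(samples)
  n <- length(samples)
  X <- array(0, c(n, side, side, 3L))
  Y <- t(vapply(samples, function(s) .flatten_mat(s$Y), numeric(18L * npts)))
  for (i in seq_len(n)) {
    native <- signal_image_native(samples[[i]]$X)
    for (ch in 1:3) X[i, , , ch] <- .resize_bilinear(native[, , ch], side, side)
  }
  .new_dataset_tensors("image", X, Y, .sample_index_df(samples), npts, side = side)
}

#' Fit feature scalers on a training partition
#'
#' Flat and sequence inputs/outputs are standardised per feature (per
#' channel-time point); image inputs are min-max scaled to `[0, 1]` per
#' colour channel. Scalers must be fitted on training rows only and are
#' then applied unchanged to test data.
#'
#' @param tensors a `dataset_tensors`
#' @param rows integer row indices to fit on (the training partition);
#'   defaults to all rows
#' @return a `feature_scalers` object
#' @export
fit_scalers <- function(tensors, rows = NULL) {
  stopifnot(inherits(tensors, "dataset_tensors"))
  if (is.null(rows)) rows <- seq_len(nrow(tensors$sample_index))
  guard <- function(s) ifelse(s < 1e-12, 1, s)
  y <- tensors$Y
  if (tensors$layout == "sequence") {
    ys <- y[rows, , , drop = FALSE]
    y_center <- apply(ys, c(2L, 3L), mean)
    y_scale <- guard(apply(ys, c(2L, 3L), stats::sd))
  } else {
    ys <- y[rows, , drop = FALSE]
    y_center <- colMeans(ys)
    y_scale <- guard(apply(ys, 2L, stats::sd))
  }
  if (tensors$layout == "image") {
    xs <- tensors$X[rows, , , , drop = FALSE]
    x_min <- apply(xs, 4L, min)
    x_rng <- guard(apply(xs, 4L, max) - x_min)
    xp <- list(min = x_min, range = x_rng)
  } else if (tensors$layout == "sequence") {
    xs <- tensors$X[rows, , , drop = FALSE]
    xp <- list(center = apply(xs, c(2L, 3L), mean),
               scale = guard(apply(xs, c(2L, 3L), stats::sd)))
  } else {
    xs <- tensors$X[rows, , drop = FALSE]
    xp <- list(center = colMeans(xs), scale = guard(apply(xs, 2L, stats::sd)))
  }
  # output features constant on the training partition carry no signal;
  # the inverse transform pins them back to their constant
  y_frozen <- if (is.matrix(y_center)) {
    if (tensors$layout == "sequence")
      apply(ys, c(2L, 3L), stats::sd) < 1e-12
    else NULL
  } else apply(ys, 2L, stats::sd) < 1e-12
  structure(list(layout = tensors$layout, x = xp,
                 y = list(center = y_center, scale = y_scale,
                          frozen = y_frozen)),
            class = "feature_scalers")
}

.scale_seq <- function(A, center, scale, inverse = FALSE) {
  n <- dim(A)[1L]
  C <- aperm(array(center, c(dim(center), n)), c(3L, 1L, 2L))
  S <- aperm(array(scale, c(dim(scale), n)), c(3L, 1L, 2L))
  if (inverse) A * S + C else (A - C) / S
}

#' Apply fitted scalers to a tensor set
#'
#' @param tensors a `dataset_tensors`
#' @param scalers a `feature_scalers` from [fit_scalers()] (same layout)
#' @return the scaled `dataset_tensors` (with `scalers` recorded)
#' @export
apply_scalers <- function(tensors, scalers) {
  stopifnot(inherits(tensors, "dataset_tensors"),
            inherits(scalers, "feature_scalers"))
  if (!identical(tensors$layout, scalers$layout))
    stop("scaler layout does not match tensors")
  out <- tensors
  if (tensors$layout == "image") {
    for (ch in 1:3)
      out$X[, , , ch] <- (tensors$X[, , , ch] - scalers$x$min[ch]) / scalers$x$range[ch]
  } else if (tensors$layout == "sequence") {
    out$X <- .scale_seq(tensors$X, scalers$x$center, scalers$x$scale)
  } else {
    out$X <- sweep(sweep(tensors$X, 2L, scalers$x$center), 2L, scalers$x$scale, "/")
  }
  if (scalers$layout == "sequence") {
    out$Y <- .scale_seq(tensors$Y, scalers$y$center, scalers$y$scale)
  } else {
    out$Y <- sweep(sweep(tensors$Y, 2L, scalers$y$center), 2L, scalers$y$scale, "/")
  }
  out$scalers <- scalers
  out
}

#' Invert output scaling on predictions
#'
#' @param scalers a `feature_scalers`
#' @param Y predictions in scaled units: a matrix `[n, 18 * n_points]` for
#'   flat/image layouts or an array `[n, 18, n_points]` for sequence
#' @return predictions in original units, same shape
#' @export
invert_y_scaling <- function(scalers, Y) {
  stopifnot(inherits(scalers, "feature_scalers"))
  frozen <- scalers$y$frozen
  if (scalers$layout == "sequence") {
    stopifnot(length(dim(Y)) == 3L)
    out <- .scale_seq(Y, scalers$y$center, scalers$y$scale, inverse = TRUE)
    if (!is.null(frozen) && any(frozen)) {
      for (i in seq_len(dim(out)[1L]))
        out[i, , ][frozen] <- scalers$y$center[frozen]
    }
    out
  } else {
    out <- sweep(sweep(Y, 2L, scalers$y$scale, "*"), 2L, scalers$y$center, "+")
    if (!is.null(frozen) && any(frozen))
      out[, frozen] <- rep(scalers$y$center[frozen], each = nrow(out))
    out
  }
}

#' Subject-disjoint train/test split of assembled samples
#'
#' @param sample_index the `sample_index` data.frame of a `dataset_tensors`
#' @param test_subjects character vector of held-out subject ids
#' @param test_measured_only if `TRUE` (LOSO protocol), the test rows are
#'   only the held-out subjects' measured trials and every trial of a
#'   held-out subject (simulated or measured) is dropped from training
#' @return list with integer `train` and `test` row indices
#' @export
split_by_subject <- function(sample_index, test_subjects,
                             test_measured_only = TRUE) {
  is_test_subj <- sample_index$subject_id %in% test_subjects
  test <- if (test_measured_only)
    which(is_test_subj & sample_index$kind == "measured")
  else which(is_test_subj)
  train <- which(!is_test_subj)
  list(train = train, test = test)
}

#' Row subset of a tensor set
#' @param tensors a `dataset_tensors`
#' @param rows integer row indices
#' @return the subset `dataset_tensors`
#' @export
tensor_rows <- function(tensors, rows) {
  out <- tensors
  out$X <- switch(tensors$layout,
                  flat = tensors$X[rows, , drop = FALSE],
                  sequence = tensors$X[rows, , , drop = FALSE],
                  image = tensors$X[rows, , , , drop = FALSE])
  out$Y <- if (length(dim(tensors$Y)) == 3L) tensors$Y[rows, , , drop = FALSE]
  else tensors$Y[rows, , drop = FALSE]
  out$sample_index <- tensors$sample_index[rows, , drop = FALSE]
  out
}
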