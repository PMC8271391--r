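#' Metrics and leave-one-subject-out evaluation
#'
#' Prediction quality is reported as the root-mean-square error normalised
#' to the range of the ground-truth series (nRMSE, per trial and channel)
#' and the Pearson correlation coefficient. The LOSO protocol holds out
#' every trial of one measured-IMU subject per fold.
#'
#' @name evaluate
NULL

#' Range-normalised root-mean-square error
#'
#' `RMSE(pred, truth) / (max(truth) - min(truth))`. Undefined for constant
#' truth (returns `NA` with a warning so the caller can exclude it from
#' aggregates).
#'
#' @param pred,truth numeric vectors of equal length (>= 2)
#' @return nRMSE as a fraction (>= 0), or `NA` for constant truth
#' @export
nrmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(truth) < 2L) stop("need at least 2 points")
  rng <- max(truth) - min(truth)
  if (rng < 1e-12) {
    warning("constant truth: nRMSE undefined")
    return(NA_real_)
  }
  sqrt(mean((pred - truth)^2)) / rng
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation computed from the covariance formula.
#' Undefined (`NA` with warning) when either series has zero variance.
#'
#' @param pred,truth numeric vectors of equal length
#' @return correlation in `[-1, 1]`, or `NA` for zero-variance input
#' @export
pearson_r <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  dp <- pred - mean(pred); dt_ <- truth - mean(truth)
  vp <- sum(dp^2); vt <- sum(dt_^2)
  if (vp < 1e-24 || vt < 1e-24) {
    warning("zero-variance series: correlation undefined")
    return(NA_real_)
  }
  sum(dp * dt_) / sqrt(vp * vt)
}

.channel_meta <- function() {
  cn <- channel_names()
  parts <- do.call(rbind, strsplit(cn, "_"))
  data.frame(channel = cn, joint = parts[, 1], side = parts[, 2],
             component = parts[, 3], stringsAsFactors = FALSE)
}

#' Leave-one-subject-out evaluation of one network family
#'
#' One fold per measured-IMU subject: all trials of the held-out subject
#' (simulated and measured) are excluded from training, the scalers are
#' fitted on the fold's training rows only, and the held-out subject's
#' measured trials form the test set. Metrics are computed per channel on
#' each test trial's 101-point curve and averaged within the fold.
#'
#' @param study a `gait_study`
#' @param spec a [net_spec()]
#' @param target `"angles"` or `"moments"`
#' @param n_points normalised curve length
#' @param side image side (CNN families)
#' @param samples optional precomputed [study_samples()] list (to share
#'   preprocessing across families)
#' @param verbose print per-fold progress
#' @return a `metric_table` data.frame with columns `model`, `subject`,
#'   `channel`, `joint`, `side`, `component`, `nrmse`, `r`; the `"folds"`
#'   attribute records each fold's train/test subjects for protocol audits
#' @export
loso_run <- function(study, spec, target = "angles", n_points = 101L,
                     side = 224L, samples = NULL, verbose = FALSE) {
  stopifnot(inherits(study, "gait_study"), inherits(spec, "net_spec"))
  if (is.null(samples))
    samples <- study_samples(study, target, n_points = n_points)
  layout <- .layout_for_family(spec$family)
  tensors <- switch(layout,
                    flat = assemble_flat(samples),
                    sequence = assemble_sequence(samples),
                    image = assemble_image(samples, side = side))
  idx <- tensors$sample_index
  fold_subjects <- sort(unique(idx$subject_id[idx$kind == "measured"]))
  if (length(fold_subjects) < 2L)
    stop("LOSO needs at least 2 subjects with measured IMU trials")
  meta <- .channel_meta()
  rows <- list(); audits <- list()
  for (fi in seq_along(fold_subjects)) {
    held <- fold_subjects[fi]
    sp <- split_by_subject(idx, held)
    if (length(sp$test) == 0L) {
      warning("subject ", held, " has no measured trials; fold skipped")
      next
    }
    scalers <- fit_scalers(tensors, rows = sp$train)
    train_sc <- apply_scalers(tensor_rows(tensors, sp$train), scalers)
    test_sc <- apply_scalers(tensor_rows(tensors, sp$test), scalers)
    fold_spec <- spec
    fold_spec$seed <- spec$seed + fi
    model <- build_model(fold_spec, train_sc)
    model <- train_model(model, train_sc)
    pred <- predict_model(model, test_sc, scalers)
    truth <- test_sc$Y
    truth_orig <- if (layout == "sequence") invert_y_scaling(scalers, truth)
    else invert_y_scaling(scalers, truth)
    nr <- matrix(NA_real_, length(sp$test), 18L)
    rr <- matrix(NA_real_, length(sp$test), 18L)
    for (ti in seq_along(sp$test)) for (ch in 1:18) {
      tcurve <- if (length(dim(truth_orig)) == 3L) truth_orig[ti, ch, ]
      else .unflatten_mat(truth_orig[ti, ], 18L, tensors$n_points)[ch, ]
      pcurve <- pred[ti, ch, ]
      nr[ti, ch] <- suppressWarnings(nrmse(pcurve, tcurve))
      rr[ti, ch] <- suppressWarnings(pearson_r(pcurve, tcurve))
    }
    rows[[fi]] <- data.frame(model = spec$family, subject = held,
                             meta, nrmse = colMeans(nr, na.rm = TRUE),
                             r = colMeans(rr, na.rm = TRUE),
                             row.names = NULL)
    audits[[fi]] <- list(held_out = held,
                         train_subjects = unique(idx$subject_id[sp$train]),
                         test_rows = sp$test, train_rows = sp$train,
                         best_epoch = model$history$best_epoch)
    if (verbose)
      message(sprintf("fold %d/%d (%s): median r = %.3f", fi,
                      length(fold_subjects), held,
                      stats::median(rows[[fi]]$r, na.rm = TRUE)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", class(out))
  attr(out, "folds") <- audits
  attr(out, "target") <- target
  out
}

#' Aggregate a metric table
#'
#' Correlations are aggregated by the median, nRMSE by the mean, per
#' channel across folds.
#'
#' @param table a `metric_table`
#' @return data.frame with per-channel `mean_nrmse` and `median_r`
#' @export
aggregate_metrics <- function(table) {
  agg <- function(v, f) tapply(v, table$channel, f)
  cn <- channel_names()
  data.frame(channel = cn,
             mean_nrmse = as.numeric(agg(table$nrmse, mean)[cn]),
             median_r = as.numeric(agg(table$r, stats::median)[cn]),
             row.names = NULL)
}

#' Per-channel improvement of one model over a baseline
#'
#' `100 * (nRMSE_base - nRMSE_other) / nRMSE_base` with nRMSE first
#' averaged over folds per channel; positive values mean `other` improves
#' on `base`.
#'
#' @param base,other `metric_table`s over the same channels and subjects
#' @return data.frame with `channel`, `joint`, `side`, `component`,
#'   `improvement_pct`
#' @export
improvement_table <- function(base, other) {
  cn <- channel_names()
  if (!all(cn %in% base$channel) || !all(cn %in% other$channel))
    stop("both tables must cover all 18 channels")
  mb <- tapply(base$nrmse, base$channel, mean)[cn]
  mo <- tapply(other$nrmse, other$channel, mean)[cn]
  data.frame(.channel_meta(),
             improvement_pct = as.numeric(100 * (mb - mo) / mb),
             row.names = NULL)
}
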