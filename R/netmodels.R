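#' Network families, training and hyperparameter search
#'
#' Three regression families map the tensor layouts to joint curves: an
#' MLP on the flat layout (two hidden dense layers), an LSTM on the
#' sequence layout (two recurrent layers with a per-timestep linear head),
#' and a five-convolution-block CNN on the image layout with two dense
#' layers (`cnn_frozen_conv` keeps the seeded random convolutions fixed,
#' the structural analogue of transferring pretrained convolutional
#' weights). All are trained with Adam on mean absolute error.
#'
#' @name netmodels
NULL

#' Network hyperparameter specification
#'
#' @param family `"mlp"`, `"lstm"`, `"cnn"` or `"cnn_frozen_conv"`
#' @param layer_widths two dense widths (MLP/CNN head) or two LSTM hidden
#'   sizes
#' @param learning_rate Adam learning rate
#' @param dropout dropout fraction in `[0, 1)`
#' @param activation `"relu"` or `"tanh"` (dense layers; LSTM gates use
#'   their standard sigmoid/tanh activations regardless)
#' @param epochs maximum training epochs (default 40)
#' @param patience early-stopping horizon: stop when the validation loss
#'   has not improved for this many epochs (default 5)
#' @param batch_size minibatch size (default 64)
#' @param seed RNG seed for initialisation and batch shuffling
#' @param conv_channels five convolution widths (CNN families)
#' @return a `net_spec` object
#' @export
net_spec <- function(family = c("mlp", "lstm", "cnn", "cnn_frozen_conv"),
                     layer_widths, learning_rate = 3e-4, dropout = 0,
                     activation = c("relu", "tanh"), epochs = 40L,
                     patience = 5L, batch_size = 64L, seed = 1L,
                     conv_channels = c(96L, 256L, 384L, 384L, 256L)) {
  family <- match.arg(family)
  activation <- match.arg(activation)
  stopifnot(length(layer_widths) == 2L, all(layer_widths >= 1L),
            learning_rate > 0, dropout >= 0, dropout < 1, epochs >= 1L)
  structure(list(family = family, layer_widths = as.integer(layer_widths),
                 learning_rate = learning_rate, dropout = dropout,
                 activation = activation, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 conv_channels = as.integer(conv_channels)),
            class = "net_spec")
}

#' @export
print.net_spec <- function(x, ...) {
  cat(sprintf("<net_spec %s: widths %s, lr %g, dropout %g, %s>\n", x$family,
              paste(x$layer_widths, collapse = "-"), x$learning_rate,
              x$dropout, x$activation))
  invisible(x)
}

.layout_for_family <- function(family)
  switch(family, mlp = "flat", lstm = "sequence", "image")

#' Build an untrained model for a tensor layout
#'
#' Initialises seeded weights for the requested family. The family must
#' match the layout: MLP on flat, LSTM on sequence, CNN variants on image.
#' For `cnn_frozen_conv` the convolution and pooling parameters are
#' excluded from training, so only the dense head adapts.
#'
#' @param spec a [net_spec()]
#' @param tensors a `dataset_tensors` providing input/output shapes
#' @return a `net_model` object
#' @export
build_model <- function(spec, tensors) {
  stopifnot(inherits(spec, "net_spec"), inherits(tensors, "dataset_tensors"))
  if (!identical(tensors$layout, .layout_for_family(spec$family)))
    stop(sprintf("family '%s' requires the '%s' layout, got '%s'",
                 spec$family, .layout_for_family(spec$family), tensors$layout))
  set.seed(spec$seed)
  if (spec$family == "mlp") {
    params <- .dense_init(ncol(tensors$X), spec$layer_widths, ncol(tensors$Y))
    frozen <- character()
    conv_channels <- NULL
  } else if (spec$family == "lstm") {
    params <- .lstm_init(dim(tensors$X)[2L], spec$layer_widths,
                         dim(tensors$Y)[2L])
    frozen <- character()
    conv_channels <- NULL
  } else {
    side <- dim(tensors$X)[2L]
    if (side %% 8L != 0L) stop("image side must be divisible by 8")
    conv_channels <- spec$conv_channels
    params <- .cnn_init(side, conv_channels, spec$layer_widths, ncol(tensors$Y))
    frozen <- if (spec$family == "cnn_frozen_conv")
      grep("^conv", names(params), value = TRUE) else character()
  }
  structure(list(family = spec$family, spec = spec, params = params,
                 frozen = frozen, conv_channels = conv_channels,
                 layout = tensors$layout, n_points = tensors$n_points,
                 scalers = tensors$scalers,
                 channels_out = tensors$channels_out),
            class = "net_model")
}

#' @export
print.net_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  nt <- sum(vapply(x$params[setdiff(names(x$params), x$frozen)], length,
                   numeric(1)))
  cat(sprintf("<net_model %s on %s: %d parameters (%d trainable)>\n",
              x$family, x$layout, np, nt))
  invisible(x)
}

#' Count of (trainable) parameters
#' @param model a `net_model`
#' @param trainable_only count only parameters updated during training
#' @return integer parameter count
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  nms <- names(model$params)
  if (trainable_only) nms <- setdiff(nms, model$frozen)
  sum(vapply(model$params[nms], length, numeric(1)))
}

#' Train a model with Adam on mean absolute error
#'
#' Minimises the MAE between predictions and scaled targets with
#' minibatch Adam. Training stops early when the validation loss has not
#' improved for `spec$patience` consecutive epochs; the best-epoch weights
#' are restored. Deterministic given the spec seed and single-threaded
#' execution.
#'
#' @param model a `net_model` from [build_model()]
#' @param train,val scaled `dataset_tensors` (train/val must be
#'   subject-disjoint in the LOSO protocol)
#' @param verbose print per-epoch losses
#' @return the fitted `net_model` with a `history` element (per-epoch
#'   train/validation MAE, `stop_epoch`, `best_epoch`)
#' @export
train_model <- function(model, train, val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "net_model"))
  sp <- model$spec
  Xtr <- train$X; Ytr <- train$Y
  n <- dim(Xtr)[1L]
  set.seed(sp$seed + 1L)
  adam <- .adam_init(model$params)
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  wait <- 0L
  hist_tr <- numeric(0); hist_val <- numeric(0)
  y_is_3d <- length(dim(Ytr)) == 3L
  sub_Y <- function(Y, idx) if (y_is_3d) Y[idx, , , drop = FALSE]
  else Y[idx, , drop = FALSE]
  for (epoch in seq_len(sp$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / sp$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      Xb <- .subset_X(Xtr, bt); Yb <- sub_Y(Ytr, bt)
      fwd <- .model_forward(model, Xb, training = TRUE)
      P <- fwd$out
      ep_loss <- ep_loss + .mae(P, Yb) * length(bt)
      dOut <- sign(P - Yb) / length(P)
      grads <- .model_backward(model, fwd, dOut)
      if (any(!is.finite(unlist(lapply(grads, range)))))
        stop("non-finite gradient: training diverged (check learning rate)")
      st <- .adam_step(model$params, grads, adam, sp$learning_rate, model$frozen)
      model$params <- st$params; adam <- st$state
    }
    tr_loss <- ep_loss / n
    if (!is.finite(tr_loss)) stop("NaN training loss: training diverged")
    val_loss <- if (is.null(val)) tr_loss else {
      pv <- .model_forward(model, val$X, training = FALSE)$out
      .mae(pv, val$Y)
    }
    hist_tr <- c(hist_tr, tr_loss); hist_val <- c(hist_val, val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss, val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- model$params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > sp$patience) break
    }
  }
  model$params <- best_params
  model$history <- list(train_loss = hist_tr, val_loss = hist_val,
                        stop_epoch = length(hist_tr), best_epoch = best_epoch)
  model
}

#' Predict joint curves in original units
#'
#' Runs the model forward in evaluation mode, inverts the output scaling
#' fitted on the training partition, and reshapes every layout's output to
#' `[n, 18, n_points]`.
#'
#' @param model a fitted `net_model`
#' @param tensors scaled `dataset_tensors` to predict
#' @param scalers the `feature_scalers` used for the targets; defaults to
#'   the scalers carried by `tensors`
#' @return array `[n, 18, n_points]` in original units
#' @export
predict_model <- function(model, tensors, scalers = NULL) {
  stopifnot(inherits(model, "net_model"), inherits(tensors, "dataset_tensors"))
  scalers <- scalers %||% tensors$scalers
  if (is.null(scalers)) stop("no scalers available; scale the tensors first")
  P <- .model_forward(model, tensors$X, training = FALSE)$out
  P <- invert_y_scaling(scalers, P)
  if (length(dim(P)) == 3L) return(P)
  n <- nrow(P); npts <- model$n_points
  out <- array(0, c(n, 18L, npts))
  for (i in seq_len(n)) out[i, , ] <- .unflatten_mat(P[i, ], 18L, npts)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hyperband hyperparameter search
#'
#' Successive-halving brackets with elimination factor `eta`: each bracket
#' samples configurations from the open search space, trains them for a
#' small epoch budget, and promotes the top `1/eta` fraction to the next
#' rung with `eta` times the budget. Returns the specification with the
#' lowest validation loss; sampled values lie strictly inside the search
#' bounds, and the winner is checked against them.
#'
#' @param space list with elements `widths1`, `widths2` (integer ranges),
#'   `learning_rate` (range, sampled log-uniformly), `dropout` (range) and
#'   `activation` (character choices); ranges are `c(lower, upper)`
#' @param train,val scaled `dataset_tensors`
#' @param family network family to search
#' @param max_epochs maximum resource per configuration (hyperband R)
#' @param eta elimination factor, default 3
#' @param seed RNG seed
#' @param conv_channels convolution widths (CNN families)
#' @return the winning `net_spec`; attribute `"trajectory"` holds the
#'   per-rung evaluation log
#' @export
hyperband_search <- function(space, train, val, family = "mlp",
                             max_epochs = 9L, eta = 3L, seed = 1L,
                             conv_channels = c(8L, 8L, 8L, 8L, 8L)) {
  required <- c("widths1", "widths2", "learning_rate", "dropout", "activation")
  if (!all(required %in% names(space)))
    stop("search space must define: ", paste(required, collapse = ", "))
  if (length(space$activation) == 0L) stop("empty activation choices")
  set.seed(seed)
  sample_spec <- function() {
    w1 <- if (diff(range(space$widths1)) <= 2L) round(mean(space$widths1))
    else sample(seq(space$widths1[1] + 1L, space$widths1[2] - 1L), 1L)
    w2 <- if (diff(range(space$widths2)) <= 2L) round(mean(space$widths2))
    else sample(seq(space$widths2[1] + 1L, space$widths2[2] - 1L), 1L)
    lr_log <- stats::runif(1, log(space$learning_rate[1]), log(space$learning_rate[2]))
    dr <- stats::runif(1, space$dropout[1], space$dropout[2])
    act <- sample(space$activation, 1L)
    net_spec(family, c(w1, w2), exp(lr_log), dr, act,
             epochs = max_epochs, seed = sample(1e6, 1L),
             conv_channels = conv_channels)
  }
  eval_spec <- function(sp, budget) {
    sp$epochs <- as.integer(max(1L, round(budget)))
    sp$patience <- sp$epochs            # no early stop inside the search
    m <- build_model(sp, train)
    m <- train_model(m, train, val)
    min(m$history$val_loss)
  }
  s_max <- floor(log(max_epochs) / log(eta))
  log_rows <- list()
  best_loss <- Inf; best <- NULL
  for (s in s_max:0) {
    n_cfg <- ceiling((s_max + 1) / (s + 1) * eta^s)
    r <- max_epochs * eta^(-s)
    configs <- replicate(n_cfg, sample_spec(), simplify = FALSE)
    for (rung in 0:s) {
      budget <- r * eta^rung
      losses <- vapply(configs, eval_spec, numeric(1), budget = budget)
      for (ci in seq_along(configs))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          bracket = s, rung = rung, budget = round(budget),
          widths1 = configs[[ci]]$layer_widths[1],
          widths2 = configs[[ci]]$layer_widths[2],
          learning_rate = configs[[ci]]$learning_rate,
          dropout = configs[[ci]]$dropout,
          activation = configs[[ci]]$activation, val_loss = losses[ci])
      if (min(losses) < best_loss) {
        best_loss <- min(losses)
        best <- configs[[which.min(losses)]]
      }
      keep <- max(1L, floor(n_cfg / eta^(rung + 1)))
      if (rung < s) configs <- configs[order(losses)][seq_len(keep)]
    }
  }
  inside <- function(v, rng) v > rng[1] & v < rng[2]
  ok <- inside(best$layer_widths[1], space$widths1) &&
    inside(best$layer_widths[2], space$widths2) &&
    inside(best$learning_rate, space$learning_rate) &&
    inside(best$dropout, space$dropout)
  attr(best, "inside_bounds") <- ok
  attr(best, "trajectory") <- do.call(rbind, log_rows)
  attr(best, "val_loss") <- best_loss
  if (!ok) warning("hyperband winner lies on a search bound; widen the space")
  best$epochs <- 40L
  best$patience <- 5L
  best
}
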