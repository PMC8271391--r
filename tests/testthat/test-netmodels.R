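toy_flat <- function(n = 64, d_in = 12, d_out = 8, seed = 111, noise = 0) {
  set.seed(seed)
  A <- matrix(rnorm(d_in * d_out, 0, 0.5), d_in, d_out)
  X <- matrix(rnorm(n * d_in), n)
  Y <- X %*% A + matrix(rnorm(n * d_out, 0, noise), n)
  dt <- imugait:::.new_dataset_tensors("flat", X, Y,
    data.frame(subject_id = rep("a", n), trial = 1:n,
               placement = "own", kind = "simulated"), d_out / 2)
  sc <- fit_scalers(dt)
  apply_scalers(dt, sc)
}

test_that("model builders enforce family/layout compatibility and shapes", {
  dt <- toy_flat()
  expect_error(build_model(net_spec("lstm", c(8, 8)), dt), "layout")
  m <- build_model(net_spec("mlp", c(6000, 4000), 3e-4, 0.5, "relu"), dt)
  expect_equal(dim(m$params$fc1_W), c(12, 6000))
  expect_equal(dim(m$params$fc2_W), c(6000, 4000))

  Xs <- array(rnorm(5 * 30 * 101), c(5, 30, 101))
  Ys <- array(rnorm(5 * 18 * 101), c(5, 18, 101))
  dts <- imugait:::.new_dataset_tensors("sequence", Xs, Ys,
    data.frame(subject_id = rep("a", 5)), 101)
  ml <- build_model(net_spec("lstm", c(32, 32), 3e-4, 0.7, "tanh"), dts)
  out <- imugait:::.model_forward(ml, Xs)$out
  expect_equal(dim(out), c(5, 18, 101))
})

test_that("frozen-convolution models train only the dense head", {
  Xi <- array(rnorm(4 * 16 * 16 * 3), c(4, 16, 16, 3))
  Yi <- matrix(rnorm(4 * 10), 4)
  dti <- imugait:::.new_dataset_tensors("image", Xi, Yi,
    data.frame(subject_id = rep("a", 4)), 5)
  cc <- c(4L, 4L, 4L, 4L, 4L)
  frozen <- build_model(net_spec("cnn_frozen_conv", c(8, 6), conv_channels = cc), dti)
  full <- build_model(net_spec("cnn", c(8, 6), conv_channels = cc), dti)
  expect_equal(n_parameters(frozen), n_parameters(full))
  dense_only <- sum(vapply(full$params[grep("^fc", names(full$params))],
                           length, numeric(1)))
  expect_equal(n_parameters(frozen, trainable_only = TRUE), dense_only)
  expect_lt(n_parameters(frozen, trainable_only = TRUE), n_parameters(frozen))
  # frozen weights do not move during training
  sc <- fit_scalers(dti); dts <- apply_scalers(dti, sc)
  mf <- build_model(net_spec("cnn_frozen_conv", c(8, 6), learning_rate = 1e-2,
                             epochs = 3, batch_size = 2, conv_channels = cc), dts)
  w_before <- mf$params$conv3_W
  mf <- train_model(mf, dts)
  expect_identical(mf$params$conv3_W, w_before)
})

test_that("training reduces loss on a learnable linear mapping", {
  dt <- toy_flat(n = 96)
  spec <- net_spec("mlp", c(32, 16), learning_rate = 3e-3, dropout = 0,
                   epochs = 12, patience = 12, batch_size = 16, seed = 5)
  m <- train_model(build_model(spec, dt), dt, dt)
  h <- m$history
  expect_true(all(diff(h$train_loss[1:6]) < 0))
  # validation equal to training: no early stop on the learnable toy
  expect_equal(h$stop_epoch, 12)
  expect_lt(h$train_loss[12], 0.5 * h$train_loss[1])
})

test_that("early stopping honours the patience contract", {
  dt <- toy_flat(n = 32)
  # anti-correlated validation targets: fitting the training set can only
  # worsen the validation loss, so the first non-improving epoch comes early
  val <- dt
  val$Y <- -dt$Y
  spec <- net_spec("mlp", c(8, 8), learning_rate = 3e-3, dropout = 0,
                   epochs = 30, patience = 0, batch_size = 16, seed = 6)
  m <- train_model(build_model(spec, dt), dt, val)
  h <- m$history
  # with patience 0 training stops at the first epoch that fails to improve
  expect_lt(h$stop_epoch, 30)
  expect_true(all(diff(h$val_loss[seq_len(h$stop_epoch - 1)]) < 0))
  expect_gte(h$val_loss[h$stop_epoch], min(h$val_loss[seq_len(h$stop_epoch - 1)]))
  expect_equal(h$best_epoch, which.min(h$val_loss))
})

test_that("training is deterministic given the seed", {
  dt <- toy_flat(n = 48)
  spec <- net_spec("mlp", c(16, 8), learning_rate = 1e-3, dropout = 0.3,
                   epochs = 4, batch_size = 16, seed = 9)
  m1 <- train_model(build_model(spec, dt), dt, dt)
  m2 <- train_model(build_model(spec, dt), dt, dt)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("predictions return original units in [n, 18, npts] shape", {
  set.seed(7)
  npts <- 7
  samples <- lapply(1:12, function(i) list(
    X = matrix(rnorm(30 * npts), 30, npts), Y = matrix(rnorm(18 * npts), 18, npts),
    subject_id = "a", trial = i, placement = "own", kind = "simulated"))
  dt <- assemble_flat(samples)
  sc <- fit_scalers(dt)
  dts <- apply_scalers(dt, sc)
  spec <- net_spec("mlp", c(8, 8), epochs = 1, batch_size = 4, seed = 2)
  m <- train_model(build_model(spec, dts), dts)
  P <- predict_model(m, dts, sc)
  expect_equal(dim(P), c(12, 18, npts))
  # inverse-scaling round trip: feeding back the scaled targets recovers
  # the original-unit targets
  Yhat <- invert_y_scaling(sc, dts$Y)
  expect_equal(Yhat, dt$Y, tolerance = 1e-9)
})

test_that("hyperband returns the sane spec and stays inside bounds", {
  dt <- toy_flat(n = 60)
  space <- list(widths1 = c(4, 24), widths2 = c(4, 24),
                learning_rate = c(1e-4, 1e-1), dropout = c(0, 0.2),
                activation = "relu")
  best <- hyperband_search(space, dt, dt, family = "mlp", max_epochs = 3,
                           seed = 11)
  expect_s3_class(best, "net_spec")
  expect_true(attr(best, "inside_bounds"))
  expect_true(best$layer_widths[1] > 4 && best$layer_widths[1] < 24)
  expect_true(best$learning_rate > 1e-4 && best$learning_rate < 1e-1)
  traj <- attr(best, "trajectory")
  expect_true(all(c("bracket", "rung", "val_loss") %in% names(traj)))

  # a single-point space returns that configuration
  single <- list(widths1 = c(8, 8), widths2 = c(6, 6),
                 learning_rate = c(1e-3, 1e-3 * 1.0001), dropout = c(0, 1e-9),
                 activation = "relu")
  got <- suppressWarnings(hyperband_search(single, dt, dt, family = "mlp",
                                           max_epochs = 1, seed = 12))
  expect_equal(got$layer_widths, c(8L, 6L))

  # identical seeds give identical trajectories
  b1 <- hyperband_search(space, dt, dt, max_epochs = 3, seed = 13)
  b2 <- hyperband_search(space, dt, dt, max_epochs = 3, seed = 13)
  expect_identical(attr(b1, "trajectory"), attr(b2, "trajectory"))
  expect_error(hyperband_search(list(), dt, dt), "must define")
})

test_that("a degenerate learning rate loses the hyperband comparison", {
  dt <- toy_flat(n = 60)
  sane <- net_spec("mlp", c(16, 8), 3e-3, 0, "relu", epochs = 6, patience = 6,
                   batch_size = 16, seed = 3)
  crazy <- sane; crazy$learning_rate <- 10
  loss_of <- function(sp) {
    m <- train_model(build_model(sp, dt), dt, dt)
    min(m$history$val_loss)
  }
  l_sane <- loss_of(sane)
  l_crazy <- tryCatch(loss_of(crazy), error = function(e) Inf)
  expect_lt(l_sane, l_crazy)
})
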