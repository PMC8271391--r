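make_samples <- function(n = 6, npts = 101, seed = 101) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", 1:3), length.out = n)
  lapply(seq_len(n), function(i) list(
    X = matrix(rnorm(30 * npts), 30, npts),
    Y = matrix(rnorm(18 * npts), 18, npts),
    subject_id = subj[i], trial = i, placement = "own",
    kind = if (i %% 2 == 0) "measured" else "simulated"))
}

test_that("flat layout has the documented width and round-trips", {
  samples <- make_samples(10)
  dt <- assemble_flat(samples)
  expect_equal(dim(dt$X), c(10, 3030))
  expect_equal(dim(dt$Y), c(10, 1818))
  # un-flattening row 1 reproduces the sample matrices exactly
  expect_identical(imugait:::.unflatten_mat(dt$X[1, ], 30, 101), samples[[1]]$X)
  expect_identical(imugait:::.unflatten_mat(dt$Y[1, ], 18, 101), samples[[1]]$Y)
  expect_equal(nrow(dt$sample_index), 10)
  expect_error(assemble_flat(list()), "no samples")
  bad <- samples; bad[[2]]$X <- bad[[2]]$X[, 1:50]
  expect_error(assemble_flat(bad), "inconsistent")
})

test_that("sequence layout matches flat after flattening, bitwise", {
  samples <- make_samples(7)
  sq <- assemble_sequence(samples)
  fl <- assemble_flat(samples)
  expect_equal(dim(sq$X), c(7, 30, 101))
  expect_equal(dim(sq$Y), c(7, 18, 101))
  for (i in c(1, 4, 7)) {
    expect_identical(as.numeric(t(sq$X[i, , ])), unname(fl$X[i, ]))
    expect_identical(as.numeric(t(sq$Y[i, , ])), unname(fl$Y[i, ]))
  }
})

test_that("native image encoding maps axes to colour channels and inverts", {
  samples <- make_samples(3)
  X <- samples[[1]]$X
  img <- signal_image_native(X)
  expect_equal(dim(img), c(10, 101, 3))
  expect_identical(signal_image_to_channels(img), X)
  # signal only on x axes leaves channels 2 and 3 constant
  Xx <- matrix(0, 30, 101)
  x_rows <- seq(1, 30, by = 3)
  Xx[x_rows, ] <- rnorm(10 * 101)
  img_x <- signal_image_native(Xx)
  expect_true(all(img_x[, , 2] == 0) && all(img_x[, , 3] == 0))
  expect_false(all(img_x[, , 1] == 0))
})

test_that("image tensors are 224x224x3 and constant signals give flat images", {
  samples <- make_samples(2)
  dt <- assemble_image(samples, side = 224)
  expect_equal(dim(dt$X), c(2, 224, 224, 3))
  expect_equal(dim(dt$Y), c(2, 1818))
  const <- samples[1]
  const[[1]]$X <- matrix(5, 30, 101)
  dci <- assemble_image(const, side = 32)
  expect_lt(max(abs(dci$X - 5)), 1e-12)
})

test_that("bilinear interpolation preserves linear gradients", {
  M <- outer(seq(0, 1, length.out = 10), seq(0, 2, length.out = 101), `+`)
  R <- imugait:::.resize_bilinear(M, 224, 224)
  expect_equal(dim(R), c(224, 224))
  expect_equal(R[1, 1], M[1, 1]); expect_equal(R[224, 224], M[10, 101])
  # separable linear interpolation is exact on a bilinear surface
  expect_lt(max(abs(diff(R[, 1]) - diff(R[, 1])[1])), 1e-12)
})

test_that("standard scalers centre the training partition and invert", {
  samples <- make_samples(8)
  for (assemble in list(assemble_flat, assemble_sequence)) {
    dt <- assemble(samples)
    rows <- 1:6
    sc <- fit_scalers(dt, rows = rows)
    dts <- apply_scalers(dt, sc)
    Xs <- if (length(dim(dts$X)) == 3) matrix(dts$X[rows, , ], length(rows))
    else dts$X[rows, , drop = FALSE]
    expect_lt(max(abs(colMeans(Xs))), 1e-9)
    expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-9)
    Yb <- invert_y_scaling(sc, dts$Y)
    expect_equal(Yb, dt$Y, tolerance = 1e-9)
  }
})

test_that("image scaling maps the training range to [0,1] per colour channel", {
  samples <- make_samples(6)
  dt <- assemble_image(samples, side = 32)
  sc <- fit_scalers(dt, rows = 1:4)
  dts <- apply_scalers(dt, sc)
  for (ch in 1:3) {
    tr <- dts$X[1:4, , , ch]
    expect_equal(min(tr), 0, tolerance = 1e-12)
    expect_equal(max(tr), 1, tolerance = 1e-12)
  }
})

test_that("constant features scale to zero without division blow-ups", {
  samples <- make_samples(5)
  for (i in seq_along(samples)) samples[[i]]$X[4, ] <- 2.5
  dt <- assemble_flat(samples)
  sc <- fit_scalers(dt)
  dts <- apply_scalers(dt, sc)
  cols <- (3 * 101 + 1):(4 * 101)   # channel 4, time-major flattening
  expect_true(all(dts$X[, cols] == 0))
  expect_true(all(is.finite(dts$X)))
})

test_that("scaler statistics are independent of test-partition samples", {
  samples <- make_samples(8)
  dt <- assemble_flat(samples)
  train_rows <- which(dt$sample_index$subject_id != "S01")
  sc1 <- fit_scalers(dt, rows = train_rows)
  # perturb the held-out subject's rows: scalers must not change
  dt2 <- dt
  test_rows <- setdiff(seq_len(8), train_rows)
  dt2$X[test_rows, ] <- dt2$X[test_rows, ] + 100
  dt2$Y[test_rows, ] <- dt2$Y[test_rows, ] * -3
  sc2 <- fit_scalers(dt2, rows = train_rows)
  expect_identical(sc1, sc2)
})

test_that("subject split honours the LOSO protocol", {
  samples <- make_samples(12)
  dt <- assemble_flat(samples)
  sp <- split_by_subject(dt$sample_index, "S02")
  expect_false(any(dt$sample_index$subject_id[sp$train] == "S02"))
  expect_true(all(dt$sample_index$subject_id[sp$test] == "S02"))
  expect_true(all(dt$sample_index$kind[sp$test] == "measured"))
})
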