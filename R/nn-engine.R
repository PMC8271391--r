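# Internal neural-network engine: dense, LSTM and convolutional forward /
# backward passes with Adam updates and mean-absolute-error loss. Written
# in plain matrix algebra; all randomness flows through the R RNG so runs
# are reproducible given a seed and single-threaded BLAS.

.relu <- function(x) pmax(x, 0)
.sigm <- function(x) 1 / (1 + exp(-x))

.act_fun <- function(name) switch(name, relu = .relu, tanh = tanh,
                                  stop("unknown activation: ", name))
.act_grad <- function(name, pre, post) switch(name,
  relu = (pre > 0) * 1, tanh = 1 - post^2, stop("unknown activation: ", name))

.glorot <- function(fan_in, fan_out)
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)

.he <- function(fan_in, fan_out)
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, frozen = character(),
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% frozen || is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- dense head (shared by MLP and CNN) ------------------------------------

.dense_init <- function(d_in, widths, d_out, prefix = "fc") {
  p <- list()
  dims <- c(d_in, widths)
  for (i in seq_along(widths)) {
    p[[paste0(prefix, i, "_W")]] <- .he(dims[i], dims[i + 1])
    p[[paste0(prefix, i, "_b")]] <- numeric(widths[i])
  }
  p[[paste0(prefix, "out_W")]] <- .glorot(dims[length(dims)], d_out)
  p[[paste0(prefix, "out_b")]] <- numeric(d_out)
  p
}

.dense_forward <- function(params, X, widths, activation, dropout, training,
                           prefix = "fc") {
  act <- .act_fun(activation)
  cache <- list(H = list(X), pre = list(), mask = list())
  H <- X
  for (i in seq_along(widths)) {
    pre <- sweep(H %*% params[[paste0(prefix, i, "_W")]], 2L,
                 params[[paste0(prefix, i, "_b")]], "+")
    H <- act(pre)
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(H), 1L, 1 - dropout), nrow(H)) / (1 - dropout)
      H <- H * mask
      cache$mask[[i]] <- mask
    }
    cache$pre[[i]] <- pre
    cache$H[[i + 1L]] <- H
  }
  out <- sweep(H %*% params[[paste0(prefix, "out_W")]], 2L,
               params[[paste0(prefix, "out_b")]], "+")
  list(out = out, cache = cache)
}

.dense_backward <- function(params, cache, dOut, widths, activation,
                            prefix = "fc") {
  grads <- list()
  H_last <- cache$H[[length(widths) + 1L]]
  grads[[paste0(prefix, "out_W")]] <- t(H_last) %*% dOut
  grads[[paste0(prefix, "out_b")]] <- colSums(dOut)
  dH <- dOut %*% t(params[[paste0(prefix, "out_W")]])
  for (i in rev(seq_along(widths))) {
    if (length(cache$mask) >= i && !is.null(cache$mask[[i]]))
      dH <- dH * cache$mask[[i]]
    dpre <- dH * .act_grad(activation, cache$pre[[i]],
                           tanh(cache$pre[[i]]))
    grads[[paste0(prefix, i, "_W")]] <- t(cache$H[[i]]) %*% dpre
    grads[[paste0(prefix, i, "_b")]] <- colSums(dpre)
    dH <- dpre %*% t(params[[paste0(prefix, i, "_W")]])
  }
  list(grads = grads, dX = dH)
}

# ---- LSTM ------------------------------------------------------------------

.lstm_init <- function(d_in, hidden, d_out) {
  p <- list()
  dims <- c(d_in, hidden)
  for (l in seq_along(hidden)) {
    h <- hidden[l]
    p[[paste0("l", l, "_Wx")]] <- .glorot(dims[l], 4L * h)
    p[[paste0("l", l, "_Wh")]] <- .glorot(h, 4L * h)
    b <- numeric(4L * h)
    b[(h + 1L):(2L * h)] <- 1        # forget-gate bias
    p[[paste0("l", l, "_b")]] <- b
  }
  p[["out_W"]] <- .glorot(hidden[length(hidden)], d_out)
  p[["out_b"]] <- numeric(d_out)
  p
}

# X: [n, C, T]; returns per-timestep outputs [n, d_out, T] plus caches
.lstm_forward <- function(params, X, hidden, dropout, training) {
  n <- dim(X)[1L]; TT <- dim(X)[3L]
  layers <- length(hidden)
  caches <- vector("list", layers)
  inp <- lapply(seq_len(TT), function(t) X[, , t, drop = FALSE][, , 1L, drop = TRUE])
  if (n == 1L) inp <- lapply(inp, function(v) matrix(v, 1L))
  masks <- vector("list", layers)
  for (l in seq_len(layers)) {
    h <- hidden[l]
    Wx <- params[[paste0("l", l, "_Wx")]]
    Wh <- params[[paste0("l", l, "_Wh")]]
    b <- params[[paste0("l", l, "_b")]]
    Hm <- matrix(0, n, h); Cm <- matrix(0, n, h)
    cache <- vector("list", TT)
    outs <- vector("list", TT)
    for (t in seq_len(TT)) {
      z <- sweep(inp[[t]] %*% Wx + Hm %*% Wh, 2L, b, "+")
      i_g <- .sigm(z[, 1:h, drop = FALSE])
      f_g <- .sigm(z[, (h + 1):(2 * h), drop = FALSE])
      g_g <- tanh(z[, (2 * h + 1):(3 * h), drop = FALSE])
      o_g <- .sigm(z[, (3 * h + 1):(4 * h), drop = FALSE])
      C_new <- f_g * Cm + i_g * g_g
      tc <- tanh(C_new)
      H_new <- o_g * tc
      cache[[t]] <- list(x = inp[[t]], h_prev = Hm, c_prev = Cm, i = i_g,
                         f = f_g, g = g_g, o = o_g, c = C_new, tc = tc)
      Hm <- H_new; Cm <- C_new
      outs[[t]] <- H_new
    }
    if (training && dropout > 0) {
      mask <- matrix(stats::rbinom(n * h, 1L, 1 - dropout), n) / (1 - dropout)
      outs <- lapply(outs, function(H) H * mask)
      masks[[l]] <- mask
    }
    caches[[l]] <- cache
    inp <- outs
  }
  d_out <- length(params$out_b)
  Y <- array(0, c(n, d_out, TT))
  for (t in seq_len(TT))
    Y[, , t] <- sweep(inp[[t]] %*% params$out_W, 2L, params$out_b, "+")
  list(out = Y, caches = caches, masks = masks, top = inp)
}

.lstm_backward <- function(params, fwd, dY, hidden) {
  n <- dim(dY)[1L]; TT <- dim(dY)[3L]
  layers <- length(hidden)
  grads <- list(out_W = params$out_W * 0, out_b = params$out_b * 0)
  dTop <- vector("list", TT)
  for (t in seq_len(TT)) {
    d <- dY[, , t, drop = FALSE][, , 1L, drop = TRUE]
    if (n == 1L) d <- matrix(d, 1L)
    grads$out_W <- grads$out_W + t(fwd$top[[t]]) %*% d
    grads$out_b <- grads$out_b + colSums(d)
    dTop[[t]] <- d %*% t(params$out_W)
  }
  dOutLayer <- dTop
  for (l in rev(seq_len(layers))) {
    h <- hidden[l]
    Wx <- params[[paste0("l", l, "_Wx")]]
    Wh <- params[[paste0("l", l, "_Wh")]]
    cache <- fwd$caches[[l]]
    gWx <- Wx * 0; gWh <- Wh * 0; gb <- numeric(4L * h)
    dH_next <- matrix(0, n, h); dC_next <- matrix(0, n, h)
    dX <- vector("list", TT)
    mask <- fwd$masks[[l]]
    for (t in rev(seq_len(TT))) {
      dH <- dOutLayer[[t]]
      if (!is.null(mask)) dH <- dH * mask
      dH <- dH + dH_next
      cc <- cache[[t]]
      dC <- dC_next + dH * cc$o * (1 - cc$tc^2)
      d_o <- dH * cc$tc * cc$o * (1 - cc$o)
      d_f <- dC * cc$c_prev * cc$f * (1 - cc$f)
      d_i <- dC * cc$g * cc$i * (1 - cc$i)
      d_g <- dC * cc$i * (1 - cc$g^2)
      dz <- cbind(d_i, d_f, d_g, d_o)
      gWx <- gWx + t(cc$x) %*% dz
      gWh <- gWh + t(cc$h_prev) %*% dz
      gb <- gb + colSums(dz)
      dX[[t]] <- dz %*% t(Wx)
      dH_next <- dz %*% t(Wh)
      dC_next <- dC * cc$f
    }
    grads[[paste0("l", l, "_Wx")]] <- gWx
    grads[[paste0("l", l, "_Wh")]] <- gWh
    grads[[paste0("l", l, "_b")]] <- gb
    dOutLayer <- dX
  }
  grads
}

# ---- convolution (3x3, pad 1) and 2x2 max pooling --------------------------

.im2col3 <- function(X) {
  d <- dim(X)                        # n, H, W, C
  n <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  Xp <- array(0, c(n, H + 2L, W + 2L, C))
  Xp[, 2:(H + 1L), 2:(W + 1L), ] <- X
  cols <- matrix(0, n * H * W, 9L * C)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    sl <- Xp[, (1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE]
    dim(sl) <- c(n * H * W, C)
    cols[, (k * C + 1L):((k + 1L) * C)] <- sl
    k <- k + 1L
  }
  cols
}

.col2im3 <- function(dcols, n, H, W, C) {
  dXp <- array(0, c(n, H + 2L, W + 2L, C))
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    sl <- dcols[, (k * C + 1L):((k + 1L) * C), drop = FALSE]
    dim(sl) <- c(n, H, W, C)
    dXp[, (1L + di):(H + di), (1L + dj):(W + dj), ] <-
      dXp[, (1L + di):(H + di), (1L + dj):(W + dj), , drop = FALSE] + sl
    k <- k + 1L
  }
  dXp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

.conv_forward <- function(X, W, b) {
  d <- dim(X)
  cols <- .im2col3(X)
  Y <- sweep(cols %*% W, 2L, b, "+")
  dim(Y) <- c(d[1L], d[2L], d[3L], length(b))
  list(out = Y, cols = cols)
}

.conv_backward <- function(dY, cols, W, n, H, Wd, C_in) {
  d2 <- dY
  dim(d2) <- c(n * H * Wd, ncol(W))
  list(dW = t(cols) %*% d2, db = colSums(d2),
       dX = .col2im3(d2 %*% t(W), n, H, Wd, C_in))
}

.maxpool_forward <- function(X) {
  d <- dim(X)
  n <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  ri <- seq(1L, H - 1L, by = 2L); ci <- seq(1L, W - 1L, by = 2L)
  A <- list(X[, ri, ci, , drop = FALSE], X[, ri + 1L, ci, , drop = FALSE],
            X[, ri, ci + 1L, , drop = FALSE], X[, ri + 1L, ci + 1L, , drop = FALSE])
  out <- pmax(A[[1]], A[[2]], A[[3]], A[[4]])
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    m <- (A[[k]] == out) & !taken
    taken <- taken | m
    masks[[k]] <- m
  }
  list(out = out, masks = masks, in_dim = d)
}

.maxpool_backward <- function(dOut, pool) {
  d <- pool$in_dim
  H <- d[2L]; W <- d[3L]
  ri <- seq(1L, H - 1L, by = 2L); ci <- seq(1L, W - 1L, by = 2L)
  dX <- array(0, d)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    o <- offs[[k]]
    dX[, ri + o[1L], ci + o[2L], ] <- dOut * pool$masks[[k]]
  }
  dX
}

# classic five-block image-classification schedule: which conv layers are
# followed by 2x2 max pooling
.cnn_pool_after <- c(TRUE, TRUE, FALSE, FALSE, TRUE)

.cnn_spatial_out <- function(side) side / 8L   # three 2x2 pools

.cnn_init <- function(side, conv_channels, widths, d_out) {
  stopifnot(length(conv_channels) == 5L, side %% 8L == 0L)
  p <- list()
  C_in <- 3L
  for (l in 1:5) {
    p[[paste0("conv", l, "_W")]] <- .he(9L * C_in, conv_channels[l])
    p[[paste0("conv", l, "_b")]] <- numeric(conv_channels[l])
    C_in <- conv_channels[l]
  }
  flat <- .cnn_spatial_out(side)^2 * conv_channels[5L]
  c(p, .dense_init(flat, widths, d_out))
}

.cnn_forward <- function(params, X, conv_channels, widths, activation,
                         dropout, training) {
  cache <- list(conv = vector("list", 5L), pool = vector("list", 5L),
                pre = vector("list", 5L), in_dim = vector("list", 5L))
  A <- X
  for (l in 1:5) {
    cache$in_dim[[l]] <- dim(A)
    cv <- .conv_forward(A, params[[paste0("conv", l, "_W")]],
                        params[[paste0("conv", l, "_b")]])
    cache$conv[[l]] <- cv$cols
    cache$pre[[l]] <- cv$out
    A <- .relu(cv$out)
    if (.cnn_pool_after[l]) {
      pl <- .maxpool_forward(A)
      cache$pool[[l]] <- pl
      A <- pl$out
    }
  }
  cache$flat_dim <- dim(A)
  Af <- A; dim(Af) <- c(dim(A)[1L], prod(dim(A)[-1L]))
  dn <- .dense_forward(params, Af, widths, activation, dropout, training)
  list(out = dn$out, cache = cache, dense_cache = dn$cache)
}

.cnn_backward <- function(params, fwd, dOut, conv_channels, widths,
                          activation) {
  bk <- .dense_backward(params, fwd$dense_cache, dOut, widths, activation)
  grads <- bk$grads
  dA <- bk$dX
  dim(dA) <- fwd$cache$flat_dim
  for (l in 5:1) {
    if (.cnn_pool_after[l]) dA <- .maxpool_backward(dA, fwd$cache$pool[[l]])
    dA <- dA * (fwd$cache$pre[[l]] > 0)
    ind <- fwd$cache$in_dim[[l]]
    cb <- .conv_backward(dA, fwd$cache$conv[[l]], params[[paste0("conv", l, "_W")]],
                         ind[1L], ind[2L], ind[3L], ind[4L])
    grads[[paste0("conv", l, "_W")]] <- cb$dW
    grads[[paste0("conv", l, "_b")]] <- cb$db
    dA <- cb$dX
  }
  grads
}

# ---- shared forward/backward dispatch --------------------------------------

.model_forward <- function(model, X, training = FALSE) {
  sp <- model$spec
  switch(model$family,
    mlp = .dense_forward(model$params, X, sp$layer_widths, sp$activation,
                         sp$dropout, training),
    lstm = .lstm_forward(model$params, X, sp$layer_widths, sp$dropout, training),
    cnn = ,
    cnn_frozen_conv = .cnn_forward(model$params, X, model$conv_channels,
                                   sp$layer_widths, sp$activation, sp$dropout,
                                   training))
}

.model_backward <- function(model, fwd, dOut) {
  sp <- model$spec
  switch(model$family,
    mlp = .dense_backward(model$params, fwd$cache, dOut, sp$layer_widths,
                          sp$activation)$grads,
    lstm = .lstm_backward(model$params, fwd, dOut, sp$layer_widths),
    cnn = ,
    cnn_frozen_conv = .cnn_backward(model$params, fwd, dOut,
                                    model$conv_channels, sp$layer_widths,
                                    sp$activation))
}

.subset_X <- function(X, idx) {
  nd <- length(dim(X))
  if (is.null(dim(X))) X[idx]
  else if (nd == 2L) X[idx, , drop = FALSE]
  else if (nd == 3L) X[idx, , , drop = FALSE]
  else X[idx, , , , drop = FALSE]
}

.mae <- function(P, Y) mean(abs(P - Y))
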