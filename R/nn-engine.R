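# Minimal neural-network engine: exactly the layers the fall classifier
# needs (time-axis convolution over a 6-row feature map, batch norm, ReLU,
# time-axis max pooling, flatten, dense, dropout, bidirectional LSTM), with
# hand-written backpropagation and Adam. Feature maps are stored as
# [N*6, T, C] arrays with row index i = (n-1)*6 + r (r = motion channel);
# vector activations are N x D matrices.

glorot_mat <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

nn_layer <- function(type, params = list(), meta = list(), l2_params = character(0)) {
  list(type = type, params = params, meta = meta, l2_params = l2_params)
}

# ---- layer constructors -----------------------------------------------------

make_conv_time <- function(k, in_ch, filters) {
  nn_layer("conv_time",
           params = list(W = glorot_mat(k * in_ch, filters), b = numeric(filters)),
           meta = list(k = k, in_ch = in_ch, filters = filters),
           l2_params = "W")
}

make_batchnorm <- function(ch, momentum = 0.9, eps = 1e-5) {
  nn_layer("batchnorm",
           params = list(gamma = rep(1, ch), beta = rep(0, ch)),
           meta = list(ch = ch, momentum = momentum, eps = eps,
                       run_mean = rep(0, ch), run_var = rep(1, ch)))
}

make_dense <- function(d_in, d_out) {
  nn_layer("dense", params = list(W = glorot_mat(d_in, d_out), b = numeric(d_out)),
           meta = list(d_in = d_in, d_out = d_out), l2_params = "W")
}

make_bilstm <- function(d_in, units) {
  one_dir <- function() list(Wx = glorot_mat(d_in, 4 * units),
                             Wh = glorot_mat(units, 4 * units),
                             b = rep(c(0, 1, 0, 0), each = units))  # forget bias 1
  fw <- one_dir(); bw <- one_dir()
  nn_layer("bilstm",
           params = list(Wx_f = fw$Wx, Wh_f = fw$Wh, b_f = fw$b,
                         Wx_b = bw$Wx, Wh_b = bw$Wh, b_b = bw$b),
           meta = list(d_in = d_in, units = units),
           l2_params = c("Wx_f", "Wh_f", "Wx_b", "Wh_b"))
}

# ---- map <-> vector reshapes ------------------------------------------------

# [6, T, N] window array -> [N*6, T, 1] feature map
windows_to_map <- function(X) {
  d <- dim(X)  # 6, T, N
  A <- aperm(X, c(1, 3, 2))          # 6, N, T (vector order r, n, t)
  dim(A) <- c(d[1] * d[3], d[2], 1L) # i = (n-1)*6 + r
  A
}

map_to_vec <- function(A, n_rows = 6L) {
  d <- dim(A)  # N6, T, C
  N <- d[1] / n_rows
  dim(A) <- c(n_rows, N, d[2], d[3])
  A <- aperm(A, c(2, 1, 3, 4))
  dim(A) <- c(N, n_rows * d[2] * d[3])
  A
}

vec_to_map <- function(V, T_len, C, n_rows = 6L) {
  N <- nrow(V)
  dim(V) <- c(N, n_rows, T_len, C)
  V <- aperm(V, c(2, 1, 3, 4))
  dim(V) <- c(n_rows * N, T_len, C)
  V
}

# time slice t of a map as an N x (6*C) matrix
map_slice_to_vec <- function(A, t, n_rows = 6L) {
  d <- dim(A)
  M <- A[, t, , drop = FALSE]
  dim(M) <- c(d[1], d[3])
  map_to_vec(array(M, c(d[1], 1L, d[3])), n_rows)
}

# ---- forward / backward per layer ------------------------------------------

im2col_time <- function(A, k) {
  d <- dim(A)  # N6, T, C
  T_out <- d[2] - k + 1L
  X2 <- matrix(0, d[1] * T_out, k * d[3])
  for (off in seq_len(k)) {
    blk <- A[, off:(off + T_out - 1L), , drop = FALSE]
    dim(blk) <- c(d[1] * T_out, d[3])
    X2[, (seq_len(d[3]) - 1L) * k + off] <- blk
  }
  X2
}

conv_time_fwd <- function(layer, A) {
  k <- layer$meta$k
  d <- dim(A)
  T_out <- d[2] - k + 1L
  X2 <- im2col_time(A, k)
  out2 <- X2 %*% layer$params$W
  out2 <- sweep(out2, 2, layer$params$b, "+")
  out <- array(out2, c(d[1], T_out, layer$meta$filters))
  list(out = out, cache = list(X2 = X2, in_dim = d, T_out = T_out))
}

conv_time_bwd <- function(layer, cache, dout) {
  k <- layer$meta$k; d <- cache$in_dim; T_out <- cache$T_out
  dout2 <- dout; dim(dout2) <- c(d[1] * T_out, layer$meta$filters)
  dW <- crossprod(cache$X2, dout2)
  db <- colSums(dout2)
  dX2 <- tcrossprod(dout2, layer$params$W)
  dA <- array(0, d)
  for (off in seq_len(k)) {
    blk <- dX2[, (seq_len(d[3]) - 1L) * k + off, drop = FALSE]
    dim(blk) <- c(d[1], T_out, d[3])
    dA[, off:(off + T_out - 1L), ] <- dA[, off:(off + T_out - 1L), , drop = FALSE] + blk
  }
  list(din = dA, grads = list(W = dW, b = db))
}

batchnorm_fwd <- function(layer, A, training) {
  d <- dim(A)
  x2 <- A; dim(x2) <- c(d[1] * d[2], d[3])
  eps <- layer$meta$eps
  if (training) {
    mu <- colMeans(x2)
    v <- colMeans(x2^2) - mu^2
    m <- nrow(x2)
    layer$meta$run_mean <- layer$meta$momentum * layer$meta$run_mean + (1 - layer$meta$momentum) * mu
    layer$meta$run_var <- layer$meta$momentum * layer$meta$run_var +
      (1 - layer$meta$momentum) * v * m / max(1, m - 1)
  } else {
    mu <- layer$meta$run_mean
    v <- layer$meta$run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x2, 2, mu, "-"), 2, istd, "*")
  out2 <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  out <- array(out2, d)
  list(out = out, cache = list(xhat = xhat, istd = istd, dims = d, training = training),
       layer = layer)
}

batchnorm_bwd <- function(layer, cache, dout) {
  d <- cache$dims
  dy <- dout; dim(dy) <- c(d[1] * d[2], d[3])
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    t1 <- sweep(dy, 2, dbeta / m, "-")
    t2 <- sweep(cache$xhat, 2, dgamma / m, "*")
    dx <- sweep(t1 - t2, 2, layer$params$gamma * cache$istd, "*")
  } else {
    dx <- sweep(dy, 2, layer$params$gamma * cache$istd, "*")
  }
  dim(dx) <- d
  list(din = dx, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(A) {
  mask <- A > 0
  A[!mask] <- 0
  list(out = A, cache = mask)
}

pool_time_fwd <- function(A, p) {
  d <- dim(A)
  T_out <- d[2] %/% p
  idx1 <- p * (seq_len(T_out) - 1L) + 1L
  cur <- A[, idx1, , drop = FALSE]
  arg <- array(1L, dim(cur))
  if (p > 1) {
    for (off in 2:p) {
      cand <- A[, idx1 + off - 1L, , drop = FALSE]
      upd <- cand > cur
      cur[upd] <- cand[upd]
      arg[upd] <- off
    }
  }
  list(out = cur, cache = list(arg = arg, in_dim = d, T_out = T_out, p = p))
}

pool_time_bwd <- function(cache, dout) {
  dA <- array(0, cache$in_dim)
  idx1 <- cache$p * (seq_len(cache$T_out) - 1L) + 1L
  for (off in seq_len(cache$p)) {
    sel <- (cache$arg == off) * dout
    dA[, idx1 + off - 1L, ] <- sel
  }
  dA
}

dense_fwd <- function(layer, V) {
  out <- sweep(V %*% layer$params$W, 2, layer$params$b, "+")
  list(out = out, cache = V)
}

dense_bwd <- function(layer, cache, dout) {
  list(din = tcrossprod(dout, layer$params$W),
       grads = list(W = crossprod(cache, dout), b = colSums(dout)))
}

dropout_fwd <- function(V, rate, training) {
  if (!training || rate <= 0) return(list(out = V, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(runif(length(V)), nrow(V)) < keep) / keep
  list(out = V * mask, cache = mask)
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_dir_fwd <- function(xs, Wx, Wh, b, reverse = FALSE) {
  T_len <- length(xs)
  N <- nrow(xs[[1]])
  Hn <- ncol(Wh)
  H <- Hn / 4L
  order_t <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  cache <- vector("list", T_len)
  for (s in seq_len(T_len)) {
    t <- order_t[s]
    a <- sweep(xs[[t]] %*% Wx + h %*% Wh, 2, b, "+")
    i <- sigm(a[, 1:H, drop = FALSE])
    f <- sigm(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[s]] <- list(t = t, x = xs[[t]], i = i, f = f, g = g, o = o,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h_last = h, cache = cache)
}

lstm_dir_bwd <- function(dh_last, cache, Wx, Wh) {
  T_len <- length(cache)
  H <- ncol(dh_last)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * H)
  dxs <- vector("list", T_len)
  dh <- dh_last
  dc <- matrix(0, nrow(dh), H)
  for (s in rev(seq_len(T_len))) {
    cs <- cache[[s]]
    do_ <- dh * cs$tc
    dc <- dc + dh * cs$o * (1 - cs$tc^2)
    di <- dc * cs$g
    dg <- dc * cs$i
    df <- dc * cs$c_prev
    dc <- dc * cs$f
    da <- cbind(di * cs$i * (1 - cs$i),
                df * cs$f * (1 - cs$f),
                dg * (1 - cs$g^2),
                do_ * cs$o * (1 - cs$o))
    dWx <- dWx + crossprod(cs$x, da)
    dWh <- dWh + crossprod(cs$h_prev, da)
    db <- db + colSums(da)
    dxs[[cs$t]] <- tcrossprod(da, Wx)
    dh <- tcrossprod(da, Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

bilstm_fwd <- function(layer, A) {
  d <- dim(A)
  T_len <- d[2]
  xs <- lapply(seq_len(T_len), function(t) map_slice_to_vec(A, t))
  fw <- lstm_dir_fwd(xs, layer$params$Wx_f, layer$params$Wh_f, layer$params$b_f, FALSE)
  bw <- lstm_dir_fwd(xs, layer$params$Wx_b, layer$params$Wh_b, layer$params$b_b, TRUE)
  list(out = cbind(fw$h_last, bw$h_last),
       cache = list(fw = fw$cache, bw = bw$cache, in_dim = d, T_len = T_len))
}

bilstm_bwd <- function(layer, cache, dout) {
  H <- layer$meta$units
  bf <- lstm_dir_bwd(dout[, 1:H, drop = FALSE], cache$fw,
                     layer$params$Wx_f, layer$params$Wh_f)
  bb <- lstm_dir_bwd(dout[, (H + 1):(2 * H), drop = FALSE], cache$bw,
                     layer$params$Wx_b, layer$params$Wh_b)
  d <- cache$in_dim
  dA <- array(0, d)
  for (t in seq_len(cache$T_len)) {
    dv <- bf$dxs[[t]] + bb$dxs[[t]]        # N x (6*C)
    dA[, t, ] <- vec_to_map(dv, 1L, d[3])[, 1, ]
  }
  list(din = dA,
       grads = list(Wx_f = bf$dWx, Wh_f = bf$dWh, b_f = bf$db,
                    Wx_b = bb$dWx, Wh_b = bb$dWh, b_b = bb$db))
}

# Hybrid head: the BiLSTM is *added* to the stack — its final hidden states
# are concatenated with the flattened conv features before the dense head.
flatten_bilstm_fwd <- function(layer, A) {
  V1 <- map_to_vec(A)
  bl <- bilstm_fwd(layer, A)
  list(out = cbind(V1, bl$out),
       cache = list(bl = bl$cache, d1 = ncol(V1), in_dim = dim(A)))
}

flatten_bilstm_bwd <- function(layer, cache, dout) {
  d1 <- cache$d1
  dV1 <- dout[, seq_len(d1), drop = FALSE]
  dB <- dout[, (d1 + 1):ncol(dout), drop = FALSE]
  res <- bilstm_bwd(layer, cache$bl, dB)
  din <- res$din + vec_to_map(dV1, cache$in_dim[2], cache$in_dim[3])
  list(din = din, grads = res$grads)
}

# ---- whole-network forward/backward ----------------------------------------

# Forward through the layer stack. Returns logits, per-layer caches, and the
# (possibly updated, for batch-norm running stats) layers.
nn_forward <- function(layers, X, training = FALSE) {
  cur <- windows_to_map(X)
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    res <- switch(ly$type,
      conv_time = conv_time_fwd(ly, cur),
      batchnorm = {
        r <- batchnorm_fwd(ly, cur, training)
        layers[[l]] <- r$layer
        r
      },
      relu = relu_fwd(cur),
      pool_time = pool_time_fwd(cur, ly$meta$p),
      flatten = list(out = map_to_vec(cur), cache = dim(cur)),
      bilstm = bilstm_fwd(ly, cur),
      flatten_bilstm = flatten_bilstm_fwd(ly, cur),
      dense = dense_fwd(ly, cur),
      dropout = dropout_fwd(cur, ly$meta$rate, training),
      stop("unknown layer type: ", ly$type))
    caches[[l]] <- res$cache
    cur <- res$out
  }
  list(logits = cur, caches = caches, layers = layers)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss with L2 penalty; returns loss, probabilities and
# per-layer gradient lists.
nn_loss_grads <- function(layers, X, y_int, l2 = 0, training = TRUE) {
  fwd <- nn_forward(layers, X, training)
  probs <- softmax_rows(fwd$logits)
  N <- nrow(probs)
  p_true <- probs[cbind(seq_len(N), y_int + 1L)]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  onehot <- matrix(0, N, 2)
  onehot[cbind(seq_len(N), y_int + 1L)] <- 1
  dcur <- (probs - onehot) / N
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    ly <- fwd$layers[[l]]
    cache <- fwd$caches[[l]]
    res <- switch(ly$type,
      conv_time = conv_time_bwd(ly, cache, dcur),
      batchnorm = batchnorm_bwd(ly, cache, dcur),
      relu = list(din = dcur * cache, grads = NULL),
      pool_time = list(din = pool_time_bwd(cache, dcur), grads = NULL),
      flatten = list(din = vec_to_map(dcur, cache[2], cache[3]), grads = NULL),
      bilstm = bilstm_bwd(ly, cache, dcur),
      flatten_bilstm = flatten_bilstm_bwd(ly, cache, dcur),
      dense = dense_bwd(ly, cache, dcur),
      dropout = list(din = if (is.null(cache)) dcur else dcur * cache, grads = NULL))
    if (!is.null(res$grads) && l2 > 0) {
      for (pn in ly$l2_params) {
        res$grads[[pn]] <- res$grads[[pn]] + l2 * ly$params[[pn]]
        loss <- loss + 0.5 * l2 * sum(ly$params[[pn]]^2)
      }
    }
    grads[l] <- list(res$grads)  # [[<-]] with NULL would drop the element
    dcur <- res$din
  }
  list(loss = loss, probs = probs, grads = grads, layers = fwd$layers)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (length(ly$params) == 0) return(NULL)
    list(m = lapply(ly$params, function(p) p * 0),
         v = lapply(ly$params, function(p) p * 0))
  })
}

adam_step <- function(layers, grads, state, step, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (pn in names(g)) {
      state[[l]]$m[[pn]] <- beta1 * state[[l]]$m[[pn]] + (1 - beta1) * g[[pn]]
      state[[l]]$v[[pn]] <- beta2 * state[[l]]$v[[pn]] + (1 - beta2) * g[[pn]]^2
      mhat <- state[[l]]$m[[pn]] / bc1
      vhat <- state[[l]]$v[[pn]] / bc2
      layers[[l]]$params[[pn]] <- layers[[l]]$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

nn_count_params <- function(layers) {
  sum(vapply(layers, function(ly) sum(vapply(ly$params, length, integer(1))), numeric(1)))
}
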