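# Building blocks for the network: batched stride-1 same-padded convolution
# (via im2col), same-padded max pooling, bidirectional LSTM blocks, and the
# Adam optimizer. Forward functions cache what their backward pass needs.

rev_time <- function(a) a[, , dim(a)[3]:1, drop = FALSE]

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# --- convolution ------------------------------------------------------------

# x: [H, W, Din, B]; W_: [kh*kw*Din, F]; returns relu(conv) activations
# [H, W, F, B] plus caches for backward.
conv_relu_fwd <- function(x, W_, b_, kh, kw, need_cache = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; B <- d[4]
  F_ <- length(b_)
  out <- array(0, c(H, W, F_, B))
  for (bb in seq_len(B)) {
    cols <- im2col_same(array(x[, , , bb], d[1:3]), kh, kw)
    z <- cols %*% W_
    z <- sweep(z, 2, b_, "+")
    out[, , , bb] <- array(pmax(z, 0), c(H, W, F_))
  }
  list(out = out, x = if (need_cache) x else NULL,
       mask = if (need_cache) out > 0 else NULL)
}

conv_relu_bwd <- function(cache, dout, W_, kh, kw) {
  x <- cache$x
  d <- dim(x)
  H <- d[1]; W <- d[2]; Din <- d[3]; B <- d[4]
  F_ <- ncol(W_)
  dout <- dout * cache$mask
  dx <- array(0, d)
  dW <- matrix(0, nrow(W_), F_)
  db <- numeric(F_)
  for (bb in seq_len(B)) {
    cols <- im2col_same(array(x[, , , bb], d[1:3]), kh, kw)
    dz <- matrix(dout[, , , bb], H * W, F_)
    dW <- dW + crossprod(cols, dz)
    db <- db + colSums(dz)
    dx[, , , bb] <- col2im_same(dz %*% t(W_), H, W, Din, kh, kw)
  }
  list(dx = dx, dW = dW, db = db)
}

# --- max pooling ------------------------------------------------------------

# Same-padded max pooling with window kh x kw. stride > 1 subsamples the
# stride-1 pooled map (equivalent to strided pooling at those centres).
pool_fwd <- function(x, kh, kw, stride = 1, need_cache = FALSE) {
  d <- dim(x)
  B <- d[4]
  sel_h <- seq(1, d[1], by = stride)
  sel_w <- seq(1, d[2], by = stride)
  out <- array(0, c(length(sel_h), length(sel_w), d[3], B))
  args <- vector("list", B)
  for (bb in seq_len(B)) {
    r <- maxpool_same_fwd(array(x[, , , bb], d[1:3]), kh, kw)
    out[, , , bb] <- r$out[sel_h, sel_w, , drop = FALSE]
    if (need_cache) args[[bb]] <- r$argmax
  }
  list(out = out,
       cache = if (need_cache) list(argmax = args, dim = d, sel_h = sel_h,
                                    sel_w = sel_w) else NULL)
}

pool_bwd <- function(cache, dout) {
  d <- cache$dim
  dx <- array(0, d)
  for (bb in seq_len(d[4])) {
    dfull <- array(0, d[1:3])
    dfull[cache$sel_h, cache$sel_w, ] <- dout[, , , bb]
    dx[, , , bb] <- maxpool_same_bwd(dfull, cache$argmax[[bb]])
  }
  dx
}

# --- bidirectional LSTM block ----------------------------------------------

# x: [I, B, T]; p: list(fw = list(Wx, Wh, b), bw = ...). Output [2H, B, T]:
# forward hidden states stacked over time-realigned backward hidden states.
bilstm_fwd <- function(x, p, need_cache = FALSE) {
  fw <- lstm_fwd(x, p$fw$Wx, p$fw$Wh, p$fw$b)
  xr <- rev_time(x)
  bw <- lstm_fwd(xr, p$bw$Wx, p$bw$Wh, p$bw$b)
  H <- nrow(p$fw$Wh) / 4
  d <- dim(x)
  out <- array(0, c(2 * H, d[2], d[3]))
  out[1:H, , ] <- fw$h
  out[(H + 1):(2 * H), , ] <- rev_time(bw$h)
  list(out = out,
       cache = if (need_cache) list(x = x, xr = xr, fw = fw, bw = bw) else NULL)
}

bilstm_bwd <- function(cache, dout, p) {
  H <- nrow(p$fw$Wh) / 4
  dHf <- dout[1:H, , , drop = FALSE]
  dHb <- rev_time(dout[(H + 1):(2 * H), , , drop = FALSE])
  gf <- lstm_bwd(cache$x, cache$fw$h, cache$fw$c, cache$fw$g,
                 p$fw$Wx, p$fw$Wh, dHf)
  gb <- lstm_bwd(cache$xr, cache$bw$h, cache$bw$c, cache$bw$g,
                 p$bw$Wx, p$bw$Wh, dHb)
  list(dx = gf$dx + rev_time(gb$dx),
       grads = list(fw = list(Wx = gf$dWx, Wh = gf$dWh, b = as.numeric(gf$db)),
                    bw = list(Wx = gb$dWx, Wh = gb$dWh, b = as.numeric(gb$db))))
}

# --- optimizer --------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
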