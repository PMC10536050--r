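# CLRNet and its ablation variants. The full network: a four-layer CNN
# front-end treating an epoch as a channels x time image (stride-1 same
# padding, max pooling after conv 2 and conv 4, dropout 0.5), a learned
# linear projection to the recurrent feature width, five BiLSTM blocks
# returning sequences, cross-layer residual sums RES1 = B1 + B3 and
# RES2 = RES1 + B5, last-step read-out, and a dense-4 softmax head.

#' Network architecture configuration
#'
#' The `"paper"` preset is the published architecture: conv filters
#' 128/128/256/256 with 3x3 and 5x5 kernels, stride 1, same padding, 3x3
#' stride-1 max pooling after conv 2 and 4, dropout 0.5, five BiLSTM blocks
#' of 100 hidden units (tanh cell), residual sums over blocks 1, 3, 5, and a
#' dense-4 softmax head. The `"compact"` preset shrinks filter counts and
#' hidden width (4/4/8/8, hidden 16, projection 32) for CPU-scale training
#' runs while keeping the topology identical.
#'
#' @param variant `"clrnet"` (full), `"cnn_bilstm"` (no residual sums),
#'   `"cnn"` (conv stack + dense head only), or `"bilstm"` (raw epochs into
#'   the recurrent stack).
#' @param preset `"paper"` or `"compact"`; individual fields can be
#'   overridden afterwards through the `...` arguments.
#' @param ... named overrides of config fields (`conv_filters`,
#'   `conv_kernels`, `pool_size`, `pool_stride`, `pool_positions`,
#'   `dropout`, `n_lstm`, `lstm_hidden`, `proj_width`, `n_classes`,
#'   `residual_blocks`).
#' @return a `model_config` list.
#' @export
model_config <- function(variant = c("clrnet", "cnn_bilstm", "cnn", "bilstm"),
                         preset = c("paper", "compact"), ...) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  cfg <- list(
    variant = variant, preset = preset,
    conv_filters = c(128, 128, 256, 256),
    conv_kernels = list(c(3, 3), c(3, 3), c(5, 5), c(5, 5)),
    pool_size = c(3, 3), pool_stride = 1, pool_positions = c(2, 4),
    dropout = 0.5,
    n_lstm = 5, lstm_hidden = 100, proj_width = 200,
    residual_blocks = c(1, 3, 5),
    n_classes = 4, standardize = TRUE)
  if (preset == "compact") {
    cfg$conv_filters <- c(4, 4, 8, 8)
    cfg$lstm_hidden <- 16
    cfg$proj_width <- 32
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  for (k in names(over)) cfg[[k]] <- over[[k]]
  if (any(vapply(cfg$conv_kernels, function(k) any(k %% 2 == 0), TRUE)))
    stop("conv kernel dims must be odd for same padding")
  if (max(cfg$residual_blocks) > cfg$n_lstm)
    stop("residual_blocks refer to a BiLSTM block beyond n_lstm")
  structure(cfg, class = "model_config")
}

# Spatial dims of the CNN output for a given input (stride-1 convs preserve
# dims; pooling divides by its stride).
cnn_out_shape <- function(cfg, input_shape) {
  hw <- input_shape
  for (j in seq_along(cfg$conv_filters))
    if (j %in% cfg$pool_positions)
      hw <- ceiling(hw / cfg$pool_stride)
  hw
}

#' Describe the CNN front-end layer by layer
#'
#' Returns the layer sequence the convolutional feature extractor applies
#' (conv/pool/dropout, plus the flatten + dense softmax head when
#' `cfg$variant == "cnn"`), with output shapes for a given input.
#'
#' @param cfg a [model_config()].
#' @param input_shape `(channels, samples)` of one epoch.
#' @return data.frame with columns `layer`, `filters`, `kernel`,
#'   `out_h`, `out_w`, `out_depth`, `params`.
#' @export
build_cnn <- function(cfg = model_config("cnn"), input_shape = c(22, 240)) {
  if (any(input_shape <= 0)) stop("input_shape must be positive")
  hw <- input_shape
  depth <- 1
  rows <- list()
  add <- function(layer, filters = NA, kernel = NA_character_, params = 0)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, filters = filters, kernel = kernel,
      out_h = hw[1], out_w = hw[2], out_depth = depth, params = params)
  for (j in seq_along(cfg$conv_filters)) {
    k <- cfg$conv_kernels[[j]]
    f <- cfg$conv_filters[j]
    n_par <- (prod(k) * depth + 1) * f
    depth <- f
    add(sprintf("conv%d", j), f, sprintf("%dx%d", k[1], k[2]), n_par)
    if (j %in% cfg$pool_positions) {
      hw <- ceiling(hw / cfg$pool_stride)
      add("maxpool", NA, sprintf("%dx%d", cfg$pool_size[1], cfg$pool_size[2]))
    }
  }
  add("dropout")
  if (cfg$variant == "cnn") {
    n_in <- hw[1] * hw[2] * depth
    add("flatten")
    rows[[length(rows) + 1]] <- data.frame(
      layer = "dense_softmax", filters = cfg$n_classes, kernel = NA,
      out_h = 1, out_w = 1, out_depth = cfg$n_classes,
      params = (n_in + 1) * cfg$n_classes)
  }
  do.call(rbind, rows)
}

uinit <- function(dims, fan_in) {
  s <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

lstm_block_params <- function(input_width, hidden) {
  one_dir <- function() list(Wx = uinit(c(4 * hidden, input_width), input_width),
                             Wh = uinit(c(4 * hidden, hidden), hidden),
                             b = numeric(4 * hidden))
  list(fw = one_dir(), bw = one_dir())
}

#' Build a CLRNet model (or an ablation variant) with initialised weights
#'
#' Assembles the architecture for `cfg$variant` on epochs of `input_shape`
#' and initialises all weights from a uniform fan-in scheme with the given
#' seed. The four variants: `clrnet` = CNN -> projection -> 5 BiLSTM blocks
#' -> residual sum of blocks 1/3/5 -> last-step read-out -> dense-4 softmax;
#' `cnn_bilstm` = the same without the residual sums (block 5 feeds the
#' read-out); `bilstm` = raw epochs (channels as per-step features) into the
#' recurrent stack; `cnn` = conv stack + flatten + dense-4 softmax.
#'
#' @param cfg a [model_config()].
#' @param input_shape `(channels, samples)` of one epoch.
#' @param seed RNG seed for weight initialisation.
#' @return a `clrnet_model` object.
#' @export
build_clrnet <- function(cfg = model_config(), input_shape = c(22, 240),
                         seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- list()
  with_cnn <- cfg$variant %in% c("clrnet", "cnn_bilstm", "cnn")
  depth <- 1
  if (with_cnn) {
    for (j in seq_along(cfg$conv_filters)) {
      k <- cfg$conv_kernels[[j]]
      fan <- prod(k) * depth
      params[[sprintf("conv%d.W", j)]] <- uinit(c(fan, cfg$conv_filters[j]),
                                                fan)
      params[[sprintf("conv%d.b", j)]] <- numeric(cfg$conv_filters[j])
      depth <- cfg$conv_filters[j]
    }
  }
  hw <- if (with_cnn) cnn_out_shape(cfg, input_shape) else input_shape
  if (cfg$variant == "cnn") {
    n_in <- hw[1] * hw[2] * depth
    params[["head.W"]] <- uinit(c(n_in, cfg$n_classes), n_in)
    params[["head.b"]] <- numeric(cfg$n_classes)
  } else {
    if (with_cnn) {
      feat <- hw[1] * depth
      params[["proj.W"]] <- uinit(c(cfg$proj_width, feat), feat)
      params[["proj.b"]] <- numeric(cfg$proj_width)
      lstm_in <- cfg$proj_width
    } else {
      lstm_in <- input_shape[1]
    }
    for (l in seq_len(cfg$n_lstm)) {
      bp <- lstm_block_params(if (l == 1) lstm_in else 2 * cfg$lstm_hidden,
                              cfg$lstm_hidden)
      for (dir in c("fw", "bw"))
        for (nm in c("Wx", "Wh", "b"))
          params[[sprintf("lstm%d.%s.%s", l, dir, nm)]] <- bp[[dir]][[nm]]
    }
    params[["head.W"]] <- uinit(c(2 * cfg$lstm_hidden, cfg$n_classes),
                                2 * cfg$lstm_hidden)
    params[["head.b"]] <- numeric(cfg$n_classes)
  }
  structure(list(config = cfg, input_shape = input_shape, params = params,
                 init_seed = seed),
            class = "clrnet_model")
}

#' @export
print.clrnet_model <- function(x, ...) {
  cat(sprintf("<clrnet_model> variant=%s preset=%s input=%dx%d params=%s\n",
              x$config$variant, x$config$preset, x$input_shape[1],
              x$input_shape[2], format(count_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param model a `clrnet_model`.
#' @param component optional regular expression restricting the count to
#'   matching parameter names (e.g. `"^lstm1\\."` for the first BiLSTM
#'   block).
#' @export
count_params <- function(model, component = NULL) {
  p <- model$params
  if (!is.null(component)) p <- p[grepl(component, names(p))]
  sum(vapply(p, length, 0L))
}

#' One step of the LSTM recurrence (reference transcription)
#'
#' Direct elementwise transcription of the gated cell: forget, input and
#' output gates through the logistic sigmoid, candidate through tanh,
#' `c_t = f * c_prev + i * tanh(Wxc x + Whc h_prev + bc)`,
#' `h_t = o * tanh(c_t)`. Used as the independent oracle the fast batched
#' recurrence is tested against.
#'
#' @param x_t input column vector (or matrix with one column per batch
#'   element).
#' @param h_prev,c_prev previous hidden and cell state, same layout.
#' @param weights list with `Wxf, Whf, bf, Wxi, Whi, bi, Wxc, Whc, bc,
#'   Wxo, Who, bo`.
#' @return list `(h, c)`.
#' @export
recurrent_cell_step <- function(x_t, h_prev, c_prev, weights) {
  x_t <- as.matrix(x_t); h_prev <- as.matrix(h_prev)
  c_prev <- as.matrix(c_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  w <- weights
  f <- sig(w$Wxf %*% x_t + w$Whf %*% h_prev + w$bf)
  i <- sig(w$Wxi %*% x_t + w$Whi %*% h_prev + w$bi)
  c_t <- f * c_prev + i * tanh(w$Wxc %*% x_t + w$Whc %*% h_prev + w$bc)
  o <- sig(w$Wxo %*% x_t + w$Who %*% h_prev + w$bo)
  list(h = o * tanh(c_t), c = c_t)
}

#' Cross-layer residual combination of BiLSTM block outputs
#'
#' Elementwise `RES1 = B1 + B3`, `RES2 = RES1 + B5`; adds no trainable
#' parameters. All three sequence outputs must share one shape.
#'
#' @param b1_out,b3_out,b5_out sequence outputs (arrays of equal shape).
#' @return the summed sequence features (`RES2`).
#' @export
residual_combine <- function(b1_out, b3_out, b5_out) {
  d1 <- dim(b1_out) %||% length(b1_out)
  for (nm in c("b3_out", "b5_out")) {
    b <- get(nm)
    if (!identical(d1, dim(b) %||% length(b)))
      stop("shape of ", nm, " does not match b1_out")
  }
  b1_out + b3_out + b5_out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- forward / backward -----------------------------------------------------

# Per-trial z-scoring with one mean/sd across all channels and samples: a
# stateless input transform (no statistics carried from training into
# evaluation) that brings microvolt amplitudes to the unit scale the
# saturating nonlinearities expect while preserving the relative channel
# amplitudes that carry the ERD/ERS contrast.
standardize_trials <- function(X) {
  d <- dim(X)
  flat <- matrix(X, d[1])
  mu <- rowMeans(flat)
  sd_ <- sqrt(rowMeans((flat - mu)^2))
  (X - mu) / pmax(sd_, 1e-8)
}

# X: [B, channels, samples]. Returns probabilities and (training) caches.
model_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  if (isTRUE(cfg$standardize)) X <- standardize_trials(X)
  B <- dim(X)[1]
  cache <- list()
  variant <- cfg$variant
  with_cnn <- variant %in% c("clrnet", "cnn_bilstm", "cnn")

  if (with_cnn) {
    a <- aperm(X, c(2, 3, 1))                  # [H, W, B]
    a <- array(a, c(dim(a)[1], dim(a)[2], 1, B))
    conv_caches <- list(); pool_caches <- list()
    for (j in seq_along(cfg$conv_filters)) {
      k <- cfg$conv_kernels[[j]]
      cf <- conv_relu_fwd(a, p[[sprintf("conv%d.W", j)]],
                          p[[sprintf("conv%d.b", j)]], k[1], k[2],
                          need_cache = training)
      a <- cf$out
      conv_caches[[j]] <- cf[c("x", "mask")]
      if (j %in% cfg$pool_positions) {
        pf <- pool_fwd(a, cfg$pool_size[1], cfg$pool_size[2],
                       cfg$pool_stride, need_cache = training)
        a <- pf$out
        pool_caches[[as.character(j)]] <- pf$cache
      }
    }
    if (training && cfg$dropout > 0) {
      keep <- 1 - cfg$dropout
      mask <- array(stats::rbinom(length(a), 1, keep) / keep, dim(a))
      a <- a * mask
      cache$drop_mask <- mask
    }
    cache$conv <- conv_caches
    cache$pool <- pool_caches
    cache$cnn_out_dim <- dim(a)
  }

  if (variant == "cnn") {
    flat <- matrix(a, prod(dim(a)[1:3]), B)    # columns = samples
    logits <- crossprod(flat, p[["head.W"]])
    logits <- sweep(logits, 2, p[["head.b"]], "+")
    cache$flat <- if (training) flat else NULL
    probs <- softmax_rows(logits)
    return(list(probs = probs, cache = cache))
  }

  if (with_cnn) {
    d <- dim(a)                                # [H, W, D, B]
    feat <- d[1] * d[3]
    Tn <- d[2]
    farr <- array(0, c(feat, B, Tn))
    for (bb in seq_len(B))
      farr[, bb, ] <- matrix(aperm(array(a[, , , bb], d[1:3]), c(1, 3, 2)),
                             feat, Tn)
    fmat <- matrix(farr, feat, B * Tn)
    pmat <- p[["proj.W"]] %*% fmat + p[["proj.b"]]
    seq_in <- array(pmat, c(cfg$proj_width, B, Tn))
    cache$fmat <- if (training) fmat else NULL
  } else {
    seq_in <- aperm(X, c(2, 1, 3))             # [channels, B, T]
  }

  block_out <- vector("list", cfg$n_lstm)
  block_cache <- vector("list", cfg$n_lstm)
  xin <- seq_in
  for (l in seq_len(cfg$n_lstm)) {
    bp <- list(fw = list(Wx = p[[sprintf("lstm%d.fw.Wx", l)]],
                         Wh = p[[sprintf("lstm%d.fw.Wh", l)]],
                         b = p[[sprintf("lstm%d.fw.b", l)]]),
               bw = list(Wx = p[[sprintf("lstm%d.bw.Wx", l)]],
                         Wh = p[[sprintf("lstm%d.bw.Wh", l)]],
                         b = p[[sprintf("lstm%d.bw.b", l)]]))
    bf <- bilstm_fwd(xin, bp, need_cache = training)
    block_out[[l]] <- bf$out
    block_cache[[l]] <- bf$cache
    xin <- bf$out
  }
  combined <- if (variant == "clrnet") {
    rb <- cfg$residual_blocks
    Reduce(`+`, block_out[rb])
  } else {
    block_out[[cfg$n_lstm]]
  }
  Tn <- dim(combined)[3]
  readout <- matrix(combined[, , Tn], 2 * cfg$lstm_hidden, B)
  logits <- crossprod(readout, p[["head.W"]])
  logits <- sweep(logits, 2, p[["head.b"]], "+")
  cache$blocks <- block_cache
  cache$readout <- if (training) readout else NULL
  list(probs = softmax_rows(logits), cache = cache)
}

# Cross-entropy loss and full parameter gradients; Y is a B x n_classes
# one-hot matrix. Requires caches from model_forward(training = TRUE).
model_backward <- function(model, X, Y, fwd) {
  cfg <- model$config
  p <- model$params
  B <- dim(X)[1]
  probs <- fwd$probs
  cache <- fwd$cache
  grads <- lapply(p, function(q) q * 0)
  dlogits <- (probs - Y) / B                   # softmax + CE gradient
  variant <- cfg$variant
  with_cnn <- variant %in% c("clrnet", "cnn_bilstm", "cnn")

  if (variant == "cnn") {
    flat <- cache$flat
    grads[["head.W"]] <- flat %*% dlogits
    grads[["head.b"]] <- colSums(dlogits)
    dflat <- p[["head.W"]] %*% t(dlogits)
    da <- array(dflat, cache$cnn_out_dim)
  } else {
    readout <- cache$readout
    grads[["head.W"]] <- readout %*% dlogits
    grads[["head.b"]] <- colSums(dlogits)
    dreadout <- p[["head.W"]] %*% t(dlogits)
    H2 <- 2 * cfg$lstm_hidden
    Tn <- dim(cache$blocks[[1]]$x)[3]
    dzero <- array(0, c(H2, B, Tn))
    dblock <- vector("list", cfg$n_lstm)
    for (l in seq_len(cfg$n_lstm)) dblock[[l]] <- dzero
    inject <- function(darr) { darr[, , Tn] <- darr[, , Tn] + dreadout; darr }
    if (variant == "clrnet") {
      for (l in cfg$residual_blocks) dblock[[l]] <- inject(dblock[[l]])
    } else {
      dblock[[cfg$n_lstm]] <- inject(dblock[[cfg$n_lstm]])
    }
    dxin <- NULL
    for (l in rev(seq_len(cfg$n_lstm))) {
      dout <- dblock[[l]]
      if (!is.null(dxin)) dout <- dout + dxin
      bp <- list(fw = list(Wx = p[[sprintf("lstm%d.fw.Wx", l)]],
                           Wh = p[[sprintf("lstm%d.fw.Wh", l)]],
                           b = p[[sprintf("lstm%d.fw.b", l)]]),
                 bw = list(Wx = p[[sprintf("lstm%d.bw.Wx", l)]],
                           Wh = p[[sprintf("lstm%d.bw.Wh", l)]],
                           b = p[[sprintf("lstm%d.bw.b", l)]]))
      bb <- bilstm_bwd(cache$blocks[[l]], dout, bp)
      for (dir in c("fw", "bw"))
        for (nm in c("Wx", "Wh", "b"))
          grads[[sprintf("lstm%d.%s.%s", l, dir, nm)]] <- bb$grads[[dir]][[nm]]
      dxin <- bb$dx
    }
    if (!with_cnn) return(grads)
    # back through projection into the CNN feature map
    dpmat <- matrix(dxin, cfg$proj_width, B * dim(dxin)[3])
    fmat <- cache$fmat
    grads[["proj.W"]] <- dpmat %*% t(fmat)
    grads[["proj.b"]] <- rowSums(dpmat)
    dfmat <- t(p[["proj.W"]]) %*% dpmat
    d <- cache$cnn_out_dim                     # [H, W, D, B]
    Tn <- d[2]
    dfarr <- array(dfmat, c(d[1] * d[3], B, Tn))
    da <- array(0, d)
    for (bb2 in seq_len(B))
      da[, , , bb2] <- aperm(array(dfarr[, bb2, ], c(d[1], d[3], Tn)),
                             c(1, 3, 2))
  }

  if (!is.null(cache$drop_mask)) da <- da * cache$drop_mask
  for (j in rev(seq_along(cfg$conv_filters))) {
    if (j %in% cfg$pool_positions)
      da <- pool_bwd(cache$pool[[as.character(j)]], da)
    k <- cfg$conv_kernels[[j]]
    cb <- conv_relu_bwd(cache$conv[[j]], da, p[[sprintf("conv%d.W", j)]],
                        k[1], k[2])
    grads[[sprintf("conv%d.W", j)]] <- cb$dW
    grads[[sprintf("conv%d.b", j)]] <- cb$db
    da <- cb$dx
  }
  grads
}

#' Class probabilities for an epoch set
#'
#' @param model a (trained) `clrnet_model`.
#' @param e an `eeg_epochs` set whose channel/sample dims match the model.
#' @param batch_size forward batch size.
#' @return matrix `n_trials x n_classes` of softmax probabilities.
#' @export
predict_proba <- function(model, e, batch_size = 32) {
  validate_epochs(e)
  d <- dim(e$data)
  if (!identical(as.integer(d[2:3]), as.integer(model$input_shape)))
    stop("epoch shape ", d[2], "x", d[3], " does not match model input ",
         model$input_shape[1], "x", model$input_shape[2])
  out <- matrix(0, d[1], model$config$n_classes)
  for (s in seq(1, d[1], by = batch_size)) {
    idx <- s:min(s + batch_size - 1, d[1])
    out[idx, ] <- model_forward(model,
                                e$data[idx, , , drop = FALSE])$probs
  }
  out
}
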