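test_that("the CNN front-end matches its printed specification", {
  tab <- build_cnn(model_config("cnn"), c(22, 240))
  convs <- tab[grepl("^conv", tab$layer), ]
  expect_identical(convs$filters, c(128, 128, 256, 256))
  expect_identical(convs$kernel, c("3x3", "3x3", "5x5", "5x5"))
  expect_identical(tab$layer[tab$layer == "maxpool"], rep("maxpool", 2))
  # pools sit after conv 2 and conv 4, dropout after the final pool
  expect_identical(tab$layer[1:7],
                   c("conv1", "conv2", "maxpool", "conv3", "conv4",
                     "maxpool", "dropout"))
  # stride-1 same padding preserves the 22 x 240 spatial extent throughout
  expect_true(all(tab$out_h[tab$layer != "dense_softmax"] == 22))
  expect_true(all(tab$out_w[tab$layer != "dense_softmax"] == 240))
  expect_identical(tab$out_depth[tab$layer == "dropout"], 256)
  # closed-form parameter counts
  expect_identical(tab$params[tab$layer == "conv1"], (3 * 3 * 1 + 1) * 128)
  expect_identical(tab$params[tab$layer == "conv2"],
                   (3 * 3 * 128 + 1) * 128)
})

test_that("parameter counts follow the closed forms", {
  m <- build_clrnet(model_config("clrnet"), c(22, 240), seed = 1)
  # one BiLSTM block, input width 200, hidden 100:
  expect_identical(count_params(m, "^lstm1\\."),
                   2L * 4L * ((200L + 100L) * 100L + 100L))
  expect_identical(count_params(m, "^lstm1\\."), 240800L)
  expect_identical(count_params(m, "^conv1\\."), 1280L)
  # deeper blocks take the 200-wide bidirectional output: same count
  expect_identical(count_params(m, "^lstm3\\."), 240800L)
  # residual sums add no parameters
  m2 <- build_clrnet(model_config("cnn_bilstm"), c(22, 240), seed = 1)
  expect_identical(count_params(m), count_params(m2))
})

test_that("the recurrent cell obeys its fixed points", {
  H <- 3; I <- 2
  zeros <- pack_cell_weights(matrix(0, 4 * H, I), matrix(0, 4 * H, H),
                             numeric(4 * H), H)
  s <- recurrent_cell_step(rnorm(I), numeric(H), numeric(H), zeros)
  expect_identical(as.numeric(s$h), numeric(H))        # o=0.5, tanh(0)=0
  expect_identical(as.numeric(s$c), numeric(H))
  # forget gate forced open, input gate shut: the cell carries its memory
  b <- numeric(4 * H)
  b[1:H] <- -1e3                                       # i -> 0
  b[(H + 1):(2 * H)] <- 1e3                            # f -> 1
  w <- pack_cell_weights(matrix(0, 4 * H, I), matrix(0, 4 * H, H), b, H)
  c_prev <- c(0.3, -0.2, 1.1)
  s2 <- recurrent_cell_step(rnorm(I), numeric(H), c_prev, w)
  expect_equal(as.numeric(s2$c), c_prev, tolerance = 1e-12)
})

test_that("the batched recurrence equals the reference transcription", {
  set.seed(3)
  I <- 3; H <- 2; B <- 2; Tn <- 6
  Wx <- matrix(rnorm(4 * H * I), 4 * H, I)
  Wh <- matrix(rnorm(4 * H * H), 4 * H, H)
  b <- rnorm(4 * H)
  X <- array(rnorm(I * B * Tn), c(I, B, Tn))
  fast <- clrnet:::lstm_fwd(X, Wx, Wh, b)
  w <- pack_cell_weights(Wx, Wh, b, H)
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  for (t in seq_len(Tn)) {
    s <- recurrent_cell_step(X[, , t], h, cc, w)
    h <- s$h; cc <- s$c
    expect_lt(max(abs(h - fast$h[, , t])), 1e-6)
    expect_lt(max(abs(cc - fast$c[, , t])), 1e-6)
  }
})

test_that("residual combination is a plain elementwise sum", {
  set.seed(4)
  b1 <- array(rnorm(24), c(4, 2, 3))
  expect_identical(residual_combine(b1, b1 * 0, b1 * 0), b1)
  ones <- array(1, c(4, 2, 3))
  expect_identical(residual_combine(ones, ones, ones), ones * 3)
  b3 <- array(rnorm(24), c(4, 2, 3)); b5 <- array(rnorm(24), c(4, 2, 3))
  expect_identical(residual_combine(b1, b3, b5), (b1 + b3) + b5)
  expect_error(residual_combine(b1, b3, array(0, c(4, 2, 2))), "b5_out")
})

test_that("forward passes produce valid softmax rows, deterministically", {
  cfg <- model_config("clrnet", "compact")
  m <- build_clrnet(cfg, c(22, 240), seed = 2)
  set.seed(5)
  X <- array(rnorm(8 * 22 * 240), c(8, 22, 240))
  p1 <- clrnet:::model_forward(m, X)$probs
  expect_identical(dim(p1), c(8L, 4L))
  expect_equal(rowSums(p1), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p1 > 0))
  p2 <- clrnet:::model_forward(m, X)$probs
  expect_identical(p1, p2)
  # every ablation variant shares the probability contract
  for (v in c("cnn", "bilstm", "cnn_bilstm")) {
    mv <- build_clrnet(model_config(v, "compact"), c(22, 240), seed = 2)
    pv <- clrnet:::model_forward(mv, X[1:2, , , drop = FALSE])$probs
    expect_equal(rowSums(pv), rep(1, 2), tolerance = 1e-6)
  }
})

test_that("the published-size network forwards a batch correctly", {
  m <- build_clrnet(model_config("clrnet"), c(22, 240), seed = 1)
  expect_gt(count_params(m), 4e6)
  set.seed(6)
  X <- array(rnorm(1 * 22 * 240), c(1, 22, 240))
  p <- clrnet:::model_forward(m, X)$probs
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config("clrnet", "compact", conv_filters = c(2, 2, 3, 3),
                      lstm_hidden = 3, proj_width = 4, dropout = 0)
  m <- build_clrnet(cfg, c(4, 12), seed = 2)
  B <- 3
  set.seed(9)
  X <- array(rnorm(B * 4 * 12), c(B, 4, 12))
  Y <- clrnet:::one_hot(c(0L, 2L, 3L), 4)
  lossfn <- function(mm) {
    p <- clrnet:::model_forward(mm, X)$probs
    -sum(log(rowSums(p * Y))) / B
  }
  fwd <- clrnet:::model_forward(m, X, training = TRUE)
  gr <- clrnet:::model_backward(m, X, Y, fwd)
  eps <- 1e-5
  set.seed(4)
  for (k in names(m$params)) {
    n <- length(m$params[[k]])
    for (ii in sample(n, min(3, n))) {
      mp <- m; mp$params[[k]][ii] <- mp$params[[k]][ii] + eps
      mn <- m; mn$params[[k]][ii] <- mn$params[[k]][ii] - eps
      num <- (lossfn(mp) - lossfn(mn)) / (2 * eps)
      expect_lt(abs(num - gr[[k]][ii]), 1e-7)
    }
  }
})

test_that("the residual path keeps gradients flowing to early blocks", {
  shrink_late_blocks <- function(m) {
    for (l in 3:5) for (dir in c("fw", "bw")) for (nm in c("Wx", "Wh")) {
      key <- sprintf("lstm%d.%s.%s", l, dir, nm)
      m$params[[key]] <- m$params[[key]] * 1e-8
    }
    m
  }
  grad_at_b1 <- function(variant) {
    cfg <- model_config(variant, "compact", conv_filters = c(2, 2, 3, 3),
                        lstm_hidden = 3, proj_width = 4, dropout = 0)
    m <- shrink_late_blocks(build_clrnet(cfg, c(4, 16), seed = 3))
    set.seed(7)
    X <- array(rnorm(2 * 4 * 16), c(2, 4, 16))
    Y <- clrnet:::one_hot(c(0L, 1L), 4)
    fwd <- clrnet:::model_forward(m, X, training = TRUE)
    gr <- clrnet:::model_backward(m, X, Y, fwd)
    sqrt(sum(gr[["lstm1.fw.Wx"]]^2))
  }
  with_res <- grad_at_b1("clrnet")
  without_res <- grad_at_b1("cnn_bilstm")
  expect_gt(with_res, 1e-6)                  # cross-layer path carries signal
  expect_lt(without_res, with_res * 1e-3)    # plain stack: gradient starved
})

test_that("configuration errors are caught at build time", {
  expect_error(model_config("clrnet", conv_kernels = list(c(2, 2), c(3, 3),
                                                          c(5, 5), c(5, 5))),
               "odd")
  expect_error(model_config("clrnet", residual_blocks = c(1, 3, 7)),
               "beyond n_lstm")
  expect_error(model_config("clrnet", nonsense = 1), "unknown config field")
  e <- tiny_epochs(2, 3, 32)
  m <- build_clrnet(model_config("bilstm", "compact"), c(5, 32), seed = 1)
  expect_error(predict_proba(m, e), "does not match model input")
})
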