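# Per-subject training and evaluation: mini-batch Adam on categorical
# cross-entropy, accuracy + confusion matrix reporting, stratified
# train/test splitting emulating the two-session protocol of IV-2a.

#' Training configuration
#'
#' Defaults follow the published protocol: batch size 8, 200 training
#' epochs, Adam. The learning rate is not given there; 1e-3 is the default.
#'
#' @param batch_size mini-batch size (default 8).
#' @param epochs passes over the training set (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param clip_norm global gradient-norm ceiling (default 5); `Inf`
#'   disables clipping.
#' @param seed seed governing weight initialisation, shuffling and dropout.
#' @export
train_config <- function(batch_size = 8, epochs = 200, lr = 1e-3,
                         clip_norm = 5, seed = 1) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       optimizer = "adam", lr = lr, clip_norm = clip_norm,
       loss = "categorical_crossentropy", seed = as.integer(seed))
}

clip_gradients <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (total > max_norm) grads <- lapply(grads, function(g)
    g * (max_norm / total))
  grads
}

one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Train a model on a labelled epoch set
#'
#' Mini-batch Adam on categorical cross-entropy. Fully deterministic given
#' `cfg$seed`: the seed fixes the shuffling order and dropout masks (weight
#' initialisation is fixed by the model's own seed at build time).
#'
#' @param model a `clrnet_model` from [build_clrnet()].
#' @param train_set labelled `eeg_epochs` matching the model input shape.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch loss/accuracy.
#' @return the trained model, with a `history` data.frame (`epoch`, `loss`,
#'   `train_acc`) attached.
#' @export
train_model <- function(model, train_set, cfg = train_config(),
                        verbose = FALSE) {
  validate_epochs(train_set)
  if (is.null(train_set$labels)) stop("training set has no labels")
  d <- dim(train_set$data)
  if (!identical(as.integer(d[2:3]), as.integer(model$input_shape)))
    stop("epoch shape ", d[2], "x", d[3], " does not match model input ",
         model$input_shape[1], "x", model$input_shape[2])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- d[1]
  params <- model$params
  state <- adam_state(params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        train_acc = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      Xb <- train_set$data[idx, , , drop = FALSE]
      Yb <- one_hot(train_set$labels[idx], model$config$n_classes)
      model$params <- params
      fwd <- model_forward(model, Xb, training = TRUE)
      eps <- 1e-12
      ep_loss <- ep_loss - sum(log(rowSums(fwd$probs * Yb) + eps))
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs) == train_set$labels[idx] + 1L)
      grads <- model_backward(model, Xb, Yb, fwd)
      grads <- clip_gradients(grads, cfg$clip_norm)
      upd <- adam_step(params, grads, state, lr = cfg$lr)
      params <- upd$params
      state <- upd$state
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         train_acc = ep_correct / n))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, ep_loss / n,
                      ep_correct / n))
  }
  model$params <- params
  model$history <- history
  model$train_config <- cfg
  model
}

#' Evaluate a model on a labelled epoch set
#'
#' Pure (no weight updates): accuracy and a 4x4 confusion matrix with true
#' classes in rows and predicted classes in columns, so row sums equal the
#' per-class trial counts and `sum(diag(confusion)) / sum(confusion)` equals
#' the accuracy.
#'
#' @param model a trained `clrnet_model`.
#' @param test_set labelled `eeg_epochs`.
#' @return a `train_result` list: `test_accuracy`, `confusion`, `history`
#'   (if the model was trained), `config_snapshot`, `seed`.
#' @export
evaluate_model <- function(model, test_set) {
  validate_epochs(test_set)
  if (is.null(test_set$labels)) stop("test set has no labels")
  probs <- predict_proba(model, test_set)
  pred <- max.col(probs, ties.method = "first") - 1L
  k <- model$config$n_classes
  confusion <- table(factor(test_set$labels, 0:(k - 1)),
                     factor(pred, 0:(k - 1)))
  confusion <- matrix(confusion, k, k,
                      dimnames = list(true = test_set$class_names,
                                      pred = test_set$class_names))
  structure(list(test_accuracy = mean(pred == test_set$labels),
                 confusion = confusion,
                 history = model$history,
                 config_snapshot = list(model = model$config,
                                        train = model$train_config),
                 seed = model$train_config$seed %||% NA_integer_),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> accuracy %.3f over %d trials\n",
              x$test_accuracy, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Stratified split of an epoch set into train and test halves
#'
#' Emulates the two-session protocol of IV-2a on a single synthetic set:
#' a class-stratified 50/50 (by default) split.
#'
#' @param e a labelled `eeg_epochs` set.
#' @param fraction train fraction (default 0.5).
#' @param seed RNG seed for the split.
#' @return list with `train` and `test` epoch sets.
#' @export
split_epochs <- function(e, fraction = 0.5, seed = 1) {
  validate_epochs(e)
  if (is.null(e$labels)) stop("cannot stratify an unlabelled epoch set")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train_idx <- integer()
  for (cl in sort(unique(e$labels))) {
    cls <- which(e$labels == cl)
    train_idx <- c(train_idx, sample(cls, round(length(cls) * fraction)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(dim(e$data)[1]), train_idx)
  subset_e <- function(idx)
    epoch_set(e$data[idx, , , drop = FALSE], e$labels[idx], e$fs,
              e$channel_names, e$class_names)
  list(train = subset_e(train_idx), test = subset_e(test_idx))
}

# Train-and-evaluate one subject with one architecture variant.
run_subject <- function(train_set, test_set, variant, cfg,
                        preset = "compact", model_overrides = list()) {
  d <- dim(train_set$data)
  mcfg <- do.call(model_config,
                  c(list(variant = variant, preset = preset),
                    model_overrides))
  model <- build_clrnet(mcfg, input_shape = d[2:3], seed = cfg$seed)
  model <- train_model(model, train_set, cfg)
  evaluate_model(model, test_set)
}

#' Architecture ablation experiment
#'
#' Trains and evaluates each architecture variant on each subject under
#' identical data, split and seed — the controlled variable is the
#' architecture. Mirrors the CNN / BiLSTM / CNN-BiLSTM / CLRNet comparison.
#'
#' @param data one labelled `eeg_epochs` set, or a named list of them (one
#'   per subject). Each is split with [split_epochs()] unless `test_data`
#'   is given.
#' @param variants architecture variants to compare.
#' @param cfg a [train_config()].
#' @param preset model size preset (see [model_config()]).
#' @param test_data optional matching list of held-out sets (session E
#'   protocol); when omitted a stratified 50/50 split stands in for the two
#'   sessions.
#' @return data.frame: one row per subject with one accuracy column per
#'   variant, plus a final `"mean"` row of per-variant means.
#' @export
run_ablation <- function(data, variants = c("cnn", "bilstm", "cnn_bilstm",
                                            "clrnet"),
                         cfg = train_config(), preset = "compact",
                         test_data = NULL) {
  if (inherits(data, "eeg_epochs")) data <- list(subject1 = data)
  if (is.null(names(data))) names(data) <- paste0("subject", seq_along(data))
  rows <- list()
  for (subj in names(data)) {
    if (is.null(test_data)) {
      sp <- split_epochs(data[[subj]], seed = cfg$seed)
    } else {
      sp <- list(train = data[[subj]], test = test_data[[subj]])
    }
    accs <- vapply(variants, function(v) {
      res <- tryCatch(run_subject(sp$train, sp$test, v, cfg, preset),
                      error = function(e)
                        stop("variant '", v, "' failed: ",
                             conditionMessage(e), call. = FALSE))
      res$test_accuracy
    }, 0)
    rows[[subj]] <- data.frame(subject = subj, t(accs),
                               check.names = FALSE)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  means <- colMeans(tab[, variants, drop = FALSE])
  rbind(tab, data.frame(subject = "mean", t(means), check.names = FALSE))
}

#' Channel-subset experiment
#'
#' Evaluates the same architecture/seed on nested channel subsets (default
#' C3/C4, C3/C4/Cz, all channels) to quantify what the motor channels alone
#' carry.
#'
#' @param data a labelled `eeg_epochs` set or named list of them.
#' @param subsets list of channel-name vectors; `NULL` entries mean all
#'   channels.
#' @param cfg a [train_config()].
#' @param variant architecture variant (default `"clrnet"`).
#' @param preset model size preset.
#' @return data.frame: subject rows, one accuracy column per subset, plus a
#'   `"mean"` row.
#' @export
run_channel_experiment <- function(data,
                                   subsets = list(c("C3", "C4"),
                                                  c("C3", "C4", "Cz"),
                                                  NULL),
                                   cfg = train_config(),
                                   variant = "clrnet", preset = "compact") {
  if (inherits(data, "eeg_epochs")) data <- list(subject1 = data)
  if (is.null(names(data))) names(data) <- paste0("subject", seq_along(data))
  subset_name <- function(s, e)
    if (is.null(s)) sprintf("all%d", length(e$channel_names))
    else paste(s, collapse = "+")
  rows <- list()
  for (subj in names(data)) {
    e <- data[[subj]]
    accs <- vapply(subsets, function(s) {
      es <- if (is.null(s)) e else select_channels(e, s)
      sp <- split_epochs(es, seed = cfg$seed)
      run_subject(sp$train, sp$test, variant, cfg, preset)$test_accuracy
    }, 0)
    names(accs) <- make.unique(vapply(subsets, subset_name, "", e = e))
    rows[[subj]] <- data.frame(subject = subj, t(accs), check.names = FALSE)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  cols <- setdiff(names(tab), "subject")
  means <- colMeans(tab[, cols, drop = FALSE])
  rbind(tab, data.frame(subject = "mean", t(means), check.names = FALSE))
}

#' Published reference accuracies (constants, for comparison only)
#'
#' Per-subject four-class accuracies (%) reported on BCI Competition IV
#' dataset 2a for the architecture ablation (CNN, BiLSTM, CNN-BiLSTM,
#' CLRNet) and for the external comparison methods (TCNet, WPD_CSP_ANN,
#' ATCNet). These are stored published numbers, not results computed by this
#' package; the comparison methods are not implemented here.
#'
#' @return data.frame with columns `subject` (A01-A09 and `"mean"`) and one
#'   column per method.
#' @export
reference_accuracies <- function() {
  subj <- c(sprintf("A%02d", 1:9), "mean")
  data.frame(
    subject = subj,
    CNN = c(81.2, 79.8, 84.6, 80.2, 82.0, 85.1, 85.0, 84.7, 84.5, 83.0),
    BiLSTM = c(77.0, 72.3, 78.1, 72.1, 76.7, 78.8, 77.0, 76.9, 77.3, 76.2),
    CNN_BiLSTM = c(86.8, 83.5, 88.9, 82.8, 88.0, 89.5, 86.8, 87.0, 87.1,
                   87.0),
    CLRNet = c(90.3, 87.4, 91.3, 83.4, 88.0, 92.6, 89.5, 90.2, 88.7, 89.0),
    TCNet = c(86.1, 66.0, 93.4, 72.6, 79.9, 66.7, 90.3, 85.8, 85.4, 80.7),
    WPD_CSP_ANN = c(70.5, 60.0, 81.8, 65.6, 75.8, 72.0, 71.3, 71.5, 81.0,
                    72.2),
    ATCNet = c(88.5, 70.5, 97.6, 81.0, 83.0, 73.6, 93.1, 90.3, 91.0, 85.4))
}
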