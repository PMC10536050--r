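# Wavelet packet decomposition (WPD) on batches of epochs. A full binary
# filter-bank tree splits each signal into 2^level equal-width frequency
# subbands; leaves are indexed in frequency (sequency) order so that leaf k
# covers the k-th band from DC upward. Orthonormal Daubechies filters with
# periodised boundary handling give exact invertibility.

# Orthonormal Daubechies scaling (low-pass) filters. Quadrature mirror
# high-pass: g[m] = (-1)^m h[L-1-m].
DB_FILTERS <- list(
  db1 = c(0.70710678118654746, 0.70710678118654746),
  db2 = c(0.48296291314453416, 0.83651630373780794,
          0.22414386804201339, -0.12940952255126037),
  db4 = c(0.23037781330889651, 0.71484657055291567,
          0.63088076792985892, -0.027983769416859854,
          -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032))

wavelet_filters <- function(name) {
  h <- DB_FILTERS[[name]]
  if (is.null(h)) stop("unknown wavelet family: ", name,
                       " (available: ", paste(names(DB_FILTERS),
                                              collapse = ", "), ")")
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g)
}

#' Configuration for wavelet-packet band reconstruction
#'
#' Defaults follow the Mu/Beta selection used for IV-2a data at 250 Hz: a
#' five-level db4 decomposition (32 leaves of 3.90625 Hz), retention of the
#' leaves tiling 7.8125-23.4375 Hz (covering the Mu 8-14 Hz and Beta
#' 16-24 Hz rhythms), inverse transform, and resampling of each 750-sample
#' epoch to 240 samples (80 Hz, still above twice the highest retained
#' frequency).
#'
#' @param wavelet wavelet family (`"db4"` default).
#' @param level decomposition depth (default 5).
#' @param retained_band `(lo, hi)` in Hz; leaves fully inside are kept.
#' @param output_samples epoch length after resampling; `NA` disables
#'   resampling.
#' @export
wpd_config <- function(wavelet = "db4", level = 5,
                       retained_band = c(7.8125, 23.4375),
                       output_samples = 240) {
  if (level < 1) stop("level must be >= 1")
  if (!is.na(output_samples) && output_samples <= 0)
    stop("output_samples must be positive")
  list(wavelet = wavelet, level = as.integer(level),
       retained_band = retained_band,
       output_samples = if (is.na(output_samples)) NA_integer_
                        else as.integer(output_samples))
}

#' Frequency-ordered band edges of a uniform filter-bank partition
#'
#' Splits `[0, fs/2]` into `n_bands` contiguous equal-width bands, the bands
#' a level-`log2(n_bands)` wavelet packet tree resolves under
#' frequency-ordered leaf indexing. At `fs = 250` and 16 bands the first
#' edges fall at 7.8125, 15.625 and 23.4375 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param n_bands number of bands; must be a power of two.
#' @return list of `(lo, hi)` pairs, frequency-ordered.
#' @export
wpd_band_edges <- function(fs, n_bands) {
  if (n_bands < 1 || bitwAnd(as.integer(n_bands), as.integer(n_bands - 1)) != 0)
    stop("n_bands must be a power of two, got ", n_bands)
  width <- fs / 2 / n_bands
  lapply(seq_len(n_bands), function(k) c((k - 1) * width, k * width))
}

# One periodised analysis step on a matrix of signals (rows): returns the
# approximation and detail coefficient matrices, each with half the columns.
dwt_step <- function(X, h, g) {
  N <- ncol(X)
  stopifnot(N %% 2 == 0)
  half <- N / 2
  k2 <- 2 * (seq_len(half) - 1)
  A <- matrix(0, nrow(X), half)
  D <- matrix(0, nrow(X), half)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1)) %% N + 1
    A <- A + h[m] * X[, idx, drop = FALSE]
    D <- D + g[m] * X[, idx, drop = FALSE]
  }
  list(A = A, D = D)
}

# Transpose (exact inverse, filters orthonormal) of dwt_step.
idwt_step <- function(A, D, h, g) {
  half <- ncol(A)
  N <- 2 * half
  X <- matrix(0, nrow(A), N)
  k2 <- 2 * (seq_len(half) - 1)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1)) %% N + 1
    X[, idx] <- X[, idx] + h[m] * A + g[m] * D
  }
  X
}

# Natural (filter-tree / Paley) leaf index -> frequency-ordered position,
# both 0-based: the inverse Gray code of the path bits (MSB = first split).
# The high-pass branch inverts the spectrum at every downsampling step, so
# the cumulative parity of high-pass choices decides each bit's sense;
# verified against tone probes at every leaf's band centre.
wpd_natural_to_freq <- function(level) {
  out <- n <- 0:(2^level - 1)
  repeat {
    n <- bitwShiftR(n, 1)
    if (all(n == 0)) break
    out <- bitwXor(out, n)
  }
  out
}

# Full WPD of the rows of X to `level`; returns leaves in natural order.
wp_decompose <- function(X, h, g, level) {
  nodes <- list(X)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      s <- dwt_step(nodes[[i]], h, g)
      nxt[[2 * i - 1]] <- s$A
      nxt[[2 * i]] <- s$D
    }
    nodes <- nxt
  }
  nodes
}

wp_reconstruct <- function(leaves, h, g) {
  nodes <- leaves
  while (length(nodes) > 1) {
    nxt <- vector("list", length(nodes) / 2)
    for (i in seq_along(nxt))
      nxt[[i]] <- idwt_step(nodes[[2 * i - 1]], nodes[[2 * i]], h, g)
    nodes <- nxt
  }
  nodes[[1]]
}

# Band-limit the rows of X by zeroing all WPD leaves not fully inside
# `retained_band`, then inverting. Rows shorter than a multiple of 2^level
# are zero-padded internally and truncated after inversion.
wpd_filter_matrix <- function(X, fs, cfg) {
  filt <- wavelet_filters(cfg$wavelet)
  n <- ncol(X)
  block <- 2^cfg$level
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) {
    # symmetric-extension padding to a multiple of 2^level: the transform
    # stays exactly invertible on the padded signal and the smooth extension
    # avoids the spectral splatter a zero-padding step edge would add
    ext <- X[, n - seq_len(n_pad - n) + 1, drop = FALSE]
    X <- cbind(X, ext)
  }
  leaves <- wp_decompose(X, filt$h, filt$g, cfg$level)
  freq_pos <- wpd_natural_to_freq(cfg$level)
  edges <- wpd_band_edges(fs, 2^cfg$level)
  eps <- 1e-9
  keep <- vapply(seq_along(leaves), function(i) {
    band <- edges[[freq_pos[i] + 1]]
    band[1] >= cfg$retained_band[1] - eps && band[2] <= cfg$retained_band[2] + eps
  }, TRUE)
  if (!any(keep))
    stop("retained_band (", cfg$retained_band[1], "-", cfg$retained_band[2],
         " Hz) selects no wavelet-packet leaves at level ", cfg$level)
  for (i in which(!keep)) leaves[[i]][] <- 0
  out <- wp_reconstruct(leaves, filt$h, filt$g)
  out[, seq_len(n), drop = FALSE]
}

# Fourier-method resampling of the rows of X to n_out samples: lossless for
# content below the output Nyquist frequency.
resample_rows <- function(X, n_out) {
  n <- ncol(X)
  if (n_out == n) return(X)
  Xf <- t(stats::mvfft(t(X)))
  keep <- min(n, n_out)
  half <- keep %/% 2
  Yf <- matrix(0 + 0i, nrow(X), n_out)
  Yf[, 1:(half + 1)] <- Xf[, 1:(half + 1)]
  if (half > 0)
    Yf[, (n_out - half + 1):n_out] <- Xf[, (n - half + 1):n]
  if (keep %% 2 == 0 && half > 0) {            # split the shared Nyquist bin
    Yf[, half + 1] <- Yf[, half + 1] / 2
    Yf[, n_out - half + 1] <- Yf[, n_out - half + 1] +
      Conj(Yf[, half + 1])
  }
  Re(t(stats::mvfft(t(Yf), inverse = TRUE))) * (n_out / n) / n_out
}

#' Reconstruct epochs from selected wavelet-packet subbands
#'
#' For every trial and channel: decompose to `cfg$level`, zero every leaf
#' whose frequency band (under frequency-ordered indexing) falls outside
#' `cfg$retained_band`, invert back to the time domain, and optionally
#' resample each epoch to `cfg$output_samples`. With the defaults a
#' `288 x 22 x 750` epoch set at 250 Hz becomes `288 x 22 x 240` at 80 Hz.
#'
#' @param e an `eeg_epochs` set.
#' @param cfg a [wpd_config()].
#' @return an `eeg_epochs` set of shape
#'   `n_trials x n_channels x output_samples`.
#' @export
wpd_reconstruct <- function(e, cfg = wpd_config()) {
  validate_epochs(e)
  d <- dim(e$data)
  if (d[3] < 2^cfg$level)
    stop("epoch length ", d[3], " too short for level ", cfg$level)
  # flatten trials x channels into rows; the transform is per-signal
  X <- matrix(aperm(e$data, c(3, 1, 2)), nrow = d[1] * d[2], byrow = TRUE)
  X <- wpd_filter_matrix(X, e$fs, cfg)
  fs_out <- e$fs
  if (!is.na(cfg$output_samples) && cfg$output_samples != ncol(X)) {
    fs_out <- e$fs * cfg$output_samples / ncol(X)
    X <- resample_rows(X, cfg$output_samples)
  }
  out <- aperm(array(t(X), c(ncol(X), d[1], d[2])), c(2, 3, 1))
  epoch_set(out, e$labels, fs_out, e$channel_names, e$class_names)
}
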