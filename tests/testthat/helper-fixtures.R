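# Shared fixtures: everything is generated in code at test time.

tiny_recording <- function(n_ch = 2, n = 10, fs = 250, seed = 1) {
  set.seed(seed)
  raw_recording(matrix(rnorm(n_ch * n), n_ch), paste0("ch", seq_len(n_ch)),
                fs, events = data.frame(onset = 0L, code = 769L))
}

tiny_epochs <- function(n_trials = 8, n_ch = 3, n_s = 64, fs = 250,
                        seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_ch * n_s), c(n_trials, n_ch, n_s)),
            labels = rep(0:3, length.out = n_trials), fs = fs,
            channel_names = c("C3", "C4", "Cz")[seq_len(n_ch)])
}

# A small but paradigm-complete simulated subject, reused across tests.
small_sim <- function(n_per_class = 3, seed = 11, erd_depth = 0.8,
                      snr = 4) {
  simulate_subject(sim_config(n_trials_per_class = n_per_class,
                              erd_depth = erd_depth, snr = snr,
                              seed = seed))
}

# Packed gate-layout weights (rows i, f, g, o) -> the named per-gate list
# recurrent_cell_step() takes.
pack_cell_weights <- function(Wx, Wh, b, H) {
  idx <- function(k) ((k - 1) * H + 1):(k * H)
  list(Wxi = Wx[idx(1), , drop = FALSE], Whi = Wh[idx(1), , drop = FALSE],
       bi = b[idx(1)],
       Wxf = Wx[idx(2), , drop = FALSE], Whf = Wh[idx(2), , drop = FALSE],
       bf = b[idx(2)],
       Wxc = Wx[idx(3), , drop = FALSE], Whc = Wh[idx(3), , drop = FALSE],
       bc = b[idx(3)],
       Wxo = Wx[idx(4), , drop = FALSE], Who = Wh[idx(4), , drop = FALSE],
       bo = b[idx(4)])
}

# A fixed non-neural decoder for separability checks: picks the class whose
# expected ERD/ERS signature best matches the relative Mu+Beta power at the
# motor channels during the imagery window.
bandpower_decoder <- function(sim) {
  rec <- sim$recording
  fs <- rec$fs
  feats <- t(vapply(sim$onsets, function(on) {
    w <- c(on / fs + 3, on / fs + 6)
    c(mu3 = band_power(rec, "C3", c(8, 14), w),
      mu4 = band_power(rec, "C4", c(8, 14), w),
      muz = band_power(rec, "Cz", c(8, 14), w),
      be3 = band_power(rec, "C3", c(16, 24), w),
      be4 = band_power(rec, "C4", c(16, 24), w))
  }, numeric(5)))
  z <- scale(log(feats))
  # unit-norm templates of the expected ERD/ERS signature per class,
  # feature order (mu3, mu4, muz, be3, be4)
  templates <- cbind(left = c(0, -1, 0, 0, -1) / sqrt(2),
                     right = c(-1, 0, 0, -1, 0) / sqrt(2),
                     foot = c(0, 0, -1, 0, 0),
                     tongue = c(0, 0, 0, 1, 1) / sqrt(2))
  pred <- max.col(z %*% templates) - 1L
  mean(pred == sim$labels)
}
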