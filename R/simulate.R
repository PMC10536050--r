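# Synthetic four-class motor imagery EEG in the BCI Competition IV-2a layout:
# 25 named channels (22 EEG + 3 EOG) at 250 Hz, 288 cue-based trials, with
# class-dependent event-related desynchronisation/synchronisation (ERD/ERS)
# of the Mu and Beta sensorimotor rhythms at C3/C4/Cz on top of 1/f
# background noise and occasional ocular artifacts.

#' Default IV-2a style montage: 22 EEG channels plus 3 EOG channels.
#' @export
iv2a_channels <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4", "C5", "C3", "C1", "Cz", "C2",
    "C4", "C6", "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz",
    "EOG-left", "EOG-central", "EOG-right")
}

#' Configuration of the synthetic motor-imagery subject
#'
#' Defaults reproduce the IV-2a paradigm: 72 trials per class (288 total),
#' 250 Hz, trial timing with a 2 s preparation period, cue at 2 s and the
#' imagery window from 3 s to 6 s, followed by 1.5 s inter-trial rest. During
#' imagery the class modulates Mu (8-14 Hz) and Beta (16-24 Hz) rhythm power
#' at the motor channels: left hand attenuates the contralateral C4, right
#' hand C3, foot Cz, and tongue enhances Beta bilaterally at C3/C4.
#'
#' @param n_trials_per_class trials per class (default 72).
#' @param fs sampling rate in Hz (default 250).
#' @param channel_names 25 channel names; must include C3, C4, Cz and the
#'   three EOG channels.
#' @param trial_secs within-trial timing in seconds: preparation end, cue,
#'   imagery start, imagery end.
#' @param iti_secs inter-trial rest in seconds.
#' @param mu_band,beta_band rhythm bands in Hz.
#' @param erd_depth fraction in `[0,1]` of rhythm-power attenuation (or, for
#'   tongue ERS, enhancement) during imagery; 0 means no class effect.
#' @param snr ratio of baseline rhythm power to background-noise power at the
#'   motor channels.
#' @param eog_rate ocular artifact transients per minute.
#' @param seed integer RNG seed; identical configs give bit-identical data.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_trials_per_class = 72, fs = 250,
                       channel_names = iv2a_channels(),
                       trial_secs = c(prep_end = 2, cue = 2,
                                      mi_start = 3, mi_end = 6),
                       iti_secs = 1.5,
                       mu_band = c(8, 14), beta_band = c(16, 24),
                       erd_depth = 0.8, snr = 4, eog_rate = 4, seed = 1) {
  cfg <- list(n_trials_per_class = as.integer(n_trials_per_class), fs = fs,
              channel_names = channel_names, trial_secs = trial_secs,
              iti_secs = iti_secs, mu_band = mu_band, beta_band = beta_band,
              erd_depth = erd_depth, snr = snr, eog_rate = eog_rate,
              seed = as.integer(seed))
  required <- c("C3", "C4", "Cz", "EOG-left", "EOG-central", "EOG-right")
  missing <- setdiff(required, channel_names)
  if (length(missing))
    stop("channel_names must include ", paste(missing, collapse = ", "))
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0,1]")
  if (fs <= 2 * beta_band[2]) stop("fs must exceed twice the Beta band edge")
  if (trial_secs[["mi_start"]] >= trial_secs[["mi_end"]])
    stop("imagery window must have positive length")
  cfg
}

# 1/f^alpha (alpha = 1 in power) background noise with a white floor,
# generated by spectral shaping of white Gaussian noise; unit variance.
pink_noise <- function(n, fs, white_frac = 0.2) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1)) * fs / n            # avoid DC blow-up
  f <- pmin(f, fs - f)                          # mirror for the upper half
  shape <- 1 / sqrt(pmax(f, 1))                 # flat below 1 Hz
  pink <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)
  w <- stats::rnorm(n)
  out <- sqrt(1 - white_frac) * pink + sqrt(white_frac) * w
  out / stats::sd(out)
}

# Narrowband rhythm carrier: band-filtered white noise with unit variance
# (an amplitude-modulated random process, not a pure sine).
narrowband_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filter(bf, stats::rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]                     # drop filter warm-up
  x / stats::sd(x)
}

# Smooth per-trial gain envelope: 1 at rest, `gain` inside the imagery
# window, with 0.2 s raised-cosine ramps.
mi_envelope <- function(n_trial, fs, mi_start, mi_end, gain) {
  env <- rep(1, n_trial)
  i0 <- round(mi_start * fs) + 1
  i1 <- min(round(mi_end * fs), n_trial)
  env[i0:i1] <- gain
  ramp <- round(0.2 * fs)
  if (ramp > 1) {
    up <- (1 - cos(seq(0, pi, length.out = ramp))) / 2
    env[(i0 - ramp):(i0 - 1)] <- 1 + (gain - 1) * up
    if (i1 + ramp <= n_trial)
      env[(i1 + 1):(i1 + ramp)] <- gain + (1 - gain) * up
  }
  env
}

#' Simulate one synthetic motor-imagery subject
#'
#' Generates a continuous recording of concatenated trials. Trials are
#' balanced across the four classes and presented in a random order. Each
#' trial carries Mu and Beta rhythm carriers at the motor channels whose
#' power is modulated during the imagery window according to the trial's
#' class (contralateral ERD for the hands, Cz ERD for foot, bilateral Beta
#' ERS for tongue). Background activity is 1/f noise with a white floor on
#' every channel; the EOG channels additionally carry slow high-amplitude
#' artifact transients. Event markers are placed at trial onsets with codes
#' 769-772 encoding left/right/foot/tongue (the IV-2a cue code convention).
#'
#' @param cfg a [sim_config()].
#' @return a list with `recording` (an `eeg_raw`), `labels` (integer 0-3 per
#'   trial), `onsets` (0-based trial onset samples) and `config`.
#' @export
simulate_subject <- function(cfg = sim_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  fs <- cfg$fs
  n_classes <- 4L
  n_trials <- cfg$n_trials_per_class * n_classes
  trial_len <- cfg$trial_secs[["mi_end"]] + cfg$iti_secs
  n_trial <- round(trial_len * fs)
  n <- n_trials * n_trial
  nchan <- length(cfg$channel_names)
  labels <- sample(rep(0:3, cfg$n_trials_per_class))
  onsets <- (seq_len(n_trials) - 1L) * n_trial

  sig <- matrix(0, nchan, n)
  for (ch in seq_len(nchan)) sig[ch, ] <- pink_noise(n, fs)

  motor <- c("C3", "C4", "Cz")
  idx <- match(motor, cfg$channel_names)
  rhythm_amp <- sqrt(cfg$snr / 2)               # per band, so mu+beta = snr
  mi0 <- cfg$trial_secs[["mi_start"]]
  mi1 <- cfg$trial_secs[["mi_end"]]
  erd_gain <- sqrt(1 - cfg$erd_depth)           # amplitude gain for ERD
  ers_gain <- sqrt(1 + cfg$erd_depth)           # amplitude gain for ERS

  # class x channel amplitude gains during imagery, [class, channel, band]
  gains <- array(1, c(4, 3, 2), dimnames = list(NULL, motor, c("mu", "beta")))
  gains[1, "C4", ] <- erd_gain                  # left hand -> contralateral
  gains[2, "C3", ] <- erd_gain                  # right hand
  gains[3, "Cz", ] <- erd_gain                  # foot
  gains[4, c("C3", "C4"), "beta"] <- ers_gain   # tongue: bilateral Beta ERS

  for (b in 1:2) {
    band <- if (b == 1) cfg$mu_band else cfg$beta_band
    for (m in 1:3) {
      carrier <- narrowband_noise(n, fs, band)
      env <- rep(1, n)
      for (tr in seq_len(n_trials)) {
        g <- gains[labels[tr] + 1, m, b]
        if (g != 1) {
          span <- onsets[tr] + seq_len(n_trial)
          env[span] <- mi_envelope(n_trial, fs, mi0, mi1, g)
        }
      }
      sig[idx[m], ] <- sig[idx[m], ] + rhythm_amp * carrier * env
    }
  }

  # EOG artifacts: slow (~0.5 s) high-amplitude lobes on the EOG channels
  eog_idx <- grep("^EOG", cfg$channel_names)
  n_art <- stats::rbinom(1, n, min(1, cfg$eog_rate / 60 / fs))
  if (n_art > 0 && length(eog_idx)) {
    centers <- sort(sample.int(n, n_art))
    half <- round(0.25 * fs)
    lobe <- exp(-seq(-half, half)^2 / (2 * (half / 2)^2))
    for (ct in centers) {
      span <- (ct - half):(ct + half)
      ok <- span >= 1 & span <= n
      w <- stats::runif(length(eog_idx), 0.5, 1) * sample(c(-1, 1), 1)
      amp <- stats::runif(1, 8, 15)
      for (k in seq_along(eog_idx))
        sig[eog_idx[k], span[ok]] <- sig[eog_idx[k], span[ok]] +
          amp * w[k] * lobe[ok]
    }
  }

  sig <- sig * 10                               # microvolt scale
  rec <- raw_recording(sig, cfg$channel_names, fs,
                       events = data.frame(onset = onsets,
                                           code = 769L + labels),
                       subject_id = sprintf("sim-seed%d", cfg$seed))
  list(recording = rec, labels = labels, onsets = onsets, config = cfg)
}

#' Band power of a channel segment (Welch estimate)
#'
#' Integrates a Welch power-spectral-density estimate (Hann windows, 50%
#' overlap) over a frequency band. With the density normalisation used the
#' integral over the whole spectrum approximates the variance of the segment
#' (Parseval's relation).
#'
#' @param rec an `eeg_raw` recording.
#' @param channel channel name.
#' @param band `(lo, hi)` frequency band in Hz.
#' @param window `(t0, t1)` window in seconds; default full recording.
#' @return scalar band power (non-negative), in squared signal units.
#' @export
band_power <- function(rec, channel, band, window = NULL) {
  validate_raw(rec)
  ch <- match(channel, rec$channel_names)
  if (is.na(ch)) stop("unknown channel: ", channel)
  x <- rec$signal[ch, ]
  if (!is.null(window)) {
    i0 <- floor(window[1] * rec$fs) + 1
    i1 <- floor(window[2] * rec$fs)
    if (i1 < i0 || i0 < 1 || i1 > length(x)) stop("empty or invalid window")
    x <- x[i0:i1]
  }
  if (length(x) < 8) stop("window too short for a spectral estimate")
  psd <- welch_psd(x, rec$fs)
  sel <- psd$f >= band[1] & psd$f <= band[2]
  sum(psd$p[sel]) * psd$df
}

# Welch PSD: one-sided density such that sum(p) * df ~= var(x).
welch_psd <- function(x, fs, nseg = NULL) {
  n <- length(x)
  if (is.null(nseg)) nseg <- min(n, max(64, 2^floor(log2(n / 4))))
  nseg <- min(nseg, n)
  step <- max(1, floor(nseg / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  U <- sum(w^2)
  starts <- seq(1, n - nseg + 1, by = step)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nseg %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / length(starts) / (fs * U)
  p[-1] <- p[-1] * 2                            # one-sided doubling
  if (nseg %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  list(f = (seq_along(p) - 1) * fs / nseg, p = p, df = fs / nseg)
}
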