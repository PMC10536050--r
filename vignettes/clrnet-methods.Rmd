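---
title: "Methods: preprocessing, architecture and simulation choices in clrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing, architecture and simulation choices in clrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clrnet)
```

This vignette is the package's account of its science: the decoding
problem, the model and its assumptions, the preprocessing mathematics, what
the synthetic-data generator emulates, and the choices made where the
design was genuinely open.

## The problem

In a four-class motor imagery experiment a subject imagines moving the left
hand, right hand, feet or tongue while 22 EEG channels (plus 3 EOG
channels) are recorded at 250 Hz. Imagined movement suppresses the Mu
(8–14 Hz) and Beta (16–24 Hz) sensorimotor rhythms over the contralateral
motor cortex (event-related desynchronisation, ERD) or enhances them
(ERS). Decoding means mapping a single trial's multichannel signal to its
class. The discriminative signal is weak, non-stationary and
subject-specific, which is why the pipeline combines targeted band
selection with a model that sees both the spatial pattern (which channels)
and the temporal envelope (when and how strongly power changes).

## Preprocessing

`preprocess_pipeline()` composes four stateless, per-trial stages. Because
no statistic is estimated from data (no whitening, no CSP, no baselines),
there is no train/test leakage by construction; a test asserts that
perturbing held-out trials cannot change training results.

**Band-pass 8–30 Hz.** A 4th-order Butterworth design applied
forward-backward (`signal::filtfilt`), so the effective magnitude response
is squared and the phase response is zero: rhythm timing is not shifted
relative to the cue. The filter runs on the continuous recording, before
epoching, so filter transients fall outside the extracted windows.

**EOG handling.** The three EOG channels are excluded, not regressed out:
the published channel count after removal (25 → 22) matches plain
exclusion, and regression would entangle EEG channels with ocular
artifacts estimated per recording. EEG rows are untouched bit-for-bit.

**Epoching.** The imagery window is seconds 3–6 relative to trial onset:
`start = onset + round(3 fs)`, half-open interval of `round(3 fs) = 750`
samples, 0-based indexing. Trials whose window would cross the end of the
recording raise an error naming the offending trial indices.

**Wavelet-packet band selection.** A five-level wavelet packet
decomposition with the orthonormal db4 filter pair splits each epoch into
32 leaves of 125/32 = 3.90625 Hz under frequency-ordered indexing. The
source description of this step is internally inconsistent — it states a
five-layer tree but prints band widths of 7.8125 Hz, i.e. a 16-band
partition. We decompose to level 5 and retain the four leaves whose union
is exactly 7.8125–23.4375 Hz, which honours both the stated depth and the
printed band edges (the two retained 7.8125 Hz bands are each the union of
two level-5 leaves). Three numerical points:

* *Frequency ordering.* The filter-bank tree's natural (Paley) order does
  not list leaves by frequency because the high-pass branch inverts the
  spectrum at every downsampling step. The natural-to-frequency
  permutation is the inverse Gray code of the path bits; the tests verify
  it by probing every claimed band with a tone at its centre and checking
  where the coefficient energy lands.
* *Odd lengths.* 750 is not divisible by 2^5; epochs are extended
  symmetrically to 768 samples, transformed, and truncated after
  inversion. The transform on the padded signal is exactly orthonormal, so
  retaining all leaves reproduces the input to machine precision
  (relative RMS < 1e-8, asserted).
* *Leaf selection.* A leaf is kept only if its band lies inside the
  retained interval (edge tolerance 1e-9 Hz); a configuration retaining no
  leaves is refused. Retained energy is monotone in the width of the
  retained band (property test).

**Resampling 750 → 240.** The published epoch length after reconstruction
is 240 samples and the reduction mechanism is not described. We resample
the reconstructed epoch to 80 Hz by the Fourier method (truncating the
spectrum and inverting), which is exactly lossless for content below
40 Hz — and the retained subbands end at 23.4375 Hz. Compared with a
polyphase FIR resampler this avoids designing a filter and introduces no
transient; the two agree for band-limited inputs. Resampling can be
disabled (`wpd_config(output_samples = NA)`).

db4 is the default wavelet: short enough to be cheap, long enough that the
subband filters are selective; the filter constants are the standard
orthonormal Daubechies coefficients. Note that db4's transition bands are
soft: a 10 Hz tone, 2.2 Hz above the 7.8125 Hz cut, keeps about 86% of its
energy after reconstruction (the PyWavelets reference implementation gives
0.885 on the same signal); a 40 Hz tone keeps under 8%. Expectations in the
tests were frozen from these oracle measurements.

## Architecture

An epoch enters the network as a 22 × 240 single-plane image — channels as
rows, time as columns. The convolutional front-end is four stride-1,
same-padded layers (128/128/256/256 filters, kernels 3×3, 3×3, 5×5, 5×5)
with 3×3 max pooling after conv 2 and conv 4 and dropout 0.5 after the
final pool. Two printed statements conflict ("a pooling layer after each
convolutional layer" vs "six layers: four convolutional and two pooling");
we follow the six-layer structure. The pooling is specified with stride 1
and same padding, which performs no downsampling; we implement it as
printed and expose a stride option (default 1) for the conventional
variant. The activation after each convolution is not stated; ReLU is
used. With stride-1 same padding throughout, the feature map stays
22 × 240 × 256.

The recurrent stack is five BiLSTM blocks of 100 hidden units per
direction with tanh cell activation, all returning sequences, so each
block maps a sequence to a 200-wide sequence. The cell follows the
standard gate equations (forget/input/output gates through the logistic
sigmoid, candidate through tanh); the batched C++ implementation is tested
for equality (≤ 1e-6) against a direct R transcription of those equations,
and the whole network's analytic gradients are checked against central
finite differences (agreement ≈ 1e-11 on a small instance).

Three interface points are not specified by the source and are our
design:

* *CNN → BiLSTM bridge.* The classification head of the CNN is dropped in
  the fused variants; the feature map is re-arranged so time (240) is the
  sequence axis with a 22·256-wide feature per step, and a learned linear
  projection reduces this to width 200. The projection keeps the first
  block's input width equal to the bidirectional output width, which the
  residual sums require, and bounds the parameter count.
* *Residual topology.* RES1 = B1 + B3, RES2 = RES1 + B5 are elementwise
  sums over full sequences (blocks return sequences, so full-sequence
  summation is the shape-consistent reading); they add no parameters, and
  `clrnet` and `cnn_bilstm` have identical parameter counts (asserted).
  A gradient-flow test shows the point of the topology: with blocks 3–5
  scaled toward zero, gradient still reaches block 1 through the
  cross-layer path, while the plain stack starves.
* *Read-out.* The last time step of RES2 feeds the dense-4 softmax head.

Weights are initialised from a uniform fan-in scheme
(U(−s, s), s = √(1/fan_in)) under a recorded seed; biases start at zero.
Inputs are z-scored per trial with a single mean and standard deviation
across all channels and samples — a stateless transform that brings
microvolt amplitudes to the unit scale the saturating nonlinearities
expect while preserving the relative channel amplitudes that carry the
ERD/ERS contrast (per-channel scaling would erase exactly that feature).

## Training

Mini-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on categorical
cross-entropy, batch size 8, 200 epochs by default ("iterations" in the
source is read as training epochs, the common usage in this literature;
both are configurable). The learning rate is not published; the default is
1e-3. Gradients are clipped to a global norm of 5, a standard stabiliser
for recurrent stacks; without it small-batch training of the fused
variants occasionally diverges for an epoch before recovering. No early
stopping and no schedule, as none are described. Training is deterministic
given the seed, which fixes shuffling order and dropout masks; weight
initialisation is fixed separately by the model's build seed.

Accuracy is the evaluation index; `evaluate_model()` also returns the 4×4
confusion matrix (true classes in rows), whose trace over total equals the
accuracy by construction. The train/evaluation protocol behind the
published per-subject numbers is not described (the benchmark has separate
T and E sessions, but a within-session split cannot be ruled out);
`run_ablation()` therefore supports both an explicit held-out session
(`test_data =`) and a stratified 50/50 split standing in for two sessions.

## The simulator

`simulate_subject()` generates the paradigm exactly: 25 named channels
(22 EEG + 3 EOG) at 250 Hz, 72 trials per class presented in random order,
trial timing 0–2 s preparation, cue at 2 s, imagery 3–6 s, followed by
1.5 s inter-trial rest (the within-trial timing is prescribed; the rest
interval is our choice). Every channel carries 1/f background noise
(α = 1 power spectrum, flat below 1 Hz, plus a 20% white floor) — the
standard resting-EEG spectral shape. The motor channels C3, C4, Cz
additionally carry Mu- and Beta-band rhythm carriers built as
band-filtered white noise, i.e. amplitude-modulated narrowband processes
rather than pure sines, so the wavelet-packet stage is exercised
meaningfully. During the imagery window the class scales rhythm amplitude
with 0.2 s raised-cosine ramps: left hand attenuates C4 (contralateral),
right hand C3, foot Cz (power factor 1 − erd_depth), and tongue enhances
Beta bilaterally at C3/C4 (factor 1 + erd_depth). `snr` sets the ratio of
baseline rhythm power to background power at the motor channels. EOG
channels carry slow high-amplitude lobes at `eog_rate` per minute.
Identical configurations (including the seed) produce bit-identical
recordings.

What it does not emulate: volume conduction and channel covariance,
inter-subject variability, non-stationary drifts, line noise, or artifacts
in EEG channels. Passing the recovery tests therefore shows the pipeline
and model are wired correctly and can exploit ERD/ERS structure — not that
the published benchmark accuracies are reproduced; real EEG is harder.

## Problem sizes used in the tests

The test and acceptance runs use the `"compact"` model preset: the same
topology with conv filters 4/4/8/8, hidden width 16 and projection width
32 (≈ 40k parameters), trained 30 epochs on a 288-trial simulated subject
with `erd_depth = 0.8`, `snr = 4` under a stratified 50/50 split. These
sizes were fixed as the package's CPU-scale study conditions. The full
published geometry (128/128/256/256, hidden 100, ≈ 4.9 M parameters) is
built and forward-checked in the tests; training it is a multi-hour CPU
job and is left to users with the real dataset. The ablation ordering
check runs at further reduced scale (96 trials, 6 epochs) and is logged
rather than asserted, as a 5-seed full-scale comparison would be a
CPU-hour-scale computation.

## Known limitations

* The stride-1 same-padded pooling performs no downsampling; it is kept
  for fidelity to the printed specification, at the cost of a large CNN
  feature map.
* GDF support covers the 2.x layout used by the target benchmark
  (validated by round-trip and by cross-reading with an independent
  reader during development); GDF 1.x and EDF variants are not read.
* EOG influence is handled by channel exclusion only; regression/ICA
  cleaning of the EEG channels is out of scope.
* The internal archive format is an R serialisation with a container tag;
  it is lossless and self-describing but not a cross-language interchange
  format.
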