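---
title: "Separating tremulous from voluntary motion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating tremulous from voluntary motion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorsep)
```

## The model

Hand-arm orientation signals from people with Parkinsonian tremor are a
mixture of intended (voluntary) movement, spectrally confined below 3 Hz,
and involuntary tremor between 3 and 10 Hz, sampled here at 100 Hz. The
package separates the two adaptively — no fixed cut-off — by empirical mode
decomposition, and then classifies fixed-length windows of the resulting
modes with a small sequence network, so that the decision "tremulous or
voluntary" is learned from the data rather than engineered.

### Empirical mode decomposition

EMD extracts *intrinsic mode functions* (IMFs): oscillations whose
zero-crossing and extrema counts differ by at most one and whose local
envelope mean is near zero. One IMF is obtained by **sifting**: find the
local extrema of the working signal, interpolate cubic-spline envelopes
through maxima and minima, subtract the envelope mean, and repeat on the
result. The loop stops when the Cauchy-type criterion

$$D_j = \frac{\sum_t |h_{j-1}(t) - h_j(t)|^2}{\sum_t |h_{j-1}(t)|^2}$$

drops below a threshold. The extracted IMF is subtracted from the running
residual and the process repeats until the residual is monotone (fewer than
two maxima or minima). The decomposition telescopes: IMFs plus residual
reproduce the input to floating-point accuracy.

**EEMD** (ensemble EMD) addresses EMD's *mode-mixing* failure — disparate
frequencies sharing one IMF when a component is intermittent — by
decomposing $N$ noise-perturbed copies $x^n = x + w^n$ and averaging IMFs
index-wise. The white noise populates every scale uniformly, anchoring the
dyadic sieve; it cancels in the ensemble mean at rate $1/\sqrt N$.

### Classification

Each IMF is cut into non-overlapping windows of 50 samples (0.5 s at
100 Hz), the final window zero-padded at its end. Windows from the tremulous
modes (IMF1+IMF2 by default, and that default is re-derivable from the
benchmark module) are labeled positive. The classifier is a convolutional
bi-directional LSTM: two ReLU convolutions (30 filters, kernels 20 and 10)
each followed by max-pooling of 2, a per-time-step single-unit ReLU dense
layer, a bi-directional LSTM with 64 cells per direction, a tanh on the LSTM
outputs, and a single sigmoid unit. Training is plain SGD (learning rate
0.01, batch 64) on binary cross-entropy. Baselines: the same front-end with
a uni-directional LSTM, and KNN (k = 3, Euclidean, z-scored features) and
Gaussian naive Bayes on four window features — Hilbert instantaneous
frequency, Pearson kurtosis, crest factor (peak/RMS), and sample entropy.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| Sifting threshold on $D_j$ | 0.2 | not stated by the source method; the conventional Cauchy-criterion value. Smaller values over-sift, draining the leading mode (see below) |
| `max_siftings` | 50 | guard against non-convergence |
| Ensemble size $N$ | 100 | convention for noise-assisted EMD; residue noise scales as $1/\sqrt N$ |
| `noise_std_ratio` | 0.2 | noise SD as a fraction of signal SD, the standard pairing with $N = 100$ |
| Benchmark filters | 4th-order Butterworth, 3–10 Hz band-pass / 3 Hz low-pass, zero-phase | zero-phase (forward–backward) because the references are used as phase-faithful targets; a causal option exists behind `zero_phase = FALSE` |
| Window length | 50 samples | 0.5 s at 100 Hz, the published windowing |
| Split | 80:20, shuffled, 10 repeats | the published re-training protocol; a `subject_holdout` mode (48/12 subjects at the default ratio) is provided to measure generalization without subject leakage |
| LSTM cells | 64 per direction | published size (performance converges above ~60) |
| Optimizer | SGD, lr 0.01, batch 64, BCE | published settings; no momentum because none is stated |

## The synthetic world

The clinical recordings behind the method are not distributable, so the
simulator emulates their *described* statistical structure, per activity
(resting, outstretching, wing, drinking):

- **Voluntary component**: 3–6 random sinusoids with frequencies uniform in
  [0.2, 2.5] Hz, peak-scaled; drinking additionally gets a slow
  raised-cosine reach-and-return trajectory (four cycles per recording),
  making it dynamic and multi-phase.
- **Tremor component**: per-subject carrier uniform in [3.5, 9] Hz with
  ±0.3 Hz slow wobble and 10–50% amplitude modulation — tremor frequency and
  amplitude vary across subjects and activities.
- **Corruption**: white Gaussian sensor noise (0.1° SD), linear drift
  (0.1°/s), and 1% missing samples (never at the endpoints, so gap filling
  never extrapolates).
- **Amplitudes** (degrees, peak): resting 0.5 voluntary / 2.5 tremor;
  outstretching 1 / 2; wing 1 / 1.5; drinking 12 / 4. The source reports no
  amplitude statistics, so these are fixed once as plausible orientation
  excursions, with drinking given the largest sweep and the strongest, most
  distinct tremor (its dynamic task elicits kinetic + postural tremor).
  Static actions last 10 s (1000 samples); drinking 12 s.

What the simulator does **not** emulate: non-Gaussian sensor error, sensor
fusion artifacts of a real AHRS, medication state, tremor intermittency
within a recording, inter-axis coupling, or amplitudes calibrated to any
clinic. A green test therefore establishes that the pipeline recovers the
structure this world *states* — band-separated components mixed additively —
not clinical performance.

## Numerical choices and degenerate inputs

- **Envelopes**: natural cubic splines with the two nearest extrema mirrored
  about each endpoint (anti edge-swing); the source is silent on boundary
  handling.
- **Sifting stop**: Cauchy criterion only, which is the operative rule of
  the source method. The ideal-IMF zero-crossing/extrema parity then holds
  exactly for clean modes and within a few percent of the extrema count for
  the noise-dominated leading mode. Enforcing parity *inside* the loop was
  implemented and rejected: the additional sifting pushes the tremor band
  down the mode ladder and destroys the IMF1+IMF2 recovery property.
- **EEMD members with fewer modes** are zero-padded up to the ensemble-wide
  maximum before averaging; EEMD means are not themselves forced to be valid
  IMFs (a known property of the method).
- **Butterworth design** is done in-package (bilinear transform of the
  analog prototype; no DSP package ships with the supported stack) and
  matches the reference implementation's coefficients to printed precision;
  zero-phase filtering uses odd-extension padding with steady-state initial
  conditions.
- **log-RMSE floor**: an RMSE below 1e-15 (exact match) reports −15 with an
  `exact_match` flag instead of −∞.
- **Degenerate windows**: constant windows yield instantaneous frequency 0
  and sample entropy 0 with a `degenerate` flag; kurtosis and crest factor
  report `NA`. Undefined confusion ratios (zero denominators) are flagged
  `NA`, never silently 0, so mean ± SD aggregation stays honest.
- **Ties**: sigmoid scores at the decision threshold go to the positive
  class; KNN distance ties break toward the lower training index; naive
  Bayes posterior ties go positive.
- **Zero-padded tails** are trimmed before computing features (`pad_len` is
  tracked per window); padding is a sequence-model convenience, not signal.

## Open design points and how they were fixed

The source description leaves several architecture details open; each was
decided once and is configurable:

- **Convolution padding**: `same` (sequence 50 → 25 → 12 steps into the
  LSTM). `valid` collapses 50 → 3 steps, starving the recurrent layer; it is
  implemented for comparison.
- **Bi-directional merge**: concatenation of the final forward and backward
  hidden states (128 values) into the sigmoid unit.
- **Post-LSTM tanh**: applied as described, although LSTM outputs already
  pass through tanh; `post_lstm_tanh = FALSE` disables it.
- **Input scaling**: each window is divided by its peak magnitude
  (`input_scaling = "maxabs"`). Bounded inputs keep plain SGD stable at the
  stated learning rate, and window amplitude is uninformative for
  index-based labels; `"none"` feeds raw degrees.
- **Instantaneous frequency estimator**: mean phase-derivative of the
  analytic (Hilbert) signal over the window interior, the standard choice
  where the source only cites one.
- **Sample entropy**: m = 2, tolerance 0.2·SD — the standard
  regularity-analysis defaults, unstated in the source.
- **Combination selection**: the benchmark comparison averages each
  combination's log-RMSE over several recordings before taking the minimum,
  as the published comparison averages over patients within an activity; a
  single low-carrier recording can legitimately prefer IMF2 alone (the
  published table shows the same for its drinking activity).
- **Detrending order**: interpolation before detrending, since detrending
  needs complete data; the source does not state the order.

## Known limitations

- EEMD runs 100 EMDs per signal; even with the compiled sifting core this
  dominates pipeline runtime (the source method reports the same bottleneck
  and defers real-time use).
- The 10× re-training protocol shuffles at the window level, so windows of
  one subject can appear in both train and test; use
  `mode = "subject_holdout"` for leakage-free estimates (expect lower
  numbers).
- Tremor carriers near the 3 Hz boundary blur into the voluntary band — the
  fixed-filter benchmark and the decomposition both degrade there.
- The conv-biLSTM is trained with plain SGD as published; convergence within
  the published 100 epochs depends on the bounded input scaling described
  above.
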