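---
title: "lfpgait: methods, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lfpgait: methods, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The measurement model

### Signals

Two synchronized streams per visit of a stepping-in-place task:

* **LFP**: bilateral subthalamic local field potentials, natively 422 Hz,
  decimated to 211 Hz and causally band-pass filtered to 8–100 Hz with a
  4th-order Butterworth IIR filter. All filtering in this package is a
  single causal pass: the intended downstream use is real-time control of
  stimulation, where zero-phase (forward–backward) filtering is
  unavailable. The IIR family is not specified by the reference protocol;
  the convention we follow is that an "order-4 band-pass" has 4 analog prototype poles and
  hence a degree-8 digital denominator, matching `scipy.signal.butter` and
  MATLAB. Filter coefficients are exposed (`butter_design`,
  `attr(rec, "filter")`) and logged by the CLI for reproducibility.
* **Force**: left/right ground-reaction forces at 100 Hz (1000 Hz sources
  are decimated by 10), low-pass filtered at 2 Hz to suppress jerky
  non-gait transients.

Decimation anti-aliasing uses an 8th-order Butterworth low-pass at 0.8× the
target Nyquist before sample dropping; the reference protocol does not specify
this, and the choice is standard practice.

### Weight shift

Per visit: divide both plates by the body weight (the mean of the summed
plates over a manifest-declared motionless baseline, taken on the
*unfiltered* trace because the causal low-pass has a start-up transient
inside the baseline window); merge per sample by taking the larger plate
value, mirroring the right plate about 0.5 so that full left loading reads
1, full right loading 0 and balanced stance 0.5; then slide a 2-s window at
0.1-s stride and record the **total variation** of the merged trace inside
each window.

The amount of "change" of the merged trace over a two-second window is
not pinned to a formula by the reference protocol, so the statistic is a
documented design decision. Total
variation (the sum of absolute first differences of the 2 Hz-low-passed
trace) was chosen because it is exactly 0 for quiet standing, grows with
both excursion amplitude (it is 1-homogeneous) and stepping cadence, and is
direction-agnostic. The main alternative, windowed range (max − min),
saturates at one excursion per window and cannot distinguish one step from
three; it remains noted here as the plausible competing reading. The
mirrored plate is fixed (right) by convention; the suite verifies that
swapping plates maps the merged trace m → 1 − m and leaves shift values
unchanged, so the choice is immaterial. Ties (left = right) take the left
sample; off 0.5 they are measure-zero, at 0.5 both branches agree.

Normalization maps the maximum 2-s shift across **all** the participant's
visits to 1, as the quoted procedure states, even though that couples the
label scale across train/validation/test; `normalize_across_visits(...,
normalizer_from = "train")` restricts the normalizer to the training visit
for users who want strict separation.

### Windowed examples

One example per 0.1-s label time ≥ 5 s: a 5-s, 2-lead LFP window (1055
samples at 211 Hz) labeled with the weight shift over the window's final
2 s. A 0.1-s stride is 21.1 LFP samples, which is not an integer; window
end times live on the force grid and map to the nearest LFP sample (≤2.4 ms
misalignment, far below any period of interest). A 100.0-s task yields
exactly `floor((100 − 5)/0.1) + 1 = 951` examples. LFP windows are not
amplitude-normalized: the first batch-normalization layer handles scale
(a per-channel z-scoring switch is deliberately absent from the default
path to keep train/test statistics honest).

## 2. The network

Four blocks, in order. Shapes below use the defaults.

1. **Feature extraction.** Depthwise 1-D convolution: 32 filters per lead,
   kernel 63 samples (~0.3 s), same padding, *no bias*, no cross-lead
   mixing → batch normalization → elementwise **squaring** → average
   pooling (length 53, stride 11), imitating band-power estimation. Output:
   64 features × 92 time steps (~19 Hz frame rate — enough to represent
   beta-burst dynamics, which motivated the pooling geometry). With
   division enabled, each lead's 32 features split into 16 numerators and
   16 denominators; the output is `[numerators; numerators/(denominators +
   1e-6)]`, so the feature count is preserved and denominators never appear
   as standalone features. The numerator/denominator split ("half of the
   same-group features") is by feature index: first half numerators. The
   ε = 1e-6 stabilizer is a design choice of this package.
2. **Squeeze-and-excitation.** Per time step: encode the 64-vector to 16
   (reduction 4, with bias), ReLU, decode to 64 (with bias), sigmoid;
   multiply the gates into the features. Parameters are shared across time
   steps. This is the **only** block with bias parameters — including the
   batch-norm layers, which therefore carry a learnable scale γ but no
   shift β (a shift is a bias). The structural report audits this for every
   variant.
3. **Bidirectional LSTM.** Three stacked bias-free BiLSTM layers, 64 hidden
   units per direction; output concatenates forward and backward states per
   step (128 × 92).
4. **Regression head.** Groupwise temporal convolution (groups = forward /
   backward, kernel 5, 16 channels per group, no bias) → pointwise
   convolution merging the groups to 16 channels → global temporal average
   → dense layer to one **preactivation** scalar → prediction =
   ReLU(preactivation). The head is linear up to the final ReLU; no
   other activation is specified for this block. The preactivation is
   exposed because the variation ratio needs it. Bi-ablated variants feed
   the 64 × 92 feature map to the head with groups = 1.

None of the hidden sizes (filters, kernel, pooling, SE bottleneck, LSTM
width, head geometry) are prescribed by the reference protocol; all are `model_config()`
defaults and every one is overridable.

The eight variants map names to block flags: `FExt` (feature extraction
*including* division, + head), `±SE`, `±Bi`, and `-Div` to remove the
division. The complete model is `FExt+SE+Bi` (alias `"full"`). Division
adds no parameters, so `-Div` counterparts have identical parameter counts
— asserted in the suite.

### Implementation

No R deep-learning framework is available in the target environment, and
the network is the package's core contribution, so forward and backward
passes are hand-written vectorized R over BLAS (`Matrix` supplies sparse
pooling/averaging operators). Activations after pooling use a time-major
column layout so each LSTM step and each temporal shift is a contiguous
block. Gradients for every block — including batch norm in batch-statistics
mode, the division, the SE gates and BPTT through both LSTM directions —
are verified against central finite differences to a 1e-4 relative
tolerance in `test-model.R`, for multiple variants.

## 3. Training and evaluation

ADAM (β₁ 0.9, β₂ 0.999, ε 1e-8 — conventional; only the learning rate is part of
the stated training protocol), learning rate 1e-5, L1 loss, batch 16 on shuffled
minibatches (the last short batch is used, not dropped), at most 2000
epochs, early stopping when validation L1 (mean per example) has not
**strictly** improved for 100 epochs, and the best-validation-epoch
parameters are returned. Subject-dependent: one model per participant.

**Fast CI profile** (`training_config(fast = TRUE)`): learning rate 1e-3,
30 epochs, patience 10, combined with training/validation window
subsampling (every 5th window). This deviates from a bare
"fewer-epochs-only" reading deliberately: at learning rate 1e-5, a few
hundred ADAM steps move the parameters by ~1e-3 of their scale and nothing
measurable is learned, while the full 2000-epoch protocol at full window
density costs days of single-CPU time. The fast profile is a CI device for
the property tests; the default profile is the faithful one.

Metrics: MAE, MSE, and Kendall **tau-b** between predictions and labels.
The tie correction matters because ReLU predictions and motionless labels
both pile up at 0; the protocol names Kendall tau without a variant. The
baseline comparison computes per-lead 2-s average **beta power** (13–36 Hz,
same causal 4th-order design, squaring + window averaging — consistent with
the feature block's power-imitation framing, rather than a spectral
estimator) and reports the lower/higher of the two leads' taus next to the
model's. Group-level Mann–Whitney / Wilcoxon utilities are provided as thin
wrappers (thresholds 0.05 and 0.025) but reproduce no reference numbers —
the cohort data are not available.

## 4. Variation ratio

For each of six bands — ≤8 (delta/theta), 8–13 (alpha), 13–20 (low-beta),
20–36 (high-beta), 36–70 (low-gamma), ≥70 Hz (high-gamma) — the training
LFP is band-pass filtered, windowed exactly like the training set, and run
through the trained model; the unbiased sample variance of the **pre-ReLU**
outputs is computed per band and the six variances are normalized to sum
to 1. Open-sided bands are implemented as 1–8 Hz and 70–104 Hz: a 4th-order
IIR is unstable too close to DC or Nyquist (105.5 Hz), and the 1 Hz /
104 Hz edges change the captured band energy negligibly. Band filtering
applies to the 8–100 Hz analysis stream by default (mirroring the pipeline
ordering); the unfiltered 211 Hz stream can be passed instead — both
orderings are supported and the report records which was used. Bootstrap
CIs across replicates are percentile intervals (10,000 seeded resamples);
no CI method is prescribed, so this is a documented choice.

Interpretation caveat (inherited from the method itself): a large ratio
says the trained model's output varies with that band's content, not that
the band is physiologically coupled to gait — with relative features the
model may use a band purely as a reference denominator. Band-pass leakage
also spreads variance into adjacent bands; the toy-model test asserts that
leakage stays strictly below the in-band ratio rather than pretending it is
zero.

## 5. The synthetic world

`synthetic_spec()` defaults are the generator's stated world, chosen once:

| parameter | default | rationale |
|---|---|---|
| duration | 100 s | task protocol length ("approximately 100 seconds") |
| cadence | 0.8 Hz | self-paced alternating stepping |
| body weight | 800 N | ~80 kg adult |
| baseline | 5 s motionless | weight estimation segment |
| vigor a(t) | smoothed random walk min-max mapped to [0,1] | label ranges then span ~(0, 1) like real per-visit ranges |
| coupling | high-beta, sign +1, strength 1 | positive beta–gait association; strength 1 = band amplitude doubles at peak vigor |
| aperiodic exponent χ | 1.5, +0.25 per visit | 1/f slope in the STN LFP range, drifting across visits to emulate aperiodic change between sessions |
| oscillation amplitudes | alpha 0.5, low-beta 0.4, high-beta 0.5, low-gamma 0.3 (aperiodic sd 1) | band peaks visible above the in-band 1/f floor |
| envelope fluctuation | ±30% at ≤2 Hz | burst-like sub-second amplitude variation |
| LFP white noise | sd 0.2 | sensing noise floor |
| plate ripple / noise | 1% of W at ≤3 Hz, 2 N white | plates are not perfectly complementary, so the merge/mirror max logic is genuinely exercised |

Forces: `L = (W/2)(1 + a(t)·s(t))`, `R = W − L` plus per-plate ripple and
noise, `s(t) = tanh(3 sin(2π f t))` a smoothed square-ish alternation,
floored at 0. LFP: spectrally synthesized 1/f^χ background + sinusoidal
carriers with slow positive envelopes, the coupling band's envelope
multiplied by `1 + sign·strength·a(t)`; channels share the vigor but have
independent phases, envelopes and noise.

What the generator does **not** emulate: biophysical STN dynamics,
stimulation artifacts, cardiac/gait artifacts, freezing episodes,
inter-participant variability, or nonstationary cadence. A green end-to-end
test therefore establishes that the pipeline recovers a known coupling
through the full preprocessing/training/attribution chain — not that the
model works on patient data.

## 6. Numerical and degenerate-input choices

* Filters: causal direct-form application, initialized at the DC steady
  state of the first sample (`x - x[1]` is filtered and `x[1]·H(0)` added
  back), so constant input gives constant output from sample 1 — with zero
  initial conditions the 2 Hz force low-pass would manufacture spurious
  weight shift out of its own start-up transient. Stability is asserted by
  pole radius; steady-state gain checks discard transients.
* Decimate-then-band-pass is the fixed pipeline ordering. The reverse
  ordering agrees in signal power within 2% for band-limited input
  (asserted), but not sample-wise: causal filters designed at different
  rates differ in group delay, and no zero-phase pass is available in the
  real-time setting.
* Batch norm: ε 1e-5, running-statistics momentum 0.1; evaluation mode uses
  running statistics, making predictions batch-size invariant (asserted to
  1e-5).
* Early stopping: "improvement" is strictly lower than the best seen
  (tolerance 0); validation loss is mean-per-example, not per-batch.
* Degenerate inputs: all-zero weight shifts refuse to normalize ("no
  movement detected"); constant series refuse a Kendall tau; zero total
  output variance refuses a variation ratio; recordings shorter than one
  window return empty series with a warning.
* Seeds: every stochastic component (parameter init, shuffling, generator,
  bootstrap) takes an explicit integer seed; per-visit seeds derive from
  the template seed by small integer offsets (< 2^31).

## 7. Known limitations

* Weight-shift statistic: if the original "change in force" was windowed
  range rather than total variation, absolute label scales differ (ranks
  largely agree); the package pins one reading and documents it.
* The fast profile's learning rate (1e-3) is not the reference value; only
  the default profile replicates the stated optimization protocol.
* Training at the full protocol (2000 epochs, 951 windows) is CPU-days in
  this pure-R implementation; the implementation is faithful but not fast
  enough for that protocol without a compiled backend.
* The division's numerator/denominator split by feature index is one of
  several readings of "half of the same-group features"; since filters are
  learned, the split is symmetric up to initialization.
* Stimulation-artifact robustness is out of scope by design.
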