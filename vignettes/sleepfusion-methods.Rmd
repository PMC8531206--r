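---
title: "Multimodal sleep staging with adaptive time-frequency features and deep fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal sleep staging with adaptive time-frequency features and deep fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sleep is scored by experts in 30-second epochs into five AASM stages — wake
(W), three non-REM depths (N1, N2, N3) and REM — from overnight
polysomnography (PSG). Manual scoring of an eight-hour night is slow, so
automatic staging from a small montage (one EEG channel, one EOG channel) is
a long-standing goal. Two difficulties dominate: the signals are
non-stationary, so fixed-basis time-frequency representations (short-time
Fourier, wavelets) blur exactly the transients that matter (spindles,
K-complexes, eye-movement bursts); and no single modality carries all the
discriminative information — REM and N1 look nearly identical on EEG and are
separated mainly by the eyes, while N2 and N3 are separated by the EEG
delta/spindle content and not by the EOG.

`sleepfusion` implements a staging pipeline built around those two
observations:

1. **Adaptive features.** Each epoch is decomposed by empirical mode
   decomposition (EMD) into intrinsic mode functions (IMFs); the Hilbert
   transform of each IMF gives instantaneous amplitude and frequency, which
   are accumulated into a time-frequency energy image (the Hilbert
   spectrum). Nothing about the basis is fixed in advance.
2. **Heterogeneous subnetworks.** The 30 s EEG epoch is cut into six 5 s
   sub-segments, each yielding a 30 x 30 spectrum; the stacked 6 x 30 x 30
   tensor feeds a 3D convolutional network (the EEG tensor network, ETN)
   that respects locality in time-of-night, frequency and time. The 30 s
   EOG epoch is transformed whole into a 30 x 30 spectrum read as a
   sequence of 30 one-second spectral slices by a 200-unit LSTM (the EOG
   tensor network, OTN).
3. **Probabilistic fusion.** The 384-dimensional ETN feature and the
   200-dimensional OTN state are concatenated (584 values) and fed to a
   deep belief network (584 -> 300 -> 200 -> 100 -> softmax 5): a stack of
   restricted Boltzmann machines pretrained greedily with contrastive
   divergence, then fine-tuned end-to-end with cross-entropy. The RBM stack
   models the joint distribution of the two modalities' features rather
   than treating them as independent.

Class imbalance (N1 and N3 are rare) is addressed by training the
subnetworks with class-balanced focal loss
$\mathrm{FL} = -\alpha_{y}\,(1-p_{y})^{\gamma}\log p_{y}$.

## Index conventions

All confusion matrices, probability vectors and label files use the scoring
order **W = 1, REM = 2, N1 = 3, N2 = 4, N3 = 5** (`stage_levels()`). R&K
stages 3 and 4 are merged into N3 on ingestion, and unscorable epochs
("Sleep stage ?", "Movement time") are dropped.

## Preprocessing

EDF/EDF+ recordings are read with the package's own reader (signals in
physical units, annotations as onset/duration/label events). EEG is
band-passed 0.5–32 Hz and EOG 0.5–10 Hz with an order-3 Butterworth filter
applied forward–backward: the zero-phase choice preserves the waveform
morphology scorers rely on, at the price of squaring the magnitude
response (still ≥ 0.95 gain across the passband interior). Recordings above
100 Hz are resampled to 100 Hz by zero-stuff / zero-phase FIR / decimate.
Epochs are half-open 30 s windows `[t, t + 30)` aligned to hypnogram onsets;
an epoch is rejected when more than 5% of samples sit at the recorder's
saturation limits or any channel is constant for over a second (electrode
detachment). A `trim_wake` option is deliberately **not** provided: long
pre/post-sleep wake is kept, and the wake share of the synthetic corpus
matches that choice.

## Numerical choices in the decomposition

* **Sifting stop.** A candidate mode is accepted once the Cauchy criterion
  $\sum m_k^2 / \sum h_{k-1}^2 < 0.2$ *and* the candidate satisfies the
  defining IMF property (extrema and zero-crossing counts within one).
  The second condition matters: the energy criterion alone stops several
  sifts too early on broadband signals, leaving modes that are not IMFs.
  A cap of 50 sifts per mode guards against pathological inputs.
* **Envelopes.** Natural cubic splines through the local extrema, with two
  extrema mirrored across each boundary (and the endpoint itself added as
  a knot when mirroring cannot bracket it). Mirroring controls the
  well-known envelope divergence at the edges.
* **Termination.** Decomposition stops at 10 IMFs, on a residual with
  fewer than four extrema, or when the residual energy falls below
  1e-12 of the input energy (numerical completeness guard; without it,
  float noise after a pure tone is "decomposed" into junk modes).
* **Instantaneous frequency.** Centred difference of the unwrapped
  analytic phase, 5-point moving average, clipped to [0, fs/2]. The
  smoothing suppresses the difference operator's noise amplification
  without biasing a linear chirp (R^2 of the recovered ramp is tested at
  0.99).
* **Grids.** 30 frequency bins over 0.5–32 Hz (EEG) and 0.5–10 Hz (EOG) —
  equal to the preprocessing passbands — and 30 time bins. The 30 x 30
  geometry is not arbitrary: back-propagating the convolutional
  architecture's reference output shapes under stride-2 same-padding
  convolutions forces a 30 x 30 input face, and the recurrent subnetwork's
  declared contract is 30 inputs x 30 time steps. A shape-conformance test
  asserts the full chain.
* **Scaling.** Per-epoch `log(1 + x)` then min–max to [0, 1]. Energies span
  orders of magnitude; the log makes the images well-conditioned network
  inputs, and per-epoch normalisation (rather than per-subject or global)
  makes each epoch self-contained — the flag `normalize = "none"` exposes
  raw energies. EOG images are stored time-major (rows = seconds), matching
  the LSTM's stepping direction; the transposed reading is equally
  defensible a priori, but time-major is the one consistent with stepping
  "values that change with time" through a recurrent model.

## Architecture

The ETN follows the reference hyper-parameter table exactly; with
TensorFlow-convention "same" padding (the only padding scheme that
reproduces the reference output shapes from a 6 x 30 x 30 x 1 input):

| layer | kernel / stride / filters | output |
|---|---|---|
| conv1 | (2,5,5) / (1,2,2) / 16 | 6 x 15 x 15 x 16 |
| conv2 | (2,5,5) / (1,2,2) / 16 | 6 x 8 x 8 x 16 |
| pool1 | (1,2,2) / (1,2,2) | 6 x 4 x 4 x 16 |
| conv3 | (2,3,3) / (1,2,2) / 16 | 6 x 2 x 2 x 16 |
| pool2 | (1,2,2) / (1,1,1) | 6 x 2 x 2 x 16 |
| conv4 | (2,3,3) / (1,2,2) / 32 | 6 x 1 x 1 x 32 |
| pool3 | (2,1,1) / (1,1,1) | 6 x 1 x 1 x 32 |
| conv5 | (2,1,1) / (1,1,1) / 64 | 6 x 1 x 1 x 64 |

Batch normalisation sits after every convolution, before its ReLU. The
flattened 384-vector is the fusion feature. The OTN is a single-layer LSTM
(input 30, 30 steps, 200 hidden units, forget-gate bias 1). Both
subnetworks carry an auxiliary 5-way softmax head used *only* to train them
with focal loss; the heads are discarded at fusion time. The networks are
implemented directly on matrix algebra (im2col index plans + BLAS, with the
convolution gather/GEMM in compiled code); exact gradients are verified
against numerical differentiation in the test suite.

## Training protocol and defaults

* Adam, learning rate 1e-3, minibatch 128, up to 50 epochs (scaled-down
  runs use fewer; see below), He-normal initialisation, L2 weight decay on
  all weight matrices. The L2 coefficient (1e-4) is a package default; it
  is not part of the reference protocol.
* Focal loss: $\gamma = 2$; $\alpha$ = (0.6, 0.8, 0.9, 0.6, 0.9) in scoring
  order W, REM, N1, N2, N3. The reference weight set {0.6, 0.9, 0.6, 0.9,
  0.8} comes without a stated class order; assigning 0.9 to the minority
  stages N1 and N3 is the only reading consistent with its purpose of
  counterweighting the class distribution.
* DBN: the Gaussian-visible first RBM runs on per-dimension standardized
  features with $\sigma_i$ fixed at 1 (standardize-then-unit-sigma is the
  stable default for Gaussian–Bernoulli machines); CD-1 with learning rate
  1e-3 and 10 epochs per layer (pretraining hyper-parameters are package
  defaults — the method's original description specifies only greedy layer-wise
  training); hidden *probabilities*, not samples, are propagated as the
  next layer's training data (lower variance, common practice). Fine-tuning
  uses cross-entropy, Adam 1e-3, minibatch 32 — the reference batch of 128
  is stated for the subnetwork stage; 32 keeps a useful number of gradient
  steps per epoch on small corpora.
* Two formulas in the method's original description required
  interpretation, both flagged in the code: the hidden-unit conditional is
  written there as a Gaussian, dimensionally
  impossible for binary units, and is implemented as the standard logistic
  $p(h_j{=}1\mid v) = \sigma(b_j + \sum_i w_{ij} v_i/\sigma_i)$; and the
  visible conditional's bias symbol is read as the visible bias $a_i$.
  The focal modulating factor $(1 - p_{pre} \cdot p_{label})^\gamma$ is
  read as a one-hot inner product selecting the true-class probability.
* Subnetworks are **frozen** during fusion training by default;
  `pipeline_config(unfreeze_subnets = TRUE)` enables a joint fine-tuning
  pass that backpropagates the fusion loss into both subnetworks.
* A `val_fraction` option can hold out a sample fraction to keep the best
  epoch by validation accuracy. It defaults to 0: with the handful of
  training subjects used in scaled runs, a subject-level validation split
  is too unstable to select models on, so the original idea of a
  validation split is exposed as an option rather than a default.

## The synthetic corpus: what it emulates, and what it does not

Real Sleep-EDF recordings cannot be bundled, so the package generates PSG
with the stage structure a scorer would recognise, at 100 Hz in microvolts:

* **Hypnogram.** A first-order Markov chain whose stationary distribution
  equals the healthy-sleeper stage mix (W 30.6%, REM 14.5%, N1 8.7%,
  N2 38.1%, N3 8.0%). Each epoch stays in its stage or redraws from the
  stationary mix with probability 0.2 (mean bout ~2.5 min). Nights of 100+
  epochs are redrawn until every stage occurs — a 100-minute "night"
  missing REM entirely is not a realistic recording, and subject-held-out
  evaluation needs every stage on the test side. Real sleep has longer
  memory (cycles); a first-order chain is sufficient for a per-epoch
  classifier and is documented as such.
* **EEG.** 1/f background plus stage mixtures: alpha (10 Hz) + beta in W;
  low-amplitude theta with a trace of alpha in N1; theta plus 12–14 Hz
  Hann-windowed spindle bursts and biphasic K-complexes in N2;
  high-amplitude delta (1.2 and 2.5 Hz, ~70 uV) in N3. **REM EEG is drawn
  from the same mixture as N1** — the textbook low-amplitude
  mixed-frequency pattern, and the deliberate design choice that makes the
  EEG-only network structurally unable to separate REM from N1, so the
  N1/REM confusability seen in real scoring emerges rather than being
  asserted.
* **EOG.** Blink-like large biphasic deflections in W; slow rolling
  0.4 Hz movements in N1; quiet in N2; quiet with low-frequency crosstalk
  from the strong delta in N3; dense trains of rapid sharp deflections in
  REM. N2 and N3 EOG are nearly identical, so the EOG-only network cannot
  fully separate depth of non-REM sleep.

What passing tests on this corpus show: the full pipeline — decomposition,
feature geometry, both subnetworks, DBN fusion, scoring — is implemented
correctly, recovers stage structure it can in principle recover, and fusion
strictly improves on either modality because each modality is blind to one
distinction by construction. What they do **not** show: performance on real
PSG, where stage signatures drift with age and pathology, artifacts are
richer than the saturation/flatline model, and inter-scorer disagreement
bounds achievable accuracy. Real-data headline accuracies reported for this family of methods are
not reproducible from this package without the real corpus.

## Evaluation harness

Confusion matrices use the scoring order above; Cohen's kappa, overall
accuracy (percent) and per-class F1 with macro mean follow the standard
closed forms, tested against hand-computed values and a large-sample null
simulation. Cross-validation is subject-wise leave-one-out — a per-epoch
classifier must never see its test subject during training — with an
option (`n_report`) to score only a random subset of held-out subjects,
for protocols that evaluate a random selection of nights. Both per-fold
metrics and the pooled confusion matrix are emitted, so the user can
choose between pooling counts and averaging folds.

## Problem sizes in the shipped experiments

The package's standard end-to-end check (`run_fusion_benchmark`) uses
5 synthetic subjects x 200 epochs, features extracted once, and five
training repetitions (10 subnetwork epochs, 5 fusion epochs) each holding
out a different subject; it asserts fused accuracy >= 85% and a strict
improvement over both single-modality subnetworks on at least 4 of the 5
repetitions. These sizes are the package's chosen desk-scale experiment:
large enough that every stage appears on both sides of every fold, small
enough to run routinely.

## Known limitations

* EMD variants that stabilise mode mixing (EEMD, CEEMDAN) are out of scope,
  as is the marginal Hilbert spectrum.
* The epoch classifier is memoryless across epochs; no sequence model over
  the night, no arousal/sleep-cycle events.
* Single EEG + single EOG channel; multi-channel montages would require a
  fusion-width redesign this package does not attempt.
* The EDF writer covers the subset of EDF+ needed here (uniform 1 s
  records, one annotation channel); it is not a general-purpose EDF+
  implementation.
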