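---
title: "PSAEEGNet: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSAEEGNet: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a rapid serial visual presentation (RSVP) experiment, images flash at a
fixed location at around 10 Hz and the observer watches for rare targets
(1–4% of stimuli). A detected target evokes the P300, a positive
event-related potential peaking roughly 300 ms after the stimulus, strongest
over centro-parietal electrodes. Detecting the P300 in a *single trial* is
hard: the deflection is a few microvolts inside tens of microvolts of
structured background EEG, and the class balance is extreme. This package
implements PSAEEGNet, a compact convolutional network with pyramid squeeze
attention (PSA), for exactly this single-trial, heavily imbalanced
classification problem, together with the preprocessing, training protocol,
evaluation metrics, cross-validation drivers and a synthetic RSVP generator
that makes every stage testable without recorded data.

## The network

Epochs enter as 62 electrodes × 250 samples (1 s at 250 Hz). Four stages:

1. **Primary temporal feature extraction (PTFE).** A temporal convolution
   with 8 filters and kernel (1, 125) — half the epoch length — with "same"
   zero padding, then batch normalization. Output (8, 62, 250).
2. **Primary spatial feature extraction (PSFE).** A spatial depthwise
   convolution with kernel (62, 1) and depth multiplier 2 collapses the
   electrode axis into 16 feature channels; batch norm and ELU follow. A PSA
   block with kernels (3, 5, 7, 9) recalibrates the feature map, followed by
   a second batch norm + ELU (the reference layer table lists both pairs and
   is implemented literally), an average pool of width 8 reducing 250
   samples to 31, and dropout 0.5.
3. **Deep temporal feature extraction (DTFE).** A separable convolution:
   depthwise kernel (1, 16), then a PSA block with kernels (1, 3, 5, 7),
   then the pointwise (1, 1) convolution mixing channels; batch norm, ELU,
   an average pool of width 8 reducing 31 to 4, and dropout 0.5.
4. **Classifier.** The 16 × 4 = 64 features are flattened into an affine map
   to two units with softmax.

`stage_shapes(network_config())` prints this walk; `network_forward(...,
want_stages = TRUE)` measures it on data.

### The PSA block

PSA recalibrates a C-channel feature map in four steps. The channels are
split into S = 4 contiguous groups; group *i* is convolved along time with
its own kernel size (the multi-scale "squeeze and concat" step). Each branch
is then summarized by squeeze-and-excitation: global average over time per
channel, an affine bottleneck with a rectifier, an affine map back and a
logistic squashing, giving one attention value in (0, 1) per channel. The S
attention vectors are normalized across branches with a per-channel-slot
softmax, and each branch is multiplied by its normalized weights before the
groups are concatenated back. The output always has the input's shape, the
branch weights sum to one at every channel slot, and the block is
deterministic given its parameters.

The published description of PSA leaves internals open; the design choices
here are: contiguous channel split (a full-channel variant is available via
`psa_config(split_channels = FALSE)`), plain convolution within a branch
(`branch_groups = 1`; the channel counts are far too small for grouped
schedules), excitation bottleneck width `max((C/S)/4, 1)`, and bias-free
branch convolutions because batch normalization follows in the host network.

### Numerical and architectural decisions

* **Pooled lengths 31 and 4.** 250/8 truncates to 31, but 31/8 truncates
  to 3 while the reference table prints 4 with a flattened size of 64, which
  the classifier geometry requires. Pools therefore accept an explicit
  output length: the first pool truncates the tail, the second right-pads
  minimally and averages its last window over the 7 real samples it covers.
* **Padding.** Temporal convolutions use symmetric "same" zero padding —
  forced by the printed shape preservation; the even-length (1, 16) kernel
  pads one extra sample on the left.
* **Biases.** All convolutions are bias-free (batch norm absorbs offsets);
  only the classifier keeps its bias.
* **Initialization.** Truncated-normal (±2 SD) with fan-in scaling
  `1/sqrt(fan_in)` for every convolution and affine map, zero classifier
  bias, batch-norm scale 1 / offset 0. All draws come from the R RNG, so a
  single seed reproduces a fit bit-for-bit.
* **Batch norm.** Per-channel over time × batch, eps 1e-5, running-statistic
  momentum 0.1 (biased variance in the running estimate). Training mode
  requires batch size ≥ 2; evaluation mode uses running statistics and
  accepts single trials.
* **Implementation.** The grouped temporal convolutions and the
  62-electrode spatial contraction run as im2col + BLAS GEMM in compiled
  code; batch-norm reductions are fused compiled loops; everything else is
  vectorized R. The entire backward pass is hand-derived and verified
  against central finite differences in the test suite.

## Training protocol

Adam (learning rate 0.001, moments 0.9/0.999, eps 1e-8), batch size 64,
cross-entropy with class weights `w_c = n/(2 n_c)` to counteract the 1–4%
target rate. A stratified 20% of the *training* data is carved out to
monitor validation loss — test folds are never touched during fitting,
which is the only leak-free reading of the protocol. The learning rate is
halved after 5 consecutive epochs without a validation-loss decrease
(minimum meaningful decrease 1e-5, floor 1e-6), training stops after 20
such epochs, and the parameters of the best-validation epoch are restored.
`max_epochs` defaults to 500 with early stopping active. Mini-batches are
reshuffled every epoch from the run seed; a trailing batch of size 1 is
dropped because training-mode batch norm cannot normalize it.

The plateau/stop logic lives in a standalone state machine
(`plateau_scheduler()` / `scheduler_step()`), so its exact timing — first
halving at epoch `lr_patience + 1` under a flat loss, stop at
`early_stop_patience + 1` epochs after the best — is tested without
training anything.

## Metrics

Accuracy, TPR, FPR and F1 derive from the confusion counts at a score
threshold (default 0.5, the argmax rule for a two-class softmax; the hard
ratios report `NA` rather than silent zeros when a denominator is empty).
AUC is the pairwise statistic: the probability that a random target trial
outscores a random non-target trial. The strict indicator (ties count 0) is
implemented for fidelity to the printed definition; the reporting default
credits ties 1/2, the standard Mann–Whitney correspondence. Both are
computed from rank statistics in O(n log n) and tested against the
O(P·N) double loop.

## Evaluation protocol

`stratified_kfold()` shuffles within class and deals round-robin, making
stratification exact to ±1 trial per class per fold; `run_cv()` fits each
fold's training portion (with its internal validation carve-out) and scores
the untouched test fold. Single-class test folds yield an undefined AUC
that is excluded from means with a note — never silently zeroed.
`run_ablation()` evaluates the variant family — A+A, A+0, 0+A, the EEGNet
control, and the kernel sweeps A(3,5,7,9) … E(9,11,13,15) on the second
block — on byte-identical folds so comparisons are paired. The shipped
default is A+B, the configuration with the best TPR in the ablation family
and the smallest (cheapest) second-stage kernels. A PSA block placed in the PTFE stage is
deliberately not offered: at (8, 62, 250) the attention block would operate
on the full-rate feature map, which is computationally disproportionate for
what it adds.

## The synthetic RSVP generator

No public generative model exists for this paradigm, so every
distributional choice in `sim_config()` is a package decision, made once to
emulate classic P300 phenomenology and documented here rather than fitted
to any dataset:

* stimuli at 10 Hz, targets Bernoulli with probability 0.02 by default
  (the paradigm's 1–4% range; values outside it warn but are accepted,
  because balanced sets are useful in unit tests);
* a Gaussian-shaped positive deflection, unit peak at 300 ms, width SD
  60 ms, peak amplitude 5 µV by default at the best channel, with
  per-event latency jitter (SD 30 ms, truncated ±3 SD) and lognormal
  amplitude variability (σ = 0.3, mean 1);
* a fixed topography peaking at three designated centro-parietal channel
  indices and decaying exponentially with index distance;
* background: 1/f noise (exponent 1, RMS 5 µV) mixed across channels
  through a shared component (mixing 0.3), a 10 Hz alpha oscillation with
  random per-channel phase (2 µV), and white sensor noise (1 µV);
* overlapping 1 s epochs at the 10 Hz stimulus rate superpose linearly, as
  in real RSVP; `overlap = FALSE` spaces stimuli one epoch apart for tests
  needing independent trials.

`simulate_subject()` composes the recording with the same preprocessing a
real session receives (zero-phase order-4 Butterworth 2–30 Hz, then
0–1000 ms epoching). The default P300 amplitude is chosen so that the
learnability and null properties are meaningful: 20 µV subjects are
reliably separable, 0 µV subjects are exactly label-independent.

What the generator does *not* model: biophysical forward mixing, eye-blink
and movement artifacts, non-stationary background statistics, or the exact
statistics of any public benchmark. Passing tests on synthetic subjects
demonstrate that the architecture, optimization and evaluation machinery
behave correctly and that the pipeline can extract a P300-like signature
from realistic noise — they do not certify benchmark-level performance on
recorded EEG, which requires the real data (the package consumes generic
epoch arrays precisely so such a loader can be added as an extension).

## Preprocessing decisions

Channel selection keeps electrodes 1–32, 34–42, 44–64 of a 64-channel
montage (the montage identity of the two dropped electrodes is not
documented for the reference dataset; the index list is taken literally).
The Butterworth order is unstated in the protocol this package follows;
order 4 applied forward-backward was chosen because zero-phase filtering
preserves P300 latency, and both order and phase mode are configuration
fields. Filtering precedes epoching; no baseline correction is applied (none
is part of the protocol), and an optional one is deliberately not silently
enabled. Event indices are 1-based in the R API; epoch windows are
half-open `[start, end)`, so 0–1000 ms at 250 Hz is exactly 250 samples.

## Problem sizes used by the shipped tests

The test-suite simulations are sized for a single CPU: the learnability
check uses one 2000-stimulus subject at 5% targets and 20 µV with nine
training epochs per fold — enough for the optimizer to converge past the
separability it demonstrates, while the protocol's own cap (500 epochs with
early stopping) is far higher; the null check uses the same geometry at
amplitude 0 with one epoch (training on label-independent data cannot
create signal); the class-weighting comparison uses five paired seeds of
700-stimulus 16-channel subjects at the 2% target rate; the ablation sweep
runs all nine configurations for one epoch on two folds of a 400-stimulus
subject. These sizes are package choices that keep the full pipeline
exercised end-to-end; nothing about the architecture or protocol depends on
them.

## Known limitations

* Benchmark-scale figures for this model family (mean TPR ≈ 0.79, AUC ≈
  0.93 over 64 subjects of the public Tsinghua RSVP benchmark) require the
  external recorded dataset and are not reproducible from synthetic data;
  the expected high-0.8s/low-0.9s per-subject AUC range for a scaled-down
  real-data run (five subjects) is documented as a stretch check for users
  with access to the benchmark.
* Epoch files use R-native serialization rather than HDF5 (no HDF5 R
  bindings are declared as dependencies); the format is versioned and
  round-trips bit-exactly, with a JSON sidecar for provenance.
* Training is CPU-bound dense linear algebra; there is no GPU path.
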