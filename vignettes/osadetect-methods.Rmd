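---
title: "Detecting sleep apnea from single-lead ECG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from single-lead ECG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(osadetect)
```

## The detection problem

Obstructive sleep apnea interrupts breathing dozens of times per hour of
sleep. The clinical reference standard, polysomnography, requires a sleep
laboratory; a single ECG lead is cheap and wearable, and apneic episodes
perturb cardiac rhythm enough to be detectable from it. `osadetect` frames
the task the way the apnea ECG literature does: each one-minute window of a
nocturnal single-lead recording is classified **apnea (A)** or **normal
(N)**, supervised either by expert minute labels (`.apn` tracks) or by a
simple rule over machine-detected QRS complexes.

This vignette documents the models, every tunable that matters, the
numerical choices, and what the bundled synthetic data can and cannot
demonstrate.

## QRS-count annotation

Given beat sample indices $q_1 < q_2 < \dots$ and a window of
$w = \mathrm{round}(60 \cdot f_s)$ samples, window $i$ spans the half-open
interval $[iw, (i+1)w)$ and is labelled

$$\text{A if } \#\{k : iw \le q_k < (i+1)w\} < \tau, \quad \text{N otherwise.}$$

Three conventions are deliberate and tested rather than implied:

* **Indexing is 0-based and intervals are half-open**, so a beat exactly at
  a window start belongs to that window and no beat is ever counted twice.
* **The number of windows derives from the signal extent**,
  $\lfloor \text{extent}/w \rfloor$, supplied explicitly from the record
  length (or max beat index + 1). Beats falling in a trailing partial
  window are dropped with it.
* **The threshold $\tau$ is configuration, not a constant.** There is no
  universal beat-count boundary; the right value sits between the expected
  per-minute counts of the two regimes at hand. For the synthetic
  generator's defaults any $\tau \in (55, 65)$ separates the regimes
  exactly; the examples use 60.

The implementation is a single `tabulate()` sweep; a brute-force
interval-counting oracle, a threshold-monotonicity property (raising
$\tau$ can only grow the apnea set) and half-open boundary cases pin it
down in the tests.

## Signal conditioning

The default chain is **filter → segment → normalize**; smoothing and
outlier flagging are diagnostic side channels, not silent mutations of the
training data.

* **Bandpass 0.5–45 Hz, Butterworth order 4, zero phase.** The band edges
  keep QRS energy while removing baseline drift and mains-adjacent noise.
  The filter runs as a high-pass/low-pass cascade rather than a single
  8-pole bandpass design: at 100 Hz sampling the lower edge is 1% of
  Nyquist, where a combined bandpass polynomial is numerically fragile,
  while the cascade is stable and meets the same response (stop-band RMS
  ratio < 0.01 at 0.05 Hz, pass-band amplitude within 0.1% at 10 Hz,
  measured in the tests). Each stage is applied forward–backward
  (`filtfilt`), so group delay is zero and QRS timing — which the
  annotation rule depends on — is untouched.
* **Segmentation** cuts non-overlapping 60 s windows
  ($w = \mathrm{round}(60 f_s)$ samples); the trailing partial window is
  dropped. Provenance (record id, 0-based start sample) rides along with
  every segment and later drives the leakage guards and record-level
  splits.
* **Normalization** is a per-segment z-score; constant segments map to
  all-zeros instead of dividing by zero. Per-segment (rather than
  per-record) scaling makes segments comparable across records and
  recording gains, which is what the classifier consumes.
* **Smoothing** is a centered moving average with truncated edges, length
  preserved — a visualization aid only.
* **Outliers** are flagged where $|x_i - \mathrm{median}(x)| > k \cdot
  \mathrm{MAD}(x)$ (MAD scaled by 1.4826, $k = 5$ by default). Nothing is
  removed: with no principled reconstruction rule available, report-only is
  the conservative default, and a zero MAD returns an explicit degenerate
  flag rather than flagging everything.

## Leakage discipline

Records are split into training/validation/test **before** augmentation or
balancing, and all segments of a record stay in one partition (nocturnal
minutes within a record are strongly dependent). Three misuse patterns are
hard errors, not warnings, and each has a dedicated test: augmenting a
non-training partition, deriving the decision threshold from non-training
data, and any provenance overlap between the training and validation sets
handed to the trainer.

## Augmentation and SMOTE

Four length-preserving operators diversify the training set: time stretch
(linear resample by a factor in [0.9, 1.1], then center-crop or edge-pad),
amplitude scale ([0.8, 1.2]), additive Gaussian noise (sd 0.05 in
normalized units), and cropping (keep a random contiguous 90–100%,
edge-pad back). The ranges are deliberately mild — heart-rate and gain
variation of the order seen across subjects — and every drawn operator and
magnitude is logged in an audit attribute. When several operators are
applied to one segment they compose in draw order.

Class balance uses canonical SMOTE, written in the package: each synthetic
point is $x + \lambda(\text{nn} - x)$ with $\lambda \sim U(0,1)$ and nn one
of the $k = 5$ nearest minority neighbors (Euclidean, on the same
flattened normalized segments the network consumes). Originals are
preserved verbatim and first; output counts are exactly equal. The default
order is augment → SMOTE (so synthetic points interpolate between real and
augmented minority examples); both stages are independently switchable, as
is class weighting in the loss.

## Network architectures

Both classifiers are built from `conv → ReLU → max-pool → batch-norm`
blocks over the raw 6000-sample segment, ending in flatten → dense(ReLU) →
dropout → 1 sigmoid unit.

* **Single-branch CNN:** two blocks, kernel 3, 32 filters, pool 2.
* **Dual-branch CNN:** two parallel stacks with kernels **3 and 5** — one
  sees fine morphology, the other broader context — concatenated before an
  L2-regularized dense layer (coefficient $10^{-4}$) with dropout 0.5.

Filter counts, blocks per branch and dense width (64) are configuration:
published layer diagrams for this family of models are schematic, so the
defaults were chosen once as the smallest architecture that cleanly
separates the two-regime task on one CPU core, and every number is exposed
in `cnn_config()` / `dual_branch_config()`.

The engine is written in the package (conv/pool/batch-norm kernels in
C++ via Rcpp/RcppArmadillo, everything else base R) rather than binding a
deep-learning framework: the models are the package's core contribution,
and owning the engine buys exact gradients (verified against finite
differences to ~1e-9 relative error), bit-reproducible training under a
seed, and input gradients for saliency with no backend nondeterminism to
paper over.

### Training protocol

Adam (learning rate 0.001, default moments), weighted binary
cross-entropy, batch 32, up to 50 epochs. Per-class weights are inversely
proportional to class frequency ("balanced"), which provably reduces to
unweighted loss on balanced data (tested to 1e-9). Validation loss is
monitored every epoch: after 3 stagnant epochs the learning rate halves,
after 5 training stops, and the best-validation parameters are restored.
The patiences are configuration; 3/5 are conventional values that end the
synthetic runs within a handful of epochs of convergence.

### Decision threshold

The threshold is computed **from training-set predictions only**:
candidates are midpoints of consecutive sorted unique scores, the
criterion is Youden's J (sensitivity + specificity − 1), ties break toward
0.5, and all-identical scores fall back to 0.5 with a warning. A score
exactly at the threshold is called apnea. Youden's J is one defensible
choice among several (F1-optimal, fixed 0.5, ...); it is symmetric in the
two error types and needs no prevalence assumption.

### Saliency

`grad_input` is the elementwise input gradient of the sigmoid score times
the input; `grad_cam` weights the last conv block's feature maps by their
spatially pooled score gradients, rectifies the sum, and linearly upsamples
to the input length (branches summed after upsampling in the dual model).
Both are checked against finite differences / sign contracts in the tests.

## Baselines

The decision tree is `rpart`'s CART; the forest is `randomForest` with 100
trees and vote-fraction scores, seeded for determinism. They consume the
same flattened segments as the networks and pass through the same
thresholding and evaluation surface.

## Evaluation

Accuracy, precision, recall and F1 come from explicit confusion counts; a
0/0 ratio is reported as `NA` with a named flag, never silently zero. ROC
curves sweep all distinct scores with tie groups collapsed into single
steps, and the trapezoidal AUC then equals the Mann–Whitney statistic with
ties counted one half — an identity the tests verify on hundreds of random
instances, alongside agreement with an independent ROC implementation to
1e-12. Cross-validation is stratified by record-level apnea fraction and
split at the record level; summaries report per-fold accuracy/AUC with
means and **sample (n−1)** standard deviations. Display rounding is
half-away-from-zero at 2 decimals (reports) and 4 (fold tables); raw
values are always retained.

## The synthetic substrate

The simulator generates minutes that are independently apneic with
probability 0.4; apneic minutes draw a heart rate from 35–55 bpm, normal
minutes from 65–85 bpm, with beats at RR = 60/bpm jittered
multiplicatively by ±5% and rendered as Gaussian pulses (width 0.08 s,
amplitude 1 mV) over a 0.1 mV, 15 s sinusoidal baseline wander plus 0.02 mV
Gaussian noise, at 100 Hz. True beat samples and minute labels are emitted
alongside the signal, and generation is bit-reproducible under a seed.

The bpm gap is a **separability guarantee**: any in-gap count threshold
recovers the ground truth exactly, which is the closure property the
annotator tests rely on. The defaults model a deliberately clean version
of the physiology — apnea-associated bradycardia only. Real apneic ECG
differs in ways the simulator does not attempt: cyclic
bradycardia–tachycardia within events rather than flat slow minutes,
morphology changes (P/T waves, amplitude modulation by respiration),
artifacts, and annotation noise. Passing the learnability checks therefore
demonstrates that the pipeline is correctly wired and the models can learn
a rate-coded class boundary end-to-end — not that these hyperparameters
reach any particular accuracy on clinical recordings.

Problem sizes used by the tests and the acceptance script — 500 one-minute
segments (five 100-minute records, an 80/20 record-level split), brute-force
oracle sweeps of 200–500 random instances — were chosen as the smallest
sizes at which the properties of interest are exercised convincingly on a
single core.

## Known limitations

* The WFDB codec covers the single-signal format-16 subset plus MIT
  annotations with the SKIP extension — enough for the apnea database
  layout; multi-signal records, other storage formats and resampling are
  out of scope. Binary amplitudes quantize to 1/gain mV (gain 200 by
  default), so binary round-trips are exact only to half that step.
* Minute labels are treated as independent targets; no smoothing or HMM
  over adjacent minutes is attempted.
* The engine is CPU-oriented; there is no GPU path, and very deep
  configurations will be slow.
* Respiration/SpO2 channels present in some public records are ignored by
  design.
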