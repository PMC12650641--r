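---
title: "Triple-attention EEG emotion recognition: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-attention EEG emotion recognition: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

EEG-based emotion recognition classifies short multichannel EEG recordings
into affective categories (three emotion classes for SEED-style data;
binarised valence or arousal for DEAP-style data). The signal is noisy,
non-stationary, and highly variable between individuals, so the approach
implemented here combines three attention mechanisms over two complementary
frequency-domain feature modalities:

1. **Cross-modal attention fusion (MCA).** Per frequency band, differential
   entropy (DE) and power spectral density (PSD) feature maps of shape
   (batch, channels, windows) are fused by scaled dot-product attention over
   *channel* tokens: queries are linear projections of one modality, keys
   and values of the other, with attention dimension $d_k = 32$ and a final
   projection back to the window dimension so shapes are preserved. The
   unidirectional form (DE queries PSD) serves the SEED-style layout; the
   mutual form, $\mathrm{MCA}(f_1, f_2) = \mathrm{Att}(f_1, f_2, f_2) +
   \mathrm{Att}(f_2, f_1, f_1)$ with separate projections per direction,
   serves the DEAP-style layout. The five fused bands are stacked into a
   (batch, 5, channels, windows) tensor.
2. **CBAM refinement.** Sequential channel-then-spatial gating: channel
   gates $\sigma(\mathrm{MLP}(\mathrm{avg}) + \mathrm{MLP}(\mathrm{max}))$
   through a shared two-layer MLP with reduction 4 (hidden width
   $\lceil 5/4 \rceil = 2$), then spatial gates from a $7 \times 7$
   convolution over the stacked channel-mean and channel-max maps. Both
   gates lie in $(0,1)$, so refinement only attenuates.
3. **CNN + Conformer backbone.** Two (conv $3\times3$, batch-norm, GELU)
   stages map $5 \to 32 \to 64$ channels; adaptive average pooling fixes
   the map to $(64, 31, 10)$ for every input geometry; the time axis
   becomes the token axis and each token's $64 \times 31 = 1984$ features
   are projected to a 256-dimensional embedding with layer normalisation.
   Two Conformer blocks follow (half-step feed-forward, 8-head
   self-attention, depthwise-separable convolution with kernel 5,
   half-step feed-forward, each pre-layer-normalised with residual
   connections and a closing layer norm). Global average pooling over the
   ten tokens feeds a $256 \to 128 \to 64 \to C$ classifier with GELU and
   dropout (0.3, 0.2).

Training minimises a class-weighted, label-smoothed cross-entropy
$L = -\sum_i w_i [(1-\epsilon) y_i + \epsilon/C] \log \hat y_i$ with
$\epsilon = 0.1$ and inverse-frequency weights $w_i = N/(C n_i)$ recomputed
per training fold, using AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
decoupled weight decay), gradient accumulation over 2 micro-batches,
global-norm clipping at 1.0, and either a cosine or a one-cycle schedule.

## Feature extraction

DE features use the Gaussian closed form $h = \tfrac12 \ln(2\pi e
\sigma^2)$ (natural log, nats) on the sample variance of each band-limited
window; band limiting is a 4th-order Butterworth band-pass applied forward
and backward (`signal::filtfilt`) for zero phase. PSD features use Welch's
method: 2-s Hann segments, periodograms normalised by the window energy
$W = \sum_n w_n^2$, averaged over segments, then pooled as the *mean*
density over each band's frequency range (the mean rather than the sum is
recorded in the tensor metadata so either convention is reproducible).
Band edges follow the common SEED convention — Delta 1–4, Theta 4–8,
Alpha 8–14, Beta 14–31, Gamma 31–50 Hz — since the source method names the
bands without printing edges. Welch overlap is 50%, a standard
variance/resolution trade-off. Windows that do not fill `window_s` seconds
are dropped with a message.

## Implementation: why a hand-written tape

No deep-learning framework is part of this package's dependency set; the
network runs on a small reverse-mode automatic-differentiation tape written
in base R (BLAS-backed matrix multiplication, im2col convolutions,
batched-loop attention). This keeps the package self-contained and makes
every gradient auditable: the test suite checks the analytic gradients of
the complete network against central finite differences at about $10^{-6}$
relative error. The cost is speed — training is practical at the
synthetic-data scales used in the tests (minutes, not hours), not at
full-dataset GPU scale.

## Parameter accounting

The assembled SEED-style configuration counts **3,344,019** trainable
parameters (3.34 M at two decimals), with the feed-forward expansion factor
at the transformer-standard 4. Two bias conventions, fixed a priori, are
part of the documented architecture: query/key/value projections carry no
bias (original-Transformer convention, applied in both the cross-modal
attention and the self-attention), and convolutions immediately followed by
batch normalisation are bias-free (the normalisation supplies the shift).
The CBAM MLP keeps biases in both layers, with a `cbam_bias = FALSE`
configuration switch for bias-free analyses; its hidden activation is the
ReLU of the canonical CBAM design (the GELU elsewhere in the network
follows the stated backbone components). Conformer-internal dropout is
0.1 and the SEED-variant MCA dropout is aligned with the printed
DEAP-variant value of 0.3; neither is stated for its counterpart in the
source description.

## Synthetic data: what it emulates and what it does not

`generate_raw_eeg()` emulates stimulus-locked band-power structure: each
trial is a sum of five band-limited sinusoids (frequency uniform within the
band, independent phase per channel) whose amplitudes are
`base_amplitude * class_band_gain[class, band]`, plus Gaussian noise with
inter-channel correlation realised by mixing a shared component
(`channel_corr` is the pairwise correlation). Defaults — 10 µV base
amplitude, 5 µV noise, correlation 0.2, 200 Hz / 6 s trials — are chosen
as representative magnitudes for scalp EEG band oscillations.
`generate_feature_dataset()` skips signal space entirely: standard-Gaussian
feature tensors in the two documented layouts, with class k's mean shifted
by `effect_size` standard deviations on every cell of one designated band
(band $((k-1) \bmod 5) + 1$), which makes separability controllable and
linearly verifiable.

Neither generator models volume conduction, electrode geometry, ocular or
muscle artifacts, non-stationarity, or realistic cross-subject variability.
Passing tests on these data demonstrate that the pipeline is wired
correctly, that it can extract a genuinely present class signal, and that
no information leaks through the protocols — they say nothing about
accuracy on real recordings.

## Protocols and leakage

The SEED-style protocol standardises per (band, channel, window) cell with
statistics fitted on each fold's training data only (PSD is square-root
transformed first), inside subject-specific stratified 5-fold plans. The
DEAP-style pipeline follows the benchmark "slice-first, then divide" order:
bidirectional MCA fusion (applied in preprocessing, i.e. with fixed-seed
untrained projections), holistic min-max scaling, segmentation of the
60-step axis into twenty 3-step windows, label binarisation at 5, and a
stratified 9:1 split repeated over seeds. Because holistic scaling lets
test trials influence the scaling constants, `leakage_safe = TRUE` fits
min-max on training trials only; the default reproduces the benchmark
behaviour for comparability, and the tests verify both modes. A
leave-one-subject-out splitter covers the cross-subject setting.

The 58-to-60-step time extension is arithmetically underdetermined in its
source description ("averaging the last 4 s" extends by 2 steps); the
implementation appends two steps, each the mean of the last four, which
satisfies the binding (n, 32, 5, 60) shape contract.

## Numerical choices and degenerate inputs

Layer/batch normalisation use $\epsilon = 10^{-5}$ with biased variances;
batch-norm running statistics use momentum 0.1 (unbiased update). Gradient
routing through max-pooling takes the first maximum on ties. Softmax and
the training loss are computed via log-sum-exp; the probability-space loss
floors $\log \hat y$ at $10^{-12}$. Zero-variance windows reject
differential entropy; zero-variance scaler cells fall back to centring;
empty classes reject weight computation; degenerate (single-class)
confusion matrices reject kappa; non-finite losses abort training with a
diagnostic. The one-cycle schedule warms up linearly from lr/25 over 30% of
the steps to the peak and anneals by cosine to lr/100; the cosine schedule
spans the whole run — both are per-run, since the source names the policies
without periods. Early stopping uses patience 15 on validation accuracy
with best-weight restoration (patience unstated in the source; 15 gives the
loop room under the 100-epoch default), and `val_acc_stop` provides an
optional convergence shortcut for bounded-time runs.

## Ablation harness

`ablation_harness()` trains the full model and three ablated variants on
identical stratified folds and seeds: fusion replaced by the element-wise
modality mean, CBAM by the identity, and the Conformer stack by direct
global average pooling of the projected tokens. It reports mean ± sd
accuracy, a t-based 95% CI, F1 and kappa, and paired t or Wilcoxon
signed-rank p-values against the full model; comparing the full model with
itself yields p = 1 by construction.

## Problem sizes in the tests

Structural and oracle tests run on a scaled-down configuration (2 bands,
4 channels, 6 windows, d_model 8) where finite-difference gradient checks
are cheap. Learning-sanity runs use the full SEED-configuration model on
500 synthetic trials at 3-sd class separation (validation accuracy reaches
95% within a handful of epochs) and the ablation harness on 120 trials at
reduced epochs. The DEAP pipeline count checks run at the full documented
scale (1,280 trials, 25,600 segments).

## Known limitations

- Training speed limits practical use to small and medium problems; there
  is no GPU path and no mixed precision (an engineering concern orthogonal
  to the method's outputs).
- Persistence uses RDS plus JSON manifests rather than HDF5; checkpoints
  are portable across R sessions, not across languages.
- The multiclass F1 is macro-averaged; if a weighted average is needed for
  comparison with other software it must be computed from the confusion
  matrix.
- Real-data preprocessing (artifact rejection, re-referencing, ICA) is out
  of scope; the package starts from raw arrays or pre-extracted feature
  tensors in the two documented layouts.
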