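---
title: "Multimodal attention-based dementia staging: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal attention-based dementia staging: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Staging dementia from structural MRI alone discards clinical information that
practitioners weigh routinely: cognitive instrument scores (MMSE, FAQ, CDR,
GDS, NPI-Q), demographics, and APOE genotype. `neuronetad` implements a
multimodal classifier that fuses 2D MRI slice images with this tabular
metadata to separate normal controls (NC), mild cognitive impairment (MCI)
and Alzheimer's disease (AD), together with the full surrounding protocol:
subject-level splitting, ensemble feature selection, training with early
stopping, evaluation with fold statistics and ablations, and a synthetic
cohort generator so everything is testable without access-restricted
clinical data.

## The model

**Image backbone.** An 18-layer residual network processes grayscale slices
(replicated to three channels). Each of the four stages holds two basic
blocks with a Convolutional Block Attention Module (CBAM) inserted between
them:

$$O_0 = \mathrm{BasicBlock}_0(F_{i-1}),\qquad
  O_0' = \mathrm{CBAM}(O_0),\qquad
  F_i = \mathrm{BasicBlock}_1(O_0 + O_0').$$

CBAM gates channels first —
$\mathrm{ChA} = \sigma(\mathrm{MLP}(\mathrm{AvgPool}(O_0)) +
\mathrm{MLP}(\mathrm{MaxPool}(O_0)))$ with a shared bottleneck MLP
(reduction ratio $r$, default 16) — and then space:
the channel-gated map $\hat O_0 = O_0 \odot \mathrm{ChA}$ is reduced to its
per-pixel channel mean and maximum, and a $7\times 7$ convolution over the
two maps followed by a sigmoid yields $\mathrm{SpA}$, with
$O_0' = \mathrm{SpA} \odot \hat O_0$. Note the *additive* combination
$O_0 + O_0'$ feeding block 1: the attention output augments rather than
replaces the features, so an attention module emitting the zero map leaves
the plain residual stage behind bit-exactly.

**Text path.** The selected metadata fields are standardized (training
statistics only), serialized to a fixed template
(`"FAQ-Score: 12.0; Age: 74.5; ..."`), tokenized and embedded, then
projected per token position: $T' = T W_T + b_T$. The default encoder is a
deterministic, download-free stand-in: word tokens receive seeded hash
embeddings; numeric tokens receive sinusoidal encodings of their *value* at
geometrically spaced frequencies, so nearby values share representation and
the model generalizes across unseen numbers (hash embeddings of raw numeral
strings would not). Any pretrained contextual encoder can be plugged in as a
`function(texts)` returning an `(L, H, B)` array; it is treated as frozen.

**Meta-guided cross-attention (MGCA).** Stage-3 output (256 channels,
$14\times 14$ at 224 px) becomes 256 image tokens by linearly mapping each
channel's flattened spatial vector to length $E = 256$; the text side
contributes $L = 256$ positions of the same width. Per head $i$
($n = 4$ heads by default, $d = E/n$):

$$Q_i = F_3 W_Q^i,\quad K_i = T' W_K^i,\quad V_i = T' W_V^i,\qquad
  \mathrm{CA}_i = \mathrm{softmax}\!\left(\tfrac{Q_i K_i^\top}{\sqrt d}\right) V_i,$$

with the softmax over text positions — queries always come from the image
side. Heads are concatenated and linearly projected to the attention output
$A$, which gates the image tokens through a Hadamard residual
$F_3' = (A \odot F_3) + F_3$ before stage 4.

**Classifier and loss.** Stage-4 output is flattened, passed through dropout
(0.5) and a fully connected layer, and softmaxed; training minimizes
categorical cross-entropy with probabilities clamped at $10^{-12}$ inside
the log.

## Design choices where the design was open

- **Attention scaling.** The scaled dot product uses $1/\sqrt d$, the
  standard reading; a `linear` config flag provides the literal $1/d$
  variant.
- **Re-entering the spatial grid.** The fused tokens must return to the
  stage-4 input grid. The package re-injects the *delta*:
  stage-4 input $= F_3^{\text{spatial}} + \mathrm{unproject}(A \odot F_3)$,
  with `unproject` the transpose of the token projection. Unprojecting the
  full residual $F_3'$ instead would break the image-only equivalence,
  because the projection is not orthogonal; with the delta form, zeroing the
  output projection makes the whole network equal the image-only network
  bit-exactly — the mechanism behind the "no fusion" ablation row, and a
  tested invariant.
- **CBAM internals** beyond the gating equations (shared MLP, reduction 16,
  $7\times 7$ spatial kernel) follow the original module design; one CBAM
  sits between the two blocks of *every* stage.
- **Standardizer scope.** Metadata statistics are fit on training subjects
  only and reused for validation and held-out data; fitting globally would
  leak. The population (ddof = 0) standard deviation is used, matching the
  common StandardScaler convention.
- **Serialization uses standardized values.** The forward contract requires
  standardized metadata, so the text template renders z-scores at one
  decimal. One decimal keeps tokenization stable; the sinusoidal value
  encodings make the coarse rendering smooth in the underlying value.
- **Slice-level training, subject-level splitting.** Every slice is a
  training sample carrying its subject's metadata and label; splits never
  divide a subject. Metrics are emitted at both slice and subject
  granularity (majority vote over a subject's slices, ties broken by mean
  probability), since the reporting granularity of clinical studies varies.
- **Metrics conventions.** "Overall" precision/recall/F1 are macro averages;
  overall accuracy is the micro accuracy (confusion trace over total). AUC
  is one-vs-rest per class via the rank statistic, macro-averaged.
- **CAM layer.** Gradient-weighted class activation maps are taken at the
  last convolution of stage 4. (A bottleneck-style `conv3` does not exist in
  a basic-block 18-layer network, so the last existing convolution is used.)

## Training regimen

Adam with learning rate $10^{-3}$ and weight decay $10^{-5}$; dropout 0.5 on
the fully connected head; training-only augmentation (horizontal flip with
probability 0.5, rotations within $\pm 10^\circ$ with zero-filled corners,
intensity scaling in $[0.9, 1.1]$, output clamped to $[0,1]$); early
stopping with patience 20 epochs on validation accuracy, returning the
best-validation checkpoint rather than the last. Batch size (32) and the
epoch cap are configurable and logged in the run manifest. The whole
trajectory is deterministic in the seed under the stand-in text encoder.

## The feature selector

Five importance-producing models are fit on the standardized per-subject
metadata (one row per subject — per-slice fitting would pseudo-replicate):
random forest (mean Gini decrease), extremely randomized trees (impurity),
gradient boosting (gain), AdaBoost (SAMME over depth-1 stumps, implemented
in-package, alpha-weighted split improvements), and a ridge-penalized
multinomial logistic model (mean absolute coefficient across classes) as the
fifth, gradient-boosting-library-independent member. Per model, importances
become ranks (ties keep input order); feature $f$ earns
$v_f = \sum_m w_m / r_{m,f}$ (equal weights by default), normalized to
confidence scores $s_f = v_f / \sum_{f'} v_{f'}$; the top $k = 5$ scores are
selected. Scores are invariant to rescaling all model weights, and permuting
feature columns permutes scores and selection identically.

Two caveats the tests document rather than hide. First, impurity-based
importances carry a cardinality bias: under a signal-free cohort,
continuous features (Weight, Age) systematically outrank the few-level
categorical ones (APOE alleles, Global-CDR), and because all five models see
the same cohort their spurious rankings correlate — so the maximum
confidence score under the null is *not* tightly bounded by $2/n$; even five
perfectly independent random rank permutations over nine features fall below
that bound only ~88% of the time. The null test therefore asserts the
meaningful property: no single feature dominates across seeds, and null
scores sit far below planted-signal scores. Second, with strong planted
signal the selector is extremely reliable: the three planted features reach
the top-5 in ≥95 of 100 seeded 200-subject cohorts.

## The synthetic cohort generator

The generator emulates the cohort design the protocol assumes: 200 subjects
at proportions 0.30/0.35/0.35 (largest-remainder rounding gives exactly
60/70/70), 10 slices per subject (2000 images), class-conditioned metadata,
and a 20% subject-level stratified held-out cut with stratified 5-fold
assignment of the rest (rotating per-class remainders across folds yields
exactly 128 training and 32 validation subjects per fold).

Slices are procedural axial "brains": a bright tissue ellipse on black
background whose central dark ventricle grows with disease severity,
with geometric jitter, an axial-position size modulation across the 10
slices, and Gaussian pixel noise, clamped to $[0,1]$. Metadata instruments
are Gaussians clamped to their clinical scales with class means pulled away
from a shared baseline proportionally to a `separation` knob (MMSE
29/26/20 for NC/MCI/AD at separation 1; FAQ and NPI-Q increasing with
severity; age and weight weakly informative), and categorical mixtures for
Global-CDR (mass on 0 / 0.5 / ≥1 respectively) and the APOE alleles
(ε4 probability increasing with severity). At separation 0 all classes share
one distribution; image and metadata separation can be set independently,
which is how the multimodal-gain experiment removes the image signal while
keeping metadata informative.

What passing tests on this generator do and do not show: they validate the
*mechanics* — shapes, gradients, leakage prevention, the fusion pathway's
ability to carry tabular signal into the image stream, and the exact
protocol counts — on a cohort whose class signal (ventricle area, instrument
shifts) is far cleaner than real MRI. They say nothing about accuracy on
clinical data, scanner effects, registration, or missing values, none of
which the generator emulates.

## Problem sizes used by the test suite

Desk-scale experiments use the `tiny` schedule (32 px input, stage widths
16/32/64/128, $E = 64$, $L = 32$): a 60-subject separation-2 cohort reaches
≥90% validation accuracy within a handful of epochs on one CPU; the
multimodal-gain experiment (image separation 0, metadata separation 2)
trains the full and image-only models for at most 10 and 5 epochs.
Gradient correctness is established by central finite differences on a
16 px micro schedule across every layer type. The full-size schedule
(224 px, widths 64/128/256/512, 256 tokens of width 256) is exercised in
forward mode only.

## Known limitations

- The tiny model's stage-4 grid is $4\times4$, so class activation maps are
  coarse; localization holds reliably for the disease classes (whose
  evidence — an enlarged ventricle — is present and compact) but not for NC,
  where the evidence is an absence and Grad-CAM's positive-gradient support
  is diffuse.
- The stand-in text encoder is not contextual; it exists to make the fusion
  pathway testable and deterministic, not to model language.
- FLOPs estimates count multiply-accumulates as 2 FLOPs at the configured
  resolution, including per-head softmax work (which is why the estimate
  strictly increases with head count); absolute values depend on counting
  conventions and are reported, never asserted.
- Binary (NC vs AD) mode simply drops MCI subjects; no threshold moving or
  recalibration is attempted.
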