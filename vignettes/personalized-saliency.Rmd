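---
title: "Personalized saliency and pupil-based interest: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized saliency and pupil-based interest: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persal)
```

## The problem

Where people look in an image has two components. One is shared: almost
everyone's gaze is drawn to faces, text, high-contrast objects, and —
because photographers compose that way — the center of the frame. The
other is personal: a motorcyclist lingers on the motorcycle, a landscape
lover on the hills behind it. The shared component is what classical
saliency models predict (a *universal* saliency map, USM); the personal
residual is the *personalized* saliency map (PSM). Predicting the PSM is
what makes gaze useful for personalization — including for "grey sheep"
viewers whose tastes correlate poorly with the population, where
collaborative filtering has nothing to lean on.

The catch is supervision: a PSM model needs a per-viewer signal of
*interest*, and questionnaires do not scale. Pupillometry provides one
for free: pupils dilate when a viewer sees something that interests them.
`persal` implements the resulting pipeline end to end:

1. eye-tracker logs → fixation-count grids → smoothed saliency maps
   (PSM per subject-image; USM by pooling subjects);
2. pupil-diameter series → standardized distances → a chi-squared anomaly
   test → a binary per-image interest vector $I_n$ per subject;
3. a convolutional encoder/decoder saliency network, conditioned on $I_n$
   through a Transformer user-encoding mechanism and single-token
   cross-attention, trained with MSE and transfer-initialized from the
   USM stage.

## From gaze samples to maps

A tracker sample is binocular. The two eyes are merged per field by
arithmetic mean (one-eye samples pass through; the merge is symmetric and
an explicit design choice — the upstream literature rarely states one).
Missing data stay `NA`: `(0, 0)` is a valid top-left coordinate, so
sentinel zeros would silently relocate blinks to the image corner.

Each in-bounds merged sample increments one pixel cell — every sample
weighs 1, with no duration weighting or saccade filtering. The count grid
is then convolved with a truncated 2-D Gaussian and divided by its
maximum, giving a heat map in $[0, 1]$ with peak 1 wherever gaze was
recorded. Numerical choices:

- **Kernel** 169×169, $\sigma = 24$ px at full 1920×1080 capture. The
  historical parameterization uses 168 (even); an even kernel has no
  center pixel and shifts the map by half a pixel, so the next odd size
  is used. The truncation at ±84 px (3.5 $\sigma$) is visible as a ~0.3%
  shrinkage when $\sigma$ is re-estimated from the smoothed map's second
  central moment (23.93 recovered from 24) — the tolerance quoted for
  that check (±0.5 px) covers it.
- **Boundary**: zero padding. Gaze cannot land off screen, and renormalizing
  at borders would inflate edge cells that genuinely received little gaze.
- **Normalization**: max by default (peaks at 1); sum-to-one is available
  for distribution-style uses. Max normalization makes USM aggregation
  scale-invariant: pooling $k$ identical viewers changes nothing.
- The Gaussian product kernel is separable, so smoothing is implemented
  as two banded matrix multiplications; tests verify equality with a
  brute-force double-loop convolution on small grids.
- When maps are built at reduced resolution, $\sigma$ scales with the
  factor (24 px at 1080p ≈ 2.2% of the short side; `buildCorpus()`
  defaults to that fraction with a floor of 3 px), keeping the physical
  smoothing constant.

## From pupils to interest labels

Pupil diameter varies between people and drifts within a session, so raw
thresholds are meaningless. Per subject (and, when a session spans days,
per day — a day-level baseline shift otherwise makes the pooled
distribution bimodal), diameters are standardized to
$z = (d - \mu)/\sigma$ with the population SD. The Mahalanobis distance
of a scalar is $|z|$, so under normality $z^2 \sim \chi^2_1$ and the
two-sided anomaly region of mass $\alpha$ is
$z^2 \ge \chi^2_{1,1-\alpha}$. Only the upper (dilation) side labels an
image interesting: constriction is detected but labels 0. At
$\alpha = 0.10$ the cutoff is $z \ge 1.645$; at $\alpha = 0.01$,
$z \ge 2.576$. Raising $\alpha$ can only add labels, never remove them.

How the per-sample test aggregates over the ~300 samples of one
presentation is genuinely underdetermined, and the choice matters more
than it looks. `buildInterestVector()` exposes three readings:

- **`mean` (the default).** Summarize each image by its mean pupil
  diameter, standardize those means *across the subject's images*, flag
  images whose mean is anomalously large. This is the only calibrated
  per-image rule: under the null each image is flagged with probability
  $\alpha/2$ regardless of the number of samples per presentation.
- **`any`.** Flag if any single sample crosses the threshold. With $t$
  independent samples the family-wise null rate is
  $1 - (1 - \alpha/2)^t$ — at $t = 300$ and $\alpha = 0.10$ that is
  $1 - 0.95^{300} \approx 1$, i.e. every image gets flagged. Even with
  strong temporal autocorrelation the rate cannot drop below the
  single-sample 5%, which caps precision at ~0.69 when 10% of images are
  truly interesting. The mode is kept because it is the most literal
  per-sample reading and is informative for short windows or strongly
  smoothed series, but it is not the default for exactly this reason.
- **`fraction`.** Flag if at least a fraction $q$ of samples exceed the
  threshold — a middle ground whose $q$ has no principled default.

The simulator plants dilation over a contiguous 40% window rather than
the whole presentation precisely so these readings are distinguishable in
tests. With the `mean` rule, planted interest at 2.5 baseline-SD dilation
is recovered with precision and recall above 0.9 on the full 8-subject ×
1000-image × 300-sample condition (an acceptance test recomputes this).

## The model

Both stages share one convolutional graph. The encoder is the VGG16
stack: 13 3×3 convolutions with ReLU in five blocks separated by four 2×2
max poolings, so a $(H, W)$ input yields $(H/16, W/16, C)$ features. The
decoder mirrors it with four 2× nearest-neighbour upsamplings and ends in
a 1-channel 1×1 convolution with ReLU. The final ReLU (instead of a
sigmoid) keeps the output non-negative and lets plain MSE against the
$[0,1]$ target be the loss; no adversarial discriminator is used.
`channelScale` multiplies every depth so that desk-scale instances
(C = 32 at 1/16) and the full-width instance (C = 512) run the identical
code path; tests exercise the small widths and the user-encoding branch
is additionally instantiated at full width.

The PSM variant inserts two pieces between encoder and decoder:

- **User encoding.** The binary interest vector $I_n$ (length $M$; 800 in
  the reference configuration) passes through a Linear layer to the
  channel width $C$, then through Transformer-encoder blocks operating on
  that single 1×$C$ token, then a final LayerNorm. Reference depth: 4
  blocks.
- **Fusion.** The encoder features, viewed as a $(W\!\cdot\!H) \times C$
  matrix (row $i$ ↔ pixel $x = (i-1) \bmod W$, $y = \lfloor (i-1)/W
  \rfloor$), pass through Transformer-decoder blocks (reference depth 9,
  256 heads): token self-attention, cross-attention with queries from the
  image tokens and key/value from the user token, and a feed-forward, all
  pre-norm residual with 4×$C$ expansion.

Because the user side contributes exactly one key, the cross-attention
softmax is identically 1 whatever the logits: every head broadcasts its
value row to all $W\!\cdot\!H$ queries, and the per-head $d_k = C/\text{heads}$
only changes how that value is sliced. Two consequences are pinned down
by tests: the attention output equals broadcast-of-V to $10^{-6}$, and
the query/key projections of any single-key block receive exactly zero
gradient — personalization is carried by the value/output projections,
the feed-forwards and the residual stream. This also makes the choice
between the $1/d_k$ and the conventional $1/\sqrt{d_k}$ logit scaling
observationally irrelevant here; `logitScale` records the choice
(default `sqrt_dk`) for fidelity. At 512 heads and $C = 512$ the slices
become one-dimensional ($d_k = 1$), the degenerate corner of the design
space.

Choices the architecture leaves open, and what this package does:

- **Positional information** for the feature tokens: none by default
  (position rides the residual stream from the convolutional features);
  learned additive embeddings behind `positional = TRUE`.
- **Decoder self-attention**: included by default (standard decoder
  block), removable with `decoderSelfAttn = FALSE`.
- **Initialization**: truncated normal (sd 0.02) for Transformer weights,
  He-normal for convolution weights, fan-based uniform for convolution
  biases — zero biases would park every dead-patch cell exactly on the
  ReLU kink, where the loss is not differentiable and finite-difference
  checks disagree with any subgradient. The output convolution starts
  with damped weights and bias 0.1 so its ReLU begins active; without
  this, roughly half of all seeds initialize a network whose output — and
  therefore gradient — is identically zero.
- All gradients are hand-derived and verified against central finite
  differences on a tiny configuration.

## Training and transfer

USM stage: Adam, learning rate $10^{-5}$, batch 32 (gradient
accumulation). PSM stage: AdamW, learning rate $10^{-6}$, decoupled
weight decay 0.05, batch 1; each image appears once per subject within an
epoch, so with 8 subjects each image is trained eight times per epoch —
the two readings of that recipe coincide at 8 × 1000 = 8000 samples.
Validation runs once per epoch; early stopping triggers after 5
consecutive non-improving evaluations, and the returned checkpoint holds
the weights of the best validation epoch (standard practice; the
alternative — last epoch — is strictly worse under early stopping). The
8000 subject-image pairs split 6400/1600 with per-subject stratification
that equalizes the number of positive-labelled training images across
subjects when feasible, falling back with a warning when a subject lacks
positives. Desk-scale runs raise the learning rates (the defaults are
tuned to full-scale data volumes); `trainStage()` aborts with a
diagnostic if the loss turns non-finite.

Transfer initialization copies the convolutional encoder and decoder from
a trained USM checkpoint into a fresh PSM model, leaving the user-encoding
and fusion parts at their random initialization; nothing is frozen. On a
freshly transferred model the encoder-output tap
(`encOutputTap()` — decode the encoder features, bypassing the user
mechanism) reproduces the USM model's prediction bit for bit, which the
tests use as the transfer correctness oracle. The qualitative payoff —
USM-initialized training reaches a fixed validation-loss target at least
as fast as random initialization — is checked on the synthetic corpus
over three seeds, with the target set to half the untrained model's
validation loss; the transferred model starts about threefold below that
target before any PSM training.

## Evaluation metrics

NSS (mean standardized map value at fixated cells; population SD, with
the zero-SD map defined as NSS 0), CC (Pearson over cells), AUC-Borji
(fixations vs uniformly random cells) and shuffled AUC (negatives drawn
from *other images'* fixation cells, which cancels the central bias both
gaze and photo composition share). The AUC variants follow the saliency
benchmark definitions those names refer to: Mann–Whitney with ties
counted ½, averaged over seeded negative draws (`nSplits`, default 100;
negatives per split default to the number of fixations). Fixation sets
are the raw deduplicated in-bounds gaze cells, never smoothed maps. Small
instances are compared against exhaustive pairwise counting, and on
center-biased synthetic data shuffled AUC sits below AUC-Borji, as it
must.

## The synthetic world

The study conditions the simulator emulates, with defaults fixed once:

| parameter | default | meaning |
|---|---|---|
| subjects × images | 8 × 1000 | corpus of 8000 subject-image pairs |
| stimulus size | 1920 × 1080 px | full-screen presentation |
| samples / presentation | 300 over 5 s | tracker cadence |
| central bias | Gaussian, $\sigma$ = 18% of short side, weight 1.2 | shared gaze pull |
| objects | 2 per image, 16 categories, center-concentrated | photo composition |
| interest matrix | one primary category per subject (weight 1), one shared secondary (0.4), background < 0.15 | planted preferences |
| pupil baseline | per-subject mean ~ U(3, 4) mm, SD 0.2 mm | physiology |
| dilation | +2.5 SD over a contiguous 40% window when max category weight > 0.5 | interest signal |
| two-day subjects | 2 and 8, +3 SD baseline on day 2 | session drift |
| eye jitter / loss | 2 px per eye, 2% samples lost | measurement noise |

With 16 categories and 2 objects per image, a subject's primary category
appears in ≈ 12% of images — a planted rate at which the mean-rule
detection has a wide margin (the cross-image standardization saturates
once a large share of images is dilated, so very dense interests are the
regime where detection genuinely degrades). Stimuli are procedural —
category-colored discs on a textured background — because the model
consumes only pixel arrays and procedural objects carry exact ground-truth
masks. Everything derives deterministically from one seed via per-stream
seed mixing, so any (subject, image) log can be regenerated in isolation.

What the simulator does *not* emulate: saccade dynamics, blinks as
temporal events (loss is i.i.d.), pupil light reflexes and temporal
autocorrelation, microsaccades, photorealistic image statistics, and any
correlation between a subject's gaze style and their pupil physiology.
Passing tests on this world therefore show the pipeline's statistical
machinery is correct under its stated assumptions — not that the effect
sizes transfer to human data, where dilation amplitude (here a free
parameter, not a physiological claim) and autocorrelation differ.

## Problem sizes used in the checks

The automated checks run at desk scale by design: anomaly-test
calibration on $10^5$ standard-normal samples; planted-interest recovery
on the full 8 × 1000 × 300 pupil condition; smoothing oracles on grids up
to 32 × 32 and sigma recovery on 512 × 512; model correctness at
`channelScale` 1/16–1/32 on 16–32 px inputs (plus the user-encoding
branch at full width, C = 512 from M = 800); and the transfer comparison
on a 4-subject × 12-image corpus with 16 × 16 maps over three seeds. The
full-width, full-resolution training recipe is expressed in the defaults
but is a GPU-scale undertaking outside the scope of the checks.

## Known limitations

- Pure-R training is practical only at reduced width/resolution; there is
  no GPU path, no mixed precision, no multi-image batching beyond
  gradient accumulation.
- Bit-for-bit training reproducibility assumes single-threaded BLAS;
  multi-threaded builds are only statistically reproducible.
- The `mean` labeling rule discards within-presentation timing; a
  duration- or onset-aware statistic might separate interest from, e.g.,
  luminance responses, but needs assumptions the data model here does not
  provide.
- Screen-to-image mapping is a linear rescale; homographies and tracker
  calibration are out of scope.
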