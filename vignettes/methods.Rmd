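---
title: "Multi-modal fusion with trainable feature encodings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal fusion with trainable feature encodings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexfuse)
```

## The problem

Predicting whether a chronic kidney disease (CKD) patient will progress
within three years is a binary classification problem over highly
heterogeneous inputs: clinical covariates from the medical record (largely
binary indicators and roughly Gaussian laboratory values), urinary
proteomic and metabolomic profiles (long-tailed abundance distributions
spanning orders of magnitude), and PASM-stained kidney-biopsy pathology
tiles. `flexfuse` implements an end-to-end multi-modal fusion model for
this setting, together with a synthetic cohort generator so that every
component is testable without restricted clinical data.

## Model

### Tabular modalities: the feature encoding trainer

Each tabular modality (clinical `C`, proteomic `P`, metabolomic `M`) passes
through two stages.

**Hash mapping.** Each feature's empirical distribution — estimated on the
training split only — is cut into `B = 16` equal-probability buckets; a
value is replaced by its bucket's probability-mass midpoint $(k + 0.5)/B$
on a common $[0, 1]$ scale. The transform is monotone per feature, immune
to monotone rescaling (a feature multiplied by $10^6$ maps identically
after refitting), and clamps out-of-range values to the extreme buckets.
Missing cells are carried as an explicit out-of-range code, never a
midpoint. The bucket count is a tunable compromise: very small `B` erases
within-feature resolution, very large `B` reproduces the raw
distribution's noise; 16 buckets retain ~4 bits of each feature while
discarding scale and tail behaviour.

**Encoding training.** Each mapped scalar $v_f$ scales its feature's
trainable ten-dimensional encoding vector $e_f$; a missing cell instead
contributes the feature's learned missing-bucket encoding $m_f$. Each
embedded vector passes through the feature's own learnable fully connected
$10 \times 10$ layer (unshared by default; a shared-weights variant is
available via `shared_fc`), the transformed vectors are summed over
features — an order-invariant aggregation that accommodates arbitrary
feature counts — and projected with a ReLU layer to the modality
representation of dimension `d_rep = 32`. Encodings, per-feature layers
and projection all train end-to-end by backpropagation, so the feature
encodings absorb inter-feature structure rather than staying fixed.

Two ablation pathways are first-class: *raw* (per-feature standardized
values through a plain two-layer feedforward encoder; missing cells at the
standardized mean) and *hashed* (bucket midpoints through the same
feedforward encoder, with no trainable per-feature encodings).

### Image modality

Tiles are encoded by a configurable convolutional backbone (`tiny_cnn`, a
four-conv-layer desk-scale network; `resnet18`/`resnet34`/`resnet50` with
their standard block layouts; `vgg16`), global-average-pooled at the last
convolutional stage, pooled across a patient's tiles (unweighted mean by
default; attention pooling available), and projected to `d_rep`.
Convolutions use replicate (clamp) padding rather than zero padding: zero
padding systematically depresses border activations of the tap-point
feature map, which corrupts the mean-threshold region-of-interest
extraction described below. The residual networks here use bias
convolutions without batch normalization — batches are small tile stacks,
where batch statistics are unreliable — and no pretrained weights are
downloaded; both training from scratch and loading a saved checkpoint are
supported.

### Fusion, classification, and the Meta module

The per-modality representations are fused by one of four operators:
elementwise **summation**, elementwise **multiplication**, **gating** (one
sigmoid gate vector per modality computed from the concatenation of all
representations, fused as $\sum_m g_m \odot h_m$), or **concatenation** in
the fixed order C, P, M, I. A two-layer classifier (hidden width 64, ReLU,
sigmoid output) produces the progression probability. The output layer is
zero-initialized so every model starts at probability 0.5 and the initial
loss is $\log 2$ regardless of representation magnitudes; with
He-initialized output weights on top of sum-aggregated representations,
initial predictions saturate and the first epochs are wasted recalibrating.

Because representations are post-ReLU and therefore sparse, multiplication
fusion is fragile: a zero entry in any modality annihilates that
coordinate of the fused vector, and an all-zero representation annihilates
it entirely. The package's fusion-operator study reproduces this
degradation directionally; at some seeds multiplication training collapses
outright to chance, which is retained in the reported means rather than
filtered.

The **Meta module** addresses single-modality missingness: for each
modality $m$ it maps the concatenation of the other active modalities'
representations through a two-layer network to a replacement vector. It is
co-trained with the rest of the model: patients genuinely missing $m$ are
routed through it inside the computation graph (so the classification loss
reaches the Meta parameters), and an auxiliary reconstruction loss — mean
squared error to the true representation on complete patients, weight
$\lambda = 0.5$ — trains it even when no data are missing. The auxiliary
term uses detached inputs and targets: it shapes the Meta network only,
without pulling the encoders toward predictability. Post-hoc Meta training
is possible by retraining with frozen seeds, but joint training is the
default. Two or more missing modalities are an explicit unsupported case.

### Training protocol

Adam (learning rate $10^{-3}$ by default), minibatches of 32, up to 50
epochs with early stopping on the AUROC of an internal stratified 20%
validation split (patience 10), all seeded: two runs with the same
configuration reproduce parameters bitwise. Cross-validation is
label-stratified five-fold; hash mappers, standardization constants and
all trainable state are fitted per fold on the training split only, and
each mapper records the patient ids it was fitted on so leakage is
checkable after the fact. Metrics are the standard clinical sextet: AUROC
(rank statistic, ties one half), AUPRC, and accuracy, sensitivity,
specificity and F1 at the 0.5 threshold.

## Interpretability

**Integrated Gradients.** `integrated_gradients()` implements the path
integral $IG_i = (x_i - x'_i) \cdot \frac{1}{K}\sum_{k=1}^{K}
\partial F/\partial x_i \big|_{x' + (k/K)(x - x')}$ for any function
supplying values and gradients; for a linear model it is exact at any step
count, and the completeness axiom (attributions sum to
$F(x) - F(x')$) holds up to Riemann-sum error. For the fused model,
attribution is computed at the model's input-embedding level: each tabular
feature's contribution is the attribution of its ten-dimensional embedded
vector against the feature's *learned missing-bucket embedding* as
baseline — the model's native representation of "this measurement is
absent", which is exactly what the missing-bucket code feeds the network —
summed over embedding dimensions; image attributions are per pixel of the
standardized tile stack against an all-zero (channel-mean) tensor.
Completeness carries over to these sums. A representation-level variant
(attributing modality vectors directly) can be obtained by differentiating
from the fusion stage, but the input-embedding level is the supported
default. Modal importance is the mean absolute attribution over a
modality's inputs (signed means via `signed = TRUE`; the default is
absolute because importance distributions are compared across modalities
with different input counts); features are ranked by median absolute
attribution, ties broken by name.

**SCDA heat maps.** The tap-point feature map is summed over channels,
thresholded strictly at its mean, and the largest 4-connected
above-threshold component is kept as the region of interest; relevance is
bilinearly upsampled to tile resolution and rendered red (strong) to blue
(weak). A constant map yields an empty mask under the strict inequality.
Whole-slide views are mosaics of tile heat maps in manifest coordinates.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the real data without
claiming its parameters:

* clinical features: half Bernoulli with success probabilities drawn from
  $U[0.1, 0.5]$, half Gaussian with heterogeneous means and scales;
* proteomic/metabolomic features: log-normal$(0, 1)$ scaled per feature by
  $10^{U[-1, 2]}$ — long-tailed across several orders of magnitude;
* labels: a logistic model whose logit sums `effect_size` times each
  standardized informative feature, with the intercept calibrated by root
  finding so that mean predicted prevalence is 0.41 (mirroring a 106/259
  class split). For the long-tailed features the risk scales with
  standardized *log*-abundance, the biologically standard reading;
  outlier contamination (`outlier_rate`) multiplies random cells by
  10-100x *after* label generation, so outliers are measurement noise
  rather than signal — this is what makes the raw-value pathway fragile
  and the rank-based hash mapping robust, the mechanism the pathway study
  measures;
* images: textured tiles (smooth low-frequency noise plus pixel noise) on
  which progression patients' tiles carry a bright ellipsoidal lesion with
  probability `lesion_signal`, randomized in position, eccentricity and
  orientation. Lesion scale (semi-axis 0.20-0.30 of the tile side,
  brightness +0.5) is calibrated once to the operating granularity of
  mean-threshold ROI extraction — a trained backbone's ROI covers roughly
  a third of a tile, so localizable lesions must occupy a commensurate
  area — and frozen;
* missingness: per-modality deletion at `missing_rate`, constrained so no
  patient loses more than one modality (the Meta module's supported case);
  `cell_missing_rate` blanks individual tabular cells.

Everything is a deterministic function of the seed, and `truth.json`
records the planted ground truth (informative feature names, effect sizes,
per-tile lesion geometry) for parameter-recovery tests.

What the generator does *not* emulate: realistic PASM histology texture,
correlated feature blocks, longitudinal follow-up, batch effects, or any
real cohort's effect sizes. Passing tests therefore demonstrate that the
machinery recovers planted structure under the stated statistical shapes,
not that it reproduces any real-data performance figure.

## Study designs and problem sizes

The packaged studies (`sim_study_*`) run at desk scale on one CPU; sizes
were chosen once as the smallest cohorts at which the measured effects are
stable across seeds.

* **Multimodal benefit** (`sim_study_modalities`): n = 600 per cohort,
  disjoint informative sets in C and P (five features each, effect 1.0),
  M pure noise, lesion probability 0.3 — an image channel deliberately
  moderate so that fusion, not a single dominant modality, drives
  performance; four unimodal models and the full model, each scored by
  stratified five-fold cross-validation, across seeds.
* **Pathway ordering** (`sim_study_fet`): n = 600, signal in 13 features
  across the three tabular modalities, 2% outlier contamination;
  raw vs hashed vs encoded under identical folds.
* **Fusion operators** (`sim_study_fusion`): the same cohorts, multiplication
  vs concatenation.
* **Attribution recovery** (`sim_study_attribution`): n = 500, signal only
  in five proteomic features (effect 1.2); trained on three quarters,
  attributed on the held-out quarter.
* **SCDA localization** (`sim_study_scda`): n = 300, every progression
  tile carries a lesion; the image model trains *without* early stopping
  because discrimination saturates within an epoch while the backbone's
  lesion selectivity — what the heat maps measure — keeps sharpening under
  continued confidence training. The negative control pairs held-out
  lesion-free tiles with lesion geometries drawn from the true-lesion
  pool.
* **Meta utility** (`sim_study_meta`): n = 600 with 15% of patients
  genuinely lacking the image modality during training; at test time the
  image modality is deleted for held-out complete patients and Meta
  imputation is compared against a zero vector. The image modality is the
  deletion target because it is the clinically natural missing channel (it
  requires a biopsy) and because its representation statistics are large
  enough that a zero block visibly corrupts the classifier; for tabular
  blocks, Meta and zero replacement are statistically indistinguishable at
  this scale — both reduce to the information carried by the remaining
  modalities — and the package reports that honestly rather than claiming
  a universal ranking.
* Training inside the studies uses Adam at $2 \times 10^{-3}$, batch 64,
  early stopping on a 15% split (30-40 epochs for tabular-only models,
  10 for image-bearing ones, whose lesion signal converges in a few
  epochs).

## Numerical choices and degenerate inputs

* Constant features collapse to a single bucket mapping to 0.5; a feature
  with no observed training value is an error naming the feature.
* Hash boundaries are type-7 empirical quantiles made non-decreasing;
  values equal to a boundary fall in the upper bucket. On equal-mass
  mapped midpoints the transform is idempotent.
* AUROC uses midranks, so ties count one half; it is cross-checked in the
  tests against a brute-force pairwise oracle and against pROC.
* The SCDA threshold is a strict inequality, components are 4-connected,
  and the largest component wins (first-found on ties).
* Fold remainders go to the folds with the smallest running totals, so 259
  patients split 52/52/52/52/51 with per-class imbalance at most one.
* `predict` in eval mode consumes no randomness; dropout (off by default)
  and shuffling are seeded, making training bitwise reproducible.

## Known limitations

Single-modality missingness only (two or more missing active modalities
raise an error, matching the supported scope); no learned discretization;
no whole-slide tiling, stain normalization or segmentation; no
hyperparameter search; real-data performance figures are out of reach by
design, since the cohorts here are synthetic.
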