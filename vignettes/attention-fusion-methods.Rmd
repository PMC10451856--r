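---
title: "Attention-guided multi-phase fusion for MVI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided multi-phase fusion for MVI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

Microvascular invasion (MVI) — tumor emboli inside endothelium-lined vascular
spaces of the peritumoral liver — is a histological finding in hepatocellular
carcinoma (HCC) that strongly predicts recurrence after resection, but it is
only established on the surgical specimen. Radiology offers indirect
correlates on gadoxetate-enhanced multi-phase MRI: nonsmooth tumor margins,
rim-like arterial enhancement, peritumoral hyperenhancement in the arterial
phase (AP), and peritumoral hypointensity in the hepatobiliary phase (HBP).
`mvifusion` implements a deep-learning pipeline that predicts the binary MVI
label from four co-registered phases (pre-contrast PreP, AP, portal PP, HBP)
of a tumor-bearing liver MRI, and quantifies *where* the network looks, so
the prediction can be checked against those known radiological correlates.

Because clinical MRI cohorts cannot ship inside a package, `mvifusion` pairs
the model with a synthetic phantom generator that plants exactly those
correlates with tunable effect sizes. Every stage of the pipeline is
exercised end to end on phantoms; what that does and does not demonstrate
about clinical data is discussed at the end.

## Preprocessing: from study to cubes

A study consists of four co-registered volumes plus a binary tumor mask drawn
in the HBP (where tumor borders are most conspicuous; co-registration makes
the mask valid in every phase). Preprocessing follows a fixed recipe:

1. **Bounding box.** The tight box around the mask is expanded by 2 voxels
   per side to include the peritumoral band, clamped to the volume, and
   cube-ified by extending shorter axes to the longest axis (`mask_to_bbox()`).
   Coordinates are 0-based and half-open throughout, which removes
   off-by-one ambiguity.
2. **Global cube.** The cropped region is resampled to 16^3 by trilinear
   interpolation (`extract_global_cube()`); order-1 interpolation is the
   standard choice for intensity volumes and avoids ringing at this
   resolution. Resampling uses pixel-center alignment, so a same-size
   resample is exactly the identity.
3. **Local-cube augmentation.** The crop is resampled to 32^3 and cut into
   16^3 sub-cubes at stride 2: `floor((32-16)/2)+1 = 9` offsets per axis,
   hence 729 local cubes per tumor and phase (`augment_local_cubes()`).
   Corner cubes that miss the tumor are kept; no filtering is applied, which
   is what makes the count exactly 729. A training cohort of 168 patients
   therefore yields 729 x 168 + 168 = 122,640 samples per phase (local plus
   global); test patients are never augmented and contribute only their
   global cube, because 729 near-copies sharing one label would bias test
   statistics.
4. **Split.** Patients are divided 4:1 into training and test sides,
   stratified by MVI label, and the training side is assigned to 5
   stratified cross-validation folds (`make_split()`). Stratification is
   adopted because a 70/140 cohort split 4:1 that lands exactly on 14/28
   test positives/negatives is what exact stratification produces.
5. **Normalization.** Every cube is z-scored (mean 0, sd 1; constant cubes
   become zeros) at batch-assembly time. Some normalization is mandatory for
   SGD stability; per-cube z-scoring is the simplest choice that needs no
   cohort statistics.

Whether the original protocol cubified the bounding box before resizing, and
whether 3-slice manual segmentations were interpolated to full 3D masks, are
not derivable from the recipe alone; this package uses full 3D masks (the
phantom provides them) and cubifies, and records both choices here.

## The network

Each phase is processed by a LeNet5-style 3D backbone: three 3x3x3
convolution stages (6, 16, 32 channels, stride 1, padding 1), each fused
with a ReLU, with 2x2x2 max pooling between stages. On the deepest map
(4^3 spatial positions, so N = 64 after flattening, C = 32 channels) sit
the two attention blocks, between the last convolution and the last pooling
layer:

* **Self-attention** (`self_attention()`): queries and keys are linear
  projections to d_k = 8 dimensions (1x1x1 convolutions), values stay
  32-dimensional. The N x N attention matrix is the row-softmax of the
  scaled dot-product scores QK'/sqrt(d_k), so every row sums to 1 and every
  coefficient lies in (0,1). The attended aggregate re-enters through a
  residual gate: y = x + gamma * AV with gamma a learnable scalar
  initialized at 0, making the block an exact identity at initialization —
  a property the test suite asserts. The scaling by sqrt(d_k) and the
  zero-initialized gate are standard conditioning choices for attention on
  small data.
* **Collaborative attention** (`collaborative_attention()`, fusion models
  only): each phase queries every other phase's self-attended map with its
  own projections; the per-pair attended aggregates are averaged and added
  through a second zero-initialized residual gate. The reported matrix is
  the mean of the pair matrices, which is again row-stochastic. The
  residual form means collaborative attention supplements rather than
  replaces the self-attention output.

Attention is placed at the deepest (4^3) stage rather than at the full 16^3
resolution: dense N x N attention is quadratic in N, and N = 4096 would cost
roughly two orders of magnitude more than N = 64 per step on a CPU, while
deep, low-resolution placement is also where non-local blocks are
conventionally inserted — the features there are semantically richest. The
wording "between the convolutional and pooling layers" admits either
placement; this one is recorded as the package's choice.

After the attention blocks, each branch pools to 2^3, flattens, and maps
through a fully connected layer to a 32-dimensional phase feature (dropout
0.5 during training, on the FC features only). A single-phase model
classifies this feature directly through a 2-way softmax head. A fusion
model concatenates the per-phase features (|phases| x 32; 128 for the
four-phase model) into a fused softmax head, and additionally gives each
phase branch a lightweight auxiliary head used by the loss.

The forward/backward passes are written in the package itself (R
orchestration over C++ kernels for convolution, pooling and the attention
core, with BLAS doing the contractions); gradients of every parameter are
verified against central finite differences in the test suite.

## Training

The loss is a weighted multi-phase sum `L = sum_x omega_x * CE_x` over the
per-phase heads, with weights normalized to sum to 1 (`multi_phase_loss()`);
at the uninformed point where every head outputs (0.5, 0.5) it equals ln 2
exactly, whatever the weights. The per-phase weights are exposed in
`train_config()` and default to equal. For fusion models the fused head's
cross-entropy is added with weight 1 — the per-phase loss form requires
per-phase predictions, and auxiliary heads are the minimal mechanism that
provides them.

Optimization is momentum SGD (batch 16, learning rate 0.004, momentum 0.9,
weight decay 1e-4, no learning-rate schedule) for up to 50 epochs under a
hard cap of 501 iterations, whichever binds first. At the full augmented
scale (122,640 samples per phase) 501 iterations of batch 16 cover well
under one epoch, so the cap binds; at phantom scale the epoch budget can
bind instead. Both limits are honored. Each of the 5 folds trains its own
model from its own seeded initialization; the held-out fold's global cubes
form the validation set, evaluated every `eval_every` iterations, and the
checkpoint kept is the best-validation-loss evaluation. Early stopping
triggers after `early_stop_patience` (default 5) consecutive
non-improving evaluations. Local and global cubes are mixed uniformly at
random within batches. Test-set predictions average the softmax
probabilities of the fold models (`ensemble_predict()`) — a deliberately
simple ensemble rule, chosen because cross-validation produces five
checkpoints and the test set needs one probability per patient.

With the 1:2 MVI class imbalance no loss reweighting is applied by default
(an option exists), matching the configuration the pipeline is meant to
replicate.

## Evaluation and interpretability

`roc_auc()` computes the rank-based (Mann-Whitney) AUC with midrank tie
correction, a stratified bootstrap percentile confidence interval (default
2000 replicates, seeded; resampling within each class keeps the class ratio
fixed), and accuracy/sensitivity/specificity at an operating point — by
default the Youden-optimal threshold on the evaluated set, with a fixed
cutoff available. The bootstrap was chosen over an asymptotic interval for
uniformity with the resampling used elsewhere; both the point AUC and the
interval are checked in tests against brute-force pair counting and pROC.
`net_benefit()` implements decision-curve analysis,
`NB(p_t) = TP/n - (FP/n) p_t/(1-p_t)` on a default grid 0.01–0.60 (step
0.01), with treat-all and treat-none references.

`grad_cam()` explains a prediction at either attention block: channel
weights are the spatial means of the target logit's gradient with respect
to the block's output feature map, the CAM is the rectified weighted channel
sum, upsampled trilinearly from 4^3 to the 16^3 cube and min-max normalized
to [0,1] for display (raw values are retained for quantitative use).
Grad-CAM is defined over feature maps, so it is computed on the block
output; the raw N x N attention coefficients are also exported, covering
both readings of "CAM based on the attention weights".
`phase_weight_heatmap()` summarizes the fused head's first FC layer as the
mean absolute weight per concatenated feature, grouped into one 32-entry
grid per phase — the phase whose grid carries the most weight contributes
most to the fused prediction. `attention_mass_fraction()` turns saliency
into a number: the fraction of heatmap mass inside a region (e.g. the
margin-plus-peritumoral band from `margin_shell_region()`), whose null
expectation under random voxel permutation of the heatmap is simply the
region's voxel fraction.

## The phantom generator

`phantom_config()` / `generate_study()` build, per patient, an ellipsoidal
tumor (semi-axes drawn from 8–13 voxels) at a jittered center inside a
64^3 volume, over a constant liver-like background with distinct per-phase
means (HBP brightest, as functioning parenchyma retains gadoxetate; tumor
arterially enhancing in AP and hypointense in HBP). MVI-positive studies
additionally receive:

* **margin irregularity** — the surface radius is modulated by a smooth
  random field on the sphere (a superposition of von Mises–Fisher bumps,
  standardized and scaled by `margin_irregularity_amp`, multiplier clipped
  to [0.5, 1.5]); band-limited smoothness gives lobulated, never fragmented,
  star-shaped (hence connected) masks;
* **an AP peritumoral ring** — `+ap_ring_contrast` in the 2-voxel
  Chebyshev shell outside the mask;
* **an HBP peritumoral ring** — `-hbp_ring_contrast` in the same shell.

i.i.d. Gaussian noise (`noise_sd`) is added to every phase. Per-patient
randomness derives from a counter-based stream of `(seed, patient_index)`,
so any study can be regenerated independently of generation order, and
exactly `round(mvi_fraction * n_patients)` patients are positive.
`generate_cohort()` writes NIfTI volumes (unit isotropic voxels) plus a
roster CSV; `generate_cohort_memory()` keeps studies in memory for
simulation runs.

No quantitative effect sizes exist for the radiological correlates, so the
defaults are the package's own calibration, chosen once against the design
goal that the four-phase fusion task be learnable under the scaled training
budget below while single phases stay imperfect: ring contrasts 30,
margin amplitude 1.5 voxels, noise sd 5 on a background scale of ~100–160.
The pre-contrast and portal phases carry only the (weak) margin cue, so
their single-phase models stay clearly below the AP/HBP models; the fusion
model, which can pool both rings and the margin across phases, converges to
the best test performance.

What the phantom does *not* emulate: MRI physics (bias fields, coil
profiles), anatomy beyond a homogeneous liver, motion or registration error
between phases, multifocal disease, and intensity distributions of real
gadoxetate studies. Tests passing on phantoms therefore demonstrate that
the pipeline's machinery — augmentation arithmetic, optimization, ensemble
evaluation, saliency — behaves as specified and can recover planted signal;
they are not evidence of clinical performance.

## Problem sizes used by the simulation studies

The package's own verification runs (test suite and `scripts/acceptance.R`)
use scaled-down study sizes, chosen as the smallest sizes at which the
planted-signal properties are still expressed clearly:

* cohorts of 80 phantom patients (1/3 MVI-positive) at 64^3 voxels for the
  recovery studies, one cohort per signal scenario; the full 210-patient
  cohort size is used where only counting arithmetic is verified;
* 5 independently seeded replicates per scenario: the seed drives the
  stratified split, the initialization, the batch sampling and dropout,
  over the fixed simulated cohort;
* one cross-validation fold model per configuration (fold 0 of the 5-fold
  plan) rather than the full 5-model ensemble;
* up to 500 SGD iterations per fold — inside the 501-iteration cap — at
  batch size 4 and learning rate 0.0075 with 25% global cubes per batch:
  the defaults (batch 16, lr 0.004, uniform cube mixing) are tuned for a
  122,640-sample training set, where 501 iterations cover under one epoch
  and global cubes are a 0.14% minority; at phantom scale uniform mixing
  would mean the network effectively never trains on a global cube while
  being validated and tested exclusively on them.

These sizes are stated here as the package's chosen simulation design so
that anyone re-running the studies knows what was computed.

## Numerical and degenerate-input choices

* Softmax rows are shifted by their row maximum before exponentiation.
* Cross-entropy clamps probabilities at 1e-12; a non-finite loss aborts
  training with a diagnostic rather than continuing silently.
* Z-scoring declares a cube degenerate below sd 1e-8 and returns zeros.
* `mask_to_bbox()` errors on empty masks; cube extraction errors on boxes
  thinner than 2 voxels after clamping.
* Ties in the Youden criterion resolve to the first optimal threshold in
  descending-score order; bootstrap quantiles use the default type-7 rule.
* An all-zero Grad-CAM (a head that ignores the explained layer) is
  reported as all-zero rather than rescaled; `attention_mass_fraction()`
  returns `NA` with a warning for it.
* The residual gates make the attention blocks identities at
  initialization, so the network starts as its attention-free backbone and
  the attention paths switch on only as gamma departs from 0.

## Known limitations

* Per-phase weight attribution through the fused head is confounded by the
  collaborative-attention mechanism itself: because each branch's features
  are residually enriched with the other phases' attended evidence, a
  signal planted exclusively in the hepatobiliary phase is partly carried
  by the other phases' feature segments, and the HBP segment of the fused
  head does not reliably carry the largest mean weight in every seeded run
  (it does so on average over seeds). Phase-weight heatmaps from this
  architecture should therefore be read as indicative, not as a clean
  decomposition of per-phase information.

* The phantom's homogeneous background makes tumor/background contrast
  easier than in real livers; absolute AUC values on phantoms say nothing
  about clinical AUC.
* Dense N x N attention limits the practical attention resolution on CPU;
  at 16^3 feature maps a subsampled or windowed attention would be needed.
* The bootstrap CI is percentile-based; for very small test sets (a few
  positives) its coverage degrades, as percentile bootstraps do.
* Training is single-device and synchronous; there is no mixed precision,
  no learning-rate schedule (a constant rate matches the replicated
  configuration), and no hyperparameter search.
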