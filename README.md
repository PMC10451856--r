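# mvifusion

Preoperative prediction of **microvascular invasion (MVI)** in hepatocellular
carcinoma from four-phase gadoxetate-enhanced liver MRI — pre-contrast
(PreP), arterial (AP), portal (PP) and hepatobiliary (HBP) — with an
**attention-guided multi-phase feature-fusion network**, plus the saliency
tooling to see *where* the network looks.

MVI (tumor emboli in endothelium-lined vascular spaces of the peritumoral
liver) is decided on the surgical specimen, yet it drives recurrence risk
and therapy choice. Its radiological correlates — nonsmooth tumor margins,
arterial-phase peritumoral hyperenhancement, hepatobiliary-phase peritumoral
hypointensity — live in *different* phases of the same study, which is the
case for cross-phase fusion. The package is aimed at researchers in medical
image analysis who want a complete, testable reference implementation of
this pipeline that runs end to end without clinical data.

## The model

Each phase's tumor region (a 16×16×16 intensity cube) passes through a
LeNet5-style 3D backbone (three 3×3×3 convolution stages, 6/16/32 channels,
2×2×2 max pooling). On the deepest feature map (N = 4³ = 64 positions,
C = 32 channels), between the last convolution and the last pooling layer,
sit two attention blocks:

* **self-attention** — A = row-softmax(QKᵀ/√d_k) over the N positions of
  one phase, with y = x + γ·AV through a learnable residual gate γ
  (initialized 0, so the block starts as an exact identity);
* **collaborative attention** (fusion models) — each phase's queries attend
  over every other phase's keys/values; pair outputs are averaged and
  residual-added, importing complementary evidence across phases.

Per-phase 32-dimensional features are concatenated into a 2-way softmax
head. Training minimizes the weighted multi-phase loss
**L = Σₓ ωₓ·CEₓ** over per-phase auxiliary heads (plus the fused head's
cross-entropy), with momentum SGD (batch 16, lr 0.004, momentum 0.9, weight
decay 10⁻⁴, ≤ 501 iterations), 5-fold stratified cross-validation and early
stopping; test predictions average the fold models' probabilities.

Preprocessing follows the cubic-region recipe: tumor mask → bounding box
expanded 2 voxels to include the peritumoral band → global 16³ resample,
plus sliding-window augmentation of the 32³ resample into 9×9×9 = **729
local cubes** per tumor and phase (16³ windows at stride 2). Evaluation
reports rank AUC with stratified-bootstrap CIs, Youden operating points and
decision-curve net benefit; interpretability comes as Grad-CAM saliency at
either attention layer and the per-phase fused-head weight grids (32 per
phase).

A synthetic **phantom generator** plants the three MVI correlates with
tunable effect sizes (margin irregularity in all phases, +AP ring, −HBP
ring, Gaussian noise), so every stage is exercised and verified on data the
package itself creates.

## Worked example

Simulate a small cohort, train one single-phase model, and evaluate it:

```r
library(mvifusion)

cfg   <- phantom_config(n_patients = 40, mvi_fraction = 0.5, seed = 11)
coh   <- generate_cohort_memory(cfg)
split <- make_split(coh$roster, seed = 1)          # stratified 4:1, 5 folds
cache <- prepare_cube_cache(coh$studies, phases = "AP")
ds    <- build_training_dataset(split, cache)

nrow(ds$train)   # 32 training patients x (729 local + 1 global) = 23,360
#> [1] 23360

tc <- train_config(lr = 0.01, batch_size = 8, max_iterations = 300,
                   eval_every = 25, global_fraction = 0.25, seed = 1)
fm <- train_fold(ds, cache, fold = 0, network_config("AP"), tc)

preds <- ensemble_predict(list(fm), ds$test, cache)
roc   <- roc_auc(preds$score, preds$label, seed = 1)
roc
#> ROC: AUC 1.000 (95% CI 1.000-1.000), n = 4 pos / 4 neg
#> Operating point (threshold 0.486): accuracy 1.000, sensitivity 1.000, specificity 1.000

glance(roc)        # one-row tibble: auc, ci, accuracy, sensitivity, ...
autoplot(roc)      # ROC staircase
autoplot(net_benefit(preds$score, preds$label))   # decision curve
```

The AUC of 1.0 says the planted arterial-phase signal (peritumoral ring +
margin irregularity) is fully recovered on the held-out patients at these
effect sizes — a pipeline check, not a clinical claim. For a fusion model,
pass several phases (`network_config(c("PreP","AP","PP","HBP"))`) and
explore `phase_weight_heatmap()` (which phase drives the prediction) and
`grad_cam()` (where in the cube the evidence sits).

There is also a command-line driver for full runs
(`inst/cli/mvifusion run-all --config cfg.yaml --outdir out --seed 1`),
covering simulate → preprocess → train → evaluate → explain with a YAML
configuration and a JSON run manifest.

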