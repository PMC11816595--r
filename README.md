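# rlsaliency

Reinforcement-learning-guided patch-perturbation saliency for cell image
classifiers.

## What it does, and for whom

Convolutional classifiers for single-cell cytology images (Pap smear /
liquid-based-cytology crops) report a class probability but not *which part
of the cell* the call rests on. `rlsaliency` recovers that information by
attacking the classifier as a black box: a tabular Q-learning agent adds
and removes small, bounded distortions on an `n x n` patch grid — guided by
per-patch sensitivity of the ground-truth probability — until the
prediction flips. A greedy cleanup pass then strips every distortion not
needed for the flip, and the divergence between the original and the
minimal adversarial image becomes a saliency heatmap: the patches that had
to be perturbed are the patches the model relies on.

It is aimed at people building or auditing desk-scale image classifiers
who want attack-based saliency with a fully inspectable, dependency-light
implementation: every component (residual CNN with sigmoid channel
attention, distortion algebra, sensitivity probing, Q-learning loop,
cleanup, metrics) is plain R plus two small C++ kernels.

## The core quantities

* **Residual backbone** — stages of conv/batch-norm/ReLU plus residual
  blocks `x_{l+1} = x_l + F(x_l, W_l)`; per-channel sigmoid attention
  `z_i = sigmoid(W_i h_i)`; softmax head trained by cross-entropy (Adam,
  learning rate 0.001, weight decay 1e-4).
* **Probability dilution** — `PD = max_{c != gt} p_c − p_gt`, the signed
  margin toward the best alternative class; positive exactly when the
  image is misclassified.
* **Step reward** — `R_t = ΔPD / max(|ΔL2|, ε)`: dilution gained per unit
  of L2 perturbation spent. An `α·sensitivity − β·FPR` mode is available
  in the configuration.
* **Action space** — pairs `(add, remove)` with `remove < add ≤ P_max`
  (default 8), so each step adds net distortion; Q-values are tabular over
  a 4-feature discretized state and updated by
  `Q(s,a) += η (R_t + γ max_a' Q(s',a') − Q(s,a))`.
* **Localization enrichment** — fraction of saliency mass inside the known
  discriminative region divided by the region's area fraction (1 = chance).
* **Metrics suite** — accuracy, recall, precision, F-measure, specificity,
  G-means (`sqrt(recall × specificity)`), one-vs-rest with macro averages.

## Worked example

Train a small backbone on the built-in synthetic fixture (two cell classes
whose nucleus blobs differ in staining density; the blob disk is the
recorded ground-truth discriminative region), attack one test image, clean
it up, and score the mask:

```r
library(rlsaliency)

train <- generate_synthetic_dataset(synthetic_spec(n_per_class = 30, seed = 11))
model <- backbone_model(c(16, 16, 1), n_classes = 2, seed = 12)
model <- train_supervised(model, train,
                          train_config(max_epochs = 20, batch_size = 16,
                                       augment = list(noise_sd = 0.08),
                                       seed = 13))
tail(model$history, 1)
#>    epoch train_loss train_acc   val_loss
#> 20    20 0.07554766         1 0.04202227

test <- generate_synthetic_dataset(synthetic_spec(n_per_class = 10, seed = 14))
s <- test[[14]]
predict_proba(model, s)          # P(class 0), P(class 1); truth is class 1
#> [1] 0.1514124 0.8485876

bb <- as_blackbox(model)
set.seed(20)
ep <- run_episode(bb, s, qtable_new(36),
                  distortion_filter("gaussian_noise", noise_sd = 0.1, seed = 15),
                  qlearning_config(max_steps = 50, p_max = 8, seed = 16,
                                   eps_end = 0.2))
ep
#> <episode_result> misclassified after 4 step(s), D = 0.9390, 285 queries

cleaned <- cleanup_episode(bb, ep)
state_distance(cleaned)          # L2 cost after stripping unneeded patches
#> [1] 0.7401058
mask <- compute_mask(s$pixels, cleaned$current, segment_patches(s, 2))
localization_enrichment(mask, s$truth_region)
#> [1] 2.371929
write_heatmap(mask$values, "saliency.png")
```

The episode flipped the prediction after 4 steps and 285 black-box
queries; cleanup cut the L2 distance from 0.94 to 0.74, and the surviving
saliency mass sits in the nucleus region at about 2.4x the density a
uniform mask would put there (1.0 = chance).

The same flow is scriptable from a shell via `inst/cli/rlsaliency`
(`simulate`, `train`, `explain`, `evaluate` subcommands, YAML config,
JSON/JSONL/CSV/PNG outputs).

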