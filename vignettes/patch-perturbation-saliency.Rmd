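---
title: "Probing a cell-image classifier with reinforcement-learned patch perturbations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing a cell-image classifier with reinforcement-learned patch perturbations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated screening of single-cell cytology images (Pap smears and
liquid-based preparations) increasingly relies on convolutional
classifiers, but a bare class probability is hard to act on clinically: the
reader wants to know *which part of the cell* drove the call. `rlsaliency`
answers that question by attack: a reinforcement-learning agent perturbs an
image patch by patch, querying the classifier as a black box, until the
prediction flips. The patches whose perturbation was necessary for the flip
are, by construction, the patches the classifier relies on; the divergence
between the original and the minimally perturbed image is exported as a
saliency heatmap.

The package implements the whole loop desk-scale: a small residual CNN
backbone with sigmoid channel attention, trained by cross-entropy; a patch
segmentation and bounded-distortion layer; per-patch sensitivity probing; a
tabular Q-learning agent with a probability-dilution reward; greedy cleanup
of successful attacks toward minimal perturbations; saliency masks with a
localization score against known ground truth; and the six-statistic
classification metrics suite (accuracy, recall, precision, F-measure,
specificity, G-means).

## Model and procedure

### Backbone

The classifier is a residual CNN. Each stage applies a 3x3 convolution,
batch normalization and ReLU, followed by one residual block

$$x_{l+1} = x_l + F(x_l, W_l),$$

where the branch $F$ is convolution, batch normalization, ReLU,
convolution. Zeroing the branch weights makes every block an exact identity
map, which the tests assert. After the final stage each feature map $h_i$
is reweighted by a sigmoid attention gate

$$z_i = \sigma(W_i h_i), \qquad z_i \in (0,1),$$

applied multiplicatively; global average pooling and a linear softmax head
produce the class distribution. Training minimizes the cross-entropy
$-\tfrac1N \sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]$ (its
categorical generalization $-\log \hat y_{\text{true}}$ beyond two
classes) with Adam at learning rate 0.001, weight decay $10^{-4}$, batch
size 32, up to 100 epochs with early stopping on validation loss — all
config defaults, overridable per run.

The default architecture (2 stages, 8/16 channels, 16x16 grayscale inputs)
is deliberately small: every experiment in the package runs in minutes on
one CPU core. Depth, width and input shape are configurable, and the
structural equations are unchanged at larger scale.

### Patch perturbation

The image is segmented into an $n \times n$ patch grid ($n = 2$ by
default; a 224x224 image at $n=2$ gives the reference count of 12,544
patches). A distortion filter — Gaussian pixel noise by default
(sd 0.1), brightness and blur available — is applied to one patch at a
time, always followed by clipping to $[0,1]^d$. Filter strengths are held
constant within a run and validated to be *minimal*: a single application
must move the image L2 norm by less than 5% of the image norm.

Noise draws are a pure function of (filter seed, patch index, application
count), and every application stores the pre-application patch pixels, so
removal is an exact LIFO replay rather than arithmetic inversion: any
matched add/remove sequence restores the original image bit-exactly.

Per-patch sensitivities of the ground-truth probability $P_{GT}$ are
estimated by probing: for each patch $i$,

* $P_{add}(x_i)$ = drop in $P_{GT}$ if one more distortion lands on $i$
  (positive = damaging to the true class);
* $P_{remove}(x_i)$ = rise in $P_{GT}$ if the most recent distortion on a
  currently distorted $i$ is undone.

The sign convention makes "most sensitive" uniformly mean "largest
positive value". $P_{remove}$ is only defined for distorted patches —
removal elsewhere has no meaning. Probing costs exactly
(#patches + #distorted patches) black-box queries; queries are counted per
image evaluated, and batching is only an implementation convenience.

### The episode loop

An action is a pair (add, remove) with $1 \le add \le P_{max}$ and
$0 \le remove < add$ ($P_{max} = 8$ by default), so every step adds at
least one net distortion and the action space has $P_{max}(P_{max}+1)/2 =
36$ elements. The agent picks the add-count patches with the largest
$P_{add}$ and undoes the remove-count distorted patches with the largest
$P_{remove}$ (stable tie-break by patch index; a patch being re-distorted
in the same step is excluded from removal).

Progress is measured by *probability dilution*,

$$PD = \max_{c \ne gt} p_c - p_{gt},$$

the signed margin toward the best alternative class: zero exactly at the
decision boundary, positive exactly on misclassification — which is also
the episode's termination test. The per-step reward is the dilution gained
per unit of L2 distance spent,

$$R_t = \frac{\Delta PD}{\max(|\Delta L_2|, \varepsilon)},$$

with $\varepsilon = 10^{-8}$ and $|R|$ capped at $10^6$ to guard the
degenerate fully-clipped step. An alternative linear reward
$R_t = \alpha \cdot \text{sensitivity} - \beta \cdot \text{FPR}$, evaluated
on a held-out batch, is available as a configuration mode; the ratio form
is the default because both of its terms are per-step quantities.

Action values live in a tabular Q-function over a discretized state — four
binned features: $P_{GT}$, the L2 distance relative to a reference scale,
the step fraction $t/T$, and the top $P_{add}$ magnitude (4 bins each by
default). Updates follow the Bellman rule

$$Q(s,a) \leftarrow Q(s,a) + \eta\,[R_t + \gamma \max_{a'} Q(s',a') - Q(s,a)]$$

with $\gamma = 0.9$, $\eta = 0.1$; terminal transitions (success, or the
step limit $T = 50$) contribute zero future value — treating truncation as
terminal is a deliberate tabular simplification. The Q-table is shared
across the images of a run so the agent can learn across episodes;
$\epsilon$-greedy exploration decays per episode. Greedy selection breaks
ties among maximal Q-values uniformly at random: a fresh all-zero table
would otherwise collapse onto the first enumerated action (add = 1) and
starve the attack of large add-counts.

One design question the construction leaves open is whether the refinement
loop should operate on internal feature maps or on the input image. Only
the image-space variant is fully specified by the patch/L2/clipping
machinery, so that is what this package implements; a feature-space variant
would need its own definition of distortion and distance.

### Cleanup and saliency

A successful episode usually carries distortions that were not needed for
the flip. Cleanup greedily attempts removals — distorted patches in
ascending $P_{remove}$ (least damaging first), keeping a removal only if
the image stays misclassified, repeated to a fixed point. The L2 distance
never increases, and misclassification is re-verified after every kept
removal.

The saliency mask is the per-pixel absolute divergence between the original
and the (cleaned) adversarial image, summed over channels and normalized by
its maximum; it is zero wherever the images agree, so its support is
exactly the surviving distorted patches. Masks export as 8-bit grayscale
PNG heatmaps.

### Metrics

Confusion counts are assembled one-vs-rest; multiclass problems report
per-class and macro-averaged statistics. Two printed-formula corrections
are worth documenting: an F-measure with the *product* of recall and
precision in the denominator is degenerate (it always equals 2), so the
standard harmonic mean is used; and G-means is conventionally the
*geometric mean* $\sqrt{\text{recall} \times \text{specificity}}$, with
the bare product available behind `g_means_as_printed = TRUE`. Ratios with
zero denominators are reported as missing (`NA`), never as 0.

## The synthetic fixture

Real cytology datasets are distributed as class-per-folder trees of
single-cell crops, which the loader reads directly (labels from
lexicographic folder order, pixels rescaled to `[0,1]`, nothing else — no
resizing or normalization statistics are assumed). For controlled
experiments, however, saliency must be scored against *known* ground truth,
so the package generates its own: 16x16 grayscale cells on a mid-gray
background (level 0.5, texture noise sd 0.02) with a disk-shaped "nucleus"
whose pixel set is recorded as the discriminative region. The two default
classes differ only in staining density — one hypochromatic (blob darker
than background), one hyperchromatic (brighter), with matched radius
distributions (mean 2.0 px, sd 0.3, center jitter ±2 px), so the blob
intensity is the sole discriminative feature.

This choice is deliberate on three counts. First, chromatin density is a
real cytological contrast, and matching the radius distributions prevents
the classifier from keying on blob size. Second, the discriminative
evidence is spatially confined to the recorded disk, which is what makes
localization scoring meaningful. Third, blob levels sit close enough to
the `[0,1]` bounds that *stacked* noise applications erode the blob toward
gray through clipping — the physical mechanism by which the attack can
remove evidence of either class — while a *single* application clips
negligibly, keeping individual distortions minimal.

What the fixture does not emulate: overlapping cells, staining gradients,
multi-scale texture, class imbalance, or any correlation structure between
neighboring cells. Passing tests on the fixture therefore demonstrate the
mechanism — sensitivity-guided perturbation finds and highlights the
discriminative region — not clinical-grade performance on real smears.

## Study conditions for the attack experiments

The attack-effectiveness and localization experiments in the test suite
and the acceptance script run under fixed conditions chosen once. Both
use the default fixture, a training set of 30 images per class, an
independent test set from a different seed, the same attack (Gaussian
noise sd 0.1 on 2x2 patches, $P_{max} = 8$, $T = 50$, ratio reward,
shared Q-table), and the eligibility rule *correctly classified with
$P_{GT} < 0.99$*. The exploration floor is $\epsilon = 0.2$ rather than
the package default 0.05: the ratio reward orders add-counts only weakly,
so sustained exploration keeps large actions in play, where a
greedy-collapsed policy over-commits to single-patch additions.

Two backbones are trained, because the two questions pull the model in
opposite directions:

* **Brittle arm** (attack effectiveness, cleanup): noise augmentation
  sd 0.08, 20 epochs, batch 16, test set 35 images per class. Mild
  augmentation leaves the model attackable from many directions, the
  regime in which the success-rate question ("can the agent reliably
  reach misclassification within $T$ steps?") is informative.
* **Robustified arm** (mask localization): noise augmentation sd 0.18,
  30 fixed epochs (early stopping disabled so every initialization
  trains to the same schedule), eligible pool drawn from 150 images per
  class. Strong augmentation trains away the background-texture attack
  surface — a ReLU network otherwise rectifies zero-mean noise anywhere
  into class evidence — so the perturbations that survive cleanup
  concentrate on the discriminative region. Success rates are lower in
  this arm (the point of robustness); the larger pool keeps the number
  of successful episodes high enough for stable statistics.

Localization is scored as *enrichment*: the fraction of mask mass inside
the true region divided by the region's area fraction (1 = uniform,
i.e. chance level). The sensitivity-guided arm uses the pipeline's
post-cleanup masks; the control arm replaces sensitivity ranking with
uniform-random patch choice and skips probing entirely (it would ignore
the probes anyway), with masks taken from all episodes at termination.
One caveat the fixture makes visible: because the blob sits near the
pixel bounds, clipping can shrink per-application mask mass on blob
pixels relative to the mid-gray background, which nudges the
random-ablation enrichment slightly below the ideal chance level of 1.
This is a property of bounded-range images, not of the selection policy
under test; the blob offsets were chosen mild enough to keep the effect
small.

Problem sizes (16x16 images, 50-step cap, tens to a few hundred attacked
images per arm) were chosen so the full suite completes in minutes on a
single core while leaving enough episodes for stable stochastic checks.

## Numerical choices and degenerate inputs

* Probabilities are clamped at $10^{-12}$ before logarithms.
* The softmax subtracts the column maximum before exponentiation.
* Batch-norm uses eps $10^{-5}$ and momentum 0.9 on running statistics;
  inference always uses running statistics.
* The classifier head is zero-initialized, so an untrained model returns
  the uniform distribution — and sensitivity probes of it are exactly zero,
  which the probing code treats as valid (not an error).
* An image already misclassified at episode start returns success with an
  empty trajectory; $T = 0$ on a correctly classified image returns
  failure with zero steps.
* An all-zero saliency mask has no evidence to localize; its enrichment is
  defined as 0.
* "Net distorted patches increase each step" is enforced on the total
  number of outstanding distortion applications (the per-patch counter
  sum), which grows by exactly add − remove ≥ 1; the count of *distinct*
  distorted patches can fluctuate when a removal un-distorts a
  single-application patch while an addition stacks on an already
  distorted one.

## Known limitations

* Tabular Q-learning over a coarse 4-feature discretization cannot
  represent image-specific structure; it learns a coarse policy over
  attack phases, not per-patch values (patch choice is delegated to the
  sensitivity ranking).
* The black-box query budget grows linearly with the patch count, which is
  why the desk-scale default keeps 64 patches; at the reference 12,544
  patches a probing pass costs 12,544 queries.
* The linear sensitivity/FPR reward mode is implemented and tested at the
  unit level but is not the default; it requires a labeled held-out batch
  at attack time.
* Attention placement (one sigmoid gate per channel after the final stage)
  is one of several defensible choices; the gate's weight vector sees the
  flattened spatial map of its own channel only.
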