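---
title: "Uncertainty-gated ensembles of uni-modal and multi-modal classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-gated ensembles of uni-modal and multi-modal classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-modal classifiers that combine a cheap modality (here: a tabular vector
of 138 per-region brain volumes from segmented T1 MRI) with an expensive one
(paired left/right lateral surface-projection images of an FDG PET scan)
usually assume both modalities are always available. Clinical practice works
the other way round: the expensive scan is ordered only when the cheap one is
inconclusive. `modalgate` implements that workflow as a *selective referral
cascade*: a uni-modal model `f` predicts from the tabular features alone and
reports a per-subject uncertainty; a threshold function decides, per subject,
whether the prediction stands or the second modality is fetched and a
late-fusion multi-modal model `h` is invoked. The quantities of interest are
the accuracy of the gated ensemble and the *cost reduction* — the fraction of
subjects for whom the expensive modality was never requested.

## Uncertainty models

**Evidential head.** The final layer's activations pass through a ReLU and
are read as non-negative per-class evidence $e_k$. Evidence induces a
Dirichlet distribution with parameters $\alpha_k = e_k + 1$, total strength
$S = \sum_k \alpha_k$, belief masses $b_k = e_k / S$ and an uncertainty
(vacuity) mass $u = K/S$, so that $u + \sum_k b_k = 1$ and zero total
evidence means total uncertainty, $u = 1$. Training minimises the Dirichlet
expectation of the squared error, in closed form

$$\mathcal{L}(\alpha, y) \;=\; \sum_j \Big[ (y_j - \alpha_j/S)^2 +
\frac{(\alpha_j/S)(1-\alpha_j/S)}{S+1} \Big],$$

which `edl_sos_loss()` implements and the test suite verifies against a
Monte-Carlo Dirichlet oracle. Some of the evidential literature adds an
annealed KL regulariser toward the uniform Dirichlet; we expose it as
`kl_weight` but keep it **off** by default, in fidelity to the plain
sum-of-squares form. A consequence worth knowing (see *Limitations*): without
the KL term, the loss on genuinely conflicting data actually *prefers* high
symmetric evidence — for $\alpha = (a, a)$ and balanced labels the expected
loss is $1/2 + 1/(2(2a+1))$, decreasing in $a$ — so vacuity is a weak
detector of aleatoric ambiguity on its own.

**Monte-Carlo dropout.** The cross-entropy models keep their dropout layers
active at inference; `mc_predict()` runs `passes` stochastic forward passes
(100 by default) and reports, per subject, the population standard deviation
of the positive-class probability across passes. The loss description leaves
the exact scalar statistic open; for the binary task the class-1 SD is
symmetric and well defined, and for $K > 2$ we average per-class SDs.
`normalize_uncertainties()` divides by the largest estimate in the set being
processed, recording the reference maximum.

## Gating

`simple_gate()` refers a subject exactly when its (normalized) uncertainty
exceeds a threshold $\tau$; ties stay uni-modal — the cheaper path wins. The
distance rule compares penultimate-layer embeddings: centroids of the
lowest- and highest-uncertainty training instances are built by
`build_centroids()` (bottom/top `cutoff_fraction`, ties broken by stable
input order), and a test embedding stays uni-modal when it is at least as
close (cosine) to the low-uncertainty centroid. The published comparison
writes this rule with a *similarity* $d$ on the `<=` branch selecting the
uni-modal model, which matches the stated intent only if $d$ is a distance;
we default to the distance reading and expose the literal one via
`orientation = "similarity"`. The cutoff fraction is found empirically by
`calibrate_cutoff()` (candidates 0.1–0.5 by default; ties go to the lower
referral fraction).

`ensemble_predict()` enforces exact cost accounting: the second modality is
fetched lazily, once per referred subject, and the fetch count is recorded on
the returned decision table.

## Models and training

The tabular branch is an MLP, 138 → 256 → 128 → 64 (the 64-wide penultimate
layer is the embedding $g(x)$), with ReLU activations and **two dropout
layers at rate 0.40** after the hidden layers. The image branch stacks the
paired images as one 6-channel input and applies a strided stem convolution,
residual blocks (8 → 16 → 32 channels), global average pooling and a dense
projection to a 64-wide embedding; the multi-modal model concatenates both
embeddings (late fusion) and both models share one tabular-branch
definition, asserted structurally in the tests. Optimisation is Adam at an
initial learning rate of 1e-3 with exponential decay (0.96 per epoch) plus
decoupled weight decay (0.2, i.e. an effective per-step shrinkage of
`lr * 0.2`). The weight decay is the package's own regularization default:
it keeps weight norms, and hence logits on corrupted inputs, temperate —
without it the MC-dropout uncertainty saturates (probabilities peg at 0/1
under every dropout mask) once many regions are masked, and the mean
uncertainty stops growing with the perturbation level. Exact widths, depths
and the decay schedule are package defaults chosen for single-CPU cohorts;
everything is configurable through `train_config()`.

All training is seeded and bit-reproducible on one machine; the engine
(dense, im2col convolutions, residual blocks, inverted dropout, Adam) is
implemented in-package in plain R and its analytic gradients are checked
against numerical differentiation in the test suite.

### Feature encoding and missing data

Region volumes are positive and right-skewed with multiplicative class
effects, so the tabular branch consumes `log1p`-transformed volumes. The
scaling and the treatment of exact-zero volumes — which are physically
implausible and mark an *absent measurement*, not a tiny structure — are
resolved per head, because the two uncertainty semantics make different
demands:

* **Evidential models** z-score and **mean-impute** zeros. The evidential
  head's vacuity point is the input origin (small activations → small
  evidence), and the origin of a centred encoding is the feature baseline.
  Absence therefore maps to "no deviation from baseline": as more regions
  are blanked the input shrinks toward the origin and the Dirichlet
  strength falls monotonically — absence of input yields absence of
  evidence, which is the head's defining semantic.
* **Cross-entropy / MC models** min-max scale and pass the scaled zero
  through **as is**. Mean imputation would hide missingness from the model;
  MC-dropout uncertainty responds to prediction *instability*, which grows
  when the input is visibly out of the training support. Min-max scaling
  keeps that excursion bounded (a masked region lands a few range-widths
  below support rather than tens of standard deviations).

Both policies are explicit `train_config()` options (`scaling`, `missing`)
with `"auto"` defaults resolved by loss.

## Synthetic cohorts

`generate_cohort()` emulates the *statistical shape* of a volumetric-MRI +
surface-projection cohort: 408
subjects by default (180 train, remainder test), 138 log-normal region
volumes, paired left/right images, balanced binary labels. Class effects are
split across modalities: 10 "atrophy-like" regions are decreased and 4
"ventricle-like" regions increased in the disease class by a standardized
log-scale shift of `delta_t` (default 1.5); each image carries one circular
patch whose red-channel mean shifts by `delta_i` noise SDs between classes.
A configurable `ambiguous_fraction` (default 0.3) of subjects draws its
tabular vector from the class-independent baseline, so for them only the
images separate the classes — the structure the gate must exploit, giving
the uni-modal model an irreducible error floor of about `q/2`. Pixels are
quantized to 8 bits so cohorts round-trip their PNG/CSV on-disk form
bit-exactly, and generation is bit-reproducible under a fixed seed.

The generator makes no attempt at anatomical realism: no spatial covariance
between regions, no MRI physics, no real surface-projection geometry, no
age/sex structure. Passing tests on these cohorts demonstrates that the
machinery behaves as designed under its own assumptions — recoverable
effects, honest uncertainty trends, exact cost accounting — not that the
method reaches any particular accuracy on clinical data.

## Evaluation protocol

`sweep_thresholds()` traces the accuracy/cost frontier over a threshold grid
(default 0.1–0.9 in steps of 0.1, matching how such frontiers are usually
displayed; the grid is free configuration and the test suite uses a
0.01-step grid where it searches for an optimal operating point, since the
threshold search is the method's own calibration step). Each point records
accuracy, referral fraction and cost reduction (their sum is exactly 1), and
the curve carries the pure uni-modal and multi-modal accuracies as
endpoints; a threshold of 1 reproduces the pure uni-modal accuracy exactly
and, because the Dirichlet uncertainty mass is strictly positive, a
threshold of 0 reproduces the pure multi-modal accuracy exactly.

`ood_report()` probes uncertainty robustness: per perturbation level every
test instance is perturbed once (zero-masking `k` regions drawn once per
level; for multi-modal models also clockwise bilinear rotation of both
images, origin top-left, zero fill, with 0 degrees a bit-exact bypass) and
the in-distribution and out-of-distribution uncertainty distributions and
their means are recorded, instance-paired.

The test suite exercises the full protocol at desk scale: 400-subject
cohorts (180/220 split) over five fixed seeds, 60-epoch tabular models,
30-epoch multi-modal models, 100 Monte-Carlo passes — sizes chosen so the
whole suite trains some twenty networks in a few minutes on one CPU while
keeping every qualitative behaviour measurable.

## Explaining referrals

`label_referrals()` turns gate decisions into a binary referral target;
`train_referral_classifier()` fits a 500-tree random forest on a seeded
subsample of 20 instances per category (`mtry` defaults to a third of the
features so that sparse referral signals remain discoverable from such a
small subsample) and evaluates on the held-out remainder with a
deterministic majority vote (the underlying forest breaks vote ties at
random, which would make permutation importances noisy at exactly zero).
`feature_attribution()` ranks regions by permutation importance — the mean
held-out accuracy drop over seeded column permutations — with a direction
from the rank correlation between the feature and the forest's referral
probability. Shapley-value explanation is deliberately out of scope; any
external implementation can be plugged in through the `explainer` hook
without changing the protocol around it.

## Numerical choices

* Ties: `u = tau` stays uni-modal; equal centroid similarities stay
  uni-modal; equal uncertainties are ordered by stable input position.
* All model arithmetic is double precision; `alpha >= 1` holds by
  construction (`S >= K`), and the multinomial beta normaliser is never
  materialised — the loss uses the analytic expectation.
* `rotate_image(x, 0)` returns its input bit-exactly; a full 360-degree turn
  is identity up to bilinear interpolation error (at most 2/255 per pixel).
* Random-forest class predictions use probability argmax with first-wins
  ties for determinism.

## Limitations

* Plain sum-of-squares evidential vacuity under-detects aleatoric
  ambiguity (see the derivation above). On the synthetic cohorts the
  ambiguous subpopulation still shows a higher mean uncertainty because the
  centred encoding places baseline-only subjects near the origin, but the
  separation is modest; the MC-dropout estimate, which measures
  decision-boundary instability, separates that subpopulation much more
  sharply and is the better gate signal for the cost/accuracy operating
  point.
* MC-dropout uncertainty is not monotone in perturbation strength in every
  trained model: once inputs are extreme enough, probabilities saturate
  under every dropout mask and the spread collapses. The default weight
  decay mitigates but does not abolish this.
* Uni-modal and multi-modal, evidential and cross-entropy models are
  separate networks; their uncertainty scales are not comparable across
  models, and the package deliberately provides no cross-model uncertainty
  comparison.
* Synthetic cohorts validate mechanism, not clinical performance.
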