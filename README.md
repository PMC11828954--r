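# modalgate

Cost-aware binary disease classification from paired modalities, for
researchers studying selective multi-modal inference. The setting: a cheap
tabular modality (138 per-region brain volumes from segmented T1 MRI) is
always available, while the informative-but-expensive second modality
(paired left/right lateral surface projections of an FDG PET scan) carries
cost and radiation exposure. `modalgate` trains a uni-modal classifier whose
per-subject predictive uncertainty decides — instance by instance — whether
the second modality is requested and a late-fusion multi-modal classifier is
invoked, then quantifies the resulting accuracy/cost frontier, the
robustness of the uncertainty estimates on perturbed inputs, and the
volumetric reasons behind referral decisions.

## The model

A uni-modal MLP *f* consumes the volume vector *x₁*; a multi-modal network
*h* fuses the tabular embedding with a residual-CNN embedding of the paired
images *x₂*. Two uncertainty estimators are provided:

* **Evidential head** — the final activations pass through a ReLU and are
  read as per-class evidence *eₖ* ≥ 0, inducing a Dirichlet distribution
  with parameters *αₖ = eₖ + 1*, strength *S = Σ αₖ*, belief masses
  *bₖ = eₖ/S* and uncertainty mass *u = K/S* (so *u + Σ bₖ = 1*, and zero
  evidence means *u = 1*). Training minimises the closed-form Dirichlet
  expectation of the squared error,
  *Σⱼ (yⱼ − αⱼ/S)² + (αⱼ/S)(1 − αⱼ/S)/(S+1)*.
* **Monte-Carlo dropout** — dropout stays active at inference; the
  population standard deviation of the positive-class probability across
  repeated passes (100 by default), max-normalized per evaluation set, is
  the uncertainty.

The threshold function either compares the uncertainty to a scalar τ
(refer when *u > τ*) or compares cosine similarities of the penultimate
embedding *g(x)* to centroids of the lowest- and highest-uncertainty
training instances. The headline metrics are ensemble accuracy and **cost
reduction** — the fraction of subjects classified without the second
modality.

Real volumetric/PET cohorts are controlled-access; the package ships a
seeded generator of synthetic cohorts that emulate the data's statistical
shape, including a configurable subpopulation whose class signal exists
only in the images (the case referral is for).

## Worked example

```r
library(modalgate)
library(dplyr)

opinion_from_evidence(c(9, 0))
#> <dirichlet_opinion> K = 2
#>   evidence:    9, 0
#>   belief:      0.8182, 0
#>   uncertainty: 0.1818

cohort <- generate_cohort(synth_config(n_subjects = 200, n_train = 100, seed = 7))
train <- filter(cohort, split == "train")
test  <- filter(cohort, split == "test")

f <- train_unimodal(train, train_config("edl_sos", epochs = 40, seed = 7))
h <- train_multimodal(train, train_config("edl_sos", epochs = 20, seed = 7))

predict(f, test[1:3, ], type = "opinion")
#> # A tibble: 3 × 5
#>   .pred_cn .pred_ad .pred_class .uncertainty .strength
#>      <dbl>    <dbl> <fct>              <dbl>     <dbl>
#> 1    0.193    0.807 ad                 0.286      7.00
#> 2    0.134    0.866 ad                 0.269      7.45
#> 3    0.643    0.357 cn                 0.266      7.52

decisions <- ensemble_predict(test, f, h,
                              gate_policy("simple", tau = 0.3, uncertainty = "edl"))
mean(decisions$predicted_label == decisions$label)  # ensemble accuracy
#> [1] 0.91
cost_reduction(decisions)
#> [1] 0.55
attr(decisions, "n_x2_fetches")                     # images actually fetched
#> [1] 45

sweep_thresholds(test, f, h, uncertainty = "edl")
#> <cost_accuracy_curve> edl uncertainty | pure uni 0.780 | pure multi 0.980
#> # A tibble: 9 × 4
#>   threshold accuracy referral_fraction cost_reduction
#>       <dbl>    <dbl>             <dbl>          <dbl>
#> 1       0.1     0.98              1            0
#> 2       0.2     0.98              0.99         0.0100
#> 3       0.3     0.91              0.45         0.55
#> 4       0.4     0.84              0.12         0.88
#> ...
```

Read the curve row-wise: at τ = 0.3 the gated ensemble classifies 91% of
test subjects correctly while avoiding 55% of the expensive scans — against
a pure uni-modal accuracy of 0.78 (every scan avoided) and a pure
multi-modal accuracy of 0.98 (every scan taken). `autoplot()` methods
render the frontier, the out-of-distribution uncertainty histograms
(`ood_report()`) and the referral attribution ranking
(`feature_attribution()`); `run_pipeline()` (or the thin CLI in
`inst/cli/modalgate.R`) runs the whole workflow from a YAML config and
serializes every artifact.

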