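---
title: "Quantitative posterior-circulation stroke scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative posterior-circulation stroke scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcscale)
```

## The problem

Posterior circulation ischemic stroke (infarction in the vertebrobasilar
territory: brainstem, cerebellum, thalami, occipital lobes) carries high
mortality and disability, and its early prognosis must usually be judged
from noncontrast CT because MRI is hard to obtain acutely. The established
noncontrast-CT instrument is the semiquantitative pc-ASPECTS: 10 points,
with 1 point deducted per involved thalamus, cerebellum or PCA territory
(each side separately) and 2 points each for midbrain and pons involvement.
Being binary per territory, it ignores how much of a structure is infarcted.

`pcscale` implements the quantitative alternative: from a voxel atlas of
the nine posterior-circulation structures and a binary ischemic lesion
mask, it measures the *proportion* of each structure that is lesioned and
combines these ten numbers into an integrated risk score whose weights are
learned by cross-validated logistic regression against the dichotomized
modified Rankin Scale (mRS 0-2 good, 3-6 poor). Everything downstream of
the masks — volumetrics, features, both scores, ROC/AUC/DeLong evaluation —
is deterministic, testable code; a synthetic phantom and cohort generator
stands in for clinical data.

## The ten lesion-proportion features

For structures $i = 1..9$ (label order: left/right cerebellum, left/right
occipital lobe, left/right thalamus, medulla, midbrain, pons),

$$ f_i = \frac{\mathrm{vol}(\text{lesion} \cap \text{structure}_i)}
               {\mathrm{vol}(\text{structure}_i)} \in [0, 1]. $$

The tenth feature summarizes ischemia outside all nine structures. Its
denominator is a genuine design choice, since "proportion of lesions in
other regions" admits two readings. The default keeps all ten features on
the same fraction-of-region-lesioned scale:

$$ f_{10} = \frac{\mathrm{vol}(\text{lesion outside structures})}
                 {\mathrm{vol}(\text{brain} \setminus \text{structures})}, $$

with the alternative (fraction of total lesion volume lying outside the
structures) available via `lesion_features(..., other = "lesion")`.
Features are ratios and therefore independent of voxel spacing; volumes
(`structure_volumes()`) are voxel counts times voxel volume, in mL. A
structure with zero voxels yields feature 0 with a warning rather than
NaN, which keeps downstream fitting total.

## The integrated score

The model family behind the published "model parameter weights" is not
further specified, so this package commits to the simplest weighted-sum
model consistent with ROC evaluation: ridge-penalized logistic regression
of poor prognosis on the ten features, fitted by Newton/IRLS with step
halving. The integrated score of a visit is the linear predictor
$b + w \cdot x$, oriented so that higher means higher risk. Two numerical
choices matter:

* the intercept is never penalized, and
* the default penalty is $\lambda = 10^{-4} n$. Scaling with $n$ makes the
  fit invariant under dataset duplication and guards the separable
  small-sample case (the clinical setting has only 36 visits); at
  $n = 2000$ the induced shrinkage is negligible (verified against
  `glm()` at $\lambda \to 0$ in the tests).

Whether the published score included an intercept is also unstated; the
intercept is retained here because it only shifts the score and cannot
change any rank-based (ROC) conclusion.

Out-of-fold scores follow the published protocol: visits are partitioned
into $k = 5$ subsets (sizes differing by at most one), each subset is
scored by the model fitted on the other four, and every visit is scored
exactly once by a model that never saw it. Partitioning is by visit, as in
the source protocol; since patients can recur across visits, a strict
patient-level split is the leakage-safe alternative and can be had by
passing your own `subset` column.

## The automated pc-ASPECTS

`pc_aspects()` applies the deduction table directly to masks: a territory
is involved when the lesion volume inside it exceeds a threshold, default
0 mL (any overlap), configurable to suppress single-voxel noise. The PCA
territory is operationalized as the occipital-lobe labels, and the medulla
is annotated but carries weight 0 — that reconciles the nine annotated
structures with the eight scored locations while keeping the weights
summing to 10. The score is monotone non-increasing under lesion growth,
and an exhaustive enumeration of all $2^8$ involvement patterns against a
direct weight-sum oracle is part of the test suite. For ROC comparisons
the pc-ASPECTS is negated so that both predictors are risk-oriented.

## Evaluation statistics

* `auc()` uses the Mann-Whitney formulation with ties counted 1/2 —
  identical to the trapezoidal area under the empirical ROC curve. Tie
  handling is consequential for the integer-valued pc-ASPECTS and is
  stated in the pipeline report.
* `operating_point()` maximizes Youden's $J = \text{sens} + \text{spec} - 1$
  (the cutoff rule behind published sensitivity/specificity pairs is
  rarely stated; Youden is the standard default). Ties resolve toward
  higher sensitivity, then the lower threshold.
* `delong_test()` implements the placement-value (structural component)
  estimate of $\mathrm{var}(\widehat{AUC}_A - \widehat{AUC}_B)$ for two
  scores on the same cases, with a two-sided normal p value. It is checked
  in the tests against `pROC::roc.test()` and against a 10,000-replicate
  paired bootstrap.
* `chi2_2x2()` is the uncorrected Pearson chi-square. On the worked
  gender-by-prognosis table (13/5 vs 7/11 of 18 and 18) it gives
  p = 0.044; the continuity-corrected version gives 0.094, so the
  uncorrected test is the one consistent with the published comparison.
* `two_sample_summary()` (group mean ± SD plus Welch's t) is a reporting
  tool for synthetic cohorts. It deliberately does not claim to reproduce
  published continuous-variable p values: those are not recoverable from
  printed summaries and the underlying test family is unstated.

## The synthetic phantom

`build_atlas()` voxelizes nine disjoint ellipsoids at plausible
posterior-fossa positions: mirrored cerebella, occipital lobes and thalami
about the midsagittal plane, and the midline brainstem stack
(medulla-pons-midbrain), inside an ellipsoidal brain envelope. The layout
is specified in fractions of the grid's physical extent, so the same
topology voxelizes onto any sufficiently fine grid; the default is
40 x 256 x 256 voxels at 5 x 0.5 x 0.5 mm (slice, row, col) — routine
head-CT geometry, since the source data fix only the 512 x 512 in-plane
matrix. Only the topology (nine disjoint regions, left/right symmetry, a
midline brainstem) matters downstream: the scoring mathematics is
geometry-agnostic, and no anatomical fidelity is claimed.

Lesions (`place_lesion()`) are grown by seeded region growing restricted
to the target region: 6-connectivity, wave-by-wave random acceptance and
random within-wave order. The full growth ordering is a deterministic
function of (region, seed), and a requested fraction takes a prefix of it,
so achieved fractions are exact up to voxel quantization and are nested —
monotone in the requested fraction — for a fixed seed.

`render_ct()` assigns each tissue class its mean HU (air -1000,
parenchyma 35, lesion hypodense by 20 HU) plus Gaussian noise (default
SD 2). Each structure receives a distinct stylized mean (38 + 4·label).
Real noncontrast CT offers no such per-structure contrast — the deep
segmentation problem on clinical data is much harder — so passing
segmentation tests here demonstrates that the training/evaluation
machinery is correct, not that the small network would segment real CT.

## The synthetic cohort

`simulate_cohort()` draws per-visit features and outcomes from a stated
logistic model: each of the ten regions is involved independently with
probability 0.5, involved fractions are uniform on (0, 1), and poor
prognosis is Bernoulli with
$\Pr(\text{poor}) = \mathrm{logit}^{-1}(\beta_0 + \beta \cdot x)$, default
$\beta = (1.5, 1.5, 0.75, 0.75, 2.25, 2.25, 4.5, 6, 6, 3)$ (heaviest on
midbrain/pons, then medulla and thalami) and $\beta_0 = -7.1$, which
centers the cohort near a 50/50 good/poor split, mirroring the 18/18
split of the clinical registry.

This burden model is deliberately heavier and more dispersed than a
clinical registry, where most visits involve one or two territories at
small fractions. The choice is a power consideration made at design time:
with sparse, small fractions the per-coordinate standard errors of a
logistic fit at $n = 2000$ (about 0.25-0.35) would be comparable to the
±15% -of-$\|\beta\|_\infty$ band used by the weight-recovery diagnostic,
making recovery a coin flip rather than a test of correctness. With the
default generator the recovery check passes with large margin (about 98%
of random seeds in a 200-replicate design study). The mRS value is drawn
uniformly within the stratum implied by the prognosis, and subsets are a
seeded random partition with sizes differing by at most one.

When `masks = TRUE`, sampled fractions are realized as voxel lesions and
the recorded features are re-measured from the masks, so records and masks
agree exactly.

## The desk-scale segmentation trainer

The training protocol mirrors the published recipe: Adam, minibatches of
4, initial learning rate 0.001 decayed by a factor of 10 on tuning-set
plateaus, L2 weight decay $10^{-4}$, random crop (480 from 512, scaled
proportionally for smaller grids) or random scaling (±10%), and early
stopping by checkpointing — the parameters saved after every epoch, and
the checkpoint with the lowest tuning loss returned. "Plateau" is
operationalized as no tuning-loss improvement greater than $10^{-4}$ for
`patience` epochs (the published wording fixes only the factor).

The network itself is deliberately small — a symmetric encoder-decoder of
roughly 7k-20k parameters (two conv/ReLU/maxpool stages, a bottleneck
conv, nearest-neighbor upsampling decoder, per-pixel 10-way softmax) — in
place of a pretrained ResNet-18 encoder with a SegNet decoder: pretrained
transfer learning is out of scope without the original weights and
patient data, and a desk-scale model keeps the full 5-fold protocol
runnable on one CPU in minutes. Three architectural choices matter at
this scale, where the whole optimization budget is on the order of a
thousand steps:

* an input standardization layer, $(x - 0.5) \cdot g$ with gain $g$
  (default 10): windowed CT intensities span a narrow band of
  $[0, 1]$, and without the gain the classifier weights needed to
  separate classes are not reachable within the step budget;
* a full-resolution skip connection from the first encoder block into the
  classifier, which restores boundary detail lost through the
  pool/upsample path;
* coordinate channels (normalized row/col in $[-1, 1]$, the CoordConv
  construction): left/right paired structures are indistinguishable to a
  purely translation-equivariant network, and brain anatomy is spatially
  stereotyped, so coordinate features are principled here.

The loss is per-pixel cross-entropy with softened (square-root)
median-frequency class balancing: plain median-frequency weights let the
network grow false-positive halos into the dominant background class, and
unweighted cross-entropy never learns the smallest structures within the
budget.

`evaluate_folds()` runs the k-fold protocol over cases (one case = one
visit's slice stack): per fold, one training case is held out for tuning,
the fold's cases are predicted by a model that never saw them, and the
report is the 9 x (k+1) per-structure IoU table (per-case IoU pooled over
the case's slices, averaged over the fold's cases — the volumetric
reading; per-slice pooling is the undocumented alternative). IoU of two
empty masks is defined as 1 with a warning.

## Problem sizes and diagnostics

The test-suite experiments were sized so the entire suite runs on one CPU
in well under half an hour: cohort diagnostics at $n = 2000$ (weight
recovery within ±15% of $\|\beta\|_\infty$; out-of-fold AUC within ±0.03
of the generative AUC; permuted labels giving AUC in [0.45, 0.55]); AUC
against a brute-force pair-counting oracle on 1000 random tied score
vectors at $10^{-12}$; DeLong against a 10,000-replicate paired bootstrap
on 200 cases within ±0.02 in p; the lesion-volume partition identity on
100 random phantoms; and a deliberate-overfit segmentation run — ten
96 x 96 slices, tuning set equal to the training set, batch size 2,
no augmentation, input gain 20, at most 150 epochs — reaching mean
foreground IoU at least 0.90. The published clinical endpoints (per-
structure IoU around 0.63-0.83 on patient CT; AUC 0.74 vs 0.63 with
DeLong p = 0.035) require the original registry images and trained
weights, and are out of reach of any synthetic surrogate by construction;
this package reproduces the protocols, not those numbers.

## Known limitations

* The phantom is topological, not anatomical; its per-structure CT
  contrast is fictional, and its lesions are single connected components
  per region rather than scattered emboli.
* The synthetic cohort's lesion burden is a stress design (see above);
  absolute AUC values on it say nothing about clinical performance.
* The integrated score's model family (ridge logistic) is one defensible
  reading of "model parameter weights"; fold-averaged weights or another
  classifier would be alternatives.
* The segmentation trainer is CPU-bound and desk-scale by design; it does
  not attempt lesion segmentation (lesions are physician-annotated in the
  source setting and synthetic here).
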