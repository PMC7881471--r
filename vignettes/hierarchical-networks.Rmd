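---
title: "Hierarchical anatomical brain networks: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical anatomical brain networks: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hiernet)
```

## The problem

Single-resolution morphometric analyses — one number per brain region, or one
network at one parcellation scale — can miss group differences that express
themselves either very locally (one region's tissue volume) or only in the
coordination between regions (how similar two regions' cortical architecture
is). `hiernet` implements a multi-resolution alternative: the same cortex is
parceled at four granularities, a similarity network is built per subject at
each granularity, and regional and network features are fused in one
classifier. The package targets two-group designs (here labelled
high/low self-esteem, the positive class being `"high"`), with roughly
30–40 subjects per group and five morphometric measures per region: GM, WM
and CSF volume, mean cortical thickness (plus its within-region SD, used by
the network model), and cortical surface area.

## The hierarchy

The bottom layer is the 78-region cortical subset of the AAL parcellation
(the 12 subcortical regions removed, regions renumbered 1–78, odd = left,
even = right). Regions merge into 36 anatomical surfaces (layer 3), 14 lobar
territories (layer 2) and the whole brain (layer 1). The mapping ships as a
flat TSV (`inst/extdata/aal78_hierarchy.tsv`), one row per bottom-layer
region, so it can be audited column by column; `load_atlas()` validates
surjectivity, contiguous indexing and that the layer-4→2 map factors through
layer 3. One quirk of the source table is preserved deliberately: the index
pair 17/18 is listed there under a single left-hemisphere label; we encode it
as a left/right pair ("Rolandic operculum"), consistent with every other
homologous pair.

Layer 1 is a modelling convention rather than a network: a 1-region layer
has no edges, so it contributes zero features. The concatenated network
feature vector over layers 4, 3, 2, 1 therefore has
3003 + 630 + 91 + 0 = 3724 entries, and the regional block has
78 × 5 = 390.

## The similarity kernel

For two regions with mean thickness $t_i, t_j$ and within-region thickness
SDs $\sigma_i, \sigma_j$, the edge weight is

$$C(i,j) = \exp\!\left\{-\frac{(t_i - t_j)^2}{2(\sigma_i^2 + \sigma_j^2)}\right\},$$

a Gaussian similarity in $(0, 1]$: 1 for identical thickness, decaying with
the squared difference measured in units of the pooled dispersion. It depends
only on differences, so a uniform thickness shift leaves every network
unchanged. (Some of the literature labels this quantity a "correlation
coefficient"; it is a kernel, and the package calls it that.) Coarser-layer
regions inherit $t$ and $\sigma$ as unweighted means over their constituent
bottom-layer regions — the printed aggregation rule of the source method; a
pooled-variance alternative (`sigma_method = "pooled"`) is available because
averaging SDs rather than variances is statistically unusual, but the default
follows the stated rule. If both SDs are zero the edge is degenerate; we
return 1 when the thicknesses agree and raise an error otherwise rather than
guess a value.

Normalization divides volumes by total intracranial volume, thickness by the
subject's global mean thickness, and area by total surface area. The
within-region thickness SD is divided by the same global mean thickness as
the mean, so the kernel's dimensionless ratio is unchanged by normalization —
the contract that makes "normalize, then build networks" and "build networks,
then normalize" agree.

## Feature selection

Inside every training fold, each feature block is reduced by a three-stage
cascade:

1. **t-test screen** — two-sample pooled-variance Student t per feature,
   two-sided, kept if $p < 0.05$, no multiple-testing correction (this is a
   screen, not an inference); features with zero pooled within-group
   variance get $p = 1$.
2. **mRMR** — greedy minimum-redundancy maximum-relevance ranking with
   mutual information on features discretized into 3 bins at mean ± 1 SD,
   MID (difference) criterion by default, MIQ behind a switch. Default
   retention 200 (usually everything that survives the screen, reordered).
3. **SVM-RFE** — iterated linear SVM, features scored by squared weight,
   lowest removed (10% per iteration above 50 features, then one at a time),
   down to the retained count.

All ties — in t, in mRMR score, in RFE weight — break by feature-name
lexical order, which makes every trace reproducible bit for bit.

## Classification and the inner loop

Each block's selected features are z-scored on training statistics and turned
into an RBF kernel with $\gamma = 1/p$ ($p$ = number of retained features;
features have unit variance after scaling). The regional and network kernels
are fused as $\beta K_{\mathrm{ROI}} + (1-\beta) K_{\mathrm{net}}$,
$\beta \in [0,1]$, and a C-SVM is trained on the fused kernel
(`kernlab::ksvm` with a precomputed kernel matrix).

Generalization is estimated by repeated stratified twofold cross-validation
(default 100 repetitions; the study-scale experiments in this package use
20): per repetition a random stratified half-split, each half held out once.
Hyperparameters — per-block retained count (grid 5/10/20/50), SVM cost
(1/10) and $\beta$ (0–1 including the endpoints, so a pure-noise kernel can
be discarded) — are chosen per training fold by an inner stratified 5-fold
CV.

One design point deserves emphasis. If the selection cascade is fitted once
on the training half and the inner CV then scores hyperparameters on folds
of that same half, the inner accuracies saturate at 100% (the cascade has
already seen the inner-validation subjects) and the choice degenerates to
grid order. The package therefore makes the inner loop leakage-free: each
inner fold re-fits a light selection surrogate — the top-$k$ features by
absolute t statistic on the inner-training portion, per block — and the
grid is scored on genuinely unseen inner-validation subjects. The full
cascade then runs once per training fold at the chosen retained count. The
surrogate is the cascade's first and dominant stage; re-fitting the full
cascade per inner fold and grid point would multiply the cost by the grid
size for little change in the choice. Remaining accuracy ties break by the
standardized class separation of the pooled validation decision values.

Metrics (accuracy, sensitivity, specificity, rank-statistic AUC, Youden's
index $Y = SEN + SPE - 1$, F-score, balanced accuracy) are computed per
repetition from the pooled held-out predictions — every subject is tested
exactly once per repetition — and summarized as mean ± SD. Decision scores
are oriented so that larger means more positive-class-like; AUC is invariant
under monotone transforms of the scores. Note that some published tables
report Youden/BAC values inconsistent with their own SEN/SPE; this package
computes the standard identities and nothing else.

Selection stability is reported as the number of fold-fits (out of
repetitions × folds) in which each feature survived the cascade;
`frequency_table()` ranks features by that count with lexical tie-breaks.

## The synthetic generator

No public data accompany the method, so the generator is the package's
test-bed. Per subject and region: thickness = global factor × (regional
population mean + subject deviation), with population means N(2.5, 0.25) mm,
within-region SD ≈ 0.30 mm, between-subject regional deviation τ = 0.15 mm;
volumes and areas log-normal around tissue-typical magnitudes (8000/6000/2000
mm³, 2500 mm²) with 30% regional spread, 10% between-subject noise and a 5%
global size factor. Globals (TIV, mean thickness, total area) are summed from
the generated regions, so normalization is internally consistent. These
baselines are plausibility constants chosen once, not estimates from any
dataset.

Planted effects define ground truth:

* a **regional effect** (roi, measure, d) shifts that measure by d
  between-subject SDs in the high group;
* an **edge effect** (roi_i, roi_j, coupling) matches the two regions'
  population mean thickness and draws their subject deviations with
  correlation `coupling` in the high group, independently in the low group.
  The marginals are identical across groups, so the signal lives only in the
  joint distribution — exactly the quantity the similarity kernel measures.
  The mean-matching is part of what "planting an edge" means here: with
  mismatched population means, the fixed thickness gap dominates the kernel
  and coupling barely moves it. At τ = 0.15 mm and within-region SD 0.30 mm,
  coupling 0.95 yields a per-edge standardized effect around 1.1 — the
  strongest this mechanism can produce at realistic variance ratios, and
  deliberately weaker than a d = 2 regional effect.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring regions, site/scanner effects, age/sex covariates, non-Gaussian
tails, or any causal claim about self-esteem. Passing the recovery tests
shows the pipeline finds the statistical structure it assumes; it does not
validate the method on real MRI.

## Study-scale experiments

The packaged experiments (tests and `scripts/acceptance.R`) use 34 + 34
subjects and 20 repetitions of twofold CV — a size chosen so the whole suite
runs on a single CPU in minutes while keeping the per-repetition sampling
error of mean accuracy near one percentage point:

* **Null calibration**: no planted effects; mean accuracy should sit in
  [0.45, 0.55]. Observed ≈ 0.52.
* **Recovery**: 5 regional effects (d = 2, volume/area measures only, so the
  regional and network signals stay orthogonal) + 4 edge couplings (0.95) on
  disjoint pairs; the planted features should dominate the top-15 stability
  tables and accuracy should exceed 0.90. Accuracy varies with the simulated
  cohort draw — 0.89–0.95 across seeds in our runs — so an unlucky cohort
  can land just under that bar; the stability rankings are far more robust
  (4–5 of 5 regional and 3–4 of 4 edge features recovered).
* **Weight sweep**: cohorts with only network signal peak at small β,
  cohorts with only regional signal at large β, reproducing the expected
  shape of the kernel-weight curve.

## Numerical and degenerate-input choices

* Zero-variance features: p = 1 in the screen (never selected); constant
  features land in the middle mRMR bin; zero training SD during
  standardization is replaced by 1 (the feature contributes a constant).
* Stratified folds guarantee both classes in every fold for group sizes ≥
  the fold count; `nested_cv()` refuses cohorts with fewer than 4 subjects
  per group.
* All randomness flows from one seed: per-repetition child seeds are drawn
  once, so results are reproducible and repetitions are independent.
* Positivity of simulated measures is enforced by bounded redraws (20
  attempts) rather than truncation, to avoid biasing the tails; an
  impossible configuration errors out.
* An edge-effect set whose couplings cannot form a positive-definite
  correlation matrix (e.g. one region coupled at 0.95 to two independent
  partners) is rejected with an explicit error.

## Limitations

* The between-layer connections sometimes mentioned alongside hierarchical
  networks are not defined by the within-layer similarity model and are not
  implemented; only in-layer networks exist here.
* Networks are built from cortical thickness only: it is the measure the
  kernel is defined on and the only one with a measured within-region
  dispersion (the kernel's denominator). Substituting another measure would
  require a dispersion model that the input table does not carry, so no such
  switch is offered; the other measures enter as regional features.
* The t-test screen is applied per block, not jointly across blocks; a joint
  screen would couple the two kernels' feature sets.
* With ~3700 network features and 34 training subjects, fold-level selection
  is noisy; stability frequencies, not single-fold subsets, are the unit of
  interpretation.
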