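# hiernet

Hierarchical anatomical brain-network classification from regional
morphometry.

`hiernet` is for researchers who have a per-subject table of regional brain
measures — GM/WM/CSF volume, mean cortical thickness (with its within-region
SD) and surface area for each of 78 cortical AAL regions — and want to ask
whether two groups of subjects differ, where those differences sit, and
whether they live in single regions or in the *coordination between*
regions. It implements a multi-resolution morphometric-similarity framework:

* **Four-layer hierarchy.** The 78 cortical regions (layer 4) merge into 36
  anatomical surfaces (layer 3), 14 lobar territories (layer 2) and the
  whole brain (layer 1), following a fixed, shipped merge table.
* **Similarity networks.** Per subject and per layer, the edge between
  regions *i* and *j* is a Gaussian kernel of their thickness difference,

  `C(i,j) = exp( -(t_i - t_j)^2 / (2 (sigma_i^2 + sigma_j^2)) )`,

  where `t` is mean cortical thickness and `sigma` its within-region SD.
  The strict upper triangles become feature vectors: 3003 + 630 + 91 + 0 =
  3724 network features, next to 78 x 5 = 390 regional features.
* **Selection cascade.** Inside every training fold, each block is reduced
  by a two-sample t-test screen (p < 0.05), minimum-redundancy
  maximum-relevance (mRMR) ranking, and recursive feature elimination with a
  linear SVM (SVM-RFE).
* **Multi-kernel SVM.** Regional and network blocks each get an RBF kernel;
  the classifier trains on the convex fusion
  `beta * K_roi + (1 - beta) * K_net`, with `beta`, the SVM cost and the
  retained feature counts chosen by a leakage-free inner cross-validation.
* **Repeated nested CV.** Stratified twofold outer splits, repeated; metrics
  (ACC, SEN, SPE, AUC, Youden's Y, F, BAC) per repetition, and per-feature
  selection frequencies over all fold-fits as a stability ranking.
* **Synthetic cohorts.** A generator with planted regional effects
  (standardized shifts) and edge effects (thickness-deviation couplings)
  makes the whole pipeline testable without any clinical data.

## Worked example

Simulate a 34 + 34 cohort with three planted regional effects (d = 2) and
two planted edge couplings, then run the full pipeline:

```r
library(hiernet)

cohort <- simulate_cohort(
  sim_config(
    n_per_group = 34,
    roi_effects = data.frame(roi = c(7, 46, 19), measure = c("wm", "gm", "wm"),
                             d = 2),
    edge_effects = data.frame(roi_i = c(15, 27), roi_j = c(55, 63),
                              coupling = 0.95)
  ),
  seed = 7
)

blocks <- assemble_blocks(cohort, blocks = c("roi_L4", "net_all"))
report <- nested_cv(blocks, cv_config(repetitions = 5), seed = 8)
report
#> <cv_report> 5 repetitions x 2 folds; 68 subjects ( low=34, high=34 )
#>   ACC = 0.865 +/- 0.056
#>   SEN = 0.847 +/- 0.087
#>   SPE = 0.882 +/- 0.042
#>   AUC = 0.930 +/- 0.047
#>   Y = 0.729 +/- 0.113
#>   F = 0.861 +/- 0.063
#>   BAC = 0.865 +/- 0.056
```

The classifier separates the groups well above chance (mean accuracy 0.87,
AUC 0.93 over 5 repetitions of twofold CV; sensitivity/specificity are the
recall of the high and low group respectively). The stability tables show
*where* the signal sits — the planted features head both rankings:

```r
frequency_table(report, "roi", top_k = 5)
#>    rank feature    frequency roi_i_name               roi_i_hemi measure
#> 1     1 roi07_wm          10 Middle frontal gyrus     L          WM volume
#> 2     2 roi46_gm           9 Superior occipital gyrus R          GM volume
#> 3     3 roi19_wm           8 Supplementary motor area L          WM volume
#> 4     4 roi50_area         3 Inferior occipital gyrus R          Area
#> 5     5 roi19_csf          2 Supplementary motor area L          CSF volume

frequency_table(report, "net", top_k = 3)
#>    rank feature   frequency roi_i_name                      roi_j_name
#> 1     1 L4_e15_55         8 Orbitofrontal cortex (inferior) Superior parietal gyrus
#> 2     2 L4_e27_63         4 Rectus gyrus                    Precuneus
#> 3     3 L3_e02_10         3 Central region: precentral ...  Frontal lobe: medial ...
```

`frequency` counts the fold-fits (of repetitions x 2 = 10 here) in which a
feature survived the whole selection cascade: the planted regional features
were selected in 8–10 of 10 fits, the planted edges lead the network table.
`tidy(report)` gives per-repetition metrics, `glance(report)` a one-row
summary, `autoplot(report)` / `autoplot(weight_sweep(...))` the standard
plots, and `write_cohort()` / `read_cohort()` round-trip cohorts through a
two-file CSV interface.

A thin command-line wrapper is included for scripted runs:

```sh
Rscript inst/cli/hiernet.R simulate,train,report --config run.yaml --seed 7
```

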