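# mvclust — multi-view clustering and late integration for patient subtyping

`mvclust` discovers patient subclasses from several omics layers ("views" —
mRNA, miRNA, protein, copy number …) measured on the same patients. It
integrates *late*: each view is clustered on its own terms, and only the
clustering results are combined. This lets each view keep the algorithm and
feature set that suit it, sidesteps cross-platform representation issues,
and — unlike early or intermediate integration — makes it possible to say
how much each view determined each final patient group.

## The method

Four stages, all exposed as ordinary functions and chained by
`runPipeline()`:

1. **Prototype extraction.** Per view: drop low-variance features, cluster
   the rest (Ward / k-means / PAM / spectral, all in correlation geometry),
   and keep one representative "prototype" per cluster. Clusterings are
   scored with the composite validity function

   `VAL = ((IC+1)/2 + 1 − (EC+1)/2 + (1 − S) + CG) / 4`

   (cohesion IC = mean minimum within-cluster correlation, separation
   EC = mean minimum cross-cluster correlation, singleton factor
   S = #singletons/(K−1), compression gain CG = 1 − K/N); the cluster count
   is tuned by averaging VAL across algorithms over a k-grid.
2. **Feature ranking.** Prototypes are ranked by class separability with
   correlation-adjusted t-scores (`cat = R^(−1/2) t`, shrinkage estimates)
   and random-forest permutation importance, then cut at 60/70/80/90 % of
   the cumulative score.
3. **Per-view patient clustering.** Patients are clustered on the selected
   prototypes (K = number of classes by default); the grid of
   {algorithm} × {ranking} × {cut} is scored by majority-vote impurity and
   the argmin kept per view.
4. **Late integration.** The per-view membership matrices are stacked into
   a clusters × patients matrix `X` and combined either by non-negative
   matrix factorization `X ≈ PH` (Frobenius, multiplicative updates) or by
   the generalized Kullback–Leibler consensus model
   `min GI(M ‖ BP), B ≥ 0, P ≥ 0, B1 = 1`. Meta-clusters are labelled by
   majority class, tested with one-sided Fisher's exact tests, and the
   projection factor yields the view × meta-cluster contribution matrix
   `T` (columns sum to 1). Adding the class-label indicator as an extra
   view gives the semi-supervised variant. Robustness is quantified by a
   leave-one-out stability index (mean pairwise NMI across N reruns) and
   feature lists are aggregated across reruns by Borda count.

A synthetic multi-view generator with planted classes, subclasses,
correlated feature blocks and view-specific signals
(`generateMultiView()`) backs every test — no external downloads are
needed anywhere.

## Worked example

```r
library(mvclust)

g <- generateMultiView(n_patients = 120, seed = 1,
                       views = syntheticViewSpec(n_features = 60, n_blocks = 4,
                                                 block_size = 10, effect_size = 3))
res <- runPipeline(g$dataset, mvConfig(seed = 1, K = 4, k_range = 4))
res$report
#>   cluster size majority_class majority_count  p_value p_adjusted contrib_view1 contrib_view2
#> 1       1   31         class2             31 2.32e-12   9.29e-12         0.498         0.502
#> 2       2   27         class2             27 1.66e-10   2.21e-10         0.502         0.498
#> 3       3   30         class1             30 6.97e-12   1.39e-11         0.498         0.502
#> 4       4   32         class1             30 1.58e-09   1.58e-09         0.502         0.498

impurity(metaPartition(res$meta), classLabels(g$dataset))
#> [1] 0.01666667
nmi(metaPartition(res$meta), g$truth$subclass)
#> [1] 0.929
```

The four meta-clusters split each class in two (the planted subclasses):
every cluster is overwhelmingly one class (Fisher p ≪ 0.01), the partition
agrees with the planted subclass structure (NMI 0.93), and both views
contribute equally (~0.5 each), as expected since the signal was planted in
both. Planting a subclass in a single view moves its contribution column
toward that view; the class prior (`mode = "semi_supervised"`) drives the
residual impurity toward zero.

A thin command-line front end is installed with the package
(`system.file("cli/mvclust.R", package = "mvclust")`) with `synth` and
`run` subcommands over the same functions.

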