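# cladoda

Phylogeny-aware hierarchical differential abundance testing for
microbiome taxa tables.

## The problem

Differential abundance analysis asks which microbial taxa differ between
two groups of samples (case/control) or track a continuous phenotype.
Standard practice tests every taxon independently and corrects for the
number of tests, which is punishing when a 16S or shotgun table carries
hundreds of sparse, non-normal, mutually correlated features. Sister taxa
— taxa sharing a parent in the taxonomy — tend to relate to a phenotype
similarly, and that structure is informative: a real signal is usually
visible along a whole trajectory of the taxonomic tree, while a false
positive is not.

`cladoda` exploits this. Let `x_i^j` be the processed abundance of taxon
`j` in sample `i` and `y_i` the sample label. The features are placed on
a **cladogram of means**: observed taxa are the leaves, and every
internal node carries, per sample, the unweighted average of its direct
descendants (for a mother of three daughters, `m = (z1 + z2 + z3)/3`).
Under the null, a mother of three independent standard-normal daughters
is distributed `N(0, 1/sqrt(3))` — internal nodes are *less* likely to
fire by chance, so demanding significance along a trajectory of the tree
sharply suppresses false discoveries while retaining true ones.

The procedure has three stages:

1. **Preprocessing.** Counts are log-normalized (`x -> log10(x + eps)`,
   `eps = 0.1` by default) or converted to relative abundances, then
   merged at a chosen taxonomy level. The default merge is grouped
   principal components ("sub-PCA"): each taxonomy group is z-scored and
   replaced by the minimal set of leading components explaining more than
   half of the group variance.
2. **A priori gate (nested ANOVA).** Before any per-taxon testing, a
   nested label-effect F-test is applied to the stacked node values at
   depths 1, 2, ... (one label effect per node against a node-only null).
   If no depth is significant the label is declared *not microbially
   explainable* and nothing further is tested.
3. **Post hoc trajectory + leaf tests.** A Mann-Whitney test (Spearman
   for continuous labels) is applied to every node at the coarsest
   taxonomy level, corrected across that level only (Bonferroni by
   default). For each significant node the test descends: children are
   tested at the raw threshold, with a Benjamini-Hochberg *sister*
   correction applied to all sisters except the most significant one.
   If the start level yields nothing, it escalates (kingdom, phylum,
   class). Independently, a Bonferroni-corrected test over all leaves
   rescues rare taxa lacking a significant ancestor chain. The result is
   the union, with each taxon tagged `trajectory`, `leaf`, or `both`.

For benchmarking without ground truth the package computes the **RSP
score**: with `RP` significant taxa under the real labels and `SP` the
mean count under shuffled labels (10 shuffles by default),

    RSP(beta) = (beta * RP - SP) / (beta * RP + SP),  0 < beta <= 1.

`beta` weights discovery against shuffled-label noise; `RSP(0.05) = 0`
exactly when `RP = 20 * SP`. Truth-based metrics (TPR/FPR/F1), a
per-taxon class-separation statistic `s = |M0 - M1| / |V0 - V1|^0.5`
with its sister-pair correlation, and two simulators (hierarchical
Gaussian triplet regimes; a zero-inflated, taxonomy-structured spike-in
table) round out the evaluation toolkit.

## Worked example

Simulate a 200-sample, 300-species table in which all species of 10
genera are spiked up by 20% in positive samples and 10 further genera are
spiked in negative samples, then run the full analysis:

```r
library(cladoda)
sim <- simulate_microbiome(n_samples = 200, n_features = 300, seed = 6)
fit <- cladoda(sim$table, sim$labels)
fit
#> Hierarchical differential abundance fit
#> A priori nested test: label microbially explainable (first significant depth 1, p = 0.00608)
#> Trajectory start level: 1
#> Significant taxa: 39 ( trajectory: 32 , leaf: 5 , both: 2 )

head(as.data.frame(fit)[order(as.data.frame(fit)$p_value), ], 5)
#>                             path depth      p_value adjusted_p direction     source
#> 16 Bacteria;p01;c02;o04;f08;g016     6 2.950876e-08         NA         1 trajectory
#> 11      Bacteria;p01;c02;o04;f08     5 9.384390e-07         NA         1 trajectory
#> 17 Bacteria;p02;c03;o08;f15;g030     6 2.365394e-05         NA        -1 trajectory
#> 5               Bacteria;p01;c02     3 2.812030e-05         NA         1 trajectory
#> 8           Bacteria;p01;c02;o04     4 4.883882e-05         NA         1 trajectory
```

The a priori gate opened at the kingdom level (p = 0.006); the
trajectory test then walked the cladogram from depth 1 and found
coherent chains into spiked genera (direction +1 = higher in the
positive class), while the leaf test rescued a handful of species-level
features. Shuffled labels quantify how much of this could be noise:

```r
sp <- estimate_sp(sim$table, sim$labels, n_shuffles = 5, seed = 99)
rsp_score(rp = nrow(fit$taxa), sp = sp$sp, beta = 0.5)
#> [1] 0.902439   # RP = 39 vs mean SP = 1

confusion_metrics(unique(strip_pc_suffix(fit$taxa$path)),
                  sim$truth$trajectory)[c("tp", "fp", "f1")]
#> $tp [1] 39   $fp [1] 0   $f1 [1] 0.368
```

All 39 reported taxa are genuine (no false positives); the modest F1
reflects missed spiked taxa, the price of the 20% spike being at the
detection margin at n = 200.

`plot(fit)` displays every node by depth and `-log10(p)`;
`cladogram_plot_data()`, `interaction_network()` and
`family_relation_counts()` emit the corresponding serializable plot
data. A thin command-line front end lives at
`inst/scripts/cladoda-cli.R` (`run`, `simulate`, `report` subcommands).

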