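---
title: "Methods: hierarchical differential abundance on cladograms of means"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical differential abundance on cladograms of means}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladoda)
```

This vignette records the model, the tunable parameters, the numerical
and design choices made where the design was genuinely open, what the
simulators do and do not emulate, and the known limitations. It states
no empirical result that the package's test suite or acceptance script
does not itself compute.

## Model and assumptions

A taxa table holds processed abundances `x_i^j` (sample `i`, taxon `j`)
whose features are taxonomy paths (kingdom through species, depths 1-7).
The **cladogram of means** places features at the leaves and assigns
every internal node, per sample, the unweighted mean of its direct
children. Three consequences drive the method:

- Averaging contracts null variation: a mother of three independent
  `N(0,1)` daughters is `N(0, 1/sqrt(3))`. Internal nodes are therefore
  *harder* to reject by chance than leaves, and demanding significance
  along an entire root-to-taxon trajectory suppresses false positives
  multiplicatively.
- Averaging preserves shared signal: when sister taxa shift coherently
  with a phenotype — the empirically common case — the mother inherits
  and often amplifies the effect relative to its noise.
- The known failure mode is *opposing* sister effects of similar
  magnitude, which cancel in the mother. The separate
  Bonferroni-corrected leaf test exists precisely to rescue such taxa,
  and the `zma` simulation regime with `alpha_coef < 0` reproduces the
  scenario.

The testing cascade is: (1) an a priori **nested label-effect gate**
deciding whether the label relates to the microbiome at all; (2) a
**trajectory test** descending the cladogram from a coarse start level;
(3) the **leaf rescue test**; the result is the union of (2) and (3).

### The nested gate

For depth `k`, one observation per (sample, node) is stacked over all
nodes at depths `1..k` and the node-only fixed-effects model
`value ~ node` is compared with `value ~ node + label + label:node` by a
partial F-test (the label enters as a 0/1 factor, or as a covariate with
per-node slopes when continuous). At depth 1 with a single kingdom this
is exactly one-way ANOVA of the kingdom values by label. The scan stops
at the first significant depth; a label significant at no depth is "not
microbially explainable" and no per-taxon test is run.

The implementation computes the partial F in closed form from per-node
and per-cell sums of squares (identical to the stacked `lm` fit, which
the test suite keeps as an oracle) — stacking deep cladograms through
`lm` would materialize enormous factor design matrices for no gain.

Two caveats are deliberate and documented rather than hidden. First,
stacked node values at different depths are correlated by construction
(a parent is a function of its children), so the F reference
distribution is exact only at depth 1; the gate is a *screen*, not a
calibrated test of a sharp null, and its null calibration is verified by
simulation at depth 1 in the acceptance suite. Second, the scan across
depths performs no cross-depth correction — again appropriate for a
gate whose failure mode (passing too easily) only costs the per-taxon
stage its own, fully corrected, testing.

### Trajectory test and sister correction

Nodes at the start level are tested (two-sided Mann-Whitney for binary
labels; Spearman with the t-approximation for continuous), and corrected
across that level only — Bonferroni by default, the conservative choice
at the smallest pool; Benjamini-Hochberg is available. Below the start
level no level-wide correction is applied: children of a significant
mother are tested at the raw threshold, subject to the **sister
correction**: the most significant child (ties broken lexicographically
by path, for determinism) is kept on its raw p-value; all remaining
sisters are BH-adjusted together and survive only if both raw and
adjusted p-values clear the threshold. The BH pool includes
raw-non-significant sisters — the adjustment is applied "to all the
sisters apart from the most significant one", and including them only
makes the correction more conservative.

If the start level yields no significant taxon, the start escalates
through kingdom, phylum, class (never deeper: below class the level-wide
pool grows large enough that the trajectory logic degenerates into an
ordinary corrected sweep). A user-pinned `start_level` disables
escalation, so that what was asked for is what is reported.

### Leaf rescue

All leaves are tested and corrected across the number of leaves,
Bonferroni by default. (Where one description of the procedure says FDR
and another Bonferroni, this package defaults to Bonferroni and exposes
`leaf_correction = "bh"`.) Taxa found by both branches are reported once
with `source = "both"`.

## Preprocessing choices

- **Log normalization**: `x -> log10(x + eps)`, default `eps = 0.1`, so
  a zero count maps to -1. The alternative is per-sample relative
  abundance (`relative`), conventionally paired with mean-merging.
- **Sub-PCA merging**: features sharing a taxonomy prefix at the chosen
  level (default 7, species) are z-scored and replaced by principal
  components. "Components explaining more than half the variance" is
  read *cumulatively* — the minimal leading set whose cumulative
  explained-variance fraction exceeds 0.5 — because the per-component
  reading can return zero components for a diffuse group, leaving the
  group unrepresented; the per-component rule remains available
  (`variance_criterion = "individual"`). Components are named
  `<prefix>__pcK`; `strip_pc_suffix()` maps them back to taxonomy paths.
- **PCA sign**: each component is flipped, if needed, so it correlates
  non-negatively with the group's mean standardized abundance (fallback:
  first non-zero loading positive). Principal components are otherwise
  sign-ambiguous, which would scramble downstream direction signs.
- **Order**: normalize, then merge. Sub-PCA on raw counts would let a
  single high-count sample dominate every component.

## Statistical primitives

Standard machinery is delegated to base R: `wilcox.test` (exact when the
smaller group has at most 8 observations and the pooled sample is
tie-free, otherwise the normal approximation with tie and continuity
corrections), `cor.test(method = "spearman", exact = FALSE)`, and
`p.adjust`. The test suite verifies the exact Mann-Whitney path against
full enumeration of assignments and BH against a literal step-up
implementation, so these remain checked contracts rather than trusted
black boxes. Directions are always reported from the positive class's
perspective: +1 means higher ranks in class 1.

## Degenerate inputs and numerical guards

- Taxonomy strings: an empty rank (`s__`) terminates the path; a named
  rank after an empty one is an error (the tree would have an ambiguous
  parent). Misordered rank prefixes are an error.
- A feature whose full path coincides with an internal node (an
  unresolved taxon whose finer relatives are observed) becomes a direct
  leaf child of that node, entering its mean with unit weight.
- Relative normalization refuses all-zero sample rows, naming them.
- `sister_statistic` uses the printed denominator `|V0 - V1|^0.5` — an
  unusual quantity, retained as stated — guarded at `1e-8` when the
  variance difference underflows (`< 1e-16`); the conventional pooled
  form `(V0 + V1)^0.5` is available via `denominator = "sum"`.
- `rsp_score` returns 0 when `beta*RP + SP = 0`: an empty run is neither
  good nor bad evidence.
- Shuffled positives are estimated by permuting labels with a seeded
  generator that saves and restores the caller's RNG state; the mean
  count across shuffles is the default aggregate, with per-shuffle
  counts returned so per-shuffle RSP curves can be averaged instead.

## What the simulators emulate

`simulate_regime()` reproduces the analytical triplet regimes: three
daughters per mother, `2N` samples (`N` per class), daughter `j` drawn
`N(shift_j * y, 1)` with shifts `(0,0,0)`, `(mu,0,0)` or
`(mu, alpha_coef*mu, 0)`. Defaults: 10 triplets, `N = 50`. The planted
truth is exposed twice: leaves only (for scoring leaf-level baselines)
and with ancestors included (for scoring trajectory output, whose
correct behavior *is* to flag the ancestors of planted daughters).

`simulate_microbiome()` is a synthetic stand-in for spike-in protocols
run on real cohorts: a 7-level taxonomy (6 species per genus, 2 genera
per family, 2 families per order, 3 orders per class, 2 classes per
phylum), zero-inflated log-normal counts, independent Bernoulli(1/2)
labels, and a multiplicative `spike_factor = 1.2` applied to the raw
counts of all species of 10 "up" genera in positive samples and 10
"down" genera in negative samples — spikes hit raw counts *before*
preprocessing, as a wet-lab effect would.

The default noise regime — `sparsity = 0.05`, `dispersion = 0.5`
(log-normal sdlog), `mean_log = 2.5` — was fixed by a power analysis at
design time and emulates the dense, low-dispersion *core-taxon* fraction
of a prevalence-filtered table (tables filtered to taxa present in
nearly all samples are routine practice). The reasoning: a 20% spike
moves a species' log10 abundance by at most `log10(1.2) ≈ 0.079`; with
raw-ASV sparsity (0.7+) and dispersion (sdlog ≥ 1.5) the zero/non-zero
mixture dominates the variance and *no* method detects anything at
n = 200, which would make method comparisons vacuous (0 vs 0). At the
chosen defaults the spike sits at the detection margin — per-species
effects are individually sub-threshold, genus-level aggregation brings
them within reach — which is exactly the regime the hierarchical
procedure is designed for. What is *not* emulated: compositional
closure, sequencing-depth variation, and within-genus correlation of
real ASVs. Passing simulation tests therefore demonstrate the
hierarchical logic, not performance on any particular real cohort.

## Problem sizes in the test suite

The acceptance checks run at desk scale, chosen as the smallest sizes at
which the asserted properties are statistically decisive: 1e6 draws for
the mother-distribution check (±0.005 band, Monte-Carlo SE ≈ 4e-4);
20,000 replicates for the joint-significance rate; 1000 permutations for
null calibration of the gate (95% binomial CI half-width ≈ 0.0135); 200
seeds per sample size for the regime dominance comparison; 20 seeds of a
200 × 300 table for the spike-in F1 comparison.

## Known limitations

- **The mother-daughter joint rate exceeds the independence product.**
  Requiring `p < alpha` on both a mother and one of its daughters is
  *qualitatively* like an `alpha^2` requirement on the daughter, but the
  two statistics correlate at `1/sqrt(3) ≈ 0.577` (the daughter is a
  third of the mother), so the joint null rate lies a small constant
  factor above `alpha^2` — far below `alpha`, as the property test
  asserts, but not within a factor of 2 of `alpha^2`; the acceptance
  suite records this honestly as a failed band rather than widening it.
- The nested gate's p-values at depths beyond 1 are screens, not
  calibrated tests (correlated stacked observations; see above).
- Opposing sister effects cancel in mothers; detection then relies
  entirely on the leaf rescue, whose Bonferroni correction costs power
  for rare taxa (`zma` regime, `alpha_coef < 0`).
- Multi-class categorical labels, covariate adjustment and longitudinal
  designs are out of scope; labels are binary 0/1 or continuous.
- Compositionality is not modeled; relative normalization induces the
  usual sum-to-one coupling among taxa, and the trajectory logic does
  not attempt to correct for it.
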