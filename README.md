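# boutiquenorm

Normalization and expression cataloging for **boutique microarrays** —
small custom chips whose probe content is biased toward one gene family
(defensin-like genes and their relatives, in the motivating design:
hundreds of family probe sets, ~170 invariant anchor genes, a small
marker panel, 11 PM/MM probe pairs per probe set).

On such chips the assumptions behind standard normalization fail: when
most of the family switches on together in one condition, neither
"most genes don't change" (MAS5, loess) nor "all arrays share one
intensity distribution" (RMA/quantile) holds, and whole-distribution
normalization actively erases the signal. This package is for analysts
of custom family-focused expression chips who need normalization that
survives that coordinated shift, plus the standard downstream analyses.

## What it implements

- **Probe-set summarization** (`rmaSummarize`): exponential-plus-
  Gaussian background correction fitted per array by constrained
  maximum likelihood, quantile normalization with deterministic tie
  handling, and median-polish summarization of each probe set's
  11-probe block on the log2 scale.
- **Detection calls** (`mas5Detection`): one-sided Wilcoxon signed-rank
  test of the discrimination scores `R = (PM-MM)/(PM+MM)` against
  `tau = 0.015`, with the null enumerated exactly over all 2^11 sign
  assignments; Present at `p < 0.05` (the level recommended for 11
  probe pairs), Marginal below 0.065, Absent otherwise.
- **Three boutique normalizations**:
  - `sbqNormalize` — *stable-gene based quantile* (SBQ): quantile
    normalization anchored only on designated stable genes, other genes
    mapped by monotone piecewise-linear interpolation between the
    stable anchors;
  - `rmapsNormalize` — per-replicate-group RMA, groups rescaled so the
    median of always-Absent probe sets is equal across groups;
  - `rimsNormalize` — per-replicate-group RMA, groups rescaled on the
    median of invariant genes.
- **Downstream analysis**: detection-based expression catalogs and
  tissue-specificity classes (`catalogExpression`, `vennCounts`),
  Welch-t/ANOVA differential expression with Benjamini–Hochberg
  q-values (`differentialExpression`), co-expression screening at
  `r² ≥ 0.7` with positive r (`coexpressionScreen`), average-linkage
  Pearson clustering (`clusterExpression`), and reference-gene
  stability ranking by pairwise variation M (`genormStability`).
- **Evaluation harness** (`compareToReference`,
  `compareNormalizations`): pooled, per-category and per-array Pearson
  correlation of a boutique normalization against whole-array reference
  RMA, with scatter and density plots.
- **Probe-level simulator** (`simulationConfig`, `simulateExperiment`,
  `makeBoutiqueSubset`): generates PM/MM data with gene baselines,
  coordinated up-shifts, silent genes, probe affinities, per-array
  brightness/gain/background variation — with full ground truth for
  parameter-recovery testing.

Data objects are Bioconductor-style: `ProbeLevelMatrix`,
`ExpressionMatrix` and `DetectionCalls` extend `SummarizedExperiment`;
plain-text TSV readers/writers (`readProbeLevel`, `writeExpression`,
...) cover interchange.

## Worked example

Simulate a whole-genome array, extract a boutique subset in which 60%
of the non-invariant probe sets are 4-fold up-shifted in one condition,
normalize the subset three ways, and compare each result to whole-array
RMA:

```r
library(boutiquenorm)

set.seed(1)
cfg <- simulationConfig(
  n_probesets = 5000L, n_invariant = 400L, n_marker = 50L,
  conditions  = c(control = 3L, treatment = 3L, stress = 3L),
  frac_shifted = 0.03, effect_log2 = 2, seed = 1L)
sim <- simulateExperiment(cfg)
ref <- rmaSummarize(sim$plm)                     # whole-array reference

sub <- makeBoutiqueSubset(sim, subset_size = 300L,
                          invariant_keep = 150L, frac_shifted = 0.6)
stable <- sub$annotation$probeset_id[sub$annotation$category == "invariant"]

cmp <- compareNormalizations(sub$plm, ref, stable)
cmp$summary
#>   method overall_r
#> 1    sbq 0.9983837
#> 2  rmaps 0.9966500
#> 3   rims 0.9966431
```

Each `overall_r` is the pooled Pearson correlation between that
method's log2 expression on the 300-probe-set subset and whole-array
RMA over the same probe sets and all 9 arrays (2,700 value pairs).
SBQ tracks the whole-array reference most closely even though it sees
only the biased subset; the per-group-RMA methods trail because a
single additive offset per replicate group cannot undo gain and
background differences between groups. Fold-change recovery against
the simulator's ground truth makes the boutique pathology concrete:

```r
raw <- rmaSummarize(sub$plm, normalize = FALSE)   # no cross-array step
sbq <- exprValues(sbqNormalize(raw, stable))
qn  <- quantileNormalize(exprValues(raw))         # naive all-gene quantile
cond <- sampleMeta(sub$plm)$condition
fc <- function(m) rowMeans(m[, cond == "treatment"]) -
                  rowMeans(m[, cond == "control"])
tru <- sub$truth@trueExpression[, "treatment"] -
       sub$truth@trueExpression[, "control"]
mean(abs(fc(sbq) - tru))   # SBQ fold-change MAE:      0.128 log2 units
mean(abs(fc(qn)  - tru))   # naive quantile MAE:       0.612 log2 units
```

Whole-distribution quantile normalization flattens the coordinated
shift and misestimates fold changes by ~0.6 log2 units on average;
SBQ, anchored on the invariant genes, stays within ~0.13.

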