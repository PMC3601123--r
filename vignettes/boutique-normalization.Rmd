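---
title: "Normalizing boutique microarrays: methods and design notes"
author: "boutiquenorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing boutique microarrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutiquenorm)
```

## The problem

Standard microarray normalization rests on a global assumption: either
most genes do not change between samples (MAS5 scaling, loess), or the
intensity distributions of all arrays are essentially the same shape
(RMA and other quantile schemes). A *boutique* array — a small custom
chip whose probe content is deliberately biased toward one gene family —
can violate both. When a large fraction of the family switches on
together in one condition (hundreds of defensin-like genes expressed in
nitrogen-fixing root nodules but not in uninoculated roots, say), the
condition's intensity distribution genuinely differs, and forcing it to
match the others erases the biology: quantile normalization pushes the
up-shifted genes back down and smears the difference across every gene.

`boutiquenorm` implements the probe-level processing chain for such
chips, three normalization strategies built for the boutique setting, the
downstream detection-based cataloging and differential-expression
analyses, an evaluation harness against whole-array reference
normalization, and a fully parameterized probe-level simulator with
ground truth.

## Data model

Intensities live in a `ProbeLevelMatrix` (a `SummarizedExperiment` with
linear-scale `pm` and `mm` assays, probes × arrays, stored
probe-set-major: each probe set is a contiguous block of
`probesPerSet = 11` rows). Sample metadata (`tissue`, `condition`,
`replicate_group`, `replicate_index`) ride in `colData`; a
`ProbeSetAnnotation` records species, functional category (`defl`,
`meg`, `marker`, `invariant`, `control`) and the `_at`/`_s_at`/`_x_at`
suffix class. Intensities are stored linear-scale and must be strictly
positive; every log2 transform happens inside an operation. Missing
values are rejected at validation — none of the downstream methods
define missing-data semantics, so silent imputation would be worse than
an error.

## Probe-set summarization (RMA-style)

`rmaSummarize()` runs the standard chain:

1. **Background correction.** Each array is modeled as observed =
   exponential signal + Gaussian optical background,
   $O = S + B$, $S \sim \mathrm{Exp}(\alpha)$,
   $B \sim N(\mu, \sigma^2)$. Parameters are estimated per array by
   constrained maximum likelihood on the closed-form convolution
   density, initialized from (and falling back to) kernel-density-mode
   estimates; the mode alone is biased upward by
   $\alpha\sigma^2 + z\sigma$ where $\varphi(z)/\Phi(z)=\alpha\sigma$,
   which is why the likelihood step matters. Each intensity is replaced
   by $E[S \mid O=o]$ with $S$ truncated to $[0, o]$:
   $a + b\,\frac{\varphi(a/b)-\varphi((o-a)/b)}
   {\Phi(a/b)+\Phi((o-a)/b)-1}$ with $a = o-\mu-\sigma^2\alpha$,
   $b=\sigma$. The denominator is evaluated as
   $\Phi(a/b)-\Phi((a-o)/b)$, which stays accurate deep in the tails
   where the textbook form cancels catastrophically; where both tails
   underflow entirely the Mills-ratio limit $b^2/|a|$ is used. The map
   is strictly increasing in $o$, so ranks are never reordered.
2. **Quantile normalization** of the corrected PM matrix: every column
   is mapped onto the across-array mean of column-sorted values at its
   within-column rank. Tied entries receive the mean of the reference
   values spanned by their tied ranks — a deterministic, symmetric
   convention. `rmaSummarize(, normalize = FALSE)` skips this step and
   tags the result `raw_summary`; that is the correct input for SBQ,
   which must not see whole-distribution matching.
3. **Median polish** per probe set on the log2 scale: the additive fit
   `value = overall + probe + array + residual` by alternating median
   sweeps (`stats::medpolish`, tolerance 1e-9, at most 50 sweeps — 20
   sweeps proved insufficient for 1e-6 agreement with a to-convergence
   reference on small blocks). The per-array summary is
   `overall + array`. MM probes are never used in summarization.

## Detection calls

`mas5Detection()` computes, per probe set and array, discrimination
scores $R_i = (PM_i - MM_i)/(PM_i + MM_i)$ and tests
$H_0:\ \mathrm{median}(R-\tau)=0$ against $>\tau$ with a one-sided
Wilcoxon signed-rank test. Because $n \le 11$ and tied ranks occur, the
null is enumerated *exactly* over all $2^n$ sign assignments of the
observed $|R-\tau|$ ranks (cached by rank multiset), rather than using
a normal approximation or the tie-free `psignrank` distribution. Scores
within 1e-12 of $\tau$ are dropped before ranking (the standard
signed-rank zero-handling, made floating-point tolerant). Calls follow
`DetectionParams`: Present below $\alpha_1 = 0.05$ (the recommended
level for 11 probe pairs), Marginal below $\alpha_2 = 0.065$, Absent
otherwise; $\tau = 0.015$. Calls are computed from raw PM/MM (the MAS5
convention); background-corrected input can be supplied by constructing
a corrected `ProbeLevelMatrix` if a user wants the variant.

Being a discrete exact test, the attained size under a continuous
symmetric null is the largest achievable level below $\alpha_1$
(0.0415 for $n = 11$), slightly conservative by construction.

## The three boutique normalizations

**SBQ — stable-gene based quantile normalization**
(`sbqNormalize`). Quantile normalization anchored only on a designated
stable set (annotated invariant genes, or a CV screen via
`selectInvariants`). The reference is the across-array mean of sorted
stable-gene values; per array, stable genes map to the reference at
their within-array stable-gene rank, and every other gene maps through
monotone piecewise-linear interpolation between that array's
(observed → reference) stable anchors. Outside the stable range, values
shift by the boundary anchor's offset, keeping the map monotone on the
whole line. With the stable set equal to all genes, SBQ *is* full
quantile normalization — a useful degenerate check. SBQ operates on
summarized probe-set values (`raw_summary`), not probe-level data.

**RMAPS — RMA with median absent-probe-set scaling**
(`rmapsNormalize`). RMA is run separately within each biological
replicate group, where the distributional assumptions still hold; each
group's log2 matrix is then shifted by a single additive constant so
the median over the probe sets called Absent in *every* array of the
experiment is equal across groups. The common target is the grand
median of the per-group statistic (symmetric and order-independent),
and the offsets are reported in a `ScalingReport`. If no probe set is
Absent everywhere, RMAPS is inapplicable and says so in a typed error.

**RIMS — RMA with invariant median scaling** (`rimsNormalize`). As
RMAPS, but the anchor is the median over a designated invariant-gene
set. Additive log2 scaling (equivalently multiplicative linear scaling)
is the minimal one-parameter family a median anchor can identify, which
is why nothing richer is fitted.

All three are equivariant to array order within groups. A single
replicate group degenerates to plain RMA with zero offset.

`selectInvariants()` screens by coefficient of variation on the linear
scale (`sd/mean` of $2^{\log_2}$ values) with a *strict* `< 0.10`
default threshold; a `scale = "log2"` switch is provided since the
convention is not universal. `medianScaleRows()` centres each row at
its median for heat-map display (`plotExpressionHeatmap`, green = low,
white = average, magenta = high).

## Downstream analysis

- `catalogExpression()`: a gene is expressed in a tissue when called
  Present in at least 2 of that tissue's replicates (capped at the
  replicate count, so one-replicate tissues need their single P).
  Classes partition genes into `constitutive` / `unique_to_one_tissue`
  / `multi_tissue` / `not_expressed`. `vennCounts()` counts every
  region of up to four named tissue-set diagrams; regions sum to the
  union, and counts are reported together with their explicit
  denominators rather than bare percentages.
- `differentialExpression()`: per-probe-set t-test for two groups or
  one-way ANOVA for more, with Benjamini–Hochberg q-values
  (`stats::p.adjust`) and a `q < 0.05` significance flag. The default
  pools the group variances: at $n = 3$ per group the pooled test's
  4 df are guaranteed, while Welch's Satterthwaite df can fall toward
  2, and on a 2–3 df t-null the stringent per-test thresholds BH
  induces cost roughly a quarter of the sensitivity for effects of
  realistic size — an asymmetric price for robustness that log2
  summaries with similar within-group spread rarely need
  (`var_equal = FALSE` restores Welch). Degenerate zero-variance rows
  get p = 1 when the means agree.
- `coexpressionScreen()`: Pearson r against a seed probe set; reported
  when $r^2 \ge 0.7$ *and* $r > 0$ — co-regulation means same-direction
  change, and $r^2$ alone would admit perfectly anti-correlated genes.
  The $r^2$-with-sign convention is configurable through
  `analysisConfig`.
- `clusterExpression()`: UPGMA on $d = 1 - r$. Rows are processed in
  lexicographic id order so merge sequences are reproducible
  regardless of input order; zero-variance rows get correlation 0
  (distance 1) with a warning.
- `genormStability()`: the pairwise-variation stability value
  $M_j = \mathrm{mean}_k\, \mathrm{sd}(\log_2 x_j - \log_2 x_k)$ on
  linear-scale values (log2 input is exponentiated first, as the
  original method specifies), with optional iterative worst-gene
  exclusion.

## Evaluation harness

`compareToReference()` compares a boutique normalization to a
whole-array reference over shared probe sets and arrays: pooled Pearson
r over all log2 pairs, per-category r (defl / invariant / marker),
per-array r, RMS difference and the scatter table. All three
conventions are reported because pooled-vs-per-array correlation is a
known ambiguity in such comparisons. `compareNormalizations()` runs
SBQ, RMAPS and RIMS on one subset and ranks them; `replicateAverage()`
collapses replicate groups before cross-platform comparison;
`intensityDensity()` gives per-array log2(PM) kernel densities
(Silverman bandwidth, 512 shared grid points) whose low-intensity
background peak and between-array divergence make the
distribution-shift problem visible.

## The simulator: what it emulates, and what it does not

`simulateExperiment()` draws, per gene, a baseline log2 expression;
marks a fraction `frac_shifted` of the family genes as up-shifted by
`effect_log2` in one condition; adds per-replicate biological noise and
renders 11 PM/MM probe pairs per probe set. Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_probesets`, `n_invariant`, `n_marker` | 500 / 170 / 25 | boutique-chip proportions: a few hundred family probe sets, ~170 invariant anchors, a small marker panel |
| `probes_per_set` | 11 | 11 PM/MM pairs per probe set |
| `conditions` | 2 × 3 replicates | three biological replicates per treatment |
| `frac_shifted`, `effect_log2` | 0.7, 2 | the boutique pathology: well over half the family switching on (4-fold) in one condition |
| `frac_silent`, `silent_log2_mean` | 0.15, 0 | family members not expressed in any sampled tissue contribute essentially zero specific signal; these supply RMAPS's always-Absent anchor |
| `baseline_log2_mean/sd` | 7 / 1.5 | expressed genes spanning roughly 2^4–2^10 against a background of ~100 |
| `invariant_log2_mean/sd` | 8 / 1.5 | invariant anchors chosen to span the signal range, as real invariant sets are |
| `invariant_noise_log2` | 0.05 | calibrates invariant linear-scale CV to ~3.5%, comfortably under the 10% selection rule |
| `biological_sd_log2` | 0.25 | typical within-group variability for plant tissue replicates |
| `probe_affinity_sd` | 0.7 | probe-to-probe sensitivity spread, drawn once per probe and shared across arrays (affinity is a probe property — the additive structure median polish assumes) |
| `array_effect_log2_sd` | 0.2 | global per-array brightness differences |
| `array_gain_log2_sd` | 0.08 | per-array dynamic-range gain about the baseline mean; a purely additive array model would make single-offset scaling artificially perfect and the method comparison vacuous |
| `bg_mu`, `bg_sd`, `bg_array_sd_log2` | 100, 20, 0.3 | Gaussian optical background whose level varies array to array |
| `mm_crosshyb` | 0.05 | MM sees a small cross-hybridized signal fraction plus background |

PM is $2^{\theta + \text{affinity}} + N(\mu_a, \sigma_a)$ truncated at
1 (the truncation slightly reshapes the extreme lower tail — stated
because it changes moments); MM replaces the signal with its
cross-hybridized fraction. Everything is bit-reproducible from
`(config, seed)`, and `SimulationTruth` retains the noise-free
condition means, the per-array biological expression, shifted/silent
identities, effects and affinities for parameter-recovery tests.

`makeBoutiqueSubset()` models a boutique chip as a biased draw from a
whole-genome simulation: all requested invariants plus non-invariant
slots filled with shifted genes at a chosen fraction (default 0.6),
mimicking family-biased content.

**Study-scale choices used by the tests and the acceptance script.**
The evaluation experiment simulates a 5,000-gene whole array (400
invariants, 3 conditions × 3 replicates, genome-wide `frac_shifted`
0.03 — a reference-grade array where RMA's assumptions approximately
hold, since a reference that itself distorts fold changes cannot
adjudicate between methods) and extracts a 300-probe-set subset with
150 invariants and 60% of the remaining slots shifted. Calibration
checks use 1,000-probe-set expression simulations (3 vs 3, log2 sd
0.25) and 2,000 symmetric-null probe sets for the detection test. These
sizes keep every run deterministic and desk-scale while leaving
binomial error well inside the asserted tolerances.

**What the generator does not emulate** — and what passing tests
therefore do not establish about real chips: spatial artifacts and
scanner saturation; probe-sequence-dependent affinity (GC content,
cross-hybridization structure); condition-correlated background;
cross-platform probe-set differences (real cross-platform comparisons
match probe sets by sequence identity, ours match by id); and RNA
quality or batch effects beyond a global gain/offset. The harness shows
the methods behave as designed under the stated model, not that any
method is best for a particular real dataset.

## Numerical conventions, in one place

- Quantile-normalization ties: mean of reference values at tied ranks.
- Median polish: tolerance 1e-9, 50-sweep cap, non-convergence at the
  cap is accepted silently (it is the stopping rule, not a failure).
- Detection: exact $2^n$ enumeration; $|R-\tau| \le$ 1e-12 treated as
  a zero; all scores at $\tau$ gives Absent with p = 1 plus a warning.
- Background correction: tail-stable $\Phi$ difference, Mills-ratio
  fallback on double underflow; output strictly positive and monotone.
- UPGMA: lexicographic row order before `stats::hclust`; zero-variance
  rows get distance 1 with a warning.
- RMAPS/RIMS anchor medians agree across groups to 1e-9 after scaling.
- Degenerate DE rows (zero variance everywhere): p = 1 if means are
  equal, else 0.

## Limitations

SBQ assumes the stable set spans enough of the intensity range; genes
far outside it are only offset-corrected, so a stable set confined to a
narrow band weakens the method exactly where expression is most
extreme. RMAPS requires an always-Absent anchor and inherits detection
noise; RIMS (and RMAPS) correct only a per-group constant, so any
distortion beyond an offset — gain differences, nonlinear response —
survives scaling. The exact detection test is conservative at small
$n$. None of the normalizations model probe-level correlation between
arrays beyond the shared affinity.
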