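---
title: "Deriving cross-study consensus gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving cross-study consensus gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensig)
```

## The problem

Small transcriptomic studies of the same cellular contrast — for example
tolerogenic versus immature dendritic cells profiled by different labs on
different platforms — rarely agree on their top differentially expressed
genes. Each study has few samples per phenotype (3–8 is typical), its own
normalization quirks, and platform-specific gene coverage. Pooling the raw
samples invites batch effects; looking only at each study's strongest hits
finds almost no overlap. consensig implements the alternative: analyse each
study separately, then ask which genes show *homogeneous* differential
expression across all studies, and call those the consensus signature.

## The model, stage by stage

### Per-study preprocessing

Each study is an `expression_study`: a gene-by-sample matrix on the log2
scale with a phenotype label per sample. Raw intensities or counts are
detected by `log_transform_if_needed()` (threshold 50: log-scale expression
essentially never exceeds ~20, raw values almost always do). Genes sitting
at the study's floor value in every sample are removed
(`filter_unexpressed()`); arrays are quantile-normalized
(`quantile_normalize()`), RNA-seq counts are scaled by TMM factors
(`tmm_factors()`). Ties in quantile normalization take the mean of the
reference quantiles spanned by their rank range — the deterministic,
order-independent dialect. The TMM factors use a 30% two-sided trim on
log-ratios and 5% on average log-abundance against the sample whose upper
quartile fraction is most typical; unlike composition-only factors they
absorb library size, so doubling every count of a sample doubles its factor
(before the geometric-mean-1 rescale). Precision weights are computed on
count *fractions* rather than raw counts, which makes the factors exactly
scale-equivariant. `pca_qc()` and `sample_correlation_clustering()` provide
the usual checks that samples group by phenotype rather than by batch.

### Moderated differential expression

Within each study, `run_de()` fits the two-group model per gene: log2 fold
change, pooled variance `s2` on `n1 + n2 - 2` degrees of freedom. Because a
handful of samples estimate each variance poorly, variances are shrunk
toward a common prior under the standard hierarchical model in which `s2`
follows a scaled F distribution around a prior variance `s0_sq` with prior
degrees of freedom `d0`. The pair `(d0, s0_sq)` is estimated by moment
matching on `log s2`: under the model
`Var[log s2] = trigamma(df/2) + trigamma(d0/2)`, so `d0` comes from
inverting the trigamma function (monotone bisection on (0.1, 500]). When
the observed spread of `log s2` does not exceed the sampling term, the
variances are declared exchangeable (`d0 = Inf`) and the prior is matched on
the raw scale, `s0_sq = mean(s2)` — this is unbiased under the model and
reproduces the obvious answer when every gene reports the same variance.
The moderated statistic `t_mod = log2_fc / (sqrt(s2_post) * se_unit)` gains
`d0` degrees of freedom. With fewer than 10 usable genes moderation is
skipped (`d0 = 0`, classical pooled t). Benjamini–Hochberg adjustment is
applied within each study; the per-study DE count is defined as
`p_adj < 0.05`.

### Directional combination across studies

`t_to_z()` maps each moderated statistic to the standard normal quantile
with the same two-sided tail, keeping the sign; the computation runs in
log-tail space so even `|t| ~ 40` converts without underflow.
`pearson_combine()` then implements Pearson's method for signed effects:
per gene, one-sided p-values are combined separately upward and downward
via `-2 * sum(log p) ~ chisq(2k)`, and the overall significance score is
`min(1, 2 * min(p_up, p_down))`, with direction given by the smaller side
(ties broken by the sign of the z sum; a zero sum defaults to "up" —
cosmetically arbitrary and essentially unreachable with continuous data).
This two-one-sided-products rule is the standard modern reading of
Pearson's meta-analysis for signed effects; the classical single-product
Fisher combination and Stouffer's z-sum are available behind
`method = "fisher"` / `"stouffer"` for comparison. A gene must by default
appear in *all* studies (`min_studies`), configurable downward for
cross-platform coverage gaps. Combined p-values are floored at 1e-300 to
keep downstream log transforms finite.

`derive_signature()` thresholds the combined score at 1e-5 (the
conventional operating point for calling a consensus transcriptome) and
partitions by direction. The threshold is applied to the *unadjusted*
combined score: the within-study BH correction handles per-study multiplicity,
and 1e-5 on the combined score is itself a genome-wide-strict rule; an
optional BH-on-combined mode is deliberately not the default.

### Enrichment, validation, projection

`wilcoxon_pathway_test()` asks whether a pathway's members carry more
significant combined p-values than the rest of the universe. With both
groups at most 12 genes the exact permutation distribution of the rank sum
is computed by dynamic programming over midranks (ties are handled exactly);
larger problems use the normal approximation with tie and continuity
correction. The two branches agree to well under 0.02 absolute at the
boundary. `gsea_preranked()` implements the weighted Kolmogorov–Smirnov
running-sum enrichment score (weight 1 by default, 1,000 seeded gene-label
permutations; `NES = ES / mean |same-sign permutation ES|`). A set covering
the whole ranked list has no misses; its ES is defined as +1 and flagged
degenerate. The GSEA ranking statistic used by the pipeline is the mean
per-study z, because direction matters in the downstream interpretation.

`directional_concordance()` validates a signature on a held-out study: the
fraction of signature genes whose validation z carries the expected sign,
referred to a permutation null of random same-size, same-split gene sets.
This quantitative summary stands in for the directional heatmap validation
common in the field, and is labelled as such in outputs.
`module_score()` projects a signature onto single-cell data: per-cell mean
expression of the signature minus expression-bin-matched controls (25
equal-frequency bins, 100 seeded control draws per gene — the common
single-cell scoring convention). Raw counts are detected and normalized to
counts-per-10k log1p first. `compare_scores()` runs all pairwise
cluster comparisons (rank-sum or Welch t) with BH across pairs.

## The synthetic data generator

Every stage is exercised against `simulate_bulk_studies()`, which emulates
the structure of the real multi-study setting: several small studies
(default 5 studies × 4 samples per phenotype, 10,000 genes), a set of
consensus genes DE in every study with a fixed common sign but per-study
effect variation (default 100 up + 100 down, per-study log2 effects drawn
from N(1.5, 0.25²)), 50 discordant genes DE in exactly one study (the
heterogeneity that defeats naive top-gene comparisons), gene-level study
offsets (sd 0.25) standing in for platform and batch shifts, and optional
per-study gene dropout. Per-gene variances follow the scaled
inverse-chi-square law `s0_sim * d0_sim / chisq(d0_sim)` with `d0_sim = 4`
and prior sd `noise_sd = 0.5` — the hierarchical model the moderation stage
assumes, with moderate heterogeneity typical of small array studies. Values
are simulated directly on the log2 scale (all the motivating discovery sets
are arrays); `expression_scale = "intensity"` exponentiates to exercise the
log-transform path. A single master seed drives a hierarchical seed
sequence (one derived seed per study), so adding studies never changes
earlier studies' draws, and a fixed seed reproduces byte-identical output.

`simulate_single_cell()` draws negative-binomial counts (gamma-distributed
baseline means, dispersion 2) with cells partitioned into clusters and the
signature genes' means multiplied by `2^spike_lfc` in cluster 1 only.

What the generator does *not* emulate: probe-level array artifacts,
correlated gene modules, donor pairing, doublets or ambient RNA. Passing
tests therefore demonstrate that the statistics behave as designed under
the assumed model — calibrated nulls, recovered effects — not that any
particular public dataset would reproduce a particular gene list. The
published noise structure of the motivating datasets is unknown; generator
defaults were chosen once for testability and realism, not fitted to any
accession.

## Numerical choices and edge cases

- `t_to_z` and the Pearson combination work in log-tail space throughout;
  combined p-values floor at 1e-300.
- Trigamma inversion brackets `d0` in (0.1, 500]; spreads below the
  sampling term give `d0 = Inf`, spreads above the bracket cap at 0.1.
- Zero posterior variance with non-zero fold change yields p = 0 and is
  flagged degenerate; with zero fold change, p = 1.
- Duplicate gene symbols collapse to the highest-mean row (the usual
  probe-collapse heuristic; the field has no single standard, so the rule
  is deterministic and logged).
- Gene identifiers are opaque, case-sensitive strings.
- Signature lists sort by ascending combined p with gene-name tie-break,
  making pipeline output byte-reproducible.
- All simulation, permutation and control-gene draws are seeded; pipeline
  randomness flows from the single config seed.

## Problem sizes used in the test suite

The shipped tests run the full recovery experiment at the default
5-study × 10,000-gene configuration, null calibration at 50,000 genes × 5
studies, empirical-Bayes recovery at 20,000 genes, 1,000-draw null
concordance, and a 2,000-cell spiked single-cell projection — sizes chosen
to make binomial error bands tight enough for 3-standard-deviation checks
while keeping the whole suite fast on one CPU.

## A worked run

```{r example, eval = FALSE}
cfg <- list(seed = 1,
            simulate = list(n_studies = 5, n_genes = 10000),
            threshold = 1e-5)
res <- run_pipeline(cfg, "consensus_run")
res$signature
#> <gene_signature> consensus: 99 up, 100 down (p < 1e-05; 5 studies)
```

## Known limitations

- "Pearson's method" has several historical readings; the directional
  two-one-sided-products rule implemented here is the standard one for
  signed effects, but a pipeline using the classical single-product variant
  will produce slightly different gene lists near the threshold.
- The exact reproduction of published gene counts from public accessions
  additionally depends on probe-collapse rules and gene universes that are
  rarely stated; this package therefore validates behaviour on synthetic
  truth rather than chasing specific published counts.
- TMM factors here fold in library size by design; divide by column sums
  first if composition-only factors are wanted.
- The Wilcoxon pathway test inherits the usual caveat that gene-gene
  correlation within pathways inflates significance; permutation GSEA is
  the more conservative companion.
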