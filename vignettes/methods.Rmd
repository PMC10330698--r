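---
title: "Statistical methods and modeling choices in melresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and modeling choices in melresponse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each module of
**melresponse**, the assumptions those models make, the default parameter
values and why they were chosen, and the known limitations of the synthetic
generators used for verification.

## 1. The paired-biopsy design

All expression analyses assume a cohort in which each patient contributes a
pre-treatment (PT) and an on-treatment (OT) tumor biopsy, receives exactly
one of two therapies, and has an OT clinical response label of responder
(`R`) or non-responder (`NR`). The unit of analysis is the *within-patient*
log2 fold change, which removes stable patient-level expression offsets by
construction and is the reason the downstream contrast needs no per-patient
random effect.

### Normalization

`tmm_normalize()` computes trimmed-mean-of-M-values (TMM) scaling factors
and log2 counts-per-million. The defaults (`trim_m = 0.30`,
`trim_a = 0.05`, `prior = 1`) are the standard choices for this estimator:
a 30% symmetric trim on the log-ratios discards genes whose expression
genuinely differs between samples, the 5% trim on average intensity
discards extreme-abundance genes where the log-ratio variance
approximation degrades, and a prior count of 1 keeps zero counts finite on
the log scale. Factors are re-centered to geometric mean 1 so that the
scaling is identifiable. The assumption underlying TMM is that the
majority of genes are not differentially expressed between samples; the
synthetic cohorts respect this (at most 50 of 2000 genes carry signal).

### Batch centering

`remove_batch()` removes additive batch effects on the log scale while
preserving the therapy/timepoint/response group structure through a design
matrix. This assumes batch acts additively on log expression and is not
confounded with the preserved groups; confounding is detected by a rank
check and raised as an error rather than silently producing a degenerate
correction.

### The responder contrast

For each gene, `delta_fc_test()` compares the paired log2 fold changes of
responders against non-responders with a Welch two-sample *t*-test
(unequal variances; responder and non-responder groups have no reason to
share a variance), and controls the false discovery rate across genes with
Benjamini-Hochberg. An *up* gene must satisfy both an effect-size rule
(`delta_fc >= 1`, i.e. a two-fold difference between group means) and an
evidence rule (`q < 0.05`). Genes with fewer than two finite fold changes
per group are dropped with a warning.

One edge case deserves note. When a gene has *zero variance in both
groups*, the *t*-statistic is undefined. We set `t = NA` and define the
p-value by the limit behavior of the test: `p = 1` when the two group
means are equal (no evidence of any difference) and `p = 0` when they
differ (the data separate the groups perfectly, which is the limit of the
Welch p-value as the within-group variances shrink to zero). This keeps
the degenerate-but-informative case (constant 2s versus constant 0s)
callable while still treating flat genes as null.

### The cross-therapy contrast

`cross_therapy_contrast()` selects genes whose responder contrast is
therapy-specific: gene *g* is assigned to therapy A when
`delta_fc_A - delta_fc_B >= 1` *and* `delta_fc_A >= 1`. The second
conjunct prevents assigning a gene to A merely because it moves *down* in
B. The rule is deliberately a pair of inequalities rather than a second
inferential test: the inputs are already FDR-controlled contrasts, and the
cross-therapy step is a classification of effect sizes.

## 2. Gene-set scoring

`single_sample_score()` implements a single-sample enrichment score as a
weighted Kolmogorov-Smirnov running sum: genes are ranked per sample (ties
receive average ranks), member genes contribute weight `rank^alpha`, and
the score is the sum of the running-sum deviations. The default
`alpha = 0.25` is the conventional weighting for this estimator; it damps
the influence of the very top ranks relative to `alpha = 1` while still
weighting members by expression. Scores are comparable *across samples
within a set*, not across sets. A `mean_z` method (mean per-gene z-score
over members) is provided as a simpler, linear alternative; both methods
agree on orderings in the constructions used by the test suite.
`min_overlap = 3` skips sets with too few measured genes for a running sum
to be meaningful.

`marker_abundance()` is the marker-mean estimator: the abundance of a cell
population in a sample is the arithmetic mean of the log2-CPM of its
marker genes present in the matrix. It assumes markers are expressed
predominantly by their population; it estimates relative abundance across
samples, not absolute cell fractions.

`overlap_enrichment()` is a one-sided Fisher exact test (hypergeometric
upper tail) of the overlap between a query gene list and each collection
set within a stated universe, BH-adjusted across the collection. The
universe must be chosen by the caller as the set of genes that *could*
have entered the query; p-values are meaningless under a mis-specified
universe, which is why a query gene outside the universe is an error.

## 3. Repertoire analysis

Clonotype records are filtered to productive sequences (the `productive`
flag, plus removal of junctions whose amino-acid sequence contains a stop
`*` or frameshift `_`), then *convergent* clonotypes — identical
amino-acid junctions arising from different nucleotide sequences — are
merged with summed counts, keeping the highest-count nucleotide sequence
as representative.

Diversity is Shannon entropy over clone frequencies (natural log);
normalized diversity divides by `log(richness)` (Pielou evenness), and
clonality is one minus normalized diversity. Two conventions are fixed by
definition rather than by the formula: a monoclonal repertoire has
clonality 1 (the `0/0` evenness limit is resolved toward maximal
dominance), and a perfectly uniform repertoire has clonality 0.

### Lineage inference and somatic hypermutation

`infer_lineages()` groups heavy-chain (IGH) junction sequences into
germline clones: sequences are partitioned by (V gene, J gene, junction
length), pairwise normalized Hamming distances are computed within each
partition, and single-linkage hierarchical clustering is cut at a distance
threshold. Single linkage is the standard choice here because a lineage is
a *chain* of point mutations: two sequences belong together if they are
connected through intermediate variants, not if all pairs are mutually
close.

The threshold can be supplied or detected automatically
(`threshold = "auto"`): nearest-neighbor distances are pooled, a Gaussian
kernel density (Silverman bandwidth) is fitted, and the threshold is the
density minimum between the two highest modes — the classical
bimodal-distance heuristic, where the low mode is within-lineage mutation
distance and the high mode is between-clone distance. Modes below 5% of
the peak density are ignored as noise, and if the two candidate modes are
not separated by a genuine valley the distribution is declared unimodal.
In the unimodal and data-poor (fewer than 20 distances) cases the
conventional fallback of 0.1 normalized Hamming is used and logged.

`shm_frequency()` is the fraction of germline clones containing at least
two mature clones, i.e. the fraction of lineages showing somatic
hypermutation. `novel_clone_fraction()` is the share of on-treatment
amino-acid clonotypes absent from the pre-treatment repertoire.

## 4. Survival models

`km_fit()` is the Kaplan-Meier product-limit estimator; `logrank_test()`
is the standard unweighted log-rank test; `cox_fit()` maximizes the Cox
partial likelihood with the Efron tie correction (default) and reports
Wald tests and 95% confidence intervals. Efron's correction is preferred
over Breslow's because simulated and clinical follow-up times are
recorded on coarse grids and ties are common.

`median_stratify()` splits a feature at its median with the *median and
above is high* rule, so the rule is deterministic under ties.
`joint_strata_analysis()` crosses two median splits into four strata,
tests them jointly by log-rank, and fits a Cox model on the two high/low
indicators plus their product; the coefficient on the product is the
interaction log hazard ratio. When the indicators are collinear (for
example, the two features induce identical splits) the interaction is not
identifiable and the fit is skipped with a warning instead of returning an
unstable estimate. Apparent complete separation (|beta| > 20) is an
error, since the Wald machinery is meaningless there.

## 5. Synthetic cohorts

Three seeded generators provide ground-truth data at desk scale. All are
pure functions of their seed: they save and restore the global RNG state,
so calling them never perturbs a surrounding analysis.

**Expression** (`simulate_expression_cohort()`): negative-binomial counts
with `variance = mu + phi * mu^2` and dispersion `phi = 0.2`, a typical
bulk RNA-seq value; log-normal baseline means (`meanlog = 4`,
`sdlog = 1`) giving a realistically wide expression range; additive
per-gene batch offsets (sd 0.3) on the log scale, balanced across arms;
per-patient offsets (sd 0.5) shared by the PT and OT samples, which makes
the paired design informative; library-depth multipliers uniform on
(0.7, 1.3); and a planted `2^delta`-fold on-treatment increase in
responders of one therapy.

**Repertoire** (`simulate_repertoire()`): Zipf-distributed clone sizes
(exponent 2, a typical repertoire skew), junctions drawn codon-wise from
the 61 sense codons so every germline junction is productive in frame,
and, with probability `shm_probability`, 2-4 descendant sequences per
germline clone mutated at `shm_per_base_rate` per base with stop-codon
rejection. The 2-4 descendant range keeps lineages large enough to be
detectable but small enough that the bimodal distance structure (low
within-lineage mode near the per-base rate, high between-clone mode near
the random-sequence distance of ~0.75) is preserved at 200 germline
clones. The generator records the *realized* fraction of multi-clone
families as the recovery target, since the rejection step makes the
realized fraction differ slightly from the nominal probability.

**Survival** (`simulate_survival()`): exponential event times with rate
`baseline_rate * exp(sum(beta * x))` — i.e. exact proportional hazards —
and uniform censoring on `(0, censoring_window)`. The defaults
(`baseline_rate = 0.1`, window 32) give roughly 30% censoring at the
covariate mean, a realistic clinical follow-up fraction.

### Limitations of the generators

The expression generator plants a shared effect size in all responders of
one therapy; real response effects are heterogeneous across patients and
genes. Batch effects are additive on the log scale and balanced; real
batches can interact with biology. The repertoire generator mutates only
the junction (real SHM also hits the V segment, which is how V-gene calls
can be perturbed), draws V/J assignments deterministically round-robin,
and ignores sequencing error. The survival generator has exponential
baselines, so it cannot probe violations of proportional hazards. These
generators verify *estimator correctness*, not biological realism.

## 6. Numerical conventions

- All fold changes and expression values are log2; repertoire entropies
  are natural-log.
- BH adjustment, hypergeometric tails and exact Wilcoxon enumeration are
  tested against independent brute-force implementations to 1e-12.
- The Wilcoxon test (`group_compare()`) uses exact enumeration of all
  group assignments when a group has fewer than 8 observations and the
  enumeration is tractable, which is valid under ties; otherwise the
  normal approximation with tie correction is used.
- Cox coefficients are tested against a direct numerical maximization of
  the Efron partial likelihood to 1e-6.
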