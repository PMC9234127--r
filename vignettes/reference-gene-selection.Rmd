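---
title: "Selecting and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(refstab)
library(dplyr)
```

## The problem

Relative RT-qPCR quantification reports a target gene's expression as a
difference of cycle-threshold (Ct) values against an internal control —
a *reference* (housekeeping) gene assumed constant across samples and
conditions. If the reference itself drifts between, say, the platelets
of cancer patients and healthy donors, every downstream fold change is
biased. refstab implements the two halves of a defensible
reference-gene workflow:

1. **Shortlisting** candidates from a bulk RNA-seq count matrix by a
   cascade of stability filters, then intersecting with a curated list
   of known reference genes; and
2. **Ranking** a small candidate panel measured by RT-qPCR with four
   established stability algorithms (comparative delta-Ct, geNorm,
   NormFinder, BestKeeper), aggregated into one comprehensive ranking,
   followed by a delta-delta-Ct validation of the chosen reference.

Both halves are exercised end to end on seeded synthetic data with
planted ground truth, so every claim the package makes is testable
without any external download.

## The shortlisting cascade

`run_shortlist()` executes, in order, on a gene x sample count matrix
with `normal` / tumor-subtype sample labels:

1. **Sample depth filter** — samples with fewer than `min_reads`
   (default 400,000) intron-spanning reads are removed. The rule is
   strictly "less than": a sample at exactly the threshold stays.
2. **Zero filter** — genes with a zero count in *more than*
   `max_zero_frac` (default 70%) of the retained samples are removed; a
   gene at exactly 70% stays.
3. **log2CPM** — `log2(count / library size * 1e6 + prior)`, prior 1
   (so a zero count maps to 0). The library size is the column sum of
   the matrix *after* the sample filter, before the gene filters: CPM
   is computed once, on the cleanest sample set, and is not recomputed
   as genes are discarded (discarding rows does not change what was
   sequenced).
4. **Stability criteria**, evaluated jointly on the post-zero-filter
   universe (they are three simultaneous conditions, not a re-ranked
   sequence):
   - *balanced means*: mean(normal)/mean(tumor) and its reciprocal both
     below `fold_max` = 1.2. Means are means of log2CPM — the scale on
     which the means are defined throughout — and genes with a
     non-positive mean in either class fail. The tumor class pools all
     non-normal labels.
   - *high expression*: rank by class mean (1 = largest) at most
     `ceiling(top_frac * G)` with `top_frac` = 0.10, in both classes;
     ties at the boundary all kept. G is the size of the
     post-zero-filter universe.
   - *low dispersion*: CV = SD/mean (SD with the n−1 denominator)
     below `cv_max` = 0.10 in both classes; an undefined CV (mean ≤ 0)
     fails.
5. **Refinement** — mean > `mean_min` = 1 and CV < `cv_max_refine` =
   0.01 in both classes. We read the refinement CV bound as *1
   percent*: a bound of 1 in absolute terms would be vacuous after the
   10% criterion above, so the percent reading is the only one that
   does any work. Both readings are runnable (`cv_max_refine = 1`
   restores the absolute one).
6. **Known-list intersection** — candidates are matched against a
   plain-text list of known reference genes after identifier
   normalization (trim, uppercase, Ensembl version suffix stripped,
   since curated lists mix symbol conventions). The shipped list
   (`inst/extdata/known_reference_genes_synthetic.txt`) is a synthetic
   stand-in of 73 widely used human housekeeping genes and is meant to
   be replaced by the user's own curated list.

Every stage logs attrition (`n_in`, `n_out`, `n_removed`), and
`tidy()` on the result exposes per-gene pass/fail flags for each
criterion, so a surprising candidate count can be traced to the filter
responsible.

## The four stability algorithms

All four consume a *collapsed* Ct panel: apply the inclusion rule
(`apply_ct_inclusion()`, Ct < 35 kept, exactly 35 excluded), then
average replicates (`collapse_replicates()`, cells with fewer than
`min_reps` = 2 surviving replicates become missing). Inclusion runs
before averaging so one failed replicate does not poison a cell's mean.

Ct values are converted to log2 relative quantities
`a(g, s) = (min Ct(g) − Ct(g, s)) * log2(E)` with amplification
efficiency `E = 2` (perfect doubling) unless configured; per-primer
efficiencies are rarely available and a constant E only rescales every
statistic by `log2(E)`, leaving all rankings unchanged. The per-gene
calibration by the minimum Ct is a constant shift and cancels in every
pairwise difference.

- **Comparative delta-Ct** (`delta_ct_stability()`):
  `S(i) = mean over k of SD_samples(Ct_i − Ct_k)` on pairwise-complete
  samples. A gene pair with fewer than 3 complete samples is an error
  by default (`on_incomplete_pair = "drop"` omits the pair instead).
- **geNorm** (`genorm()`): pairwise variation
  `V(i,k) = SD_s(a_i − a_k)`, stability `M(i) = mean_k V(i,k)`;
  the worst gene is removed and M recomputed until two remain, which
  share average rank 1.5 (the algorithm cannot separate its final
  pair, and the aggregation below needs a number). Ties in M are broken
  by removing the lexicographically last gene id, so runs are
  deterministic. The pairwise-variation series V(n/n+1) compares
  normalization factors (per-sample geometric means of the top-n
  relative quantities); it is reported as-is, with no "how many genes
  to use" decision rule attached. On complete-case data with E = 2 the
  first-step M equals the delta-Ct statistic exactly — a cross-method
  identity the tests assert to 1e-12.
- **NormFinder** (`normfinder()`): on sample-centered quantities,
  per-group means and variances give an inter-group deviation `d`
  shrunk by its sampling variance (`max(d² − v/n, 0)`, preventing
  negative bias estimates) and an intra-group term; the stability value
  is their size-weighted sum. This is a faithful transcription of the
  published variance-decomposition idea, not a port of the original
  tool, and is documented as an approximation to the full model-based
  estimator. With a single group it falls back to the intra-group SD.
- **BestKeeper** (`bestkeeper()`): descriptive statistics on the *raw*
  Ct scale — n, geometric/arithmetic mean, min, max, "SD" (the mean
  absolute deviation around the arithmetic mean, the original tool's
  descriptive convention; classical n−1 SD behind
  `sd_method = "sd"`), CV% = 100·SD/mean — plus each gene's Pearson
  correlation with the BestKeeper index (per-sample geometric mean of
  all candidate Cts, complete cases). Genes with SD above 1 cycle are
  flagged inconsistent. For aggregation, BestKeeper ranks by ascending
  dispersion; r is reported but not used for ranking (no explicit rule
  ties r to a ranking, and dispersion is the tool's headline
  criterion).

Missing-data policy: delta-Ct is pairwise-complete; geNorm, NormFinder
and BestKeeper's index drop samples missing any retained gene
(complete cases). `ct_stability(drop_gene_first = TRUE)` first drops
genes missing in more than half the samples, for panels where one bad
gene would otherwise discard most samples.

### Aggregation

`aggregate_ranks()` combines per-method ranks by their geometric mean,
ascending; exact ties break alphabetically by gene id. Feeding it the
per-method rankings of a three-gene panel (delta-Ct and NormFinder:
GAPDH, B2M, ACTB; BestKeeper: GAPDH, ACTB, B2M; geNorm: B2M/GAPDH tied
at 1.5, ACTB) gives aggregate scores

```{r}
aggregate_ranks(tibble::tibble(
  gene = c("GAPDH", "B2M", "ACTB"),
  delta_ct = c(1, 2, 3), bestkeeper = c(1, 3, 2),
  normfinder = c(1, 2, 3), genorm = c(1.5, 1.5, 3)))
```

i.e. the comprehensive order GAPDH, B2M, ACTB.

## Validation by delta-delta-Ct

`relative_expression()` quantifies a target against the chosen
reference: per sample `ΔCt = Ct_target − Ct_reference`; fold change
`2^−(ΔCt − mean control ΔCt)` (control geometric mean 1 by
construction); groups compared by a two-sided two-sample t-test on the
ΔCt values. We test on ΔCt rather than fold change because ΔCt is the
approximately normal scale on which the model is additive; the
classical equal-variance test is the default ("Student's t-test"
read literally), with Welch behind `var_equal = FALSE`. A shared
per-sample loading shift on both genes cancels exactly, and a
target-equals-reference call degenerates to fold changes of 1 with an
undefined p-value, reported as such rather than fabricated.

## The synthetic-data generators

`simulate_counts()` emulates the statistical structure the cascade
assumes: negative-binomial counts, log-normal library sizes
(median 1e6, log-sd 0.2), and four planted roles — housekeeping genes
(top-decile abundance, no class effect, near-Poisson dispersion, so
their class CV lands near 0.2–0.3%, far below every threshold),
shifted genes (class mean-log2CPM ratio 1.3, beyond the 1.2 bound),
noisy genes (size-1 dispersion, class CV well above 10%) and zero-heavy
genes (mean count 0.1, >70% zeros). Defaults are 500 genes and 50 + 50
samples with role fractions 2/34/34/30%.

Because CPM is a closed composition (it always sums to 1e6 within a
sample), expression is specified in relative-abundance space and the
realized log2CPM levels are computed analytically and reported in the
returned truth table; shifts are sized on that realized scale, and
their direction is chosen by abundance (up for low-abundance genes,
down for high-abundance ones) so shifted genes never invade the
housekeeping band in either class. One caveat the tests document: with
heavily overdispersed genes present, the per-sample count total
wobbles, which adds a small common bias (~0.005 log2 units at the
default configuration) to every gene's realized log2CPM. This is a
property of compositional denominators, not of the mean-targeting
machinery, so the large-sample calibration test runs at low
dispersion; the recovery tests run at the default, where the planted
margins dwarf the bias.

`simulate_ct()` generates Ct values under the additive model the
delta-Ct family assumes: baseline + group shift + a per-sample loading
effect `b(s) ~ N(0, 0.5²)` shared across genes + independent replicate
noise, with optional missingness (completely at random by default;
Ct-dependent dropout behind a flag). The default panel has seven genes
across five groups of six samples, three replicates each: one planted
stable gene (no shift, 0.1-cycle noise), three genes with group shifts
of at least one cycle, three with noise SD of at least 0.8 cycles. The
truth table records the implied stability ordering
(`sqrt(shift spread² + noise²)`).

What the generators do *not* emulate: batch effects, informative
library-size/condition coupling, gene–gene correlation beyond the
shared loading effect, amplification-efficiency heterogeneity, and
platelet biology (splicing dynamics, read-level artifacts). Passing the
recovery tests therefore demonstrates that the *algorithms* are
implemented correctly and separate the planted signal under their own
model assumptions — not that real platelet data will be as clean.

## Numerical and design choices

- Strict inequalities everywhere the wording is strict: depth < 4e5
  removed, zero fraction > 70% removed, Ct ≥ 35 excluded.
- Rank ties: average ranks within each method; geNorm's final pair at
  1.5/1.5; comprehensive ties alphabetical; top-decile boundary ties
  all kept.
- Degenerate inputs are defined, not errors: an all-constant panel
  yields all-zero stabilities with fully tied ranks; a constant gene
  in BestKeeper reports an undefined r and ranks by dispersion alone;
  an empty known-list intersection is an empty result with a warning.
- Gene identifiers are opaque strings; symbol/Ensembl mapping is out
  of scope (normalization only trims, uppercases and strips Ensembl
  versions).
- All simulation entry points require an explicit seed and are
  byte-reproducible given it.

## Problem sizes used by the checks

The test suite and the acceptance script verify the implementations
against independently coded brute-force oracles on one hundred random
5-gene x 8-sample panels (1e-10 relative tolerance; the geNorm
cross-identity at 1e-12), recover the planted stable gene in 200
seven-gene panels (observed rate ≈ 99%, required ≥ 95%), and recover
the planted housekeeping set exactly (sensitivity = specificity = 1)
on the default 500-gene, 50 + 50-sample count matrix. These sizes mirror
the design conditions above while keeping a full run comfortable on a
laptop.

## Limitations

- NormFinder here is the variance-decomposition estimator described
  above; numerical output can differ from the original Excel add-in on
  the same data, although orderings agree in our simulations.
- BestKeeper's dispersion uses the MAD convention by default; users
  comparing against tools that report the classical SD should switch
  `sd_method`.
- The shortlisting thresholds reproduce a published workflow whose
  exact candidate counts depend on preprocessing choices upstream of
  the count matrix; every threshold is exposed precisely so such
  sensitivity can be explored.
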