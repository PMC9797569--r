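---
title: "codepmap: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codepmap: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codepmap)
```

This vignette documents the statistical models behind each stage of the
package, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions taken where more than one defensible choice existed.

## Co-dependency mapping

Two genes are co-dependent when knocking either out has correlated fitness
consequences across cell lines, suggesting shared function. The package
quantifies this with Spearman's rank correlation of gene-effect profiles:
it is invariant to monotone distortions of the effect-score scale and
robust to the heavy left tails that essential genes produce.

* **Correlation and p-value.** Average ranks over pairwise-complete
  observations; two-sided p from the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, with
  $p = 0$ at $|\rho| = 1$. The t approximation (rather than an exact
  permutation distribution) keeps a genome-wide scan tractable; the test
  suite holds it against a brute-force average-rank oracle and, for the
  null calibration, verifies that p-values are uniform at `n = 100` lines.
* **Pairwise-complete data and `min_pairs = 20`.** Released effect-score
  matrices have scattered missing entries; correlating over pairwise
  complete lines keeps every usable observation. Below 20 joint
  observations a rank correlation is too unstable to interpret, so such
  pairs are *flagged and excluded from FDR control* rather than assigned
  p = 1 — assigning dummy p-values would dilute the Benjamini–Hochberg
  correction with tests that were never performed. Constant profiles are
  excluded the same way.
* **FDR and classes.** q-values are BH over the retained tests of one
  query-gene scan; `codependent` means $\rho > 0,\ q < \alpha$ and
  `inverse` means $\rho < 0,\ q < \alpha$, with $\alpha = 0.1$ throughout
  the package.
* **Essentiality.** A line counts as dependent when the effect score is
  *strictly* below −0.5, and as a strong cytotoxic response strictly below
  −1.0; a gene is essential when its median effect is strictly below −0.5.
  Per-lineage summaries are restricted to lineages with at least 5 cell
  lines, below which a quartile summary is mostly noise.
* **Clustering.** Correlation heatmap ordering uses agglomerative
  clustering with average linkage on the $1-\rho$ distance. Average
  linkage is the conventional choice for correlation matrices (single
  linkage chains; complete linkage is brittle to single outlying pairs).
  Missing correlations enter the distance as 1 (uninformative), and
  asymmetry beyond $10^{-9}$ is an error rather than silently symmetrized.

## The percentile survival scan

For one gene in one cancer type, the scan asks whether some expression
cutoff separates patients with different progression-free survival. For
each percentile $k = 10..50$ the cohort is split into symmetric tails: the
low group holds samples at or below the $k$-th nearest-rank percentile
value, the high group those strictly above the $(100-k)$-th. Ties go to
the low/inner side, which makes the partition a deterministic function of
the expression values and makes $k = 50$ produce complementary halves
(odd-sized cohorts place the median sample in the low group). A
single-cutpoint variant (`mode = "single-cut"`, $k = 10..90$, low = at or
below the $k$-th percentile, high = rest) is provided for the alternative
reading of "stratify at the $k$-th percentile".

Exclusion rules, applied in order per percentile: a partition identical to
one already tested contributes nothing and is skipped (heavily tied
expression makes neighbouring percentiles collide); partitions in which
either group has fewer than `min_events = 10` events are dropped — the
rule counts *events*, not samples, since the log-rank statistic gets its
information from events. BH adjustment runs across the retained
percentiles of one scan (adjustment before best-split selection); pooling
across genes or cancer types instead is a caller-side choice — run the
scans and adjust the collected best p-values.

The log-rank statistic is the Mantel–Haenszel form over distinct event
times, computed by reverse cumulative counting over the distinct-time
grid, and the Kaplan–Meier estimator is the standard product limit;
both are validated against the `survival` package on random cohorts with
ties and censoring.

### The signed effect size

`log2_ratio()` reports a signed log2 effect of high versus low expression.
The default is the observed/expected event ratio
$\log_2\frac{O_h/E_h}{O_l/E_l}$ from the log-rank table. Its sign and
ordering track the hazard ratio, but its magnitude is *attenuated* when a
large fraction of the cohort experiences the event: risk-set depletion
pulls $E$ toward $O$. For an exponential model with hazard ratio 3 and
~80% events, the estimator converges near 2.4–2.5 rather than 3 — this is
a property of the estimator, not a bug, and it is asserted as a
characterization test in the suite. When a calibrated hazard-ratio
estimate is wanted, `method = "rate"` returns the person-time
incidence-rate ratio $\log_2\frac{O_h/T_h}{O_l/T_l}$, which is the
maximum-likelihood hazard-ratio estimate under exponential hazards and is
consistent at any effect size. Both forms are antisymmetric under group
swap and return `NA` (never a silent 0) when a group has no events, no
expected events, or no follow-up time. A median-survival-time ratio was
considered and rejected: under heavy censoring the group median is
frequently undefined.

## Pre-ranked GSEA

The enrichment score is the weighted Kolmogorov–Smirnov running sum: set
members add $|r|^w / \sum_{hits}|r|^w$, non-members subtract
$1/(N-n_{set})$, and ES is the extremum. `weight_exponent = 1` is the
pre-ranked convention; with $w = 0$ the statistic reduces to the classical
KS distance (a property the suite tests). The null distribution comes from
random gene sets of matching size drawn from the ranked universe — one
null ensemble per distinct set size, `n_perm = 1000` by default (a fixed
simple scheme; p-values are floored at $1/(n_{perm}+1)$, so claims beyond
that resolution are out of scope and `n_perm < 100` records a warning in
the result). NES divides ES by the mean same-sign null $|ES|$; the
rho-scaled NES multiplies by $\max|r|$ so that ranked lists with very
different correlation magnitudes (a strongly essential kinase versus a
weakly selective one) become comparable on one heatmap — scaling is a
positive monotone map, so it never reorders results within one list, and
p/q are untouched. BH runs across the sets of one ranked list; adjusting
across a matrix of lists is again a caller-side pooling decision. Ties in
the metric are broken by gene id so the ranking is identical across
platforms.

For drug signatures, GSEA runs on the *negated* expression–AUC
correlations, so positive enrichment always reads as
sensitivity-associated (low AUC = strong growth inhibition).

## Drug-response cleaning and signatures

* **Duplicates.** For each (drug, line) pair measured more than once, the
  AUC range is max − min over *all* replicates; a range strictly above 0.2
  discards the pair as irreproducible, otherwise the mean is used.
  Applying max − min to >2 replicates is the strictest reading of "range"
  and the one that degrades gracefully as replicate counts grow.
* **Coverage.** Drugs measured in strictly fewer than 70% of the cell
  lines present in the deduplicated table are dropped; the denominator is
  all lines in the dataset, not per-drug availability. Dedup followed by
  coverage filtering is idempotent.
* **Signatures.** Per-gene Spearman of expression versus AUC across
  matched lines, BH across genes; negative correlates are sensitivity
  genes, positive are resistance genes, both at $q < 0.1$.

## The synthetic-data generator

Each generator plants structure whose recovery has a known answer, with
one global seed fanned out to independent streams (`derive_seed()`), and
every generator restores the caller's RNG state.

* **Gene effects.** Genes in a module load on a shared per-line Gaussian
  factor: $x = \mu_g + \sigma(\ell f + \sqrt{1-\ell^2}\,\varepsilon)$, so
  the expected within-module Pearson correlation is exactly $\ell^2$ (for
  Gaussians the Spearman correlation is slightly smaller,
  $\tfrac{6}{\pi}\arcsin(\ell^2/2)$). Essential genes have mean −1.5
  versus 0, sd 0.3, giving clean separation across both essentiality
  thresholds.
* **Survival.** Exponential event times whose hazard is multiplied by the
  planted ratio strictly above the nearest-rank cutpoint-percentile
  expression value; baseline hazard 1/500 per day (median ~1 year below
  the cutpoint, a plausible progression-free scale). Censoring is
  exponential with per-subject rate proportional to the event hazard,
  $c_i = \tfrac{r}{1-r}\lambda_i$, so the expected censored fraction
  equals `censor_rate` (default 0.2) in both strata exactly. Exponential
  event and censoring times give a closed-form hazard-ratio truth, and the
  log-rank test is asymptotically optimal there, which makes recovery
  tests sharp.
* **Drugs.** Drugs in a cluster load on a shared per-line sensitivity
  factor with weight `effect_size`; AUC is affine in the latent value
  (0.55 ± 0.1, clipped to [0, 1]). Planted sensitivity/resistance genes
  couple their expression to the same factor with strength `effect_size`,
  negatively/positively. A `dup_fraction` of pairs is emitted twice, half
  with an AUC gap of 0.25 (beyond the dedup tolerance) and half with 0.05,
  so both dedup branches are exercised with known bookkeeping.
* **Gene sets.** A standard-normal ranking metric over the universe;
  members of the planted sets get their metric shifted upward, and the
  shifted metric is part of the truth object so enrichment recovery is
  directly testable.

What the generator does **not** emulate: the multimodal shape and
gene-specific variance of real effect-score distributions (only location
and scale); copy-number or mutation covariates; non-proportional hazards,
cure fractions or informative censoring; dose–response curve fitting
(AUC is taken as given); correlated gene-set overlap structure of curated
collections. Consequently, passing recovery tests demonstrates the
*machinery* is correct and calibrated — not that real consortium data meet
these models' assumptions.

## Validation strategy and problem sizes

The test suite works at sizes chosen to keep the full run in roughly a
minute while leaving recovery unambiguous: oracle cross-checks use 500
random small instances per statistic; null calibration uses 2,000
independent gene pairs, 200 survival scans at hazard ratio 1, 200 random
gene sets and ~300 null expression correlations; recovery uses modules of
8 genes at loading 0.8 over 500 lines, 50 survival scans at hazard ratio 3
and n = 500, and 25 end-to-end drug replicates at effect size 0.7 over 300
lines. `scripts/acceptance.R` recomputes the same quantities from scratch
for any seed. Degenerate inputs are errors or flagged exclusions, never
silent defaults: empty cohorts, single-group log-ranks, constant
correlation inputs, sets covering the whole ranked list, all-zero hit
weights, and coverage filters that would drop every drug all raise errors
with context.

## Known limitations

* The scan's best-split q-value is adjusted within one scan; selection
  across many genes and cancer types still needs a caller-level
  correction, exactly as with any optimal-cutpoint procedure.
* The O/E effect size understates large hazard ratios (see above); use
  `method = "rate"` when magnitude matters and the exponential
  approximation is tolerable.
* Permutation p-values are bounded below by $1/(n_{perm}+1)$; multiplicity
  over thousands of gene sets at stringent thresholds would need larger
  `n_perm` or an adaptive scheme.
* `codependency_map()` computes one query-gene scan on demand; an
  all-pairs correlation store for a 17k-gene genome is deliberately out of
  scope.
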