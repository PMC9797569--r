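# codepmap

Cross-omics machinery for characterizing gene families in cancer datasets:

* **Genetic co-dependency mapping** from CRISPR knockout gene-effect
  matrices (DepMap-style): genome-wide Spearman correlation of a query
  gene's fitness profile against every other gene, with
  Benjamini–Hochberg FDR control, essentiality profiling, top-k overlap
  comparisons and correlation-matrix clustering.
* **Iterative Kaplan–Meier log-rank scanning** of survival cohorts: every
  expression-percentile stratification from the 10th/90th tails inward is
  tested, non-unique and under-powered partitions are excluded, p-values are
  FDR-adjusted within the scan, and the lowest-p split is selected.
* **Pre-ranked GSEA** implemented from the weighted running-sum statistic,
  with permutation-normalized enrichment scores (NES), permutation p-values
  and the rho-scaled NES (NES × max|ρ|) that makes enrichment comparable
  across ranked lists of very different correlation magnitude.
* **Drug-response signatures** from GDSC-style AUC tables: duplicate
  resolution, coverage filtering, median-AUC ranking, drug–drug correlation
  clustering, per-gene expression–AUC sensitivity/resistance signatures, and
  GSEA on the inverted correlations.
* A **synthetic-data generator** that plants recoverable ground truth
  (co-dependent gene modules, survival cutpoints with known hazard ratios,
  drug clusters, expression-linked sensitivity genes, enriched gene sets),
  so the whole pipeline can be exercised and validated end to end without
  any consortium download.

It is aimed at computational biologists who want these analyses as tested,
reusable functions operating on plain CSV/TSV/GMT files rather than as
one-off scripts.

## The statistics at the core

**Co-dependency.** For a query gene *g* with effect-score profile *x_g*
across cell lines, every other gene *h* gets Spearman's ρ(x_g, x_h) over
pairwise-complete lines (minimum 20), a two-sided p-value from
*t = ρ√((n−2)/(1−ρ²))*, and a BH q-value over the scan. Genes with ρ > 0
and q < 0.1 are co-dependencies; ρ < 0 and q < 0.1 are inverse
co-dependencies. A gene is *essential* in a line when its effect score is
below −0.5 (strict), and a *strong cytotoxic effect* is below −1.0.

**Survival scan.** For percentile k = 10…50, the low group holds samples at
or below the k-th nearest-rank expression percentile and the high group
those strictly above the (100−k)-th; the two-group log-rank statistic is
χ² = (ΣO₁ⱼ−E₁ⱼ)² / ΣVⱼ with the Mantel–Haenszel terms
E₁ⱼ = n₁ⱼdⱼ/nⱼ and Vⱼ = n₁ⱼn₂ⱼdⱼ(nⱼ−dⱼ)/(nⱼ²(nⱼ−1)). Scans drop duplicate
partitions and groups with fewer than 10 events, BH-adjust the retained
p-values, and report the lowest-p split with a signed log2 effect size
(observed/expected event ratio by default; person-time incidence-rate ratio
as a consistent hazard-ratio estimate).

**GSEA.** Walking a list ranked by metric r, set members add
|r|^w / Σ_hits|r|^w and non-members subtract 1/(N−n_set); ES is the maximal
deviation, NES divides ES by the mean same-sign permutation |ES|, and
scaled NES multiplies by max|r|.

## Worked example

```r
library(codepmap)

# a gene-effect matrix with two planted 8-gene co-dependent modules
ge <- simulate_gene_effect(n_genes = 60, n_lines = 500, n_modules = 2,
                           module_size = 8, loading = 0.8,
                           essential_fraction = 0.1, seed = 42)
res <- codependency_map(ge$gem, "G0001")
head(res, 8)
```

```
   gene    rho        p        q n_pairs       class
1 G0004 0.6156 1.79e-53 1.06e-51     500 codependent
2 G0007 0.6065 1.51e-51 4.45e-50     500 codependent
3 G0003 0.5945 4.10e-49 8.05e-48     500 codependent
4 G0005 0.5898 3.51e-48 4.27e-47     500 codependent
5 G0006 0.5898 3.62e-48 4.27e-47     500 codependent
6 G0002 0.5860 1.97e-47 1.94e-46     500 codependent
7 G0008 0.5643 2.18e-43 1.84e-42     500 codependent
8 G0023 0.0806 7.17e-02 5.29e-01     500        none
```

The seven planted module partners of `G0001` (genes `G0002`–`G0008`) top
the ranking with ρ ≈ 0.6 — the expected within-module Spearman correlation
for a factor loading of 0.8 — and are the only co-dependency calls; the
first background gene sits at ρ = 0.08 with q = 0.53.

```r
# a survival cohort whose hazard triples above the 30th expression percentile
sv <- simulate_survival(n = 500, cutpoint_percentile = 30,
                        hazard_ratio = 3, seed = 42)
km_scan(sv$cohort)
```

```
km_scan (tails) over 41 percentiles, 41 retained
  best: k=41 p=7.41e-17 q=8.49e-16 log2_ratio=1.203
```

The scan flags a strongly significant stratification (q ≈ 8×10⁻¹⁶) near the
planted cutpoint; the positive log2 ratio says high expression associates
with worse outcome.

A full demonstration across every stage, with planted-truth recovery checks
and all result tables, is one call (or `Rscript inst/cli/codep.R demo --out
demo_out`):

```r
run_demo("demo_out", seed = 1)$checks
```

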