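#' Derive an independent sub-stream seed from a global seed
#'
#' One global integer seed fans out to per-generator streams; the derived
#' seed stays below 2^31.
#'
#' @param seed Integer global seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + stream * 9973 + 17) %%
               2147483647)
}

#' Simulate a gene-effect matrix with planted co-dependent modules
#'
#' Genes within a module share a per-cell-line latent Gaussian factor with
#' weight `loading` plus independent noise of weight sqrt(1 - loading^2), so
#' the expected pairwise Pearson correlation within a module is loading^2
#' (the Spearman correlation is slightly smaller, 6/pi * asin(loading^2 / 2)).
#' A fraction of genes is planted as essential with mean effect -1.5 (versus
#' 0 for the rest) and residual sd `noise_sd`, giving clean separation across
#' the -0.5 / -1.0 essentiality thresholds.
#'
#' @param n_genes,n_lines Matrix dimensions.
#' @param n_modules Number of planted co-dependent modules.
#' @param module_size Genes per module (`n_modules * module_size <= n_genes`).
#' @param loading Factor loading in \[0, 1); 0 plants no correlation
#'   structure.
#' @param essential_fraction Fraction of genes planted essential.
#' @param noise_sd Effect-score sd around the gene mean (default 0.3).
#' @param n_lineages Number of lineage labels assigned round-robin to cell
#'   lines (0 for no lineage metadata).
#' @param na_fraction Fraction of entries set missing at random (default 0).
#' @param seed Integer seed; the simulation is bit-reproducible given
#'   (parameters, seed).
#' @return A list: `gem` (a [gene_effect_matrix()]) and `truth` (module
#'   assignments, essential gene set, loading, seed).
#' @export
simulate_gene_effect <- function(n_genes, n_lines, n_modules = 0,
                                 module_size = 0, loading = 0,
                                 essential_fraction = 0, noise_sd = 0.3,
                                 n_lineages = 0, na_fraction = 0, seed = 1) {
  if (loading < 0 || loading >= 1)
    stop("loading must lie in [0, 1)")
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size must not exceed n_genes")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  lines <- sprintf("CL%04d", seq_len(n_lines))
  module <- rep(NA_integer_, n_genes)
  if (n_modules > 0 && module_size > 0)
    module[seq_len(n_modules * module_size)] <-
      rep(seq_len(n_modules), each = module_size)
  n_ess <- floor(essential_fraction * n_genes)
  essential <- if (n_ess > 0) sort(sample(genes, n_ess)) else character(0)
  mu <- ifelse(genes %in% essential, -1.5, 0)
  factors <- if (n_modules > 0)
    matrix(stats::rnorm(n_modules * n_lines), n_modules, n_lines) else NULL
  eps <- matrix(stats::rnorm(n_genes * n_lines), n_genes, n_lines)
  signal <- eps
  if (!is.null(factors) && loading > 0) {
    in_mod <- !is.na(module)
    signal[in_mod, ] <- loading * factors[module[in_mod], , drop = FALSE] +
      sqrt(1 - loading^2) * eps[in_mod, , drop = FALSE]
  }
  vals <- mu + noise_sd * signal
  dimnames(vals) <- list(genes, lines)
  if (na_fraction > 0) {
    drop <- sample(length(vals), floor(na_fraction * length(vals)))
    vals[drop] <- NA_real_
  }
  lineage <- NULL
  if (n_lineages > 0)
    lineage <- stats::setNames(
      sprintf("lineage%02d", rep_len(seq_len(n_lineages), n_lines)), lines)
  truth <- list(module_assignments = stats::setNames(module, genes),
                module_loading = loading, essential_genes = essential,
                seed = seed)
  list(gem = gene_effect_matrix(vals, lineage), truth = truth)
}

#' Simulate a survival cohort with a planted expression cutpoint
#'
#' Expression is Gaussian; samples with expression strictly above the
#' nearest-rank `cutpoint_percentile` value have their exponential event
#' hazard multiplied by `hazard_ratio`. Censoring is exponential with a
#' per-sample rate proportional to the event hazard
#' (c_i = censor_rate/(1-censor_rate) * lambda_i), so the expected censored
#' fraction equals `censor_rate` in both strata.
#'
#' @param n Cohort size (>= 20).
#' @param cutpoint_percentile Planted percentile in 10..90.
#' @param hazard_ratio Hazard multiplier (> 0) above the cutpoint.
#' @param baseline_hazard Event rate per day below the cutpoint (default
#'   1/500).
#' @param censor_rate Expected censored fraction in \[0, 1) (default 0.2;
#'   0 = all events observed).
#' @param cancer_type Label for the cohort.
#' @param seed Integer seed.
#' @return A list: `cohort` (a [survival_cohort()]) and `truth`
#'   (`cutpoint_percentile`, `cutpoint_value`, `hazard_ratio`, `seed`).
#' @export
simulate_survival <- function(n, cutpoint_percentile = 30, hazard_ratio = 3,
                              baseline_hazard = 1 / 500, censor_rate = 0.2,
                              cancer_type = "SYNTH", seed = 1) {
  if (n < 20) stop("cohort too small to scan (n < 20)")
  if (cutpoint_percentile < 10 || cutpoint_percentile > 90)
    stop("cutpoint_percentile must be in 10..90")
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  expr <- stats::rnorm(n, mean = 5, sd = 1.5)
  cut_val <- .nearest_rank_percentile(expr, cutpoint_percentile)
  high <- expr > cut_val
  lambda <- baseline_hazard * ifelse(high, hazard_ratio, 1)
  t_event <- stats::rexp(n, rate = lambda)
  if (censor_rate > 0) {
    t_cens <- stats::rexp(n, rate = censor_rate / (1 - censor_rate) * lambda)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  cohort <- survival_cohort(sprintf("S%04d", seq_len(n)), time, event, expr,
                            cancer_type)
  truth <- list(cutpoint_percentile = as.integer(cutpoint_percentile),
                cutpoint_value = cut_val, hazard_ratio = hazard_ratio,
                censor_rate = censor_rate, seed = seed)
  list(cohort = cohort, truth = truth)
}

#' Simulate a drug-response dataset with planted clusters and signatures
#'
#' Drugs in a planted cluster share a per-cell-line latent sensitivity factor
#' with weight `effect_size`; their AUC values are affine in that factor.
#' Planted sensitivity genes have expression negatively coupled to the
#' cluster factor (hence negatively correlated with those drugs' AUC) and
#' resistance genes positively, both with strength `effect_size`. A fraction
#' `dup_fraction` of (drug, line) pairs is emitted twice; half of the
#' duplicated pairs get an AUC gap of 0.25 (beyond the 0.2 dedup tolerance),
#' the other half a gap of 0.05.
#'
#' @param n_drugs,n_lines Table dimensions.
#' @param n_clusters Number of planted drug clusters.
#' @param cluster_size Drugs per cluster (default 4).
#' @param n_signature_genes Sensitivity genes (and as many resistance genes)
#'   planted per cluster.
#' @param n_genes Total genes in the accompanying expression matrix.
#' @param effect_size Coupling strength in \[0, 1\]; 0 plants nothing.
#' @param dup_fraction Fraction of (drug, line) pairs duplicated.
#' @param seed Integer seed.
#' @return A list: `raw` (a [drug_response_raw()]), `expr` (an
#'   [expression_matrix()]), `truth` (cluster assignment per drug,
#'   sensitivity/resistance genes per drug, duplicate bookkeeping, seed).
#' @export
simulate_drug_response <- function(n_drugs, n_lines, n_clusters = 0,
                                   cluster_size = 4, n_signature_genes = 0,
                                   n_genes = 100, effect_size = 0,
                                   dup_fraction = 0, seed = 1) {
  if (dup_fraction < 0 || dup_fraction > 1) stop("dup_fraction must be in [0, 1]")
  if (effect_size < 0 || effect_size > 1) stop("effect_size must be in [0, 1]")
  if (n_clusters * cluster_size > n_drugs)
    stop("n_clusters * cluster_size must not exceed n_drugs")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  drugs <- sprintf("DRUG%03d", seq_len(n_drugs))
  lines <- sprintf("CL%04d", seq_len(n_lines))
  genes <- sprintf("G%04d", seq_len(n_genes))
  cluster <- rep(NA_integer_, n_drugs)
  if (n_clusters > 0)
    cluster[seq_len(n_clusters * cluster_size)] <-
      rep(seq_len(n_clusters), each = cluster_size)
  factors <- if (n_clusters > 0)
    matrix(stats::rnorm(n_clusters * n_lines), n_clusters, n_lines) else NULL
  latent <- matrix(stats::rnorm(n_drugs * n_lines), n_drugs, n_lines)
  if (!is.null(factors) && effect_size > 0) {
    in_cl <- !is.na(cluster)
    latent[in_cl, ] <- effect_size * factors[cluster[in_cl], , drop = FALSE] +
      sqrt(1 - effect_size^2) * latent[in_cl, , drop = FALSE]
  }
  auc <- pmin(pmax(0.55 + 0.1 * latent, 0), 1)
  dimnames(auc) <- list(drugs, lines)

  # expression: background noise plus planted coupling to the cluster factors
  expr_vals <- matrix(stats::rnorm(n_genes * n_lines, mean = 6, sd = 1),
                      n_genes, n_lines, dimnames = list(genes, lines))
  sens_genes <- res_genes <- stats::setNames(vector("list", n_drugs), drugs)
  if (n_clusters > 0 && n_signature_genes > 0) {
    need <- 2 * n_signature_genes * n_clusters
    if (need > n_genes) stop("not enough genes for the requested signatures")
    pool <- matrix(seq_len(need), ncol = n_clusters)
    for (cl in seq_len(n_clusters)) {
      sg <- genes[pool[seq_len(n_signature_genes), cl]]
      rg <- genes[pool[n_signature_genes + seq_len(n_signature_genes), cl]]
      if (effect_size > 0) {
        f_row <- matrix(factors[cl, ], n_signature_genes, n_lines,
                        byrow = TRUE)
        expr_vals[sg, ] <- 6 - effect_size * f_row +
          sqrt(1 - effect_size^2) *
            matrix(stats::rnorm(n_signature_genes * n_lines),
                   n_signature_genes, n_lines)
        expr_vals[rg, ] <- 6 + effect_size * f_row +
          sqrt(1 - effect_size^2) *
            matrix(stats::rnorm(n_signature_genes * n_lines),
                   n_signature_genes, n_lines)
      }
      for (d in drugs[which(cluster == cl)]) {
        sens_genes[[d]] <- sg
        res_genes[[d]] <- rg
      }
    }
  }
  expr_vals <- pmax(expr_vals, 0)

  long <- data.frame(drug_id = rep(drugs, times = n_lines),
                     cell_line_id = rep(lines, each = n_drugs),
                     auc = as.vector(auc), stringsAsFactors = FALSE)
  n_dup <- floor(dup_fraction * nrow(long))
  dup_big <- dup_small <- integer(0)
  if (n_dup > 0) {
    dup_idx <- sort(sample(nrow(long), n_dup))
    half <- seq_len(ceiling(n_dup / 2))
    dup_big <- dup_idx[half]
    dup_small <- setdiff(dup_idx, dup_big)
    mk_dup <- function(idx, gap) {
      a <- long$auc[idx]
      data.frame(drug_id = long$drug_id[idx],
                 cell_line_id = long$cell_line_id[idx],
                 auc = ifelse(a <= 1 - gap, a + gap, a - gap),
                 stringsAsFactors = FALSE)
    }
    extra <- rbind(mk_dup(dup_big, 0.25), mk_dup(dup_small, 0.05))
    long <- rbind(long, extra)
  }
  truth <- list(cluster_assignments = stats::setNames(cluster, drugs),
                sensitivity_genes = sens_genes, resistance_genes = res_genes,
                effect_size = effect_size,
                dup_pairs_removed = paste(long$drug_id[dup_big],
                                          long$cell_line_id[dup_big]),
                dup_pairs_averaged = paste(long$drug_id[dup_small],
                                           long$cell_line_id[dup_small]),
                seed = seed)
  list(raw = drug_response_raw(long$drug_id, long$cell_line_id, long$auc),
       expr = expression_matrix(expr_vals), truth = truth)
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Draws a Gaussian ranking metric over the universe, samples `n_sets` sets
#' uniformly, and shifts the metric of every member of the first `n_enriched`
#' sets upward by `shift`, so those sets are enriched at the top of the
#' ranked list. The shifted metric is returned as part of the truth so
#' recovery can be tested directly.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set (< length of universe).
#' @param n_enriched Number of planted enriched sets.
#' @param shift Metric shift applied to members of enriched sets (0 = null).
#' @param seed Integer seed.
#' @return A list: `collection` (a [gene_set_collection()]) and `truth`
#'   (`enriched_sets`, `metric` named vector, `shift`, `seed`).
#' @export
simulate_genesets <- function(universe, n_sets, set_size, n_enriched = 0,
                              shift = 0, seed = 1) {
  universe <- as.character(universe)
  if (set_size >= length(universe)) stop("set_size must be < universe size")
  if (n_enriched > n_sets) stop("n_enriched must be <= n_sets")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  metric <- stats::setNames(stats::rnorm(length(universe)), universe)
  nm <- sprintf("SET%03d", seq_len(n_sets))
  sets <- stats::setNames(
    lapply(seq_len(n_sets), function(i) sample(universe, set_size)), nm)
  enriched <- if (n_enriched > 0) nm[seq_len(n_enriched)] else character(0)
  for (s in enriched) metric[sets[[s]]] <- metric[sets[[s]]] + shift
  truth <- list(enriched_sets = enriched, metric = metric, shift = shift,
                seed = seed)
  list(collection = gene_set_collection(sets), truth = truth)
}

#' Write a complete synthetic fixture directory
#'
#' Generates one instance of every input the pipeline consumes (gene-effect
#' matrix with lineage, clinical survival table, drug-response long table,
#' matched expression matrix, gene-set GMT) plus a `truth.json` recording the
#' planted structure, using independent streams derived from one seed.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global integer seed.
#' @return Invisibly, a list with the generated objects and their truths.
#' @export
write_fixture_dir <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ge <- simulate_gene_effect(n_genes = 120, n_lines = 300, n_modules = 3,
                             module_size = 8, loading = 0.8,
                             essential_fraction = 0.1, n_lineages = 4,
                             seed = derive_seed(seed, 1))
  sv <- simulate_survival(n = 400, cutpoint_percentile = 30, hazard_ratio = 3,
                          seed = derive_seed(seed, 2))
  dr <- simulate_drug_response(n_drugs = 12, n_lines = 300, n_clusters = 1,
                               cluster_size = 4, n_signature_genes = 8,
                               n_genes = 100, effect_size = 0.8,
                               dup_fraction = 0.1, seed = derive_seed(seed, 3))
  gs <- simulate_genesets(universe = sprintf("G%04d", 1:500), n_sets = 40,
                          set_size = 20, n_enriched = 3, shift = 2,
                          seed = derive_seed(seed, 4))
  write_matrix(ge$gem, file.path(outdir, "gene_effect.csv"))
  write_table(data.frame(cell_line = colnames(ge$gem$values),
                         lineage = unname(ge$gem$lineage)),
              file.path(outdir, "lineage.tsv"))
  write_table(data.frame(sample = sv$cohort$sample_id,
                         time_days = sv$cohort$time, event = sv$cohort$event,
                         cancer_type = sv$cohort$cancer_type,
                         expression = sv$cohort$expression),
              file.path(outdir, "clinical.tsv"))
  write_table(data.frame(drug = dr$raw$drug_id, cell_line = dr$raw$cell_line_id,
                         auc = dr$raw$auc),
              file.path(outdir, "drug_response.csv"))
  write_matrix(dr$expr, file.path(outdir, "expression.tsv"))
  write_gmt(gs$collection, file.path(outdir, "genesets.gmt"))
  truth <- list(gene_effect = ge$truth, survival = sv$truth,
                drug_response = dr$truth[setdiff(names(dr$truth),
                                                 c("sensitivity_genes",
                                                   "resistance_genes"))],
                drug_signatures = list(
                  sensitivity = dr$truth$sensitivity_genes,
                  resistance = dr$truth$resistance_genes),
                genesets = list(enriched_sets = gs$truth$enriched_sets,
                                shift = gs$truth$shift),
                seed = seed)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(list(gene_effect = ge, survival = sv, drug_response = dr,
                 genesets = gs))
}
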