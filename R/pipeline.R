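#' Default analysis configuration
#'
#' All fixed thresholds of the pipeline in one place: FDR level (0.1),
#' essentiality cutoffs (-0.5 / -1.0), duplicate-AUC tolerance (0.2),
#' drug coverage fraction (0.7), minimum events per survival group (10),
#' percentile scan range (10..50), minimum pairwise-complete observations
#' (20), gene-set size window (5..500) and permutation count.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    alpha = 0.1,
    essential_threshold = -0.5,
    strong_threshold = -1.0,
    dup_max_range = 0.2,
    coverage_min_frac = 0.7,
    min_events = 10,
    k_min = 10L,
    k_max = 50L,
    min_pairs = 20L,
    min_set_size = 5L,
    max_set_size = 500L,
    n_perm = 500L,
    seed = 1L
  ), class = "run_config")
}

.config_checks <- list(
  alpha = function(v) v > 0 && v < 1,
  essential_threshold = function(v) is.finite(v) && v < 0,
  strong_threshold = function(v) is.finite(v) && v < 0,
  dup_max_range = function(v) v >= 0 && v <= 1,
  coverage_min_frac = function(v) v >= 0 && v <= 1,
  min_events = function(v) v >= 0,
  k_min = function(v) v >= 10 && v <= 50,
  k_max = function(v) v >= 10 && v <= 50,
  min_pairs = function(v) v >= 3,
  min_set_size = function(v) v >= 1,
  max_set_size = function(v) v >= 1,
  n_perm = function(v) v >= 1,
  seed = function(v) is.finite(v)
)

#' Load a YAML run configuration
#'
#' Missing keys take their defaults; unknown keys and out-of-range values are
#' errors. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    v <- user[[k]]
    if (!is.numeric(v) || length(v) != 1 || !.config_checks[[k]](v))
      stop("config key out of range: ", k)
    cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else as.numeric(v)
  }
  if (cfg$k_min > cfg$k_max) stop("config key out of range: k_min > k_max")
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Rand index between two labelings of the same items
.rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

#' One-shot synthetic demonstration run
#'
#' Generates every synthetic input with planted truth, runs each analysis
#' stage (co-dependency map, essentiality profile, correlation clustering,
#' KM percentile scan, pre-ranked GSEA, drug-response cleaning, drug-drug
#' correlations, sensitivity signature, signature GSEA), writes all result
#' tables plus a machine-readable `report.json` to `outdir`, and checks the
#' recovered structure against the planted truth.
#'
#' @param outdir Writable output directory.
#' @param seed Global integer seed (fans out to per-stage streams).
#' @param config A `run_config` (default [default_config()]).
#' @return Invisibly, a list with `passed` (logical), `checks` (named logical
#'   vector), `report` (the full report list). `passed` is TRUE iff every
#'   recovery check succeeded.
#' @export
run_demo <- function(outdir, seed = 1, config = default_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  checks <- c()
  report <- list(seed = seed)

  fix <- write_fixture_dir(file.path(outdir, "fixtures"), seed = seed)

  # --- co-dependency on a planted module -------------------------------
  ge <- fix$gene_effect
  truth_mod <- ge$truth$module_assignments
  query <- names(truth_mod)[which(truth_mod == 1L)][1L]
  partners <- setdiff(names(truth_mod)[which(truth_mod == 1L)], query)
  cmap <- codependency_map(ge$gem, query, alpha = config$alpha,
                           min_pairs = config$min_pairs)
  write_table(cmap, file.path(outdir, "codependency_map.tsv"))
  called <- cmap$gene[!is.na(cmap$class) & cmap$class == "codependent"]
  checks["codependency_partners_recovered"] <- all(partners %in% called)
  report$codependency <- list(
    query = query, n_partners = length(partners),
    n_partners_called = sum(partners %in% called),
    n_codependent_calls = length(called))

  # --- essentiality ----------------------------------------------------
  prof <- essentiality_profile(ge$gem,
                               essential_threshold = config$essential_threshold,
                               strong_threshold = config$strong_threshold)
  write_table(prof$profile, file.path(outdir, "essentiality.tsv"))
  planted <- ge$truth$essential_genes
  called_ess <- prof$profile$gene[prof$profile$is_essential]
  checks["essential_genes_recovered"] <-
    all(planted %in% called_ess) && all(called_ess %in% planted)
  report$essentiality <- list(n_planted = length(planted),
                              n_called = length(called_ess),
                              n_recovered = sum(planted %in% called_ess))

  # --- module clustering -----------------------------------------------
  mod_genes <- names(truth_mod)[!is.na(truth_mod)]
  sub <- ge$gem$values[mod_genes, ]
  M <- stats::cor(t(sub), method = "spearman")
  cm <- cluster_correlation_matrix(M)
  k <- length(unique(truth_mod[mod_genes]))
  ri <- .rand_index(unname(cut_clusters(cm, k)[mod_genes]),
                    unname(truth_mod[mod_genes]))
  checks["module_clustering_rand"] <- ri >= 0.95
  report$clustering <- list(rand_index = ri, k = k)

  # --- survival scan ---------------------------------------------------
  sv <- fix$survival
  scan <- km_scan(sv$cohort, k_range = config$k_min:config$k_max,
                  min_events = config$min_events, alpha = config$alpha)
  write_table(scan$table, file.path(outdir, "km_scan.tsv"))
  best_k <- if (is.null(scan$best)) NA_integer_ else scan$best$percentile
  checks["survival_cutpoint_recovered"] <- !is.null(scan$best) &&
    scan$best$q < config$alpha &&
    abs(best_k - sv$truth$cutpoint_percentile) <= 10
  report$survival <- list(planted_cutpoint = sv$truth$cutpoint_percentile,
                          best_percentile = best_k,
                          best_q = if (is.null(scan$best)) NA else scan$best$q,
                          log2_ratio = if (is.null(scan$best)) NA
                                       else scan$best$log2_ratio)
  if (!is.null(scan$best)) {
    grDevices::png(file.path(outdir, "km_best_split.png"), 640, 480)
    plot_km(scan, main = sprintf("Best split (k = %d)", best_k))
    grDevices::dev.off()
  }

  # --- GSEA ------------------------------------------------------------
  gs <- fix$genesets
  enr <- gsea_preranked(ranked_list(gs$truth$metric), gs$collection,
                        n_perm = config$n_perm, seed = derive_seed(seed, 5),
                        min_set_size = config$min_set_size,
                        max_set_size = config$max_set_size)
  write_table(enr, file.path(outdir, "gsea.tsv"))
  planted_sets <- gs$truth$enriched_sets
  top <- enr$set[order(-enr$scaled_NES)][seq_along(planted_sets)]
  sig_sets <- enr$set[enr$q < config$alpha & enr$NES > 0]
  checks["enriched_sets_recovered"] <-
    setequal(top, planted_sets) && all(planted_sets %in% sig_sets)
  report$gsea <- list(planted = planted_sets, top_by_scaled_nes = top,
                      n_significant = length(sig_sets))

  # --- drug response ---------------------------------------------------
  dr <- fix$drug_response
  tab <- dedup_auc(dr$raw, max_range = config$dup_max_range)
  tab <- coverage_filter(tab, min_frac = config$coverage_min_frac)
  write_table(rank_drugs_by_median_auc(tab),
              file.path(outdir, "drug_ranking.tsv"))
  dcor <- drug_drug_correlations(tab, min_pairs = config$min_pairs)
  write_table(dcor$pairs, file.path(outdir, "drug_correlations.tsv"))
  cl_truth <- dr$truth$cluster_assignments
  cl_drugs <- names(cl_truth)[!is.na(cl_truth)]
  checks["drug_cluster_recovered"] <- all(
    dcor$most_similar[cl_drugs] %in% cl_drugs)
  report$drugs <- list(n_drugs_after_filter = nrow(tab$auc),
                       n_pairs_removed = tab$n_removed,
                       cluster_drugs = cl_drugs,
                       most_similar = as.list(dcor$most_similar[cl_drugs]))

  drug1 <- cl_drugs[1L]
  sig <- sensitivity_signature(tab, drug1, dr$expr, alpha = config$alpha,
                               min_pairs = config$min_pairs)
  write_table(sig, file.path(outdir, "sensitivity_signature.tsv"))
  planted_sens <- dr$truth$sensitivity_genes[[drug1]]
  called_sens <- sig$gene[!is.na(sig$class) & sig$class == "sensitivity"]
  checks["sensitivity_genes_recovered"] <- all(planted_sens %in% called_sens)
  report$signature <- list(drug = drug1, n_planted = length(planted_sens),
                           n_recovered = sum(planted_sens %in% called_sens))

  # signature GSEA: a set of the planted sensitivity genes must enrich
  sig_sets2 <- gene_set_collection(list(
    PLANTED_SENS = planted_sens,
    PLANTED_RES = dr$truth$resistance_genes[[drug1]],
    RANDOM_A = sprintf("G%04d", 41:60),
    RANDOM_B = sprintf("G%04d", 61:80),
    RANDOM_C = sprintf("G%04d", 81:100)))
  enr2 <- signature_gsea(sig, sig_sets2, n_perm = config$n_perm,
                         seed = derive_seed(seed, 6),
                         min_set_size = config$min_set_size)
  write_table(enr2, file.path(outdir, "signature_gsea.tsv"))
  checks["signature_gsea_recovered"] <-
    enr2$set[which.max(enr2$NES)] == "PLANTED_SENS" &&
    enr2$q[enr2$set == "PLANTED_SENS"] < config$alpha
  report$signature_gsea <- list(
    top_set = enr2$set[which.max(enr2$NES)],
    planted_sens_q = enr2$q[enr2$set == "PLANTED_SENS"])

  report$checks <- as.list(checks)
  report$passed <- all(checks)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE)
  invisible(list(passed = all(checks), checks = checks, report = report))
}
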