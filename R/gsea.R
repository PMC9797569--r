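#' Build a ranked gene list
#'
#' Orders genes by a ranking metric, descending, with ties broken by gene id
#' so the ordering is deterministic across platforms. The metric here is
#' typically a Spearman rho (co-dependency profile) or its negation (drug
#' sensitivity signature).
#'
#' @param metric Named numeric vector (names = gene ids, all unique).
#' @return A named numeric vector sorted for use by the enrichment functions,
#'   of class `ranked_list`.
#' @export
ranked_list <- function(metric) {
  if (is.null(names(metric)) || anyDuplicated(names(metric)))
    stop("metric must be named with unique gene ids")
  if (any(is.na(metric))) stop("metric must not contain missing values")
  ord <- order(-metric, names(metric))
  structure(metric[ord], class = "ranked_list")
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Walking down the ranked list, genes in the set increment the running sum
#' by |metric|^w normalized by the sum of |metric|^w over set members, and
#' genes outside the set decrement it by 1/(N - n_set). The enrichment score
#' is the running-sum value of maximal absolute deviation from zero; the
#' leading edge is the set members at or before the extremum (positive ES)
#' or at or after it (negative ES).
#'
#' @param ranked A [ranked_list()] (or a named metric vector, coerced).
#' @param geneset Character vector of gene ids.
#' @param weight_exponent Weight w on |metric| (default 1, the pre-ranked
#'   GSEA convention).
#' @param min_set_size Minimum set members present in the list (default 5);
#'   fewer is an error.
#' @return A list: `ES`, `running_sum` (length N), `leading_edge` (gene ids),
#'   `n_hits`.
#' @export
enrichment_score <- function(ranked, geneset, weight_exponent = 1,
                             min_set_size = 5) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  genes <- names(ranked)
  hit <- genes %in% geneset
  nh <- sum(hit)
  N <- length(genes)
  if (nh < min_set_size)
    stop(sprintf("only %d set genes in the ranked list (min %d)", nh,
                 min_set_size))
  if (nh == N) stop("gene set covers the entire ranked list")
  w <- abs(as.numeric(ranked))^weight_exponent
  denom <- sum(w[hit])
  if (denom == 0) stop("all hit metrics are zero; hit weights undefined")
  steps <- ifelse(hit, w / denom, -1 / (N - nh))
  rs <- cumsum(steps)
  i_max <- which.max(abs(rs))
  ES <- rs[i_max]
  leading <- if (ES >= 0) genes[seq_len(i_max)][hit[seq_len(i_max)]]
             else genes[i_max:N][hit[i_max:N]]
  list(ES = unname(ES), running_sum = unname(rs), leading_edge = leading,
       n_hits = nh)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Computes the running-sum enrichment score for every gene set, builds a
#' null distribution per set size by scoring `n_perm` random gene sets drawn
#' from the ranked universe, and reports for each set: the permutation
#' p-value within the sign class of its ES (with +1 correction, so
#' p >= 1/(n_same_sign+1)), the normalized enrichment score
#' NES = ES / mean(|null ES| of the same sign), the rho-scaled NES
#' (NES x max|metric|), and Benjamini-Hochberg q-values across all tested
#' sets. Deterministic for a fixed seed.
#'
#' @param ranked A [ranked_list()] (or named metric vector).
#' @param sets A [gene_set_collection()].
#' @param n_perm Number of gene-label permutations (default 1000; below 100 a
#'   warning is recorded in the result attribute `warnings`).
#' @param seed Integer seed for the permutation stream.
#' @param min_set_size,max_set_size Size filters on set overlap with the
#'   ranked universe (defaults 5 and 500).
#' @param weight_exponent Weight on |metric| (default 1).
#' @return A `data.frame` of class `enrichment_result`: one row per tested
#'   set with `set`, `size`, `ES`, `NES`, `scaled_NES`, `p_perm`, `q`,
#'   `leading_edge` (comma-separated), `n_perm_used`; attribute
#'   `max_abs_metric`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1,
                           min_set_size = 5, max_set_size = 500,
                           weight_exponent = 1) {
  if (!inherits(ranked, "ranked_list")) ranked <- ranked_list(ranked)
  stopifnot(inherits(sets, "gene_set_collection"))
  warnings <- character(0)
  if (n_perm < 100)
    warnings <- c(warnings, sprintf("n_perm = %d is below 100; permutation p-values are coarse", n_perm))
  genes <- names(ranked)
  sizes <- vapply(sets$sets, function(g) sum(genes %in% g), 0L)
  keep <- names(sets$sets)[sizes >= min_set_size & sizes <= max_set_size &
                             sizes < length(genes)]
  if (!length(keep)) stop("no gene set passes the size filters")
  obs <- lapply(keep, function(nm)
    enrichment_score(ranked, sets$sets[[nm]], weight_exponent, min_set_size))
  es <- vapply(obs, `[[`, 0, "ES")
  nh <- vapply(obs, `[[`, 0L, "n_hits")

  # one permutation null per distinct observed set size
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null_by_size <- list()
  for (sz in sort(unique(nh))) {
    null_by_size[[as.character(sz)]] <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(genes, sz), weight_exponent,
                       min_set_size = 0)$ES
    }, 0)
  }
  p_perm <- numeric(length(es))
  nes <- numeric(length(es))
  for (i in seq_along(es)) {
    null_es <- null_by_size[[as.character(nh[i])]]
    same <- null_es[sign(null_es) == sign(es[i]) | null_es == 0]
    if (!length(same)) same <- 0
    p_perm[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    m <- mean(abs(same[same != 0]))
    nes[i] <- if (is.finite(m) && m > 0) es[i] / m else NA_real_
  }
  max_abs <- max(abs(as.numeric(ranked)))
  out <- data.frame(
    set = keep, size = nh, ES = es, NES = nes, scaled_NES = nes * max_abs,
    p_perm = p_perm, q = bh_adjust(p_perm),
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","), ""),
    n_perm_used = n_perm, stringsAsFactors = FALSE)
  out <- out[order(-out$NES, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_abs_metric") <- max_abs
  attr(out, "warnings") <- warnings
  class(out) <- c("enrichment_result", "data.frame")
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Rescale normalized enrichment scores by the ranking metric's magnitude
#'
#' Multiplies each NES by max|metric|, so enrichment results from ranked
#' lists with very different correlation magnitudes (e.g. different kinases)
#' become comparable on one heatmap. p and q are unchanged.
#'
#' @param results An [gsea_preranked()] result.
#' @param metric The ranking metric values the results came from.
#' @return The result with `scaled_NES` recomputed; attribute
#'   `max_abs_metric` updated.
#' @export
scale_nes <- function(results, metric) {
  stopifnot(inherits(results, "enrichment_result"))
  if (!length(metric)) stop("metric must be non-empty")
  max_abs <- max(abs(as.numeric(metric)))
  results$scaled_NES <- results$NES * max_abs
  attr(results, "max_abs_metric") <- max_abs
  results
}
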