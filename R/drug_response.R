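#' Resolve duplicate drug/cell-line AUC entries
#'
#' For each (drug, cell line) pair measured more than once: if the AUC range
#' (max - min over all replicates) exceeds `max_range` the pair is removed
#' entirely as irreproducible; otherwise the replicates are averaged.
#' Singletons pass through unchanged.
#'
#' @param raw A [drug_response_raw()] long table.
#' @param max_range Maximum tolerated AUC range among duplicates (default
#'   0.2; a range strictly greater than this removes the pair).
#' @return A list of class `drug_response_table`: `auc` (drugs x lines
#'   matrix, `NA` where unmeasured or removed), `from_duplicates` (logical
#'   matrix, TRUE where the value is a replicate mean), `n_removed` (pairs
#'   dropped for excessive range).
#' @export
dedup_auc <- function(raw, max_range = 0.2) {
  stopifnot(inherits(raw, "drug_response_raw"))
  key <- paste(raw$drug_id, raw$cell_line_id, sep = "\r")
  agg_mean <- tapply(raw$auc, key, mean)
  agg_rng <- tapply(raw$auc, key, function(a) max(a) - min(a))
  agg_n <- tapply(raw$auc, key, length)
  drop <- agg_rng > max_range
  drugs <- sort(unique(raw$drug_id))
  lines <- sort(unique(raw$cell_line_id))
  auc <- matrix(NA_real_, length(drugs), length(lines),
                dimnames = list(drugs, lines))
  dup <- matrix(FALSE, length(drugs), length(lines),
                dimnames = list(drugs, lines))
  keys <- names(agg_mean)[!drop]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  di <- match(vapply(parts, `[[`, "", 1L), drugs)
  li <- match(vapply(parts, `[[`, "", 2L), lines)
  auc[cbind(di, li)] <- agg_mean[!drop]
  dup[cbind(di, li)] <- agg_n[!drop] > 1
  structure(list(auc = auc, from_duplicates = dup,
                 n_removed = sum(drop)),
            class = "drug_response_table")
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat("drug_response_table:", nrow(x$auc), "drugs x", ncol(x$auc),
      "cell lines;", sum(!is.na(x$auc)), "measured entries\n")
  invisible(x)
}

#' Drop drugs with insufficient cell-line coverage
#'
#' Removes drugs measured in strictly fewer than `min_frac` of the cell lines
#' present in the table (the denominator is all lines in the dataset after
#' deduplication).
#'
#' @param table A [dedup_auc()] result.
#' @param min_frac Minimum covered fraction (default 0.7; a drug at exactly
#'   70% coverage is kept).
#' @return The filtered `drug_response_table`.
#' @export
coverage_filter <- function(table, min_frac = 0.7) {
  stopifnot(inherits(table, "drug_response_table"))
  n_lines <- ncol(table$auc)
  frac <- rowSums(!is.na(table$auc)) / n_lines
  keep <- frac >= min_frac
  if (!any(keep)) stop("coverage filter removed every drug")
  table$auc <- table$auc[keep, , drop = FALSE]
  table$from_duplicates <- table$from_duplicates[keep, , drop = FALSE]
  table
}

#' Rank drugs by median AUC
#'
#' Ascending median AUC over non-missing lines: rank 1 = lowest median =
#' strongest anti-proliferative effect. Tied medians share the minimum rank;
#' the row order breaks ties by drug id.
#'
#' @param table A `drug_response_table`.
#' @return A data frame with columns `drug`, `median_auc`, `rank`, ordered by
#'   rank then drug id.
#' @export
rank_drugs_by_median_auc <- function(table) {
  stopifnot(inherits(table, "drug_response_table"))
  if (!nrow(table$auc)) stop("table has no drugs")
  med <- apply(table$auc, 1L, stats::median, na.rm = TRUE)
  out <- data.frame(drug = rownames(table$auc), median_auc = unname(med),
                    rank = rank(med, ties.method = "min"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise drug-drug AUC correlations with clustering
#'
#' Spearman correlation of AUC profiles for every drug pair over jointly
#' measured cell lines (minimum `min_pairs`), Benjamini-Hochberg adjustment
#' over the upper triangle (each pair tested once), average-linkage
#' clustering of the correlation matrix, and each drug's most similar
#' partner (highest rho).
#'
#' @param table A `drug_response_table` with at least 2 drugs.
#' @param min_pairs Minimum jointly measured lines per pair (default 20).
#' @return A list of class `drug_correlations`: `rho` (symmetric matrix,
#'   diagonal 1), `pairs` (data frame drug_a, drug_b, rho, p, q, n_pairs),
#'   `clustered` (a [cluster_correlation_matrix()] result), `most_similar`
#'   (named character vector).
#' @export
drug_drug_correlations <- function(table, min_pairs = 20) {
  stopifnot(inherits(table, "drug_response_table"))
  drugs <- rownames(table$auc)
  nd <- length(drugs)
  if (nd < 2) stop("need at least 2 drugs")
  rho <- matrix(NA_real_, nd, nd, dimnames = list(drugs, drugs))
  diag(rho) <- 1
  rows <- list()
  for (i in seq_len(nd - 1L)) for (j in (i + 1L):nd) {
    s <- spearman_with_p(table$auc[i, ], table$auc[j, ], min_pairs)
    rho[i, j] <- rho[j, i] <- s$rho
    rows[[length(rows) + 1L]] <- data.frame(
      drug_a = drugs[i], drug_b = drugs[j], rho = s$rho, p = s$p,
      q = NA_real_, n_pairs = s$n_pairs, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  ok <- !is.na(pairs$p)
  pairs$q[ok] <- bh_adjust(pairs$p[ok])
  clustered <- cluster_correlation_matrix(rho)
  most_similar <- vapply(seq_len(nd), function(i) {
    r <- rho[i, ]; r[i] <- NA
    if (all(is.na(r))) NA_character_ else names(which.max(r))
  }, "")
  names(most_similar) <- drugs
  structure(list(rho = rho, pairs = pairs, clustered = clustered,
                 most_similar = most_similar),
            class = "drug_correlations")
}

#' Expression-based sensitivity/resistance signature for one drug
#'
#' Correlates every gene's expression with the drug's AUC across matched cell
#' lines (Spearman, minimum `min_pairs`), adjusts by Benjamini-Hochberg
#' across genes, and classifies: `sensitivity` (rho < 0, q < alpha --
#' high expression marks responsive lines, since low AUC = growth
#' inhibition), `resistance` (rho > 0, q < alpha), else `none`.
#'
#' @param table A `drug_response_table`.
#' @param drug_id Drug present in the table.
#' @param expr An [expression_matrix()] whose samples are cell-line ids.
#' @param alpha FDR threshold (default 0.1).
#' @param min_pairs Minimum matched lines per gene (default 20).
#' @return A `data.frame` of class `sensitivity_signature` with columns
#'   `gene`, `rho`, `p`, `q`, `n_pairs`, `class`; attribute `drug_id`.
#' @export
sensitivity_signature <- function(table, drug_id, expr, alpha = 0.1,
                                  min_pairs = 20) {
  stopifnot(inherits(table, "drug_response_table"),
            inherits(expr, "expression_matrix"))
  if (!drug_id %in% rownames(table$auc))
    stop("drug not present (absent or filtered out): ", drug_id)
  shared <- intersect(colnames(table$auc), colnames(expr$values))
  if (length(shared) < min_pairs)
    stop(sprintf("only %d cell lines shared between AUC table and expression (min %d)",
                 length(shared), min_pairs))
  auc <- table$auc[drug_id, shared]
  genes <- rownames(expr$values)
  res <- lapply(genes, function(g)
    spearman_with_p(expr$values[g, shared], auc, min_pairs))
  out <- data.frame(
    gene = genes,
    rho = vapply(res, `[[`, 0, "rho"),
    p = vapply(res, `[[`, 0, "p"),
    q = NA_real_,
    n_pairs = vapply(res, `[[`, 0L, "n_pairs"),
    class = "none", stringsAsFactors = FALSE)
  ok <- vapply(res, `[[`, TRUE, "ok")
  out$q[ok] <- bh_adjust(out$p[ok])
  out$class[ok & out$rho < 0 & out$q < alpha] <- "sensitivity"
  out$class[ok & out$rho > 0 & out$q < alpha] <- "resistance"
  out$class[!ok] <- NA_character_
  out <- out[order(out$rho, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug_id") <- drug_id
  attr(out, "alpha") <- alpha
  class(out) <- c("sensitivity_signature", "data.frame")
  out
}

#' GSEA on a drug-sensitivity signature
#'
#' Runs pre-ranked GSEA on the *inverse* of the expression-AUC correlations
#' (ranking metric = -rho), so positive enrichment marks
#' sensitivity-associated gene sets and negative enrichment
#' resistance-associated sets.
#'
#' @param sig A [sensitivity_signature()].
#' @param sets A [gene_set_collection()].
#' @param n_perm,seed,min_set_size,max_set_size Passed to [gsea_preranked()].
#' @return An `enrichment_result` data frame.
#' @export
signature_gsea <- function(sig, sets, n_perm = 1000, seed = 1,
                           min_set_size = 5, max_set_size = 500) {
  stopifnot(inherits(sig, "sensitivity_signature"))
  keep <- !is.na(sig$rho)
  metric <- stats::setNames(-sig$rho[keep], sig$gene[keep])
  if (length(metric) < min_set_size)
    stop("signature has too few genes with defined correlations")
  gsea_preranked(ranked_list(metric), sets, n_perm = n_perm, seed = seed,
                 min_set_size = min_set_size, max_set_size = max_set_size)
}
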