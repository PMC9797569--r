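#' Spearman correlation with a t-approximation p-value
#'
#' Correlation of average ranks over pairwise-complete observations, with a
#' two-sided p-value from t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of
#' freedom; |rho| = 1 gives p = 0. Pairs with fewer than `min_pairs` complete
#' observations, or with a constant vector after dropping missing pairs, are
#' flagged (`ok = FALSE`) so callers can exclude them from FDR control rather
#' than treating them as null results.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @param min_pairs Minimum jointly non-missing observations (default 20).
#' @return A list with `rho`, `p`, `n_pairs`, `ok`, `reason`.
#' @export
spearman_with_p <- function(x, y, min_pairs = 20) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  n <- sum(keep)
  if (n < min_pairs)
    return(list(rho = NA_real_, p = NA_real_, n_pairs = n, ok = FALSE,
                reason = sprintf("n_pairs %d < min_pairs %d", n, min_pairs)))
  xs <- x[keep]; ys <- y[keep]
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n_pairs = n, ok = FALSE,
                reason = "constant vector"))
  rho <- stats::cor(rank(xs), rank(ys))
  list(rho = rho, p = .spearman_t_p(rho, n), n_pairs = n, ok = TRUE,
       reason = NA_character_)
}

.spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' q_(i) = min over j >= i of p_(j) * m / j on the sorted vector, mapped back
#' to input order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; no missing values.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide co-dependency map for one query gene
#'
#' Correlates the query gene's effect-score profile against every other gene
#' across cell lines (Spearman, pairwise-complete), adjusts the retained
#' p-values by Benjamini-Hochberg across the scan, and classifies each gene:
#' `codependent` (rho > 0, q < alpha), `inverse` (rho < 0, q < alpha), else
#' `none`. Genes with fewer than `min_pairs` joint observations or a constant
#' profile are excluded from FDR control and carry `NA` statistics.
#'
#' @param gem A [gene_effect_matrix()].
#' @param query_gene Gene id present in `gem`.
#' @param alpha FDR threshold for significance calls (default 0.1).
#' @param min_pairs Minimum jointly non-missing cell lines per pair.
#' @return A `data.frame` of class `codependency_result`, sorted by rho
#'   descending, with columns `gene`, `rho`, `p`, `q`, `n_pairs`, `class`,
#'   and attributes `query_gene` and `alpha`.
#' @export
codependency_map <- function(gem, query_gene, alpha = 0.1, min_pairs = 20) {
  stopifnot(inherits(gem, "gene_effect_matrix"))
  vals <- gem$values
  if (!query_gene %in% rownames(vals))
    stop("query gene not in matrix: ", query_gene)
  qx <- vals[query_gene, ]
  others <- setdiff(rownames(vals), query_gene)
  res <- lapply(others, function(g) spearman_with_p(qx, vals[g, ], min_pairs))
  out <- data.frame(
    gene = others,
    rho = vapply(res, `[[`, 0, "rho"),
    p = vapply(res, `[[`, 0, "p"),
    q = NA_real_,
    n_pairs = vapply(res, `[[`, 0L, "n_pairs"),
    class = "none",
    stringsAsFactors = FALSE)
  ok <- vapply(res, `[[`, TRUE, "ok")
  out$q[ok] <- bh_adjust(out$p[ok])
  out$class[ok & out$rho > 0 & out$q < alpha] <- "codependent"
  out$class[ok & out$rho < 0 & out$q < alpha] <- "inverse"
  out$class[!ok] <- NA_character_
  out <- out[order(-out$rho, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_gene") <- query_gene
  attr(out, "alpha") <- alpha
  class(out) <- c("codependency_result", "data.frame")
  out
}

#' Essentiality profile of a gene-effect matrix
#'
#' Per-gene median effect over non-missing cell lines, the fraction of lines
#' below the essentiality threshold (-0.5) and the strong-cytotoxicity
#' threshold (-1.0) -- both strict inequalities -- an essentiality call
#' (median strictly below -0.5), and the rank of the median (rank 1 = most
#' negative). When lineage metadata is present, per-(gene, lineage) medians
#' and quartiles are computed for lineages with at least `min_lines` lines.
#'
#' @param gem A [gene_effect_matrix()].
#' @param essential_threshold Effect score below which a line counts as
#'   dependent (default -0.5).
#' @param strong_threshold Effect score for a strong cytotoxic effect
#'   (default -1.0).
#' @param min_lines Minimum cell lines for a lineage summary (default 5).
#' @return A list of class `essentiality_profile`: `profile` (per-gene data
#'   frame) and `by_lineage` (per gene x lineage data frame, or NULL).
#' @export
essentiality_profile <- function(gem, essential_threshold = -0.5,
                                 strong_threshold = -1.0, min_lines = 5) {
  stopifnot(inherits(gem, "gene_effect_matrix"))
  vals <- gem$values
  med <- apply(vals, 1L, stats::median, na.rm = TRUE)
  frac_ess <- rowMeans(vals < essential_threshold, na.rm = TRUE)
  frac_strong <- rowMeans(vals < strong_threshold, na.rm = TRUE)
  prof <- data.frame(
    gene = rownames(vals),
    median_effect = unname(med),
    frac_essential_lines = unname(frac_ess),
    frac_strong_kill = unname(frac_strong),
    is_essential = unname(med < essential_threshold),
    rank_by_median = rank(med, ties.method = "first"),
    stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  by_lineage <- NULL
  if (!is.null(gem$lineage)) {
    tab <- table(gem$lineage[!is.na(gem$lineage)])
    keep <- names(tab)[tab >= min_lines]
    if (length(keep)) {
      rows <- lapply(keep, function(lin) {
        cols <- which(!is.na(gem$lineage) & gem$lineage == lin)
        qs <- t(apply(vals[, cols, drop = FALSE], 1L, stats::quantile,
                      probs = c(0.25, 0.5, 0.75), na.rm = TRUE))
        data.frame(gene = rownames(vals), lineage = lin, n_lines = length(cols),
                   q1 = unname(qs[, 1L]), median_effect = unname(qs[, 2L]),
                   q3 = unname(qs[, 3L]), stringsAsFactors = FALSE)
      })
      by_lineage <- do.call(rbind, rows)
      rownames(by_lineage) <- NULL
    }
  }
  structure(list(profile = prof, by_lineage = by_lineage),
            class = "essentiality_profile")
}

#' Overlap of top-k positive co-dependencies between two queries
#'
#' Takes the top `k` genes by positive rho from each co-dependency result
#' (ties broken by gene id) and partitions their union into A-only, B-only
#' and shared, as in a two-set Venn comparison. If a result has fewer than
#' `k` positive-rho genes, all of them are used and the effective k recorded.
#'
#' @param resA,resB [codependency_map()] results over the same gene universe.
#' @param k Number of top positive correlations to compare (default 500).
#' @return A list with `count_A_only`, `count_B_only`, `count_shared`,
#'   `shared_genes`, `k_A`, `k_B`.
#' @export
top_k_overlap <- function(resA, resB, k = 500) {
  topk <- function(res) {
    pos <- res[!is.na(res$rho) & res$rho > 0, , drop = FALSE]
    pos <- pos[order(-pos$rho, pos$gene), , drop = FALSE]
    utils::head(pos$gene, k)
  }
  a <- topk(resA); b <- topk(resB)
  shared <- intersect(a, b)
  list(count_A_only = length(setdiff(a, b)),
       count_B_only = length(setdiff(b, a)),
       count_shared = length(shared),
       shared_genes = sort(shared),
       k_A = length(a), k_B = length(b))
}

#' Cluster a symmetric correlation matrix
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' 1 - correlation distance, as used to order co-dependency and drug-drug
#' correlation heatmaps. Deterministic for a given input.
#'
#' @param M Symmetric numeric correlation matrix with dimnames; asymmetry
#'   beyond 1e-9 is an error. Missing entries are treated as correlation 0
#'   for the distance computation only.
#' @param linkage Agglomeration method (only `"average"` supported).
#' @return A list of class `clustered_matrix`: `matrix` (reordered), `order`
#'   (leaf order, a permutation of the original labels), `hclust` (the
#'   dendrogram as an [stats::hclust] object).
#' @export
cluster_correlation_matrix <- function(M, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  asym <- max(abs(M - t(M)), na.rm = TRUE)
  if (asym > 1e-9) stop("matrix is asymmetric (max |M - t(M)| = ", asym, ")")
  if (is.null(rownames(M))) rownames(M) <- colnames(M) <- seq_len(nrow(M))
  D <- 1 - M
  D[is.na(D)] <- 1
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  ord <- rownames(M)[hc$order]
  structure(list(matrix = M[ord, ord, drop = FALSE], order = ord, hclust = hc),
            class = "clustered_matrix")
}

#' Cut a clustered correlation matrix into k clusters
#'
#' @param cm A [cluster_correlation_matrix()] result.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(cm, k) {
  stopifnot(inherits(cm, "clustered_matrix"))
  stats::cutree(cm$hclust, k = k)
}
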