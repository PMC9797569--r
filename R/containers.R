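#' Construct a gene-effect matrix
#'
#' Container for CRISPR knockout fitness data: a genes x cell-lines matrix of
#' gene effect scores (more negative = more required for viability), with
#' optional lineage annotation per cell line. Scores are on the scale where
#' values below -0.5 indicate essentiality and below -1.0 a strong cytotoxic
#' effect.
#'
#' @param values Numeric matrix, genes in rows, cell lines in columns, with
#'   unique rownames (gene symbols) and colnames (cell-line ids). Missing
#'   entries are allowed and must be `NA`; non-missing entries must be finite.
#' @param lineage Optional named character vector mapping cell-line id to
#'   lineage label. Names must be a subset of `colnames(values)`.
#' @return An object of class `gene_effect_matrix`: a list with elements
#'   `values` and `lineage`.
#' @export
gene_effect_matrix <- function(values, lineage = NULL) {
  .check_id_matrix(values, "gene", "cell line")
  if (!is.null(lineage)) {
    if (is.null(names(lineage)))
      stop("`lineage` must be a named vector (names = cell-line ids)")
    bad <- setdiff(names(lineage), colnames(values))
    if (length(bad))
      stop("lineage entries for unknown cell lines: ",
           paste(utils::head(bad, 5), collapse = ", "))
    lineage <- as.character(lineage)[match(colnames(values), names(lineage))]
    names(lineage) <- colnames(values)
  }
  structure(list(values = values, lineage = lineage),
            class = "gene_effect_matrix")
}

#' Construct an expression matrix
#'
#' Genes x samples matrix of log2(TPM+1) expression values. Non-missing
#' entries must be finite and non-negative.
#'
#' @param values Numeric matrix with unique rownames (genes) and colnames
#'   (samples).
#' @param sample_group Optional named character vector mapping sample id to a
#'   group label (cancer type or lineage).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_group = NULL) {
  .check_id_matrix(values, "gene", "sample")
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative (log2(TPM+1) scale)")
  if (!is.null(sample_group)) {
    if (is.null(names(sample_group)))
      stop("`sample_group` must be a named vector")
    bad <- setdiff(names(sample_group), colnames(values))
    if (length(bad))
      stop("sample_group entries for unknown samples: ",
           paste(utils::head(bad, 5), collapse = ", "))
    sample_group <- as.character(sample_group)[
      match(colnames(values), names(sample_group))]
    names(sample_group) <- colnames(values)
  }
  structure(list(values = values, sample_group = sample_group),
            class = "expression_matrix")
}

.check_id_matrix <- function(values, row_what, col_what) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames and colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate ", row_what, " ids: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate ", col_what, " ids: ", paste(dup, collapse = ", "))
  if (any(is.infinite(values)))
    stop("non-missing entries must be finite")
  invisible(values)
}

#' @export
print.gene_effect_matrix <- function(x, ...) {
  cat("gene_effect_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "cell lines\n")
  if (!is.null(x$lineage))
    cat("  lineages:", length(unique(stats::na.omit(x$lineage))), "\n")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  invisible(x)
}

#' Construct a survival cohort
#'
#' Per-sample time-to-event data with a continuous expression covariate, the
#' substrate of the percentile-scan stratification.
#'
#' @param sample_id Character vector of unique sample ids.
#' @param time Numeric vector of follow-up times in days, non-negative.
#' @param event Event indicator, 0 (censored) or 1 (event).
#' @param expression Numeric expression value per sample.
#' @param cancer_type Cancer-type label (single value or per-sample vector).
#' @return A `data.frame` of class `survival_cohort` with columns
#'   `sample_id`, `time`, `event`, `expression`, `cancer_type`.
#' @export
survival_cohort <- function(sample_id, time, event, expression,
                            cancer_type = "unspecified") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (length(time) != n || length(event) != n || length(expression) != n)
    stop("sample_id, time, event and expression must have equal length")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(!is.finite(expression))) stop("expression must be finite")
  if (length(unique(expression)) < 2)
    stop("cohort needs at least 2 distinct expression values")
  out <- data.frame(sample_id = as.character(sample_id), time = as.numeric(time),
                    event = as.integer(event), expression = as.numeric(expression),
                    cancer_type = rep_len(as.character(cancer_type), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_cohort", "data.frame")
  out
}

#' Construct a gene-set collection
#'
#' @param sets Named list; each element a character vector of gene ids.
#'   Duplicate genes within a set are removed (first occurrence kept).
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) stop("`sets` must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- stats::setNames(
      as.character(descriptions)[match(names(sets), names(descriptions))],
      names(sets))
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets",
      if (length(x$sets)) paste0("(sizes ", min(lengths(x$sets)), "-",
                                 max(lengths(x$sets)), ")"), "\n")
  invisible(x)
}

#' Construct a raw drug-response table
#'
#' Long-format (drug, cell line, AUC) records as found in GDSC bulk downloads;
#' duplicated (drug, cell line) rows are permitted and are resolved by
#' [dedup_auc()].
#'
#' @param drug_id,cell_line_id Character vectors.
#' @param auc Numeric vector of areas under the dose-response curve in
#'   \[0, 1\]; lower AUC = stronger growth inhibition.
#' @return A `data.frame` of class `drug_response_raw`.
#' @export
drug_response_raw <- function(drug_id, cell_line_id, auc) {
  n <- length(drug_id)
  if (length(cell_line_id) != n || length(auc) != n)
    stop("drug_id, cell_line_id and auc must have equal length")
  if (any(!is.finite(auc)) || any(auc < 0) || any(auc > 1))
    stop("auc values must lie in [0, 1]")
  out <- data.frame(drug_id = as.character(drug_id),
                    cell_line_id = as.character(cell_line_id),
                    auc = as.numeric(auc), stringsAsFactors = FALSE)
  class(out) <- c("drug_response_raw", "data.frame")
  out
}
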