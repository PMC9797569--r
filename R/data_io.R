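#' Read a delimited gene-by-sample matrix
#'
#' Reads a CSV/TSV matrix in either orientation and returns it genes x samples.
#' The delimiter is chosen from the file extension (`.csv` comma, anything
#' else tab). The first column holds row ids; the header holds column ids.
#' DepMap-style identifiers of the form `"SYMBOL (entrezid)"` are reduced to
#' the symbol before `" ("`. Empty cells and `NA` are read as missing, never
#' as zero.
#'
#' @param path Path to a delimited text file with one header row and one id
#'   column.
#' @param orientation `"genes_by_samples"` if rows are genes (the default), or
#'   `"samples_by_genes"` if the file is transposed.
#' @param type Return type: `"effect"` for a [gene_effect_matrix()],
#'   `"expression"` for an [expression_matrix()], `"matrix"` for the bare
#'   numeric matrix.
#' @return A genes x samples matrix wrapped per `type`.
#' @export
read_matrix <- function(path,
                        orientation = c("genes_by_samples", "samples_by_genes"),
                        type = c("effect", "expression", "matrix")) {
  orientation <- match.arg(orientation)
  type <- match.arg(type)
  raw <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", row.names = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs an id column and >= 1 data column")
  row_ids <- strip_entrez_suffix(raw[[1L]])
  col_ids <- strip_entrez_suffix(colnames(raw)[-1L])
  vals <- matrix(NA_real_, nrow(raw), length(col_ids))
  for (j in seq_along(col_ids)) {
    cell <- raw[[j + 1L]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value %s at data row %d, column '%s'",
                   dQuote(cell[bad[1L]]), bad[1L], col_ids[j]))
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "samples_by_genes") vals <- t(vals)
  .assert_unique_ids(rownames(vals), "gene")
  .assert_unique_ids(colnames(vals), "sample")
  switch(type,
         effect = gene_effect_matrix(vals),
         expression = expression_matrix(vals),
         matrix = vals)
}

#' Strip a DepMap-style Entrez suffix from gene identifiers
#'
#' `"CDK9 (1025)"` becomes `"CDK9"`; identifiers without the `" (...)"`
#' suffix pass through unchanged.
#'
#' @param ids Character vector of identifiers.
#' @return Character vector of plain symbols.
#' @export
strip_entrez_suffix <- function(ids) sub(" \\(.*\\)$", "", as.character(ids))

.assert_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " ids: ", paste(dup, collapse = ", "))
  invisible(ids)
}

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a GMT gene-set file
#'
#' One set per tab-delimited line: name, description, then gene ids.
#' Duplicate genes within a set are removed, order preserved.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has %d field(s); need name, description, genes",
                 short[1L], lengths(fields)[short[1L]]))
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), nm)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a tabular result to delimited text
#'
#' Writes a data frame with a header row; the delimiter follows the file
#' extension (`.csv` comma, otherwise tab). Missing values are written as
#' `NA`. Numeric values are written with 15 significant digits so that a
#' round trip through [read_table()] reproduces them to better than 1e-12
#' relative error.
#'
#' @param result A data frame (any of the package's tabular results).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  out <- as.data.frame(result, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    out[[j]][is.na(result[[j]])] <- NA
  }
  utils::write.table(out, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a delimited table written by [write_table()]
#'
#' @param path Path to the file.
#' @return A data frame with column types inferred.
#' @export
read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    check.names = FALSE, quote = "\"", comment.char = "",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
}

#' Write a genes-by-samples matrix to delimited text
#'
#' First column `gene`, one column per sample; missing values as `NA`.
#'
#' @param mat Numeric matrix with dimnames, or a [gene_effect_matrix()] /
#'   [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(mat, path) {
  if (inherits(mat, c("gene_effect_matrix", "expression_matrix")))
    mat <- mat$values
  df <- data.frame(gene = rownames(mat), as.data.frame(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a long-format drug-response file
#'
#' Expects columns `drug`, `cell_line`, `auc` (GDSC bulk-download layout).
#'
#' @param path Path to a CSV/TSV file.
#' @return A [drug_response_raw()] table.
#' @export
read_drug_response <- function(path) {
  df <- read_table(path)
  need <- c("drug", "cell_line", "auc")
  if (!all(need %in% colnames(df)))
    stop("drug-response file needs columns: ", paste(need, collapse = ", "))
  drug_response_raw(df$drug, df$cell_line, df$auc)
}

#' Read a clinical outcome table
#'
#' Expects columns `sample`, `time_days`, `event`, `cancer_type` and an
#' `expression` column when the file was produced by the synthetic generator
#' or a merge with expression data.
#'
#' @param path Path to a TSV/CSV file.
#' @return A data frame; if an `expression` column is present, a
#'   [survival_cohort()].
#' @export
read_clinical <- function(path) {
  df <- read_table(path)
  need <- c("sample", "time_days", "event", "cancer_type")
  if (!all(need %in% colnames(df)))
    stop("clinical file needs columns: ", paste(need, collapse = ", "))
  if ("expression" %in% colnames(df))
    return(survival_cohort(df$sample, df$time_days, df$event, df$expression,
                           df$cancer_type))
  if (any(df$time_days < 0)) stop("time_days must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df
}
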