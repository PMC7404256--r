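# Two-group log fold-changes and concordant-gene selection: genes whose
# disease differential expression co-occurs with drug-induced differential
# expression are candidates for mediating the drug's effect.

#' Construct a differential-expression table
#'
#' Maps each gene to one signed log2 fold-change for a named condition
#' (a disease contrast or a drug perturbation).
#'
#' @param genes Character vector of gene identifiers (no duplicates).
#' @param logfc Numeric vector of finite log2 fold-changes.
#' @param condition Condition label.
#' @return An object of class `differential_table` with components `entries`
#'   (named numeric vector) and `condition`.
#' @export
differential_table <- function(genes, logfc, condition = "condition") {
  genes <- as.character(genes)
  logfc <- as.numeric(logfc)
  if (length(genes) != length(logfc)) stopf("genes and logfc length mismatch")
  if (anyDuplicated(genes)) stopf("each gene may appear only once")
  if (any(!is.finite(logfc))) stopf("logFC values must be finite")
  entries <- logfc
  names(entries) <- genes
  structure(
    list(entries = entries, condition = as.character(condition)[1L]),
    class = "differential_table"
  )
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf(
    "differential_table '%s': %d genes, %d up / %d down / %d unchanged\n",
    x$condition, length(x$entries),
    sum(x$entries > 0), sum(x$entries < 0), sum(x$entries == 0)
  ))
  invisible(x)
}

#' Read a two-column gene/logFC table
#'
#' Tab- or whitespace-delimited text with columns gene-id and logFC; an
#' optional header is auto-detected by a non-numeric second field.
#'
#' @param path File path.
#' @param condition Condition label for the resulting table.
#' @return A [differential_table()].
#' @export
read_differential_table <- function(path, condition = basename(path)) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("differential table is empty: %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (length(fields[[1L]]) >= 2L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))) {
    fields <- fields[-1L]
  }
  if (any(lengths(fields) != 2L)) stopf("malformed two-column table: %s", path)
  genes <- vapply(fields, `[[`, character(1L), 1L)
  logfc <- as.numeric(vapply(fields, `[[`, character(1L), 2L))
  differential_table(genes, logfc, condition)
}

#' Write a differential table as two-column TSV
#'
#' @param tab A [differential_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(tab, path) {
  stopifnot(inherits(tab, "differential_table"))
  writeLines(
    sprintf("%s\t%s", names(tab$entries), format_weight(tab$entries)),
    path
  )
  invisible(path)
}

#' Construct an expression matrix with case/control labels
#'
#' @param values Numeric matrix (log2 scale), genes in rows, samples in
#'   columns; both dimensions named.
#' @param labels Character vector of `"case"`/`"control"`, either named by
#'   sample or in column order.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must have gene row names and sample column names")
  }
  labels <- as.character(labels)
  if (!is.null(names(labels))) labels <- labels[colnames(values)]
  if (length(labels) != ncol(values) || anyNA(labels)) {
    stopf("labels must cover every sample")
  }
  if (!all(labels %in% c("case", "control"))) {
    stopf("labels must be 'case' or 'control'")
  }
  names(labels) <- colnames(values)
  structure(
    list(values = values, labels = labels),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%d case, %d control)\n",
    nrow(x$values), ncol(x$values),
    sum(x$labels == "case"), sum(x$labels == "control")
  ))
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is TSV with a header of sample identifiers and gene
#' identifiers in the first column. The labels file is two-column TSV
#' (sample-id, case|control).
#'
#' @param path Matrix file path.
#' @param labels_path Labels file path.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, labels_path) {
  values <- as.matrix(utils::read.table(
    path, header = TRUE, sep = "\t", row.names = 1L, check.names = FALSE
  ))
  lab <- utils::read.table(
    labels_path, header = FALSE, sep = "\t",
    col.names = c("sample", "label"), stringsAsFactors = FALSE
  )
  labels <- lab$label
  names(labels) <- lab$sample
  expression_matrix(values, labels)
}

#' Write an expression matrix and its labels
#'
#' @param expr An [expression_matrix()].
#' @param path,labels_path Output file paths.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, labels_path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(
    gene = rownames(expr$values), expr$values,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(
    sprintf("%s\t%s", names(expr$labels), expr$labels),
    labels_path
  )
  invisible(path)
}

#' Per-gene case vs control log fold-change
#'
#' For each gene, the difference of arithmetic mean expression between case
#' and control samples, on the log2 scale the matrix is stored in. This is
#' deliberately the plain two-group contrast; no moderated statistics.
#'
#' @param expr An [expression_matrix()] with at least one sample per group.
#' @param condition Condition label for the output table.
#' @return A [differential_table()].
#' @export
log_fold_change <- function(expr, condition = "contrast") {
  stopifnot(inherits(expr, "expression_matrix"))
  case <- expr$labels == "case"
  if (!any(case) || !all(case == (expr$labels == "case")) || all(case)) {
    if (!any(case) || !any(!case)) {
      stopf("need at least one case and one control sample")
    }
  }
  lfc <- rowMeans(expr$values[, case, drop = FALSE]) -
    rowMeans(expr$values[, !case, drop = FALSE])
  differential_table(rownames(expr$values), lfc, condition)
}

#' Select genes differentially expressed in both disease and drug response
#'
#' A gene is concordant when its absolute logFC exceeds `min_abs_logfc` in the
#' disease table and it is present with absolute logFC above the same
#' threshold in the drug table. Direction is not required to match; set
#' `require_opposite_sign = TRUE` for the stricter reversal hypothesis
#' (drug perturbation opposing the disease change).
#'
#' @param disease,drug [differential_table()] objects.
#' @param min_abs_logfc Strict lower bound on `|logFC|` (default 0, i.e. any
#'   nonzero change).
#' @param require_opposite_sign Additionally require opposite signs in the
#'   two tables (default `FALSE`).
#' @return Character vector of selected genes (sorted), a subset of the
#'   disease table's genes.
#' @export
select_concordant_genes <- function(disease, drug, min_abs_logfc = 0,
                                    require_opposite_sign = FALSE) {
  stopifnot(inherits(disease, "differential_table"))
  stopifnot(inherits(drug, "differential_table"))
  if (!is_scalar_number(min_abs_logfc) || min_abs_logfc < 0) {
    stopf("min_abs_logfc must be a non-negative number")
  }
  d <- disease$entries
  g <- drug$entries
  cand <- names(d)[abs(d) > min_abs_logfc]
  cand <- cand[cand %in% names(g)]
  cand <- cand[abs(g[cand]) > min_abs_logfc]
  if (require_opposite_sign) {
    cand <- cand[sign(d[cand]) * sign(g[cand]) < 0]
  }
  sort(cand)
}
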