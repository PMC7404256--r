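# Permutation significance of module edge weights and case/control
# differential co-expression analysis.

#' Sum of internal edge weights of a module
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes; every gene must be
#'   a node of the network.
#' @return Non-negative scalar; 0 when the module induces no edges.
#' @export
module_weight_sum <- function(net, module_genes) {
  stopifnot(inherits(net, "weighted_network"))
  module_genes <- unique(as.character(module_genes))
  missing <- setdiff(module_genes, net$nodes)
  if (length(missing)) {
    stopf("module gene(s) absent from the network: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  e <- net$edges
  sum(e$weight[e$from %in% module_genes & e$to %in% module_genes])
}

#' Permutation p-value for a module's internal weight
#'
#' Keeps the network topology fixed and, in each of `n_perm` rounds,
#' permutes the multiset of edge weights uniformly over the edges, then
#' recomputes the module's internal weight sum \eqn{S_m^{(n)}}. The p-value
#' is the fraction of rounds with \eqn{S_m \le S_m^{(n)}}; it can be exactly
#' zero. With `pseudocount = TRUE` the add-one estimate
#' `(count + 1) / (n_perm + 1)` is returned instead, which is never zero and
#' is the calibrated choice for uniformity checks.
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes.
#' @param n_perm Number of permutation rounds (>= 1; default 10000).
#' @param seed Integer seed; the permutations are deterministic given it.
#' @param pseudocount Use the add-one estimate (default `FALSE`).
#' @param module_id Optional label carried into the report.
#' @return An object of class `permutation_report`: a list with `module_id`,
#'   `s_obs`, `n_perm`, `count_ge` (rounds with permuted sum at least the
#'   observed), `p_value`, `seed`, and `pseudocount`.
#' @export
permutation_pvalue <- function(net, module_genes, n_perm = 10000L, seed = 1L,
                               pseudocount = FALSE, module_id = NA_character_) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is_scalar_count(n_perm)) stopf("n_perm must be a positive integer")
  module_genes <- unique(as.character(module_genes))
  s_obs <- module_weight_sum(net, module_genes)
  e <- net$edges
  internal <- which(e$from %in% module_genes & e$to %in% module_genes)
  if (length(internal) == 0L) {
    warnf("module has no internal edges; every permuted sum ties at 0 (p = 1)")
  }
  n_edges <- nrow(e)
  w <- e$weight
  count_ge <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_edges)
      s_perm <- sum(w[perm[internal]])
      if (s_obs <= s_perm) cnt <- cnt + 1L
    }
    cnt
  })
  p <- if (pseudocount) {
    (count_ge + 1) / (n_perm + 1)
  } else {
    count_ge / n_perm
  }
  structure(
    list(
      module_id = module_id,
      s_obs = s_obs,
      n_perm = as.integer(n_perm),
      count_ge = count_ge,
      p_value = p,
      seed = as.integer(seed),
      pseudocount = pseudocount
    ),
    class = "permutation_report"
  )
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "permutation_report%s: S_m = %.6g, count = %d / %d, p = %.4g%s\n",
    if (is.na(x$module_id)) "" else sprintf(" [%s]", x$module_id),
    x$s_obs, x$count_ge, x$n_perm, x$p_value,
    if (x$pseudocount) " (add-one)" else ""
  ))
  invisible(x)
}

#' Module co-expression network in one condition
#'
#' Computes Pearson correlations between all module gene pairs over the
#' chosen condition's samples and keeps pairs with `|r| >= r_threshold`.
#' Zero-variance genes yield no edges and a warning.
#'
#' @param expr An [expression_matrix()].
#' @param module_genes Character vector of module genes, all present in the
#'   matrix.
#' @param condition `"case"` or `"control"`; at least 3 samples required.
#' @param r_threshold Absolute correlation threshold (default 0.8).
#' @return An object of class `coexpression_network`: a list with `genes`,
#'   `condition`, `r_threshold`, and `edges` (data frame `from`, `to`, `r`
#'   with canonical pair order).
#' @export
coexpression_network <- function(expr, module_genes,
                                 condition = c("case", "control"),
                                 r_threshold = 0.8) {
  stopifnot(inherits(expr, "expression_matrix"))
  condition <- match.arg(condition)
  module_genes <- unique(as.character(module_genes))
  missing <- setdiff(module_genes, rownames(expr$values))
  if (length(missing)) {
    stopf("unknown gene(s): %s", paste(utils::head(missing, 5L), collapse = ", "))
  }
  cols <- names(expr$labels)[expr$labels == condition]
  if (length(cols) < 3L) {
    stopf("need at least 3 %s samples to compute correlations", condition)
  }
  vals <- expr$values[module_genes, cols, drop = FALSE]
  sds <- apply(vals, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warnf("constant gene(s) excluded from co-expression edges: %s",
          paste(module_genes[flat], collapse = ", "))
  }
  genes <- sort(module_genes)
  from <- character()
  to <- character()
  rr <- numeric()
  ok_genes <- module_genes[!flat]
  if (length(ok_genes) >= 2L) {
    cm <- stats::cor(t(vals[ok_genes, , drop = FALSE]))
    gs <- sort(ok_genes)
    cm <- cm[gs, gs, drop = FALSE]
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[ut]
    sel <- abs(r) >= r_threshold
    from <- gs[ut[sel, 1L]]
    to <- gs[ut[sel, 2L]]
    rr <- r[sel]
  }
  structure(
    list(
      genes = genes,
      condition = condition,
      r_threshold = r_threshold,
      edges = data.frame(from = from, to = to, r = rr,
                         stringsAsFactors = FALSE)
    ),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network (%s, |r| >= %g): %d genes, %d edges\n",
    x$condition, x$r_threshold, length(x$genes), nrow(x$edges)
  ))
  invisible(x)
}

#' Partition edges of two co-expression networks
#'
#' Splits the union of edges (as unordered gene pairs) into those present
#' only in `a`, only in `b`, and shared. Both networks must be over the same
#' gene set.
#'
#' @param a,b [coexpression_network()] objects on identical gene sets.
#' @return A list with data frames `only_in_a`, `only_in_b`, `shared`
#'   (columns `from`, `to`).
#' @export
differential_edges <- function(a, b) {
  stopifnot(inherits(a, "coexpression_network"))
  stopifnot(inherits(b, "coexpression_network"))
  if (!identical(a$genes, b$genes)) {
    stopf("the two networks must be over the same gene set")
  }
  key <- function(net) paste(net$edges$from, net$edges$to, sep = "\r")
  ka <- key(a)
  kb <- key(b)
  split_df <- function(keys) {
    if (length(keys) == 0L) {
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(keys, "\r", fixed = TRUE)
    df <- data.frame(
      from = vapply(parts, `[[`, character(1L), 1L),
      to = vapply(parts, `[[`, character(1L), 2L),
      stringsAsFactors = FALSE
    )
    df[order(df$from, df$to), , drop = FALSE]
  }
  list(
    only_in_a = split_df(setdiff(ka, kb)),
    only_in_b = split_df(setdiff(kb, ka)),
    shared = split_df(intersect(ka, kb))
  )
}
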