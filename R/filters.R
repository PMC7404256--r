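# Module-selection cascade: set-overlap measures, size and differential-
# expression containment filters, a local hypergeometric term-enrichment
# engine (offline stand-in for web enrichment services), term-overlap
# filters, first-order neighbor scoring with a sampling-based threshold, and
# pathway-overlap counting.

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; symmetric, 1 exactly when one set
#' contains the other.
#'
#' @param a,b Non-empty character vectors of gene identifiers.
#' @return Scalar in `[0, 1]`.
#' @examples
#' overlap_coefficient(c("3065", "142", "1786", "6597"),
#'                     c("3066", "3065", "5928", "2146", "6597")) # 0.5
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L) {
    stopf("overlap_coefficient is undefined for empty sets")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Are two modules overlapped?
#'
#' TRUE when the overlap coefficient is at least 2/3, compared in exact
#' integer arithmetic (3 |A intersect B| >= 2 min(|A|, |B|)) so the boundary
#' case is decided without floating error.
#'
#' @inheritParams overlap_coefficient
#' @return Logical scalar.
#' @export
is_overlapped <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L) {
    stopf("is_overlapped is undefined for empty sets")
  }
  3L * length(intersect(a, b)) >= 2L * min(length(a), length(b))
}

#' Keep modules with at least `min_size` genes
#'
#' @param modules List of `rhs_module` objects (or any lists with a `genes`
#'   field).
#' @param min_size Minimum gene count (default 3).
#' @return The qualifying modules, input order preserved.
#' @export
size_filter <- function(modules, min_size = 3L) {
  if (!is_scalar_count(min_size)) stopf("min_size must be a positive integer")
  Filter(function(m) length(m$genes) >= min_size, modules)
}

#' Keep modules containing concordant differentially expressed genes
#'
#' @param modules List of `rhs_module` objects.
#' @param concordant Named list of concordant gene sets, one per disease.
#' @param mode `"any"` (default): keep modules sharing at least one gene with
#'   the union of the sets; `"all"`: require a shared gene with every set.
#' @return The qualifying modules, input order preserved.
#' @export
deg_containment_filter <- function(modules, concordant,
                                   mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (!is.list(concordant)) concordant <- list(concordant)
  keep <- function(m) {
    if (mode == "any") {
      length(intersect(m$genes, unique(unlist(concordant)))) > 0L
    } else {
      all(vapply(concordant,
                 function(s) length(intersect(m$genes, s)) > 0L,
                 logical(1L)))
    }
  }
  Filter(keep, modules)
}

#' Construct a gene annotation map
#'
#' Stores gene-to-term assignments across namespaces (typically BP, MF, CC
#' and PATHWAY) over a background gene universe, the input of the local
#' enrichment engine.
#'
#' @param gene,namespace,term Character vectors of equal length: one
#'   annotation assignment per entry.
#' @param background Optional background gene universe; defaults to the
#'   annotated genes. Every annotated gene must be in the background.
#' @return An object of class `annotation_map` with components `entries`
#'   (data frame gene/namespace/term, deduplicated) and `background`.
#' @export
annotation_map <- function(gene, namespace, term, background = NULL) {
  gene <- as.character(gene)
  namespace <- as.character(namespace)
  term <- as.character(term)
  if (length(gene) != length(namespace) || length(gene) != length(term)) {
    stopf("gene, namespace and term must have equal length")
  }
  entries <- unique(data.frame(
    gene = gene, namespace = namespace, term = term,
    stringsAsFactors = FALSE
  ))
  background <- if (is.null(background)) {
    sort(unique(gene))
  } else {
    sort(unique(as.character(background)))
  }
  missing <- setdiff(entries$gene, background)
  if (length(missing)) {
    stopf("annotated gene(s) outside background: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  structure(
    list(entries = entries, background = background),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  ns <- table(x$entries$namespace)
  cat(sprintf(
    "annotation_map: %d assignments, %d background genes; namespaces: %s\n",
    nrow(x$entries), length(x$background),
    paste(sprintf("%s (%d)", names(ns), as.integer(ns)), collapse = ", ")
  ))
  invisible(x)
}

#' Read a three-column annotation TSV
#'
#' Columns: gene-id, namespace, term-id. An optional header line starting
#' with `gene` is skipped.
#'
#' @param path File path.
#' @param background Optional background gene universe.
#' @return An [annotation_map()].
#' @export
read_annotation <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("annotation file is empty: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1L]][1L]) == "gene") fields <- fields[-1L]
  if (any(lengths(fields) != 3L)) {
    stopf("annotation file must have exactly three tab-separated columns")
  }
  annotation_map(
    vapply(fields, `[[`, character(1L), 1L),
    vapply(fields, `[[`, character(1L), 2L),
    vapply(fields, `[[`, character(1L), 3L),
    background = background
  )
}

#' Write an annotation map as three-column TSV
#'
#' @param annotation An [annotation_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  e <- annotation$entries
  writeLines(sprintf("%s\t%s\t%s", e$gene, e$namespace, e$term), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path File path.
#' @return Named list of character vectors; descriptions are attached as
#'   attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stopf("malformed GMT line %d in %s", bad[1L], path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1L), 2L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stopf("every gene set must be named")
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For every term of the namespace hit by the query (overlap `k >= 1`),
#' computes the upper-tail hypergeometric probability of drawing at least
#' `k` of the term's `K` background genes in a query of size `n` from a
#' background of size `N`, and adjusts across the namespace's tested terms
#' by Benjamini-Hochberg.
#'
#' @param query Non-empty character vector of genes, all in the annotation
#'   background.
#' @param annotation An [annotation_map()].
#' @param namespace Namespace to test (e.g. `"BP"`).
#' @param alpha Significance level used to set the `significant` flag
#'   (default 0.05).
#' @return Data frame with columns `term`, `namespace`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adjusted`, `significant`, ordered by `p_raw`.
#' @export
enrich_terms <- function(query, annotation, namespace, alpha = 0.05) {
  stopifnot(inherits(annotation, "annotation_map"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stopf("query gene set is empty")
  outside <- setdiff(query, annotation$background)
  if (length(outside)) {
    stopf("query gene(s) outside the annotation background: %s",
          paste(utils::head(outside, 5L), collapse = ", "))
  }
  e <- annotation$entries[annotation$entries$namespace == namespace, ,
                          drop = FALSE]
  N <- length(annotation$background)
  n <- length(query)
  empty <- data.frame(
    term = character(), namespace = character(), k = integer(),
    K = integer(), n = integer(), N = integer(), p_raw = numeric(),
    p_adjusted = numeric(), significant = logical(),
    stringsAsFactors = FALSE
  )
  if (nrow(e) == 0L) return(empty)
  K_all <- table(e$term)
  hits <- e[e$gene %in% query, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  k_tab <- table(hits$term)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_all[terms])
  p_raw <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  out <- data.frame(
    term = terms, namespace = namespace, k = k, K = K, n = n, N = N,
    p_raw = p_raw, p_adjusted = p_adj, significant = p_adj <= alpha,
    stringsAsFactors = FALSE
  )
  out[order(out$p_raw, out$term), , drop = FALSE]
}

.significant_terms <- function(genes, annotation, namespace, alpha) {
  q <- intersect(unique(as.character(genes)), annotation$background)
  if (length(q) == 0L) return(character())
  res <- enrich_terms(q, annotation, namespace, alpha = alpha)
  res$term[res$significant]
}

#' Filter modules by enriched-term overlap with a reference term set
#'
#' For each module and each of the BP, MF and CC namespaces, enriches the
#' module's genes, takes the significant terms, and computes the proportion
#' of them shared with `reference_terms` (e.g. the terms enriched for the
#' drug's known targets). Modules whose proportion reaches `min_proportion`
#' in all three namespaces are kept; a module with no significant term in
#' some namespace has an undefined proportion there and is dropped with a
#' logged reason.
#'
#' @param modules List of `rhs_module` objects.
#' @param reference_terms Data frame with columns `namespace` and `term`
#'   (non-empty).
#' @param annotation An [annotation_map()].
#' @param min_proportion Per-namespace proportion threshold (default 0.2).
#' @param alpha Enrichment significance level (default 0.05).
#' @param namespaces Namespaces that must all qualify (default BP, MF, CC).
#' @return The kept modules, each with a `term_proportions` field added; a
#'   per-module report data frame is attached as attribute `"report"`.
#' @export
term_overlap_filter <- function(modules, reference_terms, annotation,
                                min_proportion = 0.2, alpha = 0.05,
                                namespaces = c("BP", "MF", "CC")) {
  if (!is.data.frame(reference_terms) ||
      !all(c("namespace", "term") %in% names(reference_terms)) ||
      nrow(reference_terms) == 0L) {
    stopf("reference_terms must be a non-empty data frame with columns namespace, term")
  }
  kept <- list()
  report <- list()
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    props <- stats::setNames(rep(NA_real_, length(namespaces)), namespaces)
    reason <- "kept"
    ok <- TRUE
    for (ns in namespaces) {
      sig <- .significant_terms(m$genes, annotation, ns, alpha)
      if (length(sig) == 0L) {
        ok <- FALSE
        reason <- sprintf("no significant %s terms (proportion undefined)", ns)
        message(sprintf("module %d dropped: %s", i, reason))
        break
      }
      ref <- reference_terms$term[reference_terms$namespace == ns]
      props[ns] <- length(intersect(sig, ref)) / length(sig)
      if (props[ns] < min_proportion) {
        ok <- FALSE
        reason <- sprintf("%s overlap proportion %.3g below %g",
                          ns, props[ns], min_proportion)
        break
      }
    }
    if (ok) {
      m$term_proportions <- props
      kept[[length(kept) + 1L]] <- m
    }
    report[[i]] <- data.frame(
      module = i, kept = ok, reason = reason,
      t(as.data.frame(props)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  rep_df <- do.call(rbind, report)
  rownames(rep_df) <- NULL
  attr(kept, "report") <- rep_df
  kept
}

#' Keep modules sharing enriched terms with every disease gene set
#'
#' A module is kept when, for each disease term list and each of the BP, MF
#' and CC namespaces, it has at least one significant enriched term in
#' common with the disease's terms.
#'
#' @param modules List of `rhs_module` objects.
#' @param disease_term_lists Named list (one per disease) of data frames
#'   with columns `namespace` and `term`.
#' @param annotation An [annotation_map()].
#' @param alpha Enrichment significance level (default 0.05).
#' @param namespaces Namespaces required (default BP, MF, CC).
#' @return The kept modules, input order preserved.
#' @export
disease_term_filter <- function(modules, disease_term_lists, annotation,
                                alpha = 0.05,
                                namespaces = c("BP", "MF", "CC")) {
  if (!is.list(disease_term_lists) || length(disease_term_lists) == 0L) {
    stopf("disease_term_lists must be a non-empty list")
  }
  keep <- function(m) {
    sig <- lapply(namespaces, function(ns) {
      .significant_terms(m$genes, annotation, ns, alpha)
    })
    names(sig) <- namespaces
    for (dl in disease_term_lists) {
      for (ns in namespaces) {
        ref <- dl$term[dl$namespace == ns]
        if (length(intersect(sig[[ns]], ref)) == 0L) return(FALSE)
      }
    }
    TRUE
  }
  Filter(keep, modules)
}

#' First-order neighbors of a module
#'
#' Genes outside the module with at least one edge into it.
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes.
#' @return Sorted character vector of neighbor genes.
#' @export
first_order_neighbors <- function(net, module_genes) {
  stopifnot(inherits(net, "weighted_network"))
  module_genes <- as.character(module_genes)
  e <- net$edges
  inc <- xor(e$from %in% module_genes, e$to %in% module_genes)
  nb <- c(e$from[inc], e$to[inc])
  sort(unique(setdiff(nb, module_genes)))
}

#' Connection strength between a module and an outside gene
#'
#' The sum of edge weights linking `gene` to the module's genes; absent
#' edges contribute 0.
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes.
#' @param gene A single gene outside the module.
#' @return Non-negative scalar score.
#' @export
neighbor_score <- function(net, module_genes, gene) {
  stopifnot(inherits(net, "weighted_network"))
  module_genes <- as.character(module_genes)
  gene <- as.character(gene)[1L]
  if (gene %in% module_genes) {
    stopf("gene %s is inside the module; the neighbor score is undefined", gene)
  }
  e <- net$edges
  sel <- (e$from == gene & e$to %in% module_genes) |
    (e$to == gene & e$from %in% module_genes)
  sum(e$weight[sel])
}

# Scores of all first-order neighbors at once (internal; one pass).
.neighbor_scores <- function(net, module_genes) {
  e <- net$edges
  fin <- e$from %in% module_genes
  tin <- e$to %in% module_genes
  inc <- xor(fin, tin)
  nb <- ifelse(fin[inc], e$to[inc], e$from[inc])
  w <- e$weight[inc]
  if (length(nb) == 0L) return(stats::setNames(numeric(), character()))
  s <- tapply(w, nb, sum)
  stats::setNames(as.numeric(s), names(s))
}

#' Sampling-based neighbor-score threshold
#'
#' Draws `n_samples` first-order neighbors of the module uniformly with
#' replacement, scores each by [neighbor_score()], sorts the sampled scores
#' in descending order, and returns the `rank`-th value. With the defaults
#' (one million draws, rank 50) this estimates an extreme upper quantile of
#' the neighbor-score distribution; neighbors scoring strictly above it are
#' considered conserved.
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes (must have at least
#'   one first-order neighbor).
#' @param n_samples Number of draws (default 1e6).
#' @param rank Rank of the descending-sorted sampled scores to return
#'   (default 50; must not exceed `n_samples`).
#' @param seed Integer seed; the result is deterministic given it.
#' @return Scalar threshold score.
#' @export
neighbor_threshold <- function(net, module_genes, n_samples = 1e6,
                               rank = 50L, seed = 1L) {
  if (!is_scalar_count(n_samples)) stopf("n_samples must be a positive integer")
  if (!is_scalar_count(rank)) stopf("rank must be a positive integer")
  if (rank > n_samples) stopf("rank (%d) exceeds n_samples (%d)",
                              as.integer(rank), as.integer(n_samples))
  scores <- .neighbor_scores(net, as.character(module_genes))
  if (length(scores) == 0L) {
    stopf("the module has no first-order neighbors")
  }
  with_seed(seed, {
    draws <- scores[sample.int(length(scores), n_samples, replace = TRUE)]
    unname(sort(draws, decreasing = TRUE)[rank])
  })
}

#' Neighbors scoring strictly above a threshold
#'
#' @param net A [weighted_network()].
#' @param module_genes Character vector of module genes.
#' @param threshold Score threshold (strict inequality).
#' @return Sorted character vector of conserved first-order neighbors.
#' @export
conserved_neighbors <- function(net, module_genes, threshold) {
  scores <- .neighbor_scores(net, as.character(module_genes))
  sort(names(scores)[scores > threshold])
}

#' Number of shared terms between two term sets
#'
#' @param terms_a,terms_b Character vectors of term identifiers (e.g. KEGG
#'   pathway ids).
#' @return Integer intersection size.
#' @export
pathway_overlap_count <- function(terms_a, terms_b) {
  length(intersect(unique(as.character(terms_a)),
                   unique(as.character(terms_b))))
}
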