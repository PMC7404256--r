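# Tissue-specific weighted networks: reading, normalization, top-edge
# selection, and assembly into a multilayer tensor over the common genes.

#' Construct a weighted undirected gene network
#'
#' A `weighted_network` stores an undirected graph over gene identifiers with
#' strictly positive edge weights. Gene pairs are kept in canonical order
#' (lexicographically smaller identifier first) and each unordered pair
#' appears at most once. Self-loops are not representable.
#'
#' @param from,to Character vectors of gene identifiers (one edge per entry).
#' @param weight Numeric vector of strictly positive edge weights.
#' @param nodes Optional character vector of node identifiers; defaults to the
#'   genes appearing in the edges. Extra identifiers are kept as isolated
#'   nodes.
#' @return An object of class `weighted_network` with components `nodes`
#'   (sorted character vector) and `edges` (data frame with columns `from`,
#'   `to`, `weight`, canonically ordered).
#' @examples
#' net <- weighted_network(c("1", "2"), c("2", "3"), c(0.5, 0.8))
#' net$edges
#' @export
weighted_network <- function(from, to, weight, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  weight <- as.numeric(weight)
  if (length(from) != length(to) || length(from) != length(weight)) {
    stopf("from, to and weight must have equal length")
  }
  if (any(from == to)) stopf("self-loops are not allowed in a weighted_network")
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stopf("all edge weights must be finite and strictly positive")
  }
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate undirected gene pairs in edge set")
  ord <- order(from, to, method = "radix")
  edges <- data.frame(
    from = from[ord], to = to[ord], weight = weight[ord],
    stringsAsFactors = FALSE
  )
  nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  structure(
    list(nodes = nodes, edges = edges),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(
    sprintf(
      "weighted_network: %d nodes, %d edges, weights in [%g, %g]\n",
      length(x$nodes), nrow(x$edges),
      if (nrow(x$edges)) min(x$edges$weight) else NA,
      if (nrow(x$edges)) max(x$edges$weight) else NA
    )
  )
  invisible(x)
}

#' Read a weighted edge list
#'
#' Parses whitespace- or tab-delimited text with columns gene1, gene2, weight
#' (the "top edges" dialect used by tissue-network downloads). An optional
#' header line is auto-detected by a non-numeric third field. Duplicate
#' undirected pairs are collapsed keeping the maximum weight; self-loops are
#' dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("edge-list file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("edge-list file is empty: %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  # Header detection: non-numeric third field on the first line.
  first <- fields[[1L]]
  if (length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3L])))) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
    if (length(fields) == 0L) stopf("edge-list file has only a header: %s", path)
  }
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- line_no[which(nf != 3L)[1L]]
    stopf("malformed edge-list line %d in %s: expected 3 fields", bad, path)
  }
  mat <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  w <- suppressWarnings(as.numeric(mat[, 3L]))
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0)) {
    bad <- line_no[which(is.na(w) | !is.finite(w) | w <= 0)[1L]]
    stopf("malformed edge-list line %d in %s: weight must be a positive number",
          bad, path)
  }
  from <- mat[, 1L]
  to <- mat[, 2L]
  loops <- from == to
  if (any(loops)) {
    warnf("dropped %d self-loop(s) while reading %s", sum(loops), path)
    from <- from[!loops]
    to <- to[!loops]
    w <- w[!loops]
  }
  if (length(from) == 0L) {
    return(weighted_network(character(), character(), numeric()))
  }
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  # Duplicate undirected pairs: keep the maximum weight.
  wmax <- tapply(w, key, max)
  uk <- names(wmax)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  weighted_network(
    vapply(parts, `[[`, character(1L), 1L),
    vapply(parts, `[[`, character(1L), 2L),
    as.numeric(wmax)
  )
}

#' Write a weighted edge list
#'
#' Writes the canonical tab-delimited three-column form read by
#' [read_edge_list()], at full precision so read/write round-trips are exact.
#'
#' @param net A [weighted_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  lines <- sprintf(
    "%s\t%s\t%s",
    net$edges$from, net$edges$to, format_weight(net$edges$weight)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Rescale edge weights to a target range
#'
#' Applies the affine map sending the minimum observed weight exactly to
#' `target_min` and the maximum to `target_max`:
#' \deqn{w' = (t_{max}-t_{min}) (w - w_{min}) / (w_{max}-w_{min}) + t_{min}}
#' Topology is unchanged. The map is strictly monotone, so weight ordering is
#' preserved.
#'
#' @param net A [weighted_network()] with at least two distinct weights.
#' @param target_min,target_max Bounds of the output range (defaults 0.1, 1).
#' @return A [weighted_network()] with rescaled weights.
#' @export
normalize_weights <- function(net, target_min = 0.1, target_max = 1.0) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is_scalar_number(target_min) || !is_scalar_number(target_max) ||
      target_min >= target_max) {
    stopf("target_min must be strictly less than target_max")
  }
  w <- net$edges$weight
  if (length(w) == 0L) stopf("cannot normalize a network with no edges")
  wmin <- min(w)
  wmax <- max(w)
  if (wmax == wmin) {
    stopf("all edge weights are equal; the affine rescaling is undefined")
  }
  w2 <- (target_max - target_min) * (w - wmin) / (wmax - wmin) + target_min
  out <- net
  out$edges$weight <- w2
  out
}

#' Keep the highest-weight fraction of edges
#'
#' Retains the `ceiling(fraction * |E|)` highest-weight edges. Ties at the
#' cutoff are broken deterministically by lexicographic order of the
#' canonically sorted gene-id pair. Nodes left without edges are dropped.
#'
#' @param net A non-empty [weighted_network()].
#' @param fraction Fraction of edges to keep, in (0, 1].
#' @return A [weighted_network()] on the retained edges only.
#' @export
select_top_edges <- function(net, fraction) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    stopf("fraction must lie in (0, 1]")
  }
  e <- net$edges
  if (nrow(e) == 0L) stopf("cannot select top edges of an empty network")
  n_keep <- as.integer(ceiling(fraction * nrow(e)))
  ord <- order(-e$weight, e$from, e$to, method = "radix")
  kept <- e[ord[seq_len(n_keep)], , drop = FALSE]
  weighted_network(kept$from, kept$to, kept$weight)
}

#' Construct a multilayer tensor
#'
#' Represents `m` undirected weighted layers over `n` shared genes as a dense
#' symmetric array `a[i, j, k]` with zero diagonal. The gene index is the
#' sorted intersection of the layers' node sets; each layer's edges are
#' restricted to the common genes, and absent edges are 0.
#'
#' @param nets List of two or more [weighted_network()] objects.
#' @param layer_names Character vector naming each layer.
#' @return An object of class `multilayer_tensor` with components `genes`,
#'   `layers`, and `a` (numeric array `n x n x m`).
#' @export
build_tensor <- function(nets, layer_names) {
  if (!is.list(nets) || length(nets) < 2L) {
    stopf("build_tensor needs at least two networks")
  }
  if (!all(vapply(nets, inherits, logical(1L), "weighted_network"))) {
    stopf("all elements of nets must be weighted_network objects")
  }
  layer_names <- as.character(layer_names)
  if (length(layer_names) != length(nets) || anyDuplicated(layer_names)) {
    stopf("layer_names must be unique and match the number of networks")
  }
  common <- Reduce(intersect, lapply(nets, `[[`, "nodes"))
  if (length(common) == 0L) {
    stopf("the networks share no genes; the tensor would be empty")
  }
  genes <- sort(common)
  n <- length(genes)
  m <- length(nets)
  a <- array(
    0, dim = c(n, n, m),
    dimnames = list(genes, genes, layer_names)
  )
  for (k in seq_len(m)) {
    e <- nets[[k]]$edges
    sel <- e$from %in% genes & e$to %in% genes
    if (!any(sel)) next
    i <- match(e$from[sel], genes)
    j <- match(e$to[sel], genes)
    w <- e$weight[sel]
    a[cbind(i, j, k)] <- w
    a[cbind(j, i, k)] <- w
  }
  new_multilayer_tensor(genes, layer_names, a)
}

new_multilayer_tensor <- function(genes, layers, a) {
  structure(
    list(genes = genes, layers = layers, a = a),
    class = "multilayer_tensor"
  )
}

#' @export
print.multilayer_tensor <- function(x, ...) {
  cat(
    sprintf(
      "multilayer_tensor: %d genes x %d layers (%s)\n",
      length(x$genes), length(x$layers), paste(x$layers, collapse = ", ")
    )
  )
  invisible(x)
}

#' Node degree histogram
#'
#' Counts nodes per degree bin. `bin_edges` defines intervals
#' `[e1, e2), [e2, e3), ..., [e_{B-1}, e_B]` (rightmost closed) and must cover
#' every observed degree. Isolated nodes have degree 0.
#'
#' @param net A [weighted_network()].
#' @param bin_edges Increasing integer vector of bin boundaries.
#' @return Named integer vector of node counts, one per bin; counts sum to the
#'   number of nodes.
#' @export
degree_distribution <- function(net, bin_edges) {
  stopifnot(inherits(net, "weighted_network"))
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stopf("bin_edges must be strictly increasing with at least two values")
  }
  labels <- sprintf(
    "[%g,%g%s", bin_edges[-length(bin_edges)], bin_edges[-1L],
    c(rep(")", length(bin_edges) - 2L), "]")
  )
  counts <- integer(length(bin_edges) - 1L)
  names(counts) <- labels
  if (length(net$nodes) == 0L) return(counts)
  deg <- table(factor(
    c(net$edges$from, net$edges$to),
    levels = net$nodes
  ))
  deg <- as.integer(deg)
  if (min(deg) < bin_edges[1L] || max(deg) > bin_edges[length(bin_edges)]) {
    stopf("bin_edges do not cover all observed degrees [%d, %d]",
          min(deg), max(deg))
  }
  idx <- findInterval(deg, bin_edges, rightmost.closed = TRUE)
  tab <- tabulate(idx, nbins = length(counts))
  counts[] <- tab
  counts
}

#' Write a multilayer tensor to a directory
#'
#' Sparse plain-text representation: `gene_index.txt`, `layer_index.txt`, and
#' one canonical edge list per layer. Weights are written at full precision,
#' so [read_tensor()] restores the array bit-exactly.
#'
#' @param tensor A `multilayer_tensor`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "multilayer_tensor"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(tensor$genes, file.path(dir, "gene_index.txt"))
  writeLines(tensor$layers, file.path(dir, "layer_index.txt"))
  n <- length(tensor$genes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (k in seq_along(tensor$layers)) {
    w <- tensor$a[, , k][ut]
    nz <- w > 0
    lines <- sprintf(
      "%s\t%s\t%s",
      tensor$genes[ut[nz, 1L]], tensor$genes[ut[nz, 2L]],
      format_weight(w[nz])
    )
    writeLines(lines, file.path(dir, paste0("layer_", k, ".edges.tsv")))
  }
  invisible(dir)
}

#' Read a multilayer tensor written by [write_tensor()]
#'
#' @param dir Directory produced by [write_tensor()].
#' @return A `multilayer_tensor`.
#' @export
read_tensor <- function(dir) {
  gi <- file.path(dir, "gene_index.txt")
  li <- file.path(dir, "layer_index.txt")
  if (!file.exists(gi) || !file.exists(li)) {
    stopf("%s is not a tensor directory (missing index files)", dir)
  }
  genes <- readLines(gi)
  layers <- readLines(li)
  n <- length(genes)
  m <- length(layers)
  a <- array(0, dim = c(n, n, m), dimnames = list(genes, genes, layers))
  for (k in seq_len(m)) {
    path <- file.path(dir, paste0("layer_", k, ".edges.tsv"))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) next
    parts <- strsplit(lines, "\t", fixed = TRUE)
    i <- match(vapply(parts, `[[`, character(1L), 1L), genes)
    j <- match(vapply(parts, `[[`, character(1L), 2L), genes)
    w <- as.numeric(vapply(parts, `[[`, character(1L), 3L))
    if (anyNA(i) || anyNA(j)) stopf("layer %d refers to unknown genes", k)
    a[cbind(i, j, k)] <- w
    a[cbind(j, i, k)] <- w
  }
  new_multilayer_tensor(genes, layers, a)
}
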