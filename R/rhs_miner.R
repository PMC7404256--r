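# Recurrent-heavy-subgraph mining. A module is a gene set S together with a
# layer set L of the multilayer tensor; its heaviness is the summed weight of
# all internal edges across the selected layers,
#   H(S, L) = (1/2) sum_{i,j in S, k in L} a_ijk,
# the objective the miner maximizes. The density threshold `t` is enforced
# cohesively: every selected layer's mean internal weight is >= t and every
# member gene's mean attachment weight to the rest of the module (over the
# selected layers) is >= t. Both bounds together imply the aggregate module
# density H / (choose(|S|,2) * |L|) >= t and keep weakly attached bystander
# genes out of otherwise heavy modules.

#' Heaviness of a gene set across layers
#'
#' The summed weight of all edges internal to `genes` in each layer of
#' `layers`, i.e. \eqn{\frac12 \sum_{i,j,k} a_{ijk} x_i x_j y_k} with
#' indicator vectors `x` over genes and `y` over layers.
#'
#' @param tensor A `multilayer_tensor` (see [build_tensor()]).
#' @param genes Character vector of genes (subset of the tensor's gene index).
#' @param layers Character vector of layer names.
#' @return Non-negative scalar heaviness. Empty gene or layer sets give 0.
#' @examples
#' nets <- list(
#'   weighted_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1)),
#'   weighted_network(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
#' )
#' tens <- build_tensor(nets, c("L1", "L2"))
#' heaviness(tens, c("a", "b", "c"), c("L1", "L2")) # 3 edges x 2 layers = 6
#' @export
heaviness <- function(tensor, genes, layers) {
  stopifnot(inherits(tensor, "multilayer_tensor"))
  genes <- as.character(genes)
  layers <- as.character(layers)
  if (!all(genes %in% tensor$genes)) {
    stopf("unknown gene(s): %s",
          paste(setdiff(genes, tensor$genes), collapse = ", "))
  }
  if (!all(layers %in% tensor$layers)) {
    stopf("unknown layer(s): %s",
          paste(setdiff(layers, tensor$layers), collapse = ", "))
  }
  if (length(genes) == 0L || length(layers) == 0L) return(0)
  idx <- match(genes, tensor$genes)
  lk <- match(layers, tensor$layers)
  sum(tensor$a[idx, idx, lk, drop = FALSE]) / 2
}

#' Mean internal edge weight of a module
#'
#' Heaviness divided by the number of internal edge slots,
#' `choose(|genes|, 2) * |layers|`. Equals 1 exactly when every internal edge
#' in every selected layer has weight 1.
#'
#' @inheritParams heaviness
#' @return Scalar density in `[0, 1]` for weights in `[0, 1]`.
#' @export
module_density <- function(tensor, genes, layers) {
  genes <- as.character(genes)
  layers <- as.character(layers)
  if (length(genes) < 2L) stopf("density needs at least two genes")
  if (length(layers) < 1L) stopf("density needs at least one layer")
  h <- heaviness(tensor, genes, layers)
  h / (choose(length(genes), 2) * length(layers))
}

#' Miner configuration
#'
#' Tunables for [mine_rhs()]. The density threshold applies layer-wise and
#' gene-wise (see the package vignette); 0.41 is the operating point selected
#' by the enrichment-ratio scan of [heaviness_scan()].
#'
#' @param density_threshold Minimum mean internal edge weight, in (0, 1].
#' @param min_size Minimum number of genes per module (>= 2; default 3).
#' @param max_modules Maximum number of modules to mine.
#' @param restarts Number of perturbed restarts per mining round beyond the
#'   deterministic uniform start.
#' @param max_iterations Relaxation iteration cap.
#' @param convergence_tol Relative heaviness change at which the relaxation
#'   is declared converged.
#' @param sparsity_exponent Exponent `p > 1` of the multiplicative gene
#'   update `x_i \propto g_i^{1/(p-1)}`; `p = 2` gives the plain power
#'   iteration.
#' @param seed Integer seed making the whole run deterministic.
#' @return An object of class `miner_config`.
#' @export
miner_config <- function(density_threshold = 0.41, min_size = 3L,
                         max_modules = 100L, restarts = 3L,
                         max_iterations = 200L, convergence_tol = 1e-6,
                         sparsity_exponent = 2, seed = 1L) {
  if (!is_scalar_number(density_threshold) ||
      density_threshold <= 0 || density_threshold > 1) {
    stopf("density_threshold must lie in (0, 1]")
  }
  if (!is_scalar_count(min_size) || min_size < 2) {
    stopf("min_size must be an integer >= 2")
  }
  if (!is_scalar_count(max_modules)) stopf("max_modules must be a positive integer")
  if (!is_scalar_number(restarts) || restarts < 0 || restarts != floor(restarts)) {
    stopf("restarts must be a non-negative integer")
  }
  if (!is_scalar_count(max_iterations)) stopf("max_iterations must be positive")
  if (!is_scalar_number(convergence_tol) || convergence_tol <= 0) {
    stopf("convergence_tol must be positive")
  }
  if (!is_scalar_number(sparsity_exponent) || sparsity_exponent <= 1) {
    stopf("sparsity_exponent must exceed 1")
  }
  if (!is_scalar_number(seed)) stopf("seed must be a number")
  structure(
    list(
      density_threshold = density_threshold,
      min_size = as.integer(min_size),
      max_modules = as.integer(max_modules),
      restarts = as.integer(restarts),
      max_iterations = as.integer(max_iterations),
      convergence_tol = convergence_tol,
      sparsity_exponent = sparsity_exponent,
      seed = as.integer(seed)
    ),
    class = "miner_config"
  )
}

#' @export
print.miner_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "miner_config: density_threshold=%g, min_size=%d, max_modules=%d,\n",
      "  restarts=%d, max_iterations=%d, convergence_tol=%g, ",
      "sparsity_exponent=%g, seed=%d\n"
    ),
    x$density_threshold, x$min_size, x$max_modules, x$restarts,
    x$max_iterations, x$convergence_tol, x$sparsity_exponent, x$seed
  ))
  invisible(x)
}

# Best feasible layer choice for a gene index set, under the cohesion rules.
# `mats` is the per-layer list of weight matrices. Returns NULL when no layer
# subset is feasible, else list(layers, heaviness, rowsum matrix).
.evaluate_gene_set <- function(mats, idx, threshold) {
  s <- length(idx)
  if (s < 2L) return(NULL)
  m <- length(mats)
  eps <- 1e-12
  hk <- numeric(m)
  rs <- matrix(0, s, m)
  for (k in seq_len(m)) {
    sub <- mats[[k]][idx, idx, drop = FALSE]
    rs[, k] <- rowSums(sub)
    hk[k] <- sum(rs[, k]) / 2
  }
  c2 <- s * (s - 1) / 2
  qual <- which(hk / c2 >= threshold - eps)
  if (length(qual) == 0L) return(NULL)
  q <- length(qual)
  # Candidate layer subsets, tried in decreasing total heaviness so the first
  # feasible one maximizes heaviness. Exhaustive for small q, else prefixes
  # of the heaviness ordering.
  if (q <= 8L) {
    combos <- lapply(seq_len(2^q - 1L), function(b) {
      qual[as.logical(bitwAnd(b, 2^(seq_len(q) - 1L)))]
    })
  } else {
    lord <- qual[order(-hk[qual], qual)]
    combos <- lapply(seq_len(q), function(l) lord[seq_len(l)])
  }
  tot <- vapply(combos, function(ls) sum(hk[ls]), numeric(1L))
  ord <- order(-tot, lengths(combos))
  for (ci in ord) {
    ls <- combos[[ci]]
    att <- rowSums(rs[, ls, drop = FALSE]) / ((s - 1) * length(ls))
    if (min(att) >= threshold - eps) {
      return(list(layers = sort(ls), heaviness = tot[ci]))
    }
  }
  NULL
}

# Continuous relaxation: alternate multiplicative updates of the gene vector
# x (x_i <- g_i^{1/(p-1)}, normalized, with g = sum_k y_k A_k x) and the
# layer vector y (y_k <- h_k / ||h||, h_k = x' A_k x), from a given start,
# until the relative change of the continuous heaviness falls below tol.
.relax <- function(mats, x0, config) {
  n <- length(x0)
  m <- length(mats)
  p_exp <- 1 / (config$sparsity_exponent - 1)
  x <- x0 / sqrt(sum(x0^2))
  y <- rep(1 / sqrt(m), m)
  h_prev <- -Inf
  for (it in seq_len(config$max_iterations)) {
    g <- numeric(n)
    for (k in seq_len(m)) g <- g + y[k] * as.numeric(mats[[k]] %*% x)
    if (max(g) <= 0) return(NULL)
    x <- g^p_exp
    x <- x / sqrt(sum(x^2))
    hk <- vapply(mats, function(A) as.numeric(crossprod(x, A %*% x)), numeric(1L))
    nh <- sqrt(sum(hk^2))
    if (nh <= 0) return(NULL)
    y <- hk / nh
    h_cont <- 0.5 * sum(y * hk)
    if (is.finite(h_prev) &&
        abs(h_cont - h_prev) <= config$convergence_tol * max(h_prev, 1e-300)) {
      break
    }
    h_prev <- h_cont
  }
  list(x = x, y = y)
}

# Discretize a converged relaxation: sweep prefixes of the x-ordering,
# keeping the feasible prefix of maximum heaviness, then polish with local
# add/remove/swap moves that increase heaviness while staying feasible.
.discretize <- function(mats, x, config) {
  n <- length(x)
  t <- config$density_threshold
  ord <- order(-x, seq_len(n))
  best <- NULL
  upper <- n
  for (s in seq.int(config$min_size, upper)) {
    idx <- ord[seq_len(s)]
    ev <- .evaluate_gene_set(mats, idx, t)
    if (!is.null(ev) &&
        (is.null(best) || ev$heaviness > best$heaviness + 1e-12)) {
      best <- list(idx = sort(idx), layers = ev$layers,
                   heaviness = ev$heaviness)
    }
  }
  if (is.null(best)) return(NULL)
  .refine(mats, best, config)
}

.refine <- function(mats, mod, config) {
  n <- nrow(mats[[1L]])
  t <- config$density_threshold
  for (iter in seq_len(100L)) {
    cur <- mod$idx
    s <- length(cur)
    outside <- setdiff(seq_len(n), cur)
    improved <- NULL
    consider <- function(idx) {
      ev <- .evaluate_gene_set(mats, idx, t)
      if (!is.null(ev) &&
          (ev$heaviness > mod$heaviness + 1e-9) &&
          (is.null(improved) || ev$heaviness > improved$heaviness + 1e-12)) {
        improved <<- list(idx = sort(idx), layers = ev$layers,
                          heaviness = ev$heaviness)
      }
    }
    for (g in outside) consider(c(cur, g))
    if (s > config$min_size) {
      for (g in cur) consider(setdiff(cur, g))
    }
    for (g_out in cur) {
      base <- setdiff(cur, g_out)
      for (g_in in outside) consider(c(base, g_in))
    }
    if (is.null(improved)) break
    mod <- improved
  }
  mod
}

.mine_round <- function(mats, config) {
  n <- nrow(mats[[1L]])
  best <- NULL
  for (r in 0:config$restarts) {
    x0 <- rep(1, n)
    relax_mats <- mats
    if (r > 0L) {
      # Restarts relax against a seeded diagonally reweighted tensor so the
      # fixed point (and hence the gene ordering handed to discretization)
      # differs between restarts; discretization and refinement always score
      # against the true tensor.
      d <- stats::runif(n, 0.5, 1.5)
      relax_mats <- lapply(mats, function(A) A * outer(d, d))
    }
    rel <- .relax(relax_mats, x0, config)
    if (is.null(rel)) next
    cand <- .discretize(mats, rel$x, config)
    if (!is.null(cand) &&
        (is.null(best) || cand$heaviness > best$heaviness + 1e-12)) {
      best <- cand
    }
  }
  best
}

#' Mine recurrent heavy subgraphs from a multilayer tensor
#'
#' Discovers modules iteratively: a seeded continuous relaxation of the
#' heaviness objective concentrates a gene vector on a heavy subgraph; the
#' relaxation is discretized by scanning prefixes of the gene ordering and
#' choosing the feasible (gene set, layer set) pair of maximum heaviness;
#' a local add/remove/swap search polishes the result; the accepted module's
#' internal edges are then masked in its layers and mining repeats. Feasible
#' means: at least `min_size` genes, every selected layer's mean internal
#' weight at least the density threshold, and every gene's mean attachment
#' weight to the rest of the module at least the threshold. Mining stops when
#' a round of `restarts + 1` seeded starts yields no feasible module, or
#' after `max_modules` modules. The run is deterministic given the seed.
#'
#' @param tensor A `multilayer_tensor` (see [build_tensor()]).
#' @param config A [miner_config()].
#' @return An object of class `rhs_fit`: a list with `modules` (list of
#'   `rhs_module` objects, in discovery order), `config`, `n_genes`,
#'   `n_layers`, and `call`. Each module has `genes`, `layers`, `heaviness`,
#'   `density`, and `rank`.
#' @seealso [heaviness()], [module_density()], [heaviness_scan()]
#' @export
mine_rhs <- function(tensor, config = miner_config()) {
  stopifnot(inherits(tensor, "multilayer_tensor"))
  stopifnot(inherits(config, "miner_config"))
  cl <- match.call()
  n <- length(tensor$genes)
  m <- length(tensor$layers)
  modules <- list()
  if (n >= max(2L, config$min_size)) {
    mats <- lapply(seq_len(m), function(k) tensor$a[, , k])
    with_seed(config$seed, {
      while (length(modules) < config$max_modules) {
        if (max(vapply(mats, max, numeric(1L))) <= 0) break
        mod <- .mine_round(mats, config)
        if (is.null(mod)) break
        rank <- length(modules) + 1L
        modules[[rank]] <- structure(
          list(
            genes = tensor$genes[mod$idx],
            layers = tensor$layers[mod$layers],
            heaviness = mod$heaviness,
            density = mod$heaviness /
              (choose(length(mod$idx), 2) * length(mod$layers)),
            rank = rank
          ),
          class = "rhs_module"
        )
        for (k in mod$layers) mats[[k]][mod$idx, mod$idx] <- 0
      }
    })
  }
  structure(
    list(
      modules = modules,
      config = config,
      n_genes = n,
      n_layers = m,
      call = cl
    ),
    class = "rhs_fit"
  )
}

#' @export
print.rhs_module <- function(x, ...) {
  cat(sprintf(
    "rhs_module (rank %d): %d genes on %d layer(s), heaviness %.4g, density %.4g\n",
    x$rank, length(x$genes), length(x$layers), x$heaviness, x$density
  ))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  cat("  layers:", paste(x$layers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.rhs_fit <- function(x, ...) {
  cat(sprintf(
    "rhs_fit: %d module(s) mined from %d genes x %d layers (threshold %g)\n",
    length(x$modules), x$n_genes, x$n_layers, x$config$density_threshold
  ))
  if (length(x$modules)) print(as.data.frame(x))
  invisible(x)
}

#' @export
summary.rhs_fit <- function(object, ...) {
  df <- as.data.frame(object)
  out <- list(
    n_modules = length(object$modules),
    config = object$config,
    table = df
  )
  class(out) <- "summary.rhs_fit"
  out
}

#' @export
print.summary.rhs_fit <- function(x, ...) {
  cat(sprintf("Mined %d recurrent heavy subgraph(s)\n", x$n_modules))
  print(x$config)
  if (x$n_modules > 0) print(x$table)
  invisible(x)
}

#' @export
as.data.frame.rhs_fit <- function(x, ...) {
  mods <- x$modules
  data.frame(
    rank = vapply(mods, `[[`, integer(1L), "rank"),
    n_genes = vapply(mods, function(m) length(m$genes), integer(1L)),
    n_layers = vapply(mods, function(m) length(m$layers), integer(1L)),
    heaviness = vapply(mods, `[[`, numeric(1L), "heaviness"),
    density = vapply(mods, `[[`, numeric(1L), "density"),
    genes = vapply(mods, function(m) paste(m$genes, collapse = ","),
                   character(1L)),
    layers = vapply(mods, function(m) paste(m$layers, collapse = ","),
                    character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Write mined modules as JSON lines and a TSV summary
#'
#' @param fit An `rhs_fit` from [mine_rhs()] (or a bare list of
#'   `rhs_module` objects).
#' @param jsonl_path Output path for one-JSON-object-per-line module records.
#' @param tsv_path Optional output path for a TSV summary table.
#' @return `jsonl_path`, invisibly.
#' @export
write_modules <- function(fit, jsonl_path, tsv_path = NULL) {
  mods <- if (inherits(fit, "rhs_fit")) fit$modules else fit
  lines <- vapply(mods, function(m) {
    jsonlite::toJSON(
      list(
        rank = m$rank, genes = m$genes, layers = m$layers,
        heaviness = m$heaviness, density = m$density
      ),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1L))
  writeLines(lines, jsonl_path)
  if (!is.null(tsv_path)) {
    df <- if (inherits(fit, "rhs_fit")) as.data.frame(fit) else {
      as.data.frame(structure(list(modules = mods), class = "rhs_fit"))
    }
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(jsonl_path)
}

#' Read modules written by [write_modules()]
#'
#' @param jsonl_path Path to the JSON-lines module file.
#' @return A list of `rhs_module` objects.
#' @export
read_modules <- function(jsonl_path) {
  lines <- readLines(jsonl_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    structure(
      list(
        genes = as.character(rec$genes),
        layers = as.character(rec$layers),
        heaviness = as.numeric(rec$heaviness),
        density = as.numeric(rec$density),
        rank = as.integer(rec$rank)
      ),
      class = "rhs_module"
    )
  })
}

#' Scan the density threshold and summarize module yield
#'
#' Re-mines the tensor at each threshold and reports the total module count
#' `Na`, the count `Ne` of modules with at least one significantly enriched
#' annotation term (at the enrichment engine's defaults), their ratio
#' `Rea = Ne / Na` (undefined, not zero, when `Na = 0`), and per layer the
#' number of genes shared between the union of mined modules and that layer's
#' drug-affected gene set. Used to choose the miner's operating threshold.
#'
#' @param tensor A `multilayer_tensor`.
#' @param thresholds Numeric vector of density thresholds in (0, 1].
#' @param annotation An [annotation_map()] for enrichment.
#' @param drug_gene_sets Named list (by layer name) of drug-affected gene
#'   sets.
#' @param config A [miner_config()]; its `density_threshold` is overridden at
#'   each scan point.
#' @param alpha Significance level for the enrichment calls (default 0.05).
#' @return A data frame with one row per threshold and columns `threshold`,
#'   `n_modules`, `n_enriched`, `ratio`, `ratio_defined`, and one
#'   `overlap_<layer>` column per drug gene set. The per-threshold `rhs_fit`
#'   objects are attached as attribute `"fits"`.
#' @export
heaviness_scan <- function(tensor, thresholds, annotation, drug_gene_sets,
                           config = miner_config(), alpha = 0.05) {
  stopifnot(inherits(tensor, "multilayer_tensor"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L ||
      any(thresholds <= 0) || any(thresholds > 1)) {
    stopf("thresholds must lie in (0, 1]")
  }
  stopifnot(inherits(annotation, "annotation_map"))
  fits <- vector("list", length(thresholds))
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    cfg <- config
    cfg$density_threshold <- thresholds[i]
    fit <- mine_rhs(tensor, cfg)
    fits[[i]] <- fit
    na <- length(fit$modules)
    ne <- sum(vapply(
      fit$modules,
      function(m) module_is_enriched(m$genes, annotation, alpha = alpha),
      logical(1L)
    ))
    all_genes <- unique(unlist(lapply(fit$modules, `[[`, "genes")))
    ov <- vapply(
      drug_gene_sets,
      function(s) length(intersect(all_genes, s)),
      integer(1L)
    )
    row <- data.frame(
      threshold = thresholds[i],
      n_modules = na,
      n_enriched = ne,
      ratio = if (na > 0) ne / na else NA_real_,
      ratio_defined = na > 0,
      stringsAsFactors = FALSE
    )
    for (nm in names(drug_gene_sets)) {
      row[[paste0("overlap_", nm)]] <- ov[[nm]]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Does a gene set have any significantly enriched term?
#'
#' Convenience wrapper over [enrich_terms()] across every namespace of the
#' annotation. Genes outside the annotation background are ignored; a gene
#' set entirely outside the background counts as not enriched.
#'
#' @param genes Character vector of genes.
#' @param annotation An [annotation_map()].
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Logical scalar.
#' @export
module_is_enriched <- function(genes, annotation, alpha = 0.05) {
  q <- intersect(genes, annotation$background)
  if (length(q) == 0L) return(FALSE)
  for (ns in unique(annotation$entries$namespace)) {
    res <- enrich_terms(q, annotation, ns, alpha = alpha)
    if (nrow(res) > 0 && any(res$p_adjusted <= alpha)) return(TRUE)
  }
  FALSE
}
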