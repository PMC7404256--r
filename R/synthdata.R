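# Synthetic inputs with the statistical structure the pipeline assumes:
# multilayer networks with planted heavy modules over a noisy background,
# concordant logFC tables, case-only co-expression, planted-term annotation
# maps, and the packaged 26-module candidate fixture.

#' Simulate a multilayer network with planted heavy modules
#'
#' Background edges appear independently with probability `edge_prob` and
#' uniform weights in `background_range` on every layer. Each planted module
#' is a complete subgraph with uniform weights in its `internal_range` on its
#' designated layers. Planted ranges must lie strictly above the background
#' range unless `allow_weak = TRUE`; planted gene sets are disjoint unless
#' `allow_overlap = TRUE`. Deterministic given `seed`.
#'
#' @param n_genes,n_layers Tensor dimensions.
#' @param background_range Length-2 numeric, background weight range within
#'   (0, 1].
#' @param edge_prob Background edge probability.
#' @param planted List of planted-module descriptors, each a list with
#'   `size` (gene count), `layers` (integer layer indices), and
#'   `internal_range` (length-2 numeric within (0, 1]).
#' @param seed Integer seed.
#' @param allow_weak Permit planted ranges at or below the background range.
#' @param allow_overlap Permit overlapping planted gene sets.
#' @return A list with `tensor` (a `multilayer_tensor`) and `truth` (class
#'   `planted_truth`: planted gene/layer sets and the generator settings).
#' @export
simulate_multilayer <- function(n_genes, n_layers,
                                background_range = c(0.05, 0.2),
                                edge_prob = 0.1,
                                planted = list(), seed = 1L,
                                allow_weak = FALSE, allow_overlap = FALSE) {
  if (!is_scalar_count(n_genes) || !is_scalar_count(n_layers)) {
    stopf("n_genes and n_layers must be positive integers")
  }
  check_range <- function(r, what) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L] ||
        r[1L] <= 0 || r[2L] > 1) {
      stopf("%s must be an increasing range within (0, 1]", what)
    }
  }
  check_range(background_range, "background_range")
  if (!is_scalar_number(edge_prob) || edge_prob < 0 || edge_prob > 1) {
    stopf("edge_prob must lie in [0, 1]")
  }
  for (pm in planted) {
    check_range(pm$internal_range, "internal_range")
    if (!is_scalar_count(pm$size) || pm$size > n_genes) {
      stopf("planted size must be a positive integer <= n_genes")
    }
    if (any(pm$layers < 1L) || any(pm$layers > n_layers)) {
      stopf("planted layers out of range")
    }
    if (!allow_weak && pm$internal_range[1L] <= background_range[2L]) {
      stopf(paste0(
        "planted internal_range must lie strictly above background_range; ",
        "set allow_weak = TRUE to permit weak modules"
      ))
    }
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  layers <- sprintf("L%d", seq_len(n_layers))
  a <- array(0, dim = c(n_genes, n_genes, n_layers),
             dimnames = list(genes, genes, layers))
  truth_modules <- vector("list", length(planted))
  with_seed(seed, {
    # Planted gene sets drawn without replacement from the gene index.
    taken <- integer()
    for (i in seq_along(planted)) {
      pm <- planted[[i]]
      pool <- if (allow_overlap) seq_len(n_genes) else setdiff(seq_len(n_genes), taken)
      if (length(pool) < pm$size) stopf("not enough genes for disjoint planted modules")
      gi <- sort(sample(pool, pm$size))
      taken <- union(taken, gi)
      truth_modules[[i]] <- list(
        genes = genes[gi],
        layers = layers[pm$layers],
        internal_range = pm$internal_range,
        gene_idx = gi
      )
    }
    ut <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    for (k in seq_len(n_layers)) {
      present <- stats::runif(nrow(ut)) < edge_prob
      w <- numeric(nrow(ut))
      w[present] <- stats::runif(sum(present),
                                 background_range[1L], background_range[2L])
      lay <- matrix(0, n_genes, n_genes)
      lay[ut] <- w
      for (i in seq_along(planted)) {
        pm <- planted[[i]]
        if (!(k %in% pm$layers)) next
        gi <- truth_modules[[i]]$gene_idx
        put <- ut[ut[, 1L] %in% gi & ut[, 2L] %in% gi, , drop = FALSE]
        lay[put] <- stats::runif(nrow(put),
                                 pm$internal_range[1L], pm$internal_range[2L])
      }
      a[, , k] <- lay + t(lay)
    }
  })
  truth <- structure(
    list(
      modules = lapply(truth_modules, function(tm) tm[c("genes", "layers",
                                                        "internal_range")]),
      background_range = background_range,
      edge_prob = edge_prob,
      n_genes = n_genes,
      n_layers = n_layers,
      seed = as.integer(seed)
    ),
    class = "planted_truth"
  )
  list(tensor = new_multilayer_tensor(genes, layers, a), truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "planted_truth: %d module(s) in %d genes x %d layers (seed %d)\n",
    length(x$modules), x$n_genes, x$n_layers, x$seed
  ))
  invisible(x)
}

#' Simulate expression with case-only module co-expression
#'
#' Case samples draw the module genes from a shared latent factor so that
#' any two module genes have pairwise Pearson correlation approximately
#' `within_module_r`; control samples and all non-module genes are
#' independent standard noise. Values are on the log2 scale centred at 8.
#'
#' @param module_genes Character vector of co-expressed genes.
#' @param n_genes Total number of genes (module genes are the first rows in
#'   index order; remaining gene names are generated).
#' @param n_case,n_control Sample counts (each >= 3).
#' @param within_module_r Target pairwise correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(module_genes, n_genes, n_case, n_control,
                                within_module_r = 0.9, seed = 1L) {
  module_genes <- unique(as.character(module_genes))
  if (!is_scalar_number(within_module_r) ||
      within_module_r < 0 || within_module_r >= 1) {
    stopf("within_module_r must lie in [0, 1)")
  }
  if (!is_scalar_count(n_case) || n_case < 3L ||
      !is_scalar_count(n_control) || n_control < 3L) {
    stopf("need at least 3 case and 3 control samples")
  }
  if (length(module_genes) > n_genes) stopf("module larger than n_genes")
  extra <- sprintf("bg%04d", seq_len(n_genes - length(module_genes)))
  genes <- c(module_genes, extra)
  samples <- c(sprintf("case%03d", seq_len(n_case)),
               sprintf("ctrl%03d", seq_len(n_control)))
  labels <- stats::setNames(
    rep(c("case", "control"), c(n_case, n_control)), samples
  )
  rho <- within_module_r
  vals <- with_seed(seed, {
    v <- matrix(stats::rnorm(n_genes * (n_case + n_control)),
                nrow = n_genes, dimnames = list(genes, samples))
    if (length(module_genes) > 0L && rho > 0) {
      factor_case <- stats::rnorm(n_case)
      idx <- seq_along(module_genes)
      noise <- matrix(stats::rnorm(length(idx) * n_case), nrow = length(idx))
      v[idx, seq_len(n_case)] <-
        sqrt(rho) * matrix(factor_case, nrow = length(idx), ncol = n_case,
                           byrow = TRUE) +
        sqrt(1 - rho) * noise
    }
    v + 8
  })
  expression_matrix(vals, labels)
}

#' Simulate paired disease/drug logFC tables with a planted concordant set
#'
#' Concordant genes receive a nonzero logFC of magnitude `effect_size`
#' (random sign, independently per table); all other genes receive logFC 0
#' in the drug table (and a random value in the disease table), so
#' [select_concordant_genes()] at threshold 0 recovers exactly the planted
#' set. With `effect_size = 0` every logFC is 0 and the selection is empty.
#'
#' @param concordant_genes Character vector of planted concordant genes.
#' @param all_genes Character vector of the full gene universe (must contain
#'   the concordant genes).
#' @param effect_size Magnitude of the planted logFC (default 1).
#' @param seed Integer seed.
#' @return A list with [differential_table()] components `disease` and
#'   `drug`.
#' @export
simulate_logfc_tables <- function(concordant_genes, all_genes,
                                  effect_size = 1, seed = 1L) {
  concordant_genes <- unique(as.character(concordant_genes))
  all_genes <- unique(as.character(all_genes))
  if (!all(concordant_genes %in% all_genes)) {
    stopf("concordant genes must be contained in all_genes")
  }
  if (!is_scalar_number(effect_size) || effect_size < 0) {
    stopf("effect_size must be non-negative")
  }
  n <- length(all_genes)
  conc <- all_genes %in% concordant_genes
  with_seed(seed, {
    disease <- numeric(n)
    drug <- numeric(n)
    disease[conc] <- effect_size * sample(c(-1, 1), sum(conc), replace = TRUE)
    drug[conc] <- effect_size * sample(c(-1, 1), sum(conc), replace = TRUE)
    # Non-concordant genes: possibly differential in the disease only.
    disease[!conc] <- effect_size *
      sample(c(-1, 0, 1), sum(!conc), replace = TRUE)
    list(
      disease = differential_table(all_genes, disease, "disease"),
      drug = differential_table(all_genes, drug, "drug")
    )
  })
}

#' Simulate an annotation map with terms planted on modules
#'
#' Each designated module receives `enriched_terms_per_module` planted terms
#' per namespace; a planted term annotates every module gene plus about 1%
#' of the background, which makes it significant under the defaults of
#' [enrich_terms()] for modules that are small relative to the background.
#' Noise terms annotate random background genes.
#'
#' @param modules List of character vectors (gene sets).
#' @param enriched_terms_per_module Planted terms per module and namespace
#'   (default 2).
#' @param n_background_genes Background universe size (module genes are
#'   always included).
#' @param n_noise_terms Number of scattered noise terms per namespace
#'   (default 20).
#' @param seed Integer seed.
#' @param namespaces Namespaces to populate (default BP, MF, CC).
#' @return A list with `annotation` (an [annotation_map()]) and
#'   `planted_terms` (data frame `module`, `namespace`, `term`).
#' @export
simulate_annotation <- function(modules, enriched_terms_per_module = 2L,
                                n_background_genes = 1000L,
                                n_noise_terms = 20L, seed = 1L,
                                namespaces = c("BP", "MF", "CC")) {
  modules <- lapply(modules, function(g) unique(as.character(g)))
  module_genes <- unique(unlist(modules))
  n_extra <- max(0L, n_background_genes - length(module_genes))
  background <- c(module_genes, sprintf("bgg%05d", seq_len(n_extra)))
  gene <- character()
  nsv <- character()
  term <- character()
  planted <- list()
  with_seed(seed, {
    for (mi in seq_along(modules)) {
      for (ns in namespaces) {
        for (ti in seq_len(enriched_terms_per_module)) {
          tid <- sprintf("%s:M%02d_%02d", ns, mi, ti)
          extra <- background[stats::runif(length(background)) < 0.01]
          members <- unique(c(modules[[mi]], extra))
          gene <- c(gene, members)
          nsv <- c(nsv, rep(ns, length(members)))
          term <- c(term, rep(tid, length(members)))
          planted[[length(planted) + 1L]] <- data.frame(
            module = mi, namespace = ns, term = tid,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    for (ns in namespaces) {
      for (ti in seq_len(n_noise_terms)) {
        tid <- sprintf("%s:noise%03d", ns, ti)
        members <- background[stats::runif(length(background)) < 0.05]
        if (length(members) == 0L) members <- sample(background, 1L)
        gene <- c(gene, members)
        nsv <- c(nsv, rep(ns, length(members)))
        term <- c(term, rep(tid, length(members)))
      }
    }
  })
  list(
    annotation = annotation_map(gene, nsv, term, background = background),
    planted_terms = if (length(planted)) {
      do.call(rbind, planted)
    } else {
      data.frame(module = integer(), namespace = character(),
                 term = character(), stringsAsFactors = FALSE)
    }
  )
}

#' The 26 packaged candidate drug-target modules
#'
#' The fixture of 26 candidate modules (Entrez gene identifier lists, labeled
#' M1-M26) that survive the differential-expression containment step in the
#' trichostatin A case study; M17 and M18 are the two modules ultimately
#' selected as the drug's treatment pattern.
#'
#' @return Named list of 26 character vectors of Entrez gene identifiers.
#' @examples
#' fix <- table1_fixture()
#' length(fix)                     # 26
#' fix$M17                         # "3065" "142" "1786" "6597"
#' overlap_coefficient(fix$M17, fix$M18)
#' @export
table1_fixture <- function() {
  raw <- list(
    M1 = c(890, 7153, 4085, 6241, 701, 22974, 6790, 3161, 11130, 10403,
           6240, 10051, 51203, 1434, 1719, 3832, 7298, 5984, 10592, 4173,
           891, 9319, 2237, 3838, 990, 47, 90, 87),
    M2 = c(7520, 142, 1019, 5111, 5591, 6749, 2237, 5036, 4522, 6241,
           4175, 10606, 5982, 1736),
    M3 = c(22948, 10213, 10969, 471, 1434, 3329, 5686, 1503, 9221, 908,
           5901, 5036, 3838, 7371),
    M4 = c(5901, 7334, 7520, 7443, 10576, 7153, 10213, 26135, 6636, 6427,
           5902, 6428, 6240),
    M5 = c(22948, 7203, 6950, 10574, 11222, 1164, 4830, 7334),
    M6 = c(4172, 6627, 1503, 10528, 11130, 2237, 7398, 9521, 5985),
    M7 = c(6426, 4436, 10772, 10236, 3838, 26135, 1665, 23165, 10576, 7520),
    M8 = c(7153, 5557, 6790, 672, 8317, 10733, 4001, 1736),
    M9 = c(6426, 9221, 6434, 7334, 3015, 1736, 2237, 3184, 2956, 6427),
    M10 = c(10574, 158, 7965, 142, 1503, 7411, 4176, 1736, 8607, 7203,
            5901, 5902),
    M11 = c(6637, 5111, 3148, 3182, 6434),
    M12 = c(1434, 3308, 908, 4869, 6950, 7203, 3336, 3838),
    M13 = c(10492, 1503, 3182),
    M14 = c(3276, 5725, 3609, 6597, 4176, 6627),
    M15 = c(6194, 6124, 6201, 6137, 11224, 6143, 6193, 6217, 6152, 6139,
            6136, 6161, 23521, 6133, 6175, 4736, 6207, 6218, 6135, 6128,
            6146, 3646, 1933, 47, 87, 39, 29, 90, 95),
    M16 = c(3014, 84823, 6597, 5036),
    M17 = c(3065, 142, 1786, 6597),
    M18 = c(3066, 3065, 5928, 2146, 6597),
    M19 = c(86, 6597, 10856),
    M20 = c(6597, 6599, 5591, 4173, 4172),
    M21 = c(6597, 23246, 8662),
    M22 = c(5036, 10574, 3182),
    M23 = c(3329, 7203, 6428),
    M24 = c(10606, 6950, 4691, 3183, 6741, 3843, 5901),
    M25 = c(890, 7371, 3251, 1665),
    M26 = c(5557, 990, 9493, 9833, 1060)
  )
  lapply(raw, as.character)
}
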