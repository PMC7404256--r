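# End-to-end orchestration: network prep -> concordant-gene selection ->
# module mining -> filter cascade -> neighbor scoring -> permutation tests
# -> differential co-expression, with deterministic per-stage seeding and a
# machine-readable run manifest.

.config_defaults <- list(
  layers = NULL,            # named map: layer name -> edge-list path
  top_fractions = NULL,     # named map: layer name -> fraction in (0, 1]
  normalize = TRUE,
  disease_logfc = NULL,     # named map: disease -> two-column logFC path
  drug_logfc = NULL,        # two-column logFC path
  annotation = NULL,        # three-column TSV (optional)
  drug_targets = NULL,      # GMT of drug target gene sets (optional)
  disease_genes = NULL,     # GMT of disease gene sets (optional)
  expression = NULL,        # expression matrix TSV (optional)
  expression_labels = NULL, # sample label TSV (optional)
  min_abs_logfc = 0,
  density_threshold = 0.41,
  min_size = 3L,
  max_modules = 100L,
  restarts = 3L,
  n_perm = 10000L,
  n_samples = 100000L,
  rank = 50L,
  r_threshold = 0.8,
  alpha = 0.05,
  min_proportion = 0.2,
  top_k = 2L,
  seed = 1L,
  out_dir = "sdtp_out"
)

#' Build and validate a pipeline configuration
#'
#' Accepts the tunables of every stage as named arguments (see
#' [run_pipeline()] for their meaning); unknown keys are rejected and every
#' tunable is range-checked.
#'
#' @param ... Configuration keys overriding the defaults.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(!nzchar(names(user))))) {
    stopf("all configuration entries must be named")
  }
  unknown <- setdiff(names(user), names(.config_defaults))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- .config_defaults
  # single-bracket assignment so explicit NULLs survive the merge
  for (nm in names(user)) cfg[nm] <- list(user[[nm]])
  if (is.null(cfg$layers) || length(cfg$layers) < 2L ||
      is.null(names(cfg$layers))) {
    stopf("config needs at least two named layers (layer name -> edge-list path)")
  }
  if (!is.null(cfg$top_fractions)) {
    fr <- unlist(cfg$top_fractions)
    if (any(fr <= 0) || any(fr > 1)) stopf("top_fractions must lie in (0, 1]")
    if (!all(names(cfg$layers) %in% names(cfg$top_fractions))) {
      stopf("top_fractions must name every layer")
    }
  }
  if (!is_scalar_number(cfg$density_threshold) ||
      cfg$density_threshold <= 0 || cfg$density_threshold > 1) {
    stopf("density_threshold must lie in (0, 1]")
  }
  if (!is_scalar_number(cfg$r_threshold) ||
      cfg$r_threshold < 0 || cfg$r_threshold > 1) {
    stopf("r_threshold must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    stopf("alpha must lie in (0, 1]")
  }
  if (!is_scalar_number(cfg$min_proportion) ||
      cfg$min_proportion < 0 || cfg$min_proportion > 1) {
    stopf("min_proportion must lie in [0, 1]")
  }
  for (key in c("min_size", "max_modules", "n_perm", "n_samples", "rank",
                "top_k")) {
    if (!is_scalar_count(cfg[[key]])) stopf("%s must be a positive integer", key)
  }
  if (!is_scalar_number(cfg$min_abs_logfc) || cfg$min_abs_logfc < 0) {
    stopf("min_abs_logfc must be non-negative")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the keys of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file does not exist: %s", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.stage_error <- function(stage, code, parent_msg) {
  stop(structure(
    class = c("sdtp_stage_error", "error", "condition"),
    list(
      message = sprintf("stage '%s' failed [%s]: %s", stage, code, parent_msg),
      call = NULL, stage = stage, code = code
    )
  ))
}

.run_stage <- function(stage, code, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "sdtp_stage_error")) stop(e)
    .stage_error(stage, code, conditionMessage(e))
  })
}

#' Run the full drug-treatment-pattern pipeline
#'
#' Executes, in order: network prep (read, normalize, top-edge selection,
#' tensor assembly), concordant-gene selection, module mining, the filter
#' cascade (size, differential-expression containment and, when annotation
#' and reference gene sets are configured, the term-overlap and disease-term
#' filters plus pathway-overlap ranking), first-order neighbor scoring,
#' permutation significance, and (when expression data are configured)
#' case/control differential co-expression. Each stage writes its outputs
#' under `out_dir` before the next begins; a single global seed is expanded
#' into per-stage seeds (`seed * 100 + stage number`) so every stage is
#' independently reproducible.
#'
#' @param config A [pipeline_config()] (or path to a YAML config file).
#' @return The run manifest: a list with per-stage parameters, output files
#'   and counts, also written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sdtp")),
    seed = config$seed,
    stages = list()
  )
  stage_no <- 0L
  log_stage <- function(name, params, outputs, counts) {
    stage_no <<- stage_no + 1L
    entry <- list(
      stage = name, number = stage_no,
      seed = config$seed * 100L + stage_no,
      params = params, outputs = outputs, counts = counts
    )
    manifest$stages[[name]] <<- entry
    message(sprintf(
      "[sdtp] stage %d %s: %s", stage_no, name,
      paste(sprintf("%s=%s", names(counts), unlist(counts)), collapse = " ")
    ))
  }

  # 1. prep ------------------------------------------------------------
  nets <- NULL
  tensor <- NULL
  .run_stage("prep", "E_PREP", {
    nets <- lapply(names(config$layers), function(nm) {
      net <- read_edge_list(config$layers[[nm]])
      if (isTRUE(config$normalize)) net <- normalize_weights(net)
      frac <- if (is.null(config$top_fractions)) 1.0 else
        as.numeric(config$top_fractions[[nm]])
      if (frac < 1) net <- select_top_edges(net, frac)
      net
    })
    names(nets) <- names(config$layers)
    tensor <- build_tensor(nets, names(config$layers))
    tdir <- file.path(out, "tensor")
    write_tensor(tensor, tdir)
    log_stage(
      "prep",
      list(normalize = config$normalize,
           top_fractions = config$top_fractions),
      list(tensor = tdir),
      list(n_common_genes = length(tensor$genes),
           n_layers = length(tensor$layers))
    )
  })

  # 2. select-genes -----------------------------------------------------
  concordant <- list()
  .run_stage("select_genes", "E_SELECT", {
    if (!is.null(config$disease_logfc) && !is.null(config$drug_logfc)) {
      drug_tab <- read_differential_table(config$drug_logfc, "drug")
      concordant <- lapply(names(config$disease_logfc), function(d) {
        select_concordant_genes(
          read_differential_table(config$disease_logfc[[d]], d),
          drug_tab,
          min_abs_logfc = config$min_abs_logfc
        )
      })
      names(concordant) <- names(config$disease_logfc)
    }
    path <- file.path(out, "concordant.gmt")
    write_gmt(concordant, path)
    log_stage(
      "select_genes",
      list(min_abs_logfc = config$min_abs_logfc),
      list(concordant = path),
      c(list(n_sets = length(concordant)),
        stats::setNames(lapply(concordant, length),
                        paste0("n_", names(concordant))))
    )
  })

  # 3. mine --------------------------------------------------------------
  fit <- NULL
  .run_stage("mine", "E_MINE", {
    mc <- miner_config(
      density_threshold = config$density_threshold,
      min_size = config$min_size,
      max_modules = config$max_modules,
      restarts = config$restarts,
      seed = config$seed * 100L + 3L
    )
    fit <- mine_rhs(tensor, mc)
    jl <- file.path(out, "modules.jsonl")
    tsv <- file.path(out, "modules.tsv")
    write_modules(fit, jl, tsv)
    log_stage(
      "mine",
      list(density_threshold = config$density_threshold,
           min_size = config$min_size),
      list(modules = jl, summary = tsv),
      list(n_modules = length(fit$modules))
    )
  })

  # 4. filter ------------------------------------------------------------
  annotation <- NULL
  final_modules <- NULL
  .run_stage("filter", "E_FILTER", {
    mods <- size_filter(fit$modules, config$min_size)
    n_size <- length(mods)
    if (length(concordant)) {
      mods <- deg_containment_filter(mods, concordant, mode = "any")
    }
    n_deg <- length(mods)
    n_term <- NA_integer_
    n_disease <- NA_integer_
    if (!is.null(config$annotation)) {
      annotation <- read_annotation(config$annotation)
      if (!is.null(config$drug_targets) && length(mods)) {
        targets <- unique(unlist(read_gmt(config$drug_targets)))
        ref <- do.call(rbind, lapply(c("BP", "MF", "CC"), function(ns) {
          terms <- .significant_terms(targets, annotation, ns, config$alpha)
          if (length(terms) == 0L) return(NULL)
          data.frame(namespace = ns, term = terms, stringsAsFactors = FALSE)
        }))
        if (!is.null(ref) && nrow(ref)) {
          mods <- term_overlap_filter(
            mods, ref, annotation,
            min_proportion = config$min_proportion, alpha = config$alpha
          )
        }
        n_term <- length(mods)
      }
      if (!is.null(config$disease_genes) && length(mods)) {
        dsets <- read_gmt(config$disease_genes)
        dlists <- lapply(dsets, function(gs) {
          do.call(rbind, lapply(c("BP", "MF", "CC"), function(ns) {
            terms <- .significant_terms(gs, annotation, ns, config$alpha)
            data.frame(
              namespace = rep(ns, length(terms)), term = terms,
              stringsAsFactors = FALSE
            )
          }))
        })
        mods <- disease_term_filter(mods, dlists, annotation,
                                    alpha = config$alpha)
        n_disease <- length(mods)
      }
    }
    final_modules <- mods
    jl <- file.path(out, "filtered_modules.jsonl")
    write_modules(mods, jl)
    log_stage(
      "filter",
      list(min_size = config$min_size, min_proportion = config$min_proportion,
           alpha = config$alpha),
      list(modules = jl),
      list(n_after_size = n_size, n_after_deg = n_deg,
           n_after_term = n_term, n_after_disease = n_disease,
           n_modules = length(mods))
    )
  })

  # 5. score-neighbors ----------------------------------------------------
  .run_stage("score_neighbors", "E_NEIGHBORS", {
    rows <- list()
    conserved <- list()
    for (mi in seq_along(final_modules)) {
      m <- final_modules[[mi]]
      conserved[[mi]] <- list()
      for (nm in names(nets)) {
        net <- nets[[nm]]
        present <- intersect(m$genes, net$nodes)
        nb <- if (length(present)) first_order_neighbors(net, present) else character()
        if (length(nb) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            module = mi, layer = nm, threshold = NA_real_, n_conserved = 0L,
            genes = "", stringsAsFactors = FALSE
          )
          conserved[[mi]][[nm]] <- character()
          next
        }
        thr <- neighbor_threshold(
          net, present, n_samples = config$n_samples, rank = config$rank,
          seed = config$seed * 100L + 5L
        )
        cons <- conserved_neighbors(net, present, thr)
        conserved[[mi]][[nm]] <- cons
        rows[[length(rows) + 1L]] <- data.frame(
          module = mi, layer = nm, threshold = thr,
          n_conserved = length(cons),
          genes = paste(cons, collapse = ","), stringsAsFactors = FALSE
        )
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
      module = integer(), layer = character(), threshold = numeric(),
      n_conserved = integer(), genes = character(), stringsAsFactors = FALSE
    )
    path <- file.path(out, "conserved_neighbors.tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)

    # Pathway-overlap ranking of the surviving modules, when a PATHWAY
    # namespace and drug targets are available: count, per layer, pathways
    # shared between the conserved neighbors' enrichment and the drug
    # targets', and keep the top_k totals.
    n_before_rank <- length(final_modules)
    if (!is.null(annotation) &&
        "PATHWAY" %in% unique(annotation$entries$namespace) &&
        !is.null(config$drug_targets) && length(final_modules)) {
      targets <- unique(unlist(read_gmt(config$drug_targets)))
      target_pw <- .significant_terms(targets, annotation, "PATHWAY",
                                      config$alpha)
      totals <- vapply(seq_along(final_modules), function(mi) {
        sum(vapply(names(nets), function(nm) {
          pw <- .significant_terms(conserved[[mi]][[nm]], annotation,
                                   "PATHWAY", config$alpha)
          pathway_overlap_count(pw, target_pw)
        }, integer(1L)))
      }, integer(1L))
      keep <- order(-totals, seq_along(totals))[
        seq_len(min(config$top_k, length(final_modules)))
      ]
      final_modules <- final_modules[sort(keep)]
    }
    jl <- file.path(out, "final_modules.jsonl")
    write_modules(final_modules, jl)
    log_stage(
      "score_neighbors",
      list(n_samples = config$n_samples, rank = config$rank,
           top_k = config$top_k),
      list(conserved = path, final_modules = jl),
      list(n_scored = n_before_rank, n_final = length(final_modules))
    )
  })

  # 6. permtest -----------------------------------------------------------
  .run_stage("permtest", "E_PERMTEST", {
    reports <- list()
    for (mi in seq_along(final_modules)) {
      m <- final_modules[[mi]]
      for (nm in names(nets)) {
        net <- nets[[nm]]
        present <- intersect(m$genes, net$nodes)
        if (length(present) < 2L) next
        rep <- permutation_pvalue(
          net, present, n_perm = config$n_perm,
          seed = config$seed * 100L + 6L,
          module_id = sprintf("module%d_%s", mi, nm)
        )
        reports[[length(reports) + 1L]] <- unclass(rep)
      }
    }
    path <- file.path(out, "permutation_reports.json")
    jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA)
    log_stage(
      "permtest",
      list(n_perm = config$n_perm),
      list(reports = path),
      list(n_tests = length(reports))
    )
  })

  # 7. coexpr -------------------------------------------------------------
  .run_stage("coexpr", "E_COEXPR", {
    n_pairs <- 0L
    files <- list()
    if (!is.null(config$expression) && !is.null(config$expression_labels) &&
        length(final_modules)) {
      expr <- read_expression_matrix(config$expression,
                                     config$expression_labels)
      for (mi in seq_along(final_modules)) {
        m <- final_modules[[mi]]
        present <- intersect(m$genes, rownames(expr$values))
        if (length(present) < 2L) next
        case_net <- coexpression_network(expr, present, "case",
                                         config$r_threshold)
        ctrl_net <- coexpression_network(expr, present, "control",
                                         config$r_threshold)
        diff <- differential_edges(case_net, ctrl_net)
        for (side in names(diff)) {
          f <- file.path(out, sprintf("coexpr_module%d_%s.tsv", mi, side))
          utils::write.table(diff[[side]], f, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          files[[sprintf("module%d_%s", mi, side)]] <- f
        }
        n_pairs <- n_pairs + 1L
      }
    }
    log_stage(
      "coexpr",
      list(r_threshold = config$r_threshold),
      files,
      list(n_modules_compared = n_pairs)
    )
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$path <- manifest_path
  invisible(manifest)
}
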