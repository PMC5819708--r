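# End-to-end orchestration of one study:
# differential expression -> heat -> per-network module discovery ->
# consensus -> functional filter -> phenotype evaluation.
# Every stochastic stage derives its seed from the master seed and a stage
# tag, so reruns are byte-identical and stages can be reproduced in
# isolation.

#' Default pipeline parameters
#'
#' Collects every tunable of the pipeline with its default: restart
#' probability `beta = 0.4` (the standard choice for protein-interaction
#' networks), automatic threshold selection (`delta = NULL`) sweeping a
#' geometric grid of `n_delta = 7` values anchored at the permutation
#' heuristic (`l_max = 10`, 20 permutations), 99 significance permutations
#' (must exceed 19: the smallest attainable permutation p is 1/(B + 1)),
#' minimal module size 3, 1000 rank-product permutations, disjoint sample
#' pairing capped at 30 comparisons, heat cap `1e-10`, network-restricted
#' enrichment universe, and the association screen thresholds
#' `|rho| >= 0.4`, `p < 0.05`. A fixed `delta` (scalar or vector) disables
#' the sweep.
#'
#' @param ... overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    beta = 0.4, delta = NULL, l_max = 10L, delta_perm = 20L,
    sig_perm = 99L, n_delta = 7L, min_size = 3L, rp_perm = 1000L,
    max_pairs = 30L,
    pairing = "disjoint", heat_cap = 1e-10, universe = "network",
    min_support = NULL,
    enrich_alpha = 0.05, min_overlap = 2L, rho_min = 0.4, alpha = 0.05,
    evaluate_all_modules = FALSE
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(p)))
  p[names(dots)] <- dots
  stopifnot(p$beta > 0, p$beta < 1, p$rho_min >= 0, p$rho_min <= 1,
            p$alpha > 0, p$alpha < 1, p$enrich_alpha > 0, p$enrich_alpha < 1)
  p
}

# phenotype rows aligned to an association design: returns list(profile_rows,
# pheno_frame) where rows match 1:1
align_phenotypes <- function(scores_samples, metadata, pheno, contrast) {
  md <- metadata[match(scores_samples, metadata$sample), , drop = FALSE]
  if ("timepoint" %in% names(pheno)) {
    key_p <- paste(pheno$subject, pheno$timepoint)
    key_s <- paste(md$subject, md$timepoint)
  } else {
    key_p <- pheno$subject
    key_s <- md$subject
  }
  idx <- match(key_s, key_p)
  vars <- attr(pheno, "variables")
  list(rows = which(!is.na(idx)),
       pheno = as.data.frame(pheno)[idx[!is.na(idx)], vars, drop = FALSE])
}

#' Run one contrast end-to-end
#'
#' Executes the full chain for one differential condition: rank-product
#' differential expression, FDR heat, insulated-diffusion module discovery
#' on every harmonized network (with permutation significance), majority
#' consensus, gene-set over-representation with the functional filter, and
#' the eigengene/Kendall phenotype screen.
#'
#' For an unpaired contrast the eigengene screen uses the contrast's samples
#' and their phenotype rows; for a paired (training) contrast it uses
#' per-subject post - pre differentials of both eigengene scores and
#' phenotype variables.
#'
#' @param expr an [expression_matrix()].
#' @param nets list of [interaction_network()]s.
#' @param gmt a `GeneSetCollection` (or NULL to skip enrichment).
#' @param pheno a `PhenotypeTable` (or NULL to skip evaluation).
#' @param contrast a [contrast()] or a standard contrast label.
#' @param params a [pipeline_params()] list.
#' @param seed master seed.
#' @return List with `diffexp`, `heat`, `network_modules` (per network),
#'   `consensus`, `enrichment`, `functional`, `eigengenes`, `associations`,
#'   `report`.
#' @export
run_condition <- function(expr, nets, gmt, pheno, contrast,
                          params = pipeline_params(), seed = 1L) {
  if (is.character(contrast)) contrast <- standard_contrast(contrast,
                                                            expr$metadata)
  if (inherits(nets, "InteractionNetwork")) nets <- list(nets)
  harm <- harmonize(expr, nets)
  tag <- function(x) derive_seed(seed, paste0(contrast$label, ":", x))

  de <- diffexp(expr, contrast, n_perm = params$rp_perm,
                max_pairs = params$max_pairs, pairing = params$pairing,
                seed = tag("diffexp"))
  heat <- heat_from_fdr(de, cap = params$heat_cap)

  per_net <- list()
  deltas <- list()
  for (i in seq_along(harm$nets)) {
    net <- harm$nets[[i]]
    if (length(net$nodes) < 2L) next
    op <- build_diffusion(net, beta = params$beta)
    E <- exchanged_heat(op, heat)
    grid <- if (is.null(params$delta)) {
      # sweep from the background exchange scale (permutation heuristic) up
      # to past the scale at which the observed components become small;
      # the consensus keeps only co-occurrences stable across resolutions
      d0 <- select_delta(op, heat, n_perm = params$delta_perm,
                         l_max = params$l_max,
                         seed = tag(paste0("delta:", net$name)))
      d_hi <- minimal_delta(E, params$l_max)
      hi <- max(2 * d_hi, 4 * d0, na.rm = TRUE)
      sort(unique(exp(seq(log(d0), log(hi),
                          length.out = params$n_delta))))
    } else params$delta
    deltas[[net$name]] <- grid
    runs <- lapply(grid, function(dd) {
      extract_modules(E, dd, min_size = params$min_size,
                      provenance = list(network = net$name, delta = dd,
                                        contrast = contrast$label,
                                        beta = params$beta))
    })
    runs <- multi_delta_significance(runs, op, heat, grid,
                                     n_perm = params$sig_perm,
                                     seed = tag(paste0("sig:", net$name)))
    per_net <- c(per_net, runs)
    nh_log("%s | %s: deltas [%s], modules per delta [%s], significant [%s]",
           contrast$label, net$name,
           paste(signif(grid, 3), collapse = ", "),
           paste(vapply(runs, function(r) length(r$modules), 1L),
                 collapse = ", "),
           paste(vapply(runs, function(r) sum(r$significant), 1L),
                 collapse = ", "))
  }
  cons <- consensus(per_net, min_size = params$min_size,
                    min_support = params$min_support)

  universe <- if (identical(params$universe, "array")) expr$genes else
    sort(unique(unlist(lapply(harm$nets, `[[`, "nodes"))))
  enr <- if (!is.null(gmt) && length(cons$modules)) {
    enrich_modules(cons, gmt, universe, alpha = params$enrich_alpha,
                   min_overlap = params$min_overlap)
  } else list(table = NULL, functional = logical(length(cons$modules)))

  eval_idx <- if (isTRUE(params$evaluate_all_modules)) {
    seq_along(cons$modules)
  } else which(enr$functional)
  eig <- list(); assoc <- NULL
  if (!is.null(pheno) && length(eval_idx)) {
    samples_for_scores <- c(contrast$a, contrast$b)
    eig <- lapply(eval_idx, function(i) {
      module_eigengenes(expr$values[cons$modules[[i]], samples_for_scores,
                                    drop = FALSE],
                        genes_in_rows = TRUE)
    })
    names(eig) <- sprintf("M%02d", eval_idx)
    if (contrast$design == "paired") {
      # post - pre differentials of scores, one row per subject
      subj <- expr$metadata$subject[match(contrast$a, expr$metadata$sample)]
      d_eig <- lapply(eig, function(e) {
        sc <- e$scores[contrast$a, , drop = FALSE] -
          e$scores[contrast$b, , drop = FALSE]
        rownames(sc) <- subj
        e$scores <- sc
        e
      })
      vars <- attr(pheno, "variables")
      ph <- as.data.frame(pheno)
      pre <- ph[ph$timepoint == "pre", , drop = FALSE]
      post <- ph[ph$timepoint == "post", , drop = FALSE]
      keep <- intersect(subj, intersect(pre$subject, post$subject))
      d_ph <- post[match(keep, post$subject), vars, drop = FALSE] -
        pre[match(keep, pre$subject), vars, drop = FALSE]
      d_eig <- lapply(d_eig, function(e) {
        e$scores <- e$scores[keep, , drop = FALSE]; e
      })
      assoc <- associate(d_eig, d_ph, rho_min = params$rho_min,
                         alpha = params$alpha)
    } else {
      al <- align_phenotypes(samples_for_scores, expr$metadata, pheno,
                             contrast)
      eig_sub <- lapply(eig, function(e) {
        e$scores <- e$scores[al$rows, , drop = FALSE]; e
      })
      assoc <- associate(eig_sub, al$pheno, rho_min = params$rho_min,
                         alpha = params$alpha)
    }
  }

  report <- list(
    contrast = contrast$label, design = contrast$design,
    n_genes = length(expr$genes),
    n_samples_a = length(contrast$a), n_samples_b = length(contrast$b),
    networks = harm$report, beta = params$beta,
    delta = deltas,
    rp_perm = params$rp_perm, delta_perm = params$delta_perm,
    sig_perm = params$sig_perm, l_max = params$l_max,
    min_size = params$min_size, heat_cap = params$heat_cap,
    universe = params$universe,
    min_support = cons$provenance$min_support,
    rho_min = params$rho_min, alpha = params$alpha,
    master_seed = seed,
    n_consensus_modules = length(cons$modules),
    n_functional_modules = sum(enr$functional)
  )
  list(diffexp = de, heat = heat, network_modules = per_net,
       consensus = cons, enrichment = enr$table,
       functional = enr$functional, eigengenes = eig,
       associations = assoc, report = report)
}

#' Run the full study (all three contrasts)
#'
#' Runs COPD-DE, COPD-TE and Healthy-TE, then compares the two
#' training-effect module sets: genes appearing in consensus modules of
#' both groups form the shared training response, the remainder are
#' group-specific.
#'
#' @inheritParams run_condition
#' @param contrasts contrast labels to run.
#' @param out_dir optional directory; when given, all stage tables and a
#'   JSON run report are written there.
#' @return List with one entry per contrast plus `shared_te_genes` and
#'   `report`.
#' @export
run_study <- function(expr, nets, gmt, pheno,
                      contrasts = c("COPD-DE", "COPD-TE", "Healthy-TE"),
                      params = pipeline_params(), seed = 1L,
                      out_dir = NULL) {
  res <- lapply(contrasts, function(lbl) {
    run_condition(expr, nets, gmt, pheno, lbl, params = params, seed = seed)
  })
  names(res) <- contrasts
  shared <- character()
  if (all(c("COPD-TE", "Healthy-TE") %in% contrasts)) {
    g1 <- unique(unlist(res[["COPD-TE"]]$consensus$modules))
    g2 <- unique(unlist(res[["Healthy-TE"]]$consensus$modules))
    shared <- sort(intersect(g1, g2))
  }
  report <- list(contrasts = lapply(res, `[[`, "report"),
                 shared_te_genes = shared)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lbl in contrasts) {
      safe <- gsub("[^A-Za-z0-9]+", "_", lbl)
      write_diffexp(res[[lbl]]$diffexp,
                    file.path(out_dir, paste0("diffexp_", safe, ".tsv")))
      write_modules(res[[lbl]]$consensus,
                    file.path(out_dir, paste0("modules_", safe, ".tsv")),
                    contrast = lbl)
      if (!is.null(res[[lbl]]$enrichment)) {
        write.table(res[[lbl]]$enrichment,
                    file.path(out_dir, paste0("enrichment_", safe, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (!is.null(res[[lbl]]$associations)) {
        write.table(res[[lbl]]$associations,
                    file.path(out_dir, paste0("associations_", safe, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  c(res, list(shared_te_genes = shared, report = report))
}

#' Read and validate a pipeline configuration file
#'
#' Flat YAML (or JSON) mirroring [pipeline_params()] plus input paths
#' (`expression`, `metadata`, `networks` list, `gene_sets`, `phenotypes`,
#' optional `probe_map`), `contrasts` and `seed`. Referenced files are
#' checked before any computation.
#'
#' @param path path to the YAML/JSON config.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  req <- c("expression", "metadata", "networks")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  paths <- c(cfg$expression, cfg$metadata, unlist(cfg$networks),
             cfg$gene_sets, cfg$phenotypes, cfg$probe_map)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("config references missing file(s): ", paste(absent, collapse = ", "))
  }
  if (is.null(cfg$contrasts)) cfg$contrasts <- c("COPD-DE", "COPD-TE",
                                                 "Healthy-TE")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  known <- names(pipeline_params())
  cfg$params <- do.call(pipeline_params, cfg[intersect(names(cfg), known)])
  cfg
}

#' Run a study from a configuration file
#' @param path config path (see [read_run_config()]).
#' @param out_dir output directory (defaults to the config's `out_dir`).
#' @return See [run_study()].
#' @export
run_study_config <- function(path, out_dir = NULL) {
  cfg <- read_run_config(path)
  expr <- read_expression(cfg$expression, cfg$metadata,
                          probe_map = cfg$probe_map)
  nets <- lapply(unlist(cfg$networks), read_network)
  gmt <- if (!is.null(cfg$gene_sets)) read_gmt(cfg$gene_sets) else NULL
  pheno <- if (!is.null(cfg$phenotypes)) read_phenotypes(cfg$phenotypes) else NULL
  run_study(expr, nets, gmt, pheno, contrasts = cfg$contrasts,
            params = cfg$params, seed = cfg$seed,
            out_dir = out_dir %||% cfg$out_dir)
}

#' Jaccard index between two gene sets
#' @param a,b character vectors.
#' @return Numeric in [0, 1].
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (!u) return(0)
  length(intersect(a, b)) / u
}

#' Compare discovered modules against planted ground truth
#'
#' @param modules a `ModuleSet` (typically the consensus).
#' @param truth list of planted gene sets.
#' @return data.frame with one row per planted module: its size, the best
#'   Jaccard index against any discovered module, and which module matched.
#' @export
module_recovery <- function(modules, truth) {
  do.call(rbind, lapply(seq_along(truth), function(i) {
    js <- if (length(modules$modules)) {
      vapply(modules$modules, jaccard, numeric(1L), b = truth[[i]])
    } else 0
    data.frame(planted = i, size = length(truth[[i]]),
               best_jaccard = max(js),
               matched = if (max(js) > 0) which.max(js) else NA_integer_)
  }))
}
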