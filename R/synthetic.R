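# Synthetic study generator.
#
# Emulates the study design the pipeline targets: two groups (COPD n=15,
# healthy n=12) sampled at two timepoints (pre/post an endurance-training
# program), gene expression on a scale-free interactome with a minority of
# genes differentially expressed in connected network neighbourhoods, and
# phenotype variables coupled to the transcriptional activity of planted
# modules. Everything is deterministic under the scenario seed, and every
# generated object is a valid input to the package's readers.

#' Define a synthetic study scenario
#'
#' @param seed master seed; every downstream draw derives from it.
#' @param n_genes number of genes / network nodes (default 1000).
#' @param m_edges preferential-attachment edges per node (default 2).
#' @param n_copd,n_healthy subjects per group (defaults 15 and 12, the
#'   study sizes).
#' @param planted data.frame (or NULL) with columns `size`, `effect`
#'   (log2 units) and `contrast` (one of COPD-DE, COPD-TE, Healthy-TE),
#'   one row per planted module; an optional `topology` column chooses
#'   between `"clique-ish"` (the default: the planted subgraph is densified
#'   so its members interact like a protein complex) and
#'   `"connected-subgraph"` (the grown subgraph is left as is).
#' @param couplings data.frame (or NULL) with columns `module` (planted
#'   module index), `variable`, `tau` (target population Kendall tau) and
#'   `direction` (+1/-1).
#' @param uncoupled character vector of pure-noise phenotype variables.
#' @param baseline_mean,baseline_sd gene baseline distribution (log2 scale).
#' @param subject_sd per-subject random effect SD.
#' @param noise_sd i.i.d. measurement noise SD.
#' @param diffuse_sd SD of weak per-gene group and training effects applied
#'   to every gene (log2 units). Real transcriptome contrasts show a
#'   continuum of small fold-changes on top of the few strong ones; this
#'   term reproduces that continuous FDR landscape (set 0 for a hard null
#'   background).
#' @param n_networks how many interactomes to emit (base + perturbed
#'   variants that preserve planted-module edges; default 3).
#' @param n_random_sets random gene sets in the generated GMT (default 30).
#' @return A `SyntheticScenario` list.
#' @export
synth_scenario <- function(seed, n_genes = 1000L, m_edges = 2L,
                           n_copd = 15L, n_healthy = 12L,
                           planted = NULL, couplings = NULL,
                           uncoupled = character(),
                           baseline_mean = 7, baseline_sd = 1,
                           subject_sd = 0.3, noise_sd = 0.5,
                           diffuse_sd = 0.15,
                           n_networks = 3L, n_random_sets = 30L) {
  if (!is.null(planted)) {
    stopifnot(all(c("size", "effect", "contrast") %in% names(planted)),
              all(is.finite(planted$effect)),
              sum(planted$size) <= n_genes)
  }
  if (!is.null(couplings)) {
    stopifnot(all(c("module", "variable", "tau", "direction") %in%
                    names(couplings)),
              all(abs(couplings$tau) < 1),   # tau = 0 couples to pure noise
              all(couplings$module <= nrow(planted)))
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 m_edges = as.integer(m_edges), n_copd = as.integer(n_copd),
                 n_healthy = as.integer(n_healthy), planted = planted,
                 couplings = couplings, uncoupled = uncoupled,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 diffuse_sd = diffuse_sd,
                 n_networks = as.integer(n_networks),
                 n_random_sets = as.integer(n_random_sets)),
            class = "SyntheticScenario")
}

#' Preset scenarios
#'
#' Ready-made study conditions: `disease-effect` plants four modules of
#' sizes 6-10 with a 2.0 log2 effect on the COPD group (echoing the four
#' disease-effect modules of the motivating design) and couples the first
#' module to a VO2-peak-like variable at population tau 0.5;
#' `training-effect-healthy` plants a bioenergetics-like post-training
#' response in the healthy group; `training-effect-copd` a smaller
#' remodeling-like response in the COPD group; `global-null` plants nothing.
#'
#' @param name preset name.
#' @param seed master seed.
#' @return A `SyntheticScenario`.
#' @export
synth_preset <- function(name = c("disease-effect", "training-effect-healthy",
                                  "training-effect-copd", "global-null"),
                         seed = 1L) {
  name <- match.arg(name)
  sizes <- with_seed(derive_seed(seed, paste0("sizes-", name)),
                     sample(6:10, 4L, replace = TRUE))
  common_vars <- c("FEV1", "Watts_peak", "lactate", "IL6",
                   "glutamine", "protein_carbonyl")
  switch(name,
    "disease-effect" = synth_scenario(
      seed,
      planted = data.frame(size = sizes, effect = 2.0, contrast = "COPD-DE"),
      couplings = data.frame(module = 1L, variable = "VO2_peak", tau = 0.5,
                             direction = 1),
      uncoupled = common_vars
    ),
    "training-effect-healthy" = synth_scenario(
      seed,
      planted = data.frame(size = sizes[1:3], effect = 2.0,
                           contrast = "Healthy-TE"),
      couplings = data.frame(module = 1L, variable = "creatine", tau = 0.5,
                             direction = 1),
      uncoupled = common_vars
    ),
    "training-effect-copd" = synth_scenario(
      seed,
      planted = data.frame(size = sizes[1:2], effect = 2.0,
                           contrast = "COPD-TE"),
      couplings = data.frame(module = 1L, variable = "collagen_marker",
                             tau = 0.5, direction = 1),
      uncoupled = common_vars
    ),
    "global-null" = synth_scenario(seed, planted = NULL, couplings = NULL,
                                   uncoupled = c("VO2_peak", common_vars))
  )
}

#' Generate a scale-free interactome
#'
#' Preferential attachment (Barabasi-Albert) with `m` edges per incoming
#' node: connected, heavy-tailed degree distribution, a reasonable stand-in
#' for protein-interaction network topology.
#'
#' @param n_genes nodes.
#' @param m_edges edges per node.
#' @param seed RNG seed.
#' @param name network name.
#' @return An [interaction_network()].
#' @export
generate_network <- function(n_genes, m_edges = 2L, seed = 1L,
                             name = "synthetic_ppi") {
  g <- with_seed(seed, igraph::sample_pa(n_genes, power = 1, m = m_edges,
                                         directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  ids <- sprintf("G%04d", seq_len(n_genes))
  interaction_network(cbind(ids[el[, 1L]], ids[el[, 2L]]), name = name,
                      nodes = ids)
}

#' Plant connected modules in a network
#'
#' Each module is a connected subgraph of the requested size grown by seeded
#' breadth-first search from a random start node. Modules are pairwise
#' disjoint and separated by at least `min_separation` graph hops, so each
#' planted module is a distinct network neighbourhood (two transcriptional
#' programs planted next to each other would form a single heat-coherent
#' region and an ill-posed ground truth).
#'
#' @param net an [interaction_network()].
#' @param sizes integer vector of module sizes.
#' @param seed RNG seed.
#' @param min_separation minimal graph distance between members of
#'   different modules (default 3, i.e. at least two background genes on
#'   any path between two modules).
#' @return List of character gene vectors.
#' @export
plant_modules <- function(net, sizes, seed = 1L, min_separation = 3L) {
  if (sum(sizes) > length(net$nodes)) stop("requested modules exceed network size")
  g <- as_igraph(net)
  adj <- igraph::as_adj_list(g)
  vnames <- igraph::V(g)$name
  with_seed(seed, {
    blocked <- logical(length(vnames))   # too close to an earlier module
    used <- logical(length(vnames))
    out <- vector("list", length(sizes))
    for (mi in seq_along(sizes)) {
      size <- sizes[mi]
      grown <- NULL
      for (attempt in seq_len(500L)) {
        free <- which(!blocked)
        if (!length(free)) break
        start <- free[sample.int(length(free), 1L)]
        sel <- start
        cand <- setdiff(as.integer(adj[[start]]), sel)
        cand <- cand[!blocked[cand]]
        while (length(sel) < size && length(cand)) {
          nxt <- cand[sample.int(length(cand), 1L)]
          sel <- c(sel, nxt)
          cand <- union(cand, as.integer(adj[[nxt]]))
          cand <- setdiff(cand, sel)
          cand <- cand[!blocked[cand]]
        }
        if (length(sel) == size) { grown <- sel; break }
      }
      if (is.null(grown)) stop("could not grow a connected module of size ", size)
      used[grown] <- TRUE
      # block the grown module plus its (min_separation - 1)-hop halo
      halo <- grown
      for (hop in seq_len(max(0L, min_separation - 1L))) {
        halo <- union(halo, unlist(lapply(halo, function(v) as.integer(adj[[v]]))))
      }
      blocked[halo] <- TRUE
      out[[mi]] <- sort(vnames[grown])
    }
    out
  })
}

#' Densify planted modules into clique-ish neighbourhoods
#'
#' Adds each missing within-module edge with probability `p_edge`, so a
#' planted module interacts like a protein complex (a quasi-clique) rather
#' than a sparse tree -- the structure a heat-diffusion module method is
#' designed to detect.
#'
#' @param net an [interaction_network()].
#' @param planted list of planted gene sets.
#' @param p_edge probability of adding each missing within-module edge.
#' @param seed RNG seed.
#' @return The densified [interaction_network()].
#' @export
densify_modules <- function(net, planted, p_edge = 0.8, seed = 1L) {
  if (!length(planted)) return(net)
  add <- with_seed(seed, {
    rows <- list()
    for (gs in planted) {
      prs <- utils::combn(sort(gs), 2L)
      take <- runif(ncol(prs)) < p_edge
      if (any(take)) rows[[length(rows) + 1L]] <- t(prs[, take, drop = FALSE])
    }
    do.call(rbind, rows)
  })
  if (is.null(add)) return(net)
  interaction_network(rbind(net$edges, add), name = net$name,
                      nodes = net$nodes)
}

# perturbed copy of a network: removes `frac` of the edges not protected
# (both endpoints in the same planted module) and adds as many random new
# edges; keeps planted subgraphs intact
perturb_network <- function(net, protected_sets, frac = 0.05, seed = 1L,
                            name = paste0(net$name, "_v")) {
  with_seed(seed, {
    edges <- net$edges
    prot <- rep(FALSE, nrow(edges))
    for (gs in protected_sets) {
      prot <- prot | (edges[, 1L] %in% gs & edges[, 2L] %in% gs)
    }
    removable <- which(!prot)
    n_rm <- floor(frac * length(removable))
    rm_idx <- removable[sample.int(length(removable), n_rm)]
    kept <- edges[setdiff(seq_len(nrow(edges)), rm_idx), , drop = FALSE]
    nodes <- net$nodes
    mod_of <- integer(0)
    if (length(protected_sets)) {
      mod_of <- setNames(rep(seq_along(protected_sets),
                             lengths(protected_sets)),
                         unlist(protected_sets))
    }
    bridges <- function(x, y) {
      mx <- mod_of[x]; my <- mod_of[y]
      !is.na(mx) & !is.na(my) & mx != my
    }
    new_edges <- matrix(character(), 0L, 2L)
    while (nrow(new_edges) < n_rm) {
      cand <- matrix(nodes[sample.int(length(nodes), 2L * n_rm, replace = TRUE)],
                     ncol = 2L)
      keep <- cand[, 1L] != cand[, 2L] & !bridges(cand[, 1L], cand[, 2L])
      new_edges <- rbind(new_edges, cand[keep, , drop = FALSE])
    }
    interaction_network(rbind(kept, new_edges[seq_len(n_rm), , drop = FALSE]),
                        name = name, nodes = nodes)
  })
}

#' Simulate the expression matrix of a scenario
#'
#' `value = gene baseline + subject effect + planted contrast effect +
#' i.i.d. Gaussian noise`, on the log2 scale, for every gene x (subject,
#' timepoint) combination. Planted effects act on the COPD group (both
#' timepoints) for COPD-DE modules and on the post-training samples of the
#' affected group for TE modules.
#'
#' @param scenario a [synth_scenario()].
#' @param truth list of planted gene sets (from [plant_modules()]), in the
#'   row order of `scenario$planted`.
#' @param genes gene ids (network nodes).
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(scenario, truth, genes) {
  sc <- scenario
  subjects <- c(sprintf("C%02d", seq_len(sc$n_copd)),
                sprintf("H%02d", seq_len(sc$n_healthy)))
  group <- c(rep("COPD", sc$n_copd), rep("healthy", sc$n_healthy))
  md <- data.frame(
    sample = paste(rep(subjects, each = 2L), c("pre", "post"), sep = "_"),
    group = rep(group, each = 2L),
    timepoint = rep(c("pre", "post"), length(subjects)),
    subject = rep(subjects, each = 2L),
    stringsAsFactors = FALSE
  )
  G <- length(genes)
  S <- nrow(md)
  with_seed(derive_seed(sc$seed, "expression"), {
    baseline <- rnorm(G, sc$baseline_mean, sc$baseline_sd)
    subj_eff <- setNames(rnorm(length(subjects), 0, sc$subject_sd), subjects)
    vals <- matrix(baseline, G, S) +
      matrix(subj_eff[md$subject], G, S, byrow = TRUE) +
      matrix(rnorm(G * S, 0, sc$noise_sd), G, S)
    dimnames(vals) <- list(genes, md$sample)
    if (sc$diffuse_sd > 0) {
      # weak per-gene effects on every gene: a disease effect and one
      # training effect per group, giving the continuous fold-change
      # landscape of real transcriptome contrasts
      is_copd <- md$group == "COPD"
      is_post <- md$timepoint == "post"
      vals[, is_copd] <- vals[, is_copd] + rnorm(G, 0, sc$diffuse_sd)
      vals[, is_copd & is_post] <- vals[, is_copd & is_post] +
        rnorm(G, 0, sc$diffuse_sd)
      vals[, !is_copd & is_post] <- vals[, !is_copd & is_post] +
        rnorm(G, 0, sc$diffuse_sd)
    }
    if (!is.null(sc$planted)) {
      for (mi in seq_len(nrow(sc$planted))) {
        eff <- sc$planted$effect[mi]
        for (ctr in strsplit(sc$planted$contrast[mi], ";", fixed = TRUE)[[1L]]) {
          target <- switch(ctr,
            "COPD-DE" = md$group == "COPD",
            "COPD-TE" = md$group == "COPD" & md$timepoint == "post",
            "Healthy-TE" = md$group == "healthy" & md$timepoint == "post",
            stop("unknown planted contrast: ", ctr)
          )
          vals[truth[[mi]], target] <- vals[truth[[mi]], target] + eff
        }
      }
    }
    expression_matrix(vals, md)
  })
}

# calibrate the noise SD so that cor(a, a + sd * z) has Kendall tau ~ target,
# by bisection on a large common-random-numbers sample
calibrate_noise_sd <- function(target_tau, seed, m = 4000L, tol = 0.01) {
  stopifnot(target_tau > 0, target_tau < 1)
  with_seed(seed, {
    a <- rnorm(m)
    z <- rnorm(m)
    tau_at <- function(s) cor(a, a + s * z, method = "kendall")
    lo <- 1e-3; hi <- 1
    while (tau_at(hi) > target_tau) {
      lo <- hi; hi <- hi * 2
      if (hi > 1e3) break
    }
    for (it in seq_len(60L)) {
      mid <- (lo + hi) / 2
      t_mid <- tau_at(mid)
      if (abs(t_mid - target_tau) < tol) return(mid)
      if (t_mid > target_tau) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

#' Simulate phenotype variables coupled to planted-module activity
#'
#' Each coupled variable is a monotone (linear) function of the planted
#' module's mean standardized expression per sample plus Gaussian noise,
#' with the noise SD calibrated by bisection so the population Kendall tau
#' matches the coupling target; uncoupled variables are pure noise. The
#' table has one row per (subject, timepoint), aligned with the expression
#' samples.
#'
#' @param scenario a [synth_scenario()].
#' @param truth planted gene sets.
#' @param expr the simulated [expression_matrix()].
#' @return A `PhenotypeTable` data.frame.
#' @export
simulate_phenotypes <- function(scenario, truth, expr) {
  sc <- scenario
  md <- expr$metadata
  out <- data.frame(subject = md$subject, timepoint = md$timepoint,
                    stringsAsFactors = FALSE)
  with_seed(derive_seed(sc$seed, "phenotypes"), {
    if (!is.null(sc$couplings)) {
      for (ci in seq_len(nrow(sc$couplings))) {
        cp <- sc$couplings[ci, ]
        mod_genes <- truth[[cp$module]]
        sub <- expr$values[mod_genes, , drop = FALSE]
        sds <- apply(sub, 1L, sd)
        if (all(sds == 0)) stop("coupled module has no varying genes")
        if (cp$tau == 0) {
          out[[cp$variable]] <- round(rnorm(nrow(out)), 6)
          next
        }
        sub <- sub[sds > 0, , drop = FALSE]
        act <- colMeans(t(scale(t(sub))))
        act <- as.numeric(scale(act))
        sd_noise <- calibrate_noise_sd(abs(cp$tau),
                                       derive_seed(sc$seed,
                                                   paste0("calib-", ci)))
        y <- sign(cp$direction) * sign(cp$tau) * act +
          sd_noise * rnorm(length(act))
        out[[cp$variable]] <- round(y, 6)
      }
    }
    for (v in sc$uncoupled) out[[v]] <- round(rnorm(nrow(out)), 6)
  })
  attr(out, "variables") <- setdiff(names(out), c("subject", "timepoint"))
  class(out) <- c("PhenotypeTable", "data.frame")
  out
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator for a scenario: interactome (plus perturbed
#' variant networks that preserve planted edges), planted modules,
#' expression, gene sets (terms for each planted module plus random sets)
#' and phenotypes. Fully deterministic under the scenario seed.
#'
#' @param scenario a [synth_scenario()] or preset name.
#' @param seed used only when `scenario` is a preset name.
#' @return List with `expr`, `nets` (list), `gmt`, `pheno`, `truth`
#'   (planted gene sets + couplings), `scenario`.
#' @export
synth_generate <- function(scenario, seed = 1L) {
  if (is.character(scenario)) scenario <- synth_preset(scenario, seed)
  sc <- scenario
  base_net <- generate_network(sc$n_genes, sc$m_edges,
                               seed = derive_seed(sc$seed, "network"),
                               name = "ppi_base")
  planted <- if (!is.null(sc$planted)) {
    plant_modules(base_net, sc$planted$size,
                  seed = derive_seed(sc$seed, "plant"))
  } else list()
  if (length(planted)) {
    topo <- if ("topology" %in% names(sc$planted)) sc$planted$topology else
      rep("clique-ish", length(planted))
    cliqueish <- planted[topo == "clique-ish"]
    base_net <- densify_modules(base_net, cliqueish,
                                seed = derive_seed(sc$seed, "densify"))
  }
  nets <- list(base_net)
  if (sc$n_networks > 1L) {
    for (k in seq_len(sc$n_networks - 1L)) {
      nets[[k + 1L]] <- perturb_network(
        base_net, planted, frac = 0.05,
        seed = derive_seed(sc$seed, paste0("perturb-", k)),
        name = paste0("ppi_variant", k)
      )
    }
  }
  expr <- simulate_expression(sc, planted, base_net$nodes)
  pheno <- simulate_phenotypes(sc, planted, expr)
  sets <- list()
  set_names <- character()
  if (length(planted)) {
    for (mi in seq_along(planted)) {
      id <- sprintf("PM:%03d", mi)
      sets[[id]] <- planted[[mi]]
      set_names[id] <- sprintf("planted module %d (%s)", mi,
                               sc$planted$contrast[mi])
    }
  }
  rnd <- with_seed(derive_seed(sc$seed, "gmt"), {
    lapply(seq_len(sc$n_random_sets), function(k) {
      sort(sample(base_net$nodes, sample(5:50, 1L)))
    })
  })
  for (k in seq_along(rnd)) {
    id <- sprintf("RS:%03d", k)
    sets[[id]] <- rnd[[k]]
    set_names[id] <- sprintf("random set %d", k)
  }
  gmt <- gene_set_collection(sets, set_names)
  list(expr = expr, nets = nets, gmt = gmt, pheno = pheno,
       truth = list(planted = planted,
                    planted_meta = sc$planted,
                    couplings = sc$couplings),
       scenario = sc)
}

#' Write all files of a generated synthetic study
#'
#' Emits expression TSV, metadata CSV, one edge list per network, GMT,
#' phenotype CSV and a ground-truth JSON into `dir`; every file reads back
#' through the package's standard readers.
#'
#' @param study result of [synth_generate()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named list of written paths.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.csv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression(study$expr, paths$expression, paths$metadata)
  write_gmt(study$gmt, paths$gmt)
  write.csv(study$pheno, paths$phenotypes, row.names = FALSE, quote = FALSE)
  for (i in seq_along(study$nets)) {
    p <- file.path(dir, paste0("network_", study$nets[[i]]$name, ".txt"))
    write_network(study$nets[[i]], p)
    paths[[paste0("network_", i)]] <- p
  }
  jsonlite::write_json(
    list(seed = study$scenario$seed,
         planted = lapply(study$truth$planted, identity),
         planted_meta = study$truth$planted_meta,
         couplings = study$truth$couplings),
    paths$truth, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
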