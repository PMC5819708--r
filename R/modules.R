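# Module discovery on the exchanged-heat matrix.
#
# The exchanged-heat matrix is thresholded at delta and modules are the
# strongly connected components of the resulting directed graph: gene sets
# whose members all exchange at least delta heat along directed cycles.
# delta itself is chosen by a permutation heuristic (smallest delta at which
# a heat-permuted network has no component larger than l_max), module
# count/size significance comes from heat-label permutations, and modules
# found in several interactomes are merged by a majority consensus rule.

# directed edges of E at threshold delta: i <- j wherever E[i,j] >= delta, i != j
threshold_edges <- function(E, delta) {
  n <- nrow(E)
  k <- which(E >= delta)
  if (!length(k)) return(cbind(from = integer(), to = integer()))
  row <- (k - 1L) %% n + 1L
  col <- (k - 1L) %/% n + 1L
  off <- row != col
  cbind(from = col[off], to = row[off])
}

# strongly connected component membership for an integer edge list over n nodes;
# returns list of integer node vectors, one per component of size >= min_size
scc_sets <- function(edges, n, min_size = 2L) {
  if (!nrow(edges)) return(list())
  used <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, "from"], used), match(edges[, "to"], used)),
    directed = TRUE
  )
  comp <- igraph::components(g, mode = "strong")
  keep <- which(comp$csize >= min_size)
  lapply(keep, function(ci) used[comp$membership == ci])
}

# largest strongly connected component size
max_scc_size <- function(edges) {
  if (!nrow(edges)) return(1L)
  used <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, "from"], used), match(edges[, "to"], used)),
    directed = TRUE
  )
  max(igraph::components(g, mode = "strong")$csize)
}

#' Extract network modules from an exchanged-heat matrix
#'
#' Builds the directed graph with an edge i <- j wherever `E[i, j] >= delta`
#' (i != j) and returns its strongly connected components of size at least
#' `min_size` as modules, each with its mean heat.
#'
#' @param E exchanged-heat matrix from [exchanged_heat()].
#' @param delta positive edge-retention threshold.
#' @param min_size minimal reported module size (default 3).
#' @param provenance optional list (network, contrast, ...) stored with the
#'   result.
#' @return Object of class `ModuleSet`: list with `modules` (list of gene
#'   vectors), `mean_heat`, `delta`, `provenance`, and `component_sizes`
#'   (all strongly-connected-component sizes >= 2, used for the
#'   significance tabulation).
#' @export
extract_modules <- function(E, delta, min_size = 3L, provenance = list()) {
  stopifnot(delta > 0)
  genes <- rownames(E)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(E)))
  heat <- attr(E, "heat")
  if (is.null(heat)) heat <- setNames(rep(NA_real_, nrow(E)), genes)
  edges <- threshold_edges(E, delta)
  comps <- scc_sets(edges, nrow(E), min_size = 2L)
  sizes <- lengths(comps)
  keep <- sizes >= min_size
  modules <- lapply(comps[keep], function(ix) sort(genes[ix]))
  mean_heat <- vapply(comps[keep], function(ix) mean(heat[ix]), numeric(1L))
  structure(
    list(modules = modules, mean_heat = mean_heat, delta = delta,
         min_size = as.integer(min_size), provenance = provenance,
         component_sizes = sizes),
    class = "ModuleSet"
  )
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d module(s) of sizes [%s] at delta=%.3g\n",
              length(x$modules), paste(lengths(x$modules), collapse = ", "),
              x$delta))
  invisible(x)
}

# sorted distinct positive off-diagonal values of E, decreasing, with the
# edge count at each threshold (ties included)
delta_candidates <- function(E) {
  n <- nrow(E)
  e <- as.vector(E)
  e[seq.int(1L, n * n, by = n + 1L)] <- 0   # zero the diagonal
  vals <- e[e > 0]
  if (!length(vals)) return(NULL)
  vals <- sort(vals, decreasing = TRUE, method = "radix")
  starts <- !duplicated(vals)
  d <- vals[starts]
  ends <- c(which(starts)[-1L] - 1L, length(vals))
  list(values = d, counts = ends)
}

# minimal delta (over the distinct positive entries of E) at which the
# largest SCC is <= l_max; exponential + binary search over the sorted
# candidate list (max SCC size is monotone non-increasing in delta)
minimal_delta <- function(E, l_max) {
  cand <- delta_candidates(E)
  if (is.null(cand)) return(NA_real_)
  d <- cand$values
  M <- length(d)
  ok <- function(m) max_scc_size(threshold_edges(E, d[m])) <= l_max
  if (!ok(1L)) return(d[1L] * (1 + 1e-9))   # even the top value fails: no edges kept
  # exponential probe for the first failing index
  lo <- 1L; hi <- 2L
  while (hi <= M && ok(hi)) { lo <- hi; hi <- hi * 2L }
  if (hi > M) {
    if (lo < M && ok(M)) return(d[M]) else hi <- M + 1L
    if (lo == M) return(d[M])
  }
  # invariant: ok(lo), !ok(hi) (hi <= M)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) lo <- mid else hi <- mid
  }
  d[lo]
}

#' Choose the edge-retention threshold delta by heat permutation
#'
#' For each permutation the heat values are shuffled over the network nodes,
#' and the minimal delta is found (over the sorted distinct entries of the
#' permuted exchanged-heat matrix) at which the largest strongly connected
#' component is no larger than `l_max`. The returned delta is the median of
#' these per-permutation minima.
#'
#' @param op a [build_diffusion()] operator.
#' @param heat named heat vector.
#' @param n_perm number of heat permutations (default 20).
#' @param l_max largest tolerated component size under permuted heat
#'   (default 10).
#' @param seed RNG seed.
#' @return The selected delta (numeric scalar).
#' @export
select_delta <- function(op, heat, n_perm = 20L, l_max = 10L, seed = 1L) {
  stopifnot(n_perm >= 10L)
  h <- attr(exchanged_heat(op, heat), "heat")   # aligned, zero-filled
  deltas <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    hp <- setNames(sample(unname(h)), names(h))
    minimal_delta(exchanged_heat(op, hp), l_max)
  }, numeric(1L)))
  deltas <- deltas[is.finite(deltas)]
  if (!length(deltas)) stop("no positive exchanged heat under any permutation")
  median(deltas)
}

# component-size tabulation: counts of SCCs with size >= k for k = 2..k_max
count_at_least <- function(sizes, k_max) {
  vapply(2:k_max, function(k) sum(sizes >= k), integer(1L))
}

#' Permutation significance of module count and size
#'
#' Re-runs module extraction at the observed delta under `n_perm` heat-label
#' permutations and tabulates, for every size k in [2, k_max], how often the
#' permuted networks produce at least as many components of size >= k as
#' observed: `p_k = (1 + #{perm: count_k >= X_k}) / (1 + n_perm)`. A module
#' is flagged significant when `p_k < 0.05` for some k up to its size.
#'
#' @param modules observed [extract_modules()] result.
#' @param op the [build_diffusion()] operator used for the observation.
#' @param heat the observed heat vector.
#' @param n_perm number of permutations (>= 19; default 99).
#' @param seed RNG seed.
#' @return The `ModuleSet` with a `significance` data.frame (k, observed,
#'   expected, p) and a logical vector `significant` per module.
#' @export
module_significance <- function(modules, op, heat, n_perm = 99L, seed = 1L) {
  stopifnot(n_perm >= 19L)
  delta <- modules$delta
  obs_sizes <- modules$component_sizes
  k_max <- max(2L, obs_sizes, 0L)
  X <- count_at_least(obs_sizes, k_max)
  h <- attr(exchanged_heat(op, heat), "heat")
  counts <- with_seed(seed, {
    out <- matrix(0L, n_perm, k_max - 1L)
    for (b in seq_len(n_perm)) {
      hp <- setNames(sample(unname(h)), names(h))
      Ep <- exchanged_heat(op, hp)
      sizes <- lengths(scc_sets(threshold_edges(Ep, delta), nrow(Ep), 2L))
      out[b, ] <- count_at_least(sizes, k_max)
    }
    out
  })
  p_k <- (1 + colSums(counts >= rep(X, each = n_perm))) / (1 + n_perm)
  sig_tab <- data.frame(k = 2:k_max, observed = X,
                        expected = colMeans(counts), p = p_k)
  modules$significance <- sig_tab
  modules$n_perm <- as.integer(n_perm)
  modules$significant <- vapply(lengths(modules$modules), function(s) {
    any(sig_tab$p[sig_tab$k <= s] < 0.05)
  }, logical(1L))
  modules
}

#' Permutation significance across a delta sweep
#'
#' Like [module_significance()], but evaluates several thresholds in one
#' permutation pass: each permuted exchanged-heat matrix is thresholded at
#' every delta of the sweep, so the per-delta significance tables share the
#' same permutations.
#'
#' @param modules_list list of [extract_modules()] results, one per delta.
#' @param op the diffusion operator.
#' @param heat observed heat vector.
#' @param deltas numeric vector of thresholds, same order as
#'   `modules_list`.
#' @param n_perm permutations (>= 19; default 99).
#' @param seed RNG seed.
#' @return `modules_list` with `significance` and `significant` filled in.
#' @export
multi_delta_significance <- function(modules_list, op, heat, deltas,
                                     n_perm = 99L, seed = 1L) {
  stopifnot(n_perm >= 19L, length(modules_list) == length(deltas))
  k_maxes <- vapply(modules_list, function(m) {
    max(2L, m$component_sizes, 0L)
  }, integer(1L))
  Xs <- lapply(seq_along(deltas), function(d) {
    count_at_least(modules_list[[d]]$component_sizes, k_maxes[d])
  })
  h <- attr(exchanged_heat(op, heat), "heat")
  n <- length(h)
  dmin <- min(deltas)
  # columns whose largest off-diagonal exchange cannot reach the grid floor
  # contribute no edges at any swept threshold and are skipped exactly
  Fo <- op$F
  diag(Fo) <- 0
  colmax <- apply(Fo, 2L, max)
  counts <- lapply(k_maxes, function(km) matrix(0L, n_perm, km - 1L))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      hp <- sample(unname(h))
      keep_col <- which(hp * colmax >= dmin)
      if (length(keep_col)) {
        Ep <- op$F[, keep_col, drop = FALSE] *
          rep(hp[keep_col], each = n)
        k <- which(Ep >= dmin)
        row <- (k - 1L) %% n + 1L
        col <- keep_col[(k - 1L) %/% n + 1L]
        off <- row != col
        row <- row[off]; col <- col[off]; vals <- Ep[k][off]
      } else {
        row <- col <- integer(); vals <- numeric()
      }
      for (d in seq_along(deltas)) {
        kp <- vals >= deltas[d]
        sizes <- lengths(scc_sets(cbind(from = col[kp], to = row[kp]),
                                  n, 2L))
        counts[[d]][b, ] <- count_at_least(sizes, k_maxes[d])
      }
    }
  })
  for (d in seq_along(deltas)) {
    X <- Xs[[d]]
    p_k <- (1 + colSums(counts[[d]] >= rep(X, each = n_perm))) / (1 + n_perm)
    sig_tab <- data.frame(k = 2:k_maxes[d], observed = X,
                          expected = colMeans(counts[[d]]), p = p_k)
    modules_list[[d]]$significance <- sig_tab
    modules_list[[d]]$n_perm <- as.integer(n_perm)
    modules_list[[d]]$significant <-
      vapply(lengths(modules_list[[d]]$modules), function(s) {
        any(sig_tab$p[sig_tab$k <= s] < 0.05)
      }, logical(1L))
  }
  modules_list
}

#' Consensus modules across interactomes
#'
#' Builds an undirected co-occurrence graph: two genes are linked by each
#' run in which they fall in the same significant module. Edges supported
#' by at least `min_support` runs (default: a majority,
#' `ceiling(n_runs / 2)`) are kept, and consensus modules are the connected
#' components of size >= `min_size`, annotated with their supporting
#' networks.
#'
#' @param module_sets list of [module_significance()]-annotated `ModuleSet`s,
#'   one per run (e.g. one per network, or one per network x delta when the
#'   pipeline sweeps thresholds).
#' @param min_size minimal consensus module size (default 3).
#' @param min_support minimal number of supporting networks per co-occurrence
#'   edge; `NULL` for the majority rule.
#' @return A `ModuleSet` whose provenance records the supporting networks
#'   per module (`support`).
#' @export
consensus <- function(module_sets, min_size = 3L, min_support = NULL) {
  stopifnot(length(module_sets) >= 1L)
  n_runs <- length(module_sets)
  if (is.null(min_support)) min_support <- ceiling(n_runs / 2)
  pair_net <- list()
  for (ri in seq_along(module_sets)) {
    ms <- module_sets[[ri]]
    net_name <- if (!is.null(ms$provenance$network)) ms$provenance$network else "net"
    run_id <- paste0(ri, ":", net_name)
    sig <- if (!is.null(ms$significant)) ms$significant else
      rep(TRUE, length(ms$modules))
    for (mod in ms$modules[sig]) {
      if (length(mod) < 2L) next
      prs <- utils::combn(sort(mod), 2L)
      keys <- paste(prs[1L, ], prs[2L, ], sep = "\r")
      for (kk in seq_along(keys)) {
        pair_net[[keys[kk]]] <- c(pair_net[[keys[kk]]], run_id)
      }
    }
  }
  heat_all <- unlist(lapply(module_sets, function(ms) {
    setNames(rep(ms$mean_heat, lengths(ms$modules)), unlist(ms$modules))
  }))
  support <- lengths(pair_net)   # number of supporting runs per pair
  keep <- support >= min_support
  if (!any(keep)) {
    return(structure(list(modules = list(), mean_heat = numeric(),
                          delta = NA_real_, min_size = as.integer(min_size),
                          provenance = list(n_runs = n_runs,
                                            min_support = min_support),
                          component_sizes = integer(),
                          significant = logical()),
                     class = "ModuleSet"))
  }
  prs <- do.call(rbind, strsplit(names(pair_net)[keep], "\r", fixed = TRUE))
  g <- igraph::graph_from_edgelist(prs, directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  mods <- list(); supp <- list()
  for (ci in which(comp$csize >= min_size)) {
    genes <- sort(vnames[comp$membership == ci])
    mods[[length(mods) + 1L]] <- genes
    in_mod <- prs[, 1L] %in% genes & prs[, 2L] %in% genes
    supp[[length(supp) + 1L]] <-
      sort(unique(sub("^[0-9]+:", "", unlist(pair_net[keep][in_mod]))))
  }
  mh <- vapply(mods, function(gs) {
    v <- heat_all[intersect(gs, names(heat_all))]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  structure(
    list(modules = mods, mean_heat = mh, delta = NA_real_,
         min_size = as.integer(min_size),
         provenance = list(n_runs = n_runs, min_support = min_support,
                           support = supp),
         component_sizes = lengths(mods),
         significant = rep(TRUE, length(mods))),
    class = "ModuleSet"
  )
}

#' Write a module set as a tidy TSV (one row per module gene)
#' @param modules a `ModuleSet`.
#' @param path output path.
#' @param contrast optional contrast label column.
#' @export
write_modules <- function(modules, path, contrast = NA_character_) {
  rows <- if (length(modules$modules)) {
    do.call(rbind, lapply(seq_along(modules$modules), function(i) {
      supp <- modules$provenance$support
      data.frame(
        module = sprintf("M%02d", i),
        gene = modules$modules[[i]],
        support = if (!is.null(supp)) paste(supp[[i]], collapse = ";") else
          as.character(modules$provenance$network %||% NA),
        mean_heat = modules$mean_heat[i],
        contrast = contrast,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(module = character(), gene = character(), support = character(),
               mean_heat = numeric(), contrast = character())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
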