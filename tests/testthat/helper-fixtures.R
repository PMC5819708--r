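# small in-code fixtures shared across the suite

options(netheat.quiet = TRUE)

# genes x samples toy expression with full two-group / two-timepoint metadata
toy_expression <- function(n_genes = 6L, n_copd = 3L, n_healthy = 3L,
                           seed = 1L) {
  subjects <- c(sprintf("C%02d", seq_len(n_copd)),
                sprintf("H%02d", seq_len(n_healthy)))
  group <- rep(c("COPD", "healthy"), c(n_copd, n_healthy))
  md <- data.frame(
    sample = paste(rep(subjects, each = 2L), c("pre", "post"), sep = "_"),
    group = rep(group, each = 2L),
    timepoint = rep(c("pre", "post"), length(subjects)),
    subject = rep(subjects, each = 2L),
    stringsAsFactors = FALSE
  )
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * nrow(md), 7, 1), n_genes, nrow(md),
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 md$sample))
  expression_matrix(vals, md)
}

# independent rank computation by counting (average ranks for ties)
count_ranks <- function(x) {
  vapply(x, function(v) 1 + sum(x < v) + (sum(x == v) - 1) / 2, numeric(1L))
}

# brute-force strongly connected components of a directed adjacency matrix,
# via boolean transitive closure; returns sorted list of components >= min_size
closure_sccs <- function(A, min_size = 2L) {
  n <- nrow(A)
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  mutual <- R & t(R)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(mutual[i, ])] <- cid
    }
  }
  out <- split(seq_len(n), comp)
  out <- out[lengths(out) >= min_size]
  unname(lapply(out, as.integer))
}

# canonical form for comparing component partitions
canon_sets <- function(sets) {
  if (!length(sets)) return(list())
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, sets[[1]][1], 1))]
}

# brute-force Kendall tau-b with tie correction, explicit pair loops
brute_tau_b <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  S / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# tiny planted-module scenario used by module-level tests: a hot near-clique
# on a sparse background graph
toy_hot_graph <- function(n_bg = 24L, clique = 6L, h_hot = 8, h_bg = 0.3,
                          seed = 1L) {
  set.seed(seed)
  n <- n_bg + clique
  ids <- sprintf("N%02d", seq_len(n))
  ring <- cbind(ids[seq_len(n_bg)], ids[c(seq_len(n_bg)[-1L], 1L)])
  extra <- t(replicate(n_bg, sample(ids[seq_len(n_bg)], 2L)))
  hot <- t(utils::combn(ids[(n_bg + 1L):n], 2L))
  anchor <- cbind(ids[1L], ids[n_bg + 1L])   # attach clique to background
  net <- interaction_network(rbind(ring, extra, hot, anchor), name = "toy")
  heat <- setNames(rep(h_bg, n), ids)
  heat[(n_bg + 1L):n] <- h_hot
  list(net = net, heat = heat, hot = ids[(n_bg + 1L):n])
}
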