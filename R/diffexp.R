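# Rank-product differential expression.
#
# The rank product is robust for noisy, small-n designs: within each
# replicate comparison genes are ranked by log-ratio, and a gene's statistic
# is the geometric mean of its ranks across comparisons. Significance comes
# from a permutation scheme that shuffles the rank column of each comparison
# independently and pools the permuted statistics over all genes
# (the expected-false-positives construction, normalized to a p-value).

#' Build the comparison matrix for a contrast
#'
#' For an unpaired two-class contrast, class-A samples are compared with
#' class-B samples (log-ratio = A - B on the log2 scale). Two pairing
#' schemes are available. `"disjoint"` (the default) draws a seeded random
#' matching in which every sample is used at most once, giving
#' `min(n_A, n_B)` mutually independent comparisons -- under the
#' column-shuffle permutation null these are exactly calibrated. `"all"`
#' enumerates all n_A x n_B sample pairs (the classical two-class recipe),
#' subsampled to `max_pairs` with the given seed when larger; because those
#' comparisons share samples, their permutation p-values are
#' anti-conservative in the extreme tail. For a paired contrast there is
#' one comparison per subject: post - pre.
#'
#' @param expr an [expression_matrix()].
#' @param contrast a [contrast()].
#' @param max_pairs cap on the number of unpaired sample pairs (default 30).
#' @param seed seed for the pair draw.
#' @param pairing `"disjoint"` or `"all"` (unpaired designs only).
#' @return Numeric matrix, genes x comparisons, of log2 differences.
#' @export
pairwise_comparisons <- function(expr, contrast, max_pairs = 30L, seed = 1L,
                                 pairing = c("disjoint", "all")) {
  pairing <- match.arg(pairing)
  v <- expr$values
  if (contrast$design == "paired") {
    cmp <- v[, contrast$a, drop = FALSE] - v[, contrast$b, drop = FALSE]
    colnames(cmp) <- paste0(contrast$a, "-", contrast$b)
  } else {
    pairs <- if (pairing == "all") {
      expand.grid(a = contrast$a, b = contrast$b, stringsAsFactors = FALSE)
    } else {
      k <- min(length(contrast$a), length(contrast$b))
      with_seed(seed, data.frame(
        a = sample(contrast$a, k), b = sample(contrast$b, k),
        stringsAsFactors = FALSE
      ))
    }
    if (nrow(pairs) > max_pairs) {
      idx <- with_seed(derive_seed(seed, "cap"),
                       sample.int(nrow(pairs), max_pairs))
      pairs <- pairs[sort(idx), , drop = FALSE]
    }
    cmp <- v[, pairs$a, drop = FALSE] - v[, pairs$b, drop = FALSE]
    colnames(cmp) <- paste0(pairs$a, "-", pairs$b)
  }
  if (ncol(cmp) < 3L) stop("fewer than 3 comparisons available")
  cmp
}

#' Rank-product statistics
#'
#' Within each comparison genes are ranked ascending by log-ratio for
#' `RP_down` and descending for `RP_up` (rank 1 = most extreme in that
#' direction); ties receive average ranks. The rank product is the geometric
#' mean of a gene's ranks across comparisons, so it lies in [1, G].
#'
#' @param comparisons genes x comparisons matrix of log-ratios (finite).
#' @return List with numeric vectors `RP_up` and `RP_down` (named by gene)
#'   and the rank matrices `ranks_up`, `ranks_down` used (for permutation).
#' @export
rank_product <- function(comparisons) {
  comparisons <- as.matrix(comparisons)
  if (!all(is.finite(comparisons))) stop("non-finite log-ratios")
  G <- nrow(comparisons)
  if (G < 2L) stop("need at least 2 genes")
  r_dn <- apply(comparisons, 2L, rank)          # ascending: most negative = 1
  r_up <- (G + 1) - r_dn                        # descending (holds for ties too)
  rp <- function(r) exp(rowMeans(log(r)))
  list(
    RP_up = setNames(rp(r_up), rownames(comparisons)),
    RP_down = setNames(rp(r_dn), rownames(comparisons)),
    ranks_up = r_up, ranks_down = r_dn
  )
}

# geometric-mean rank products for one permuted rank matrix
rp_of_ranks <- function(r) exp(rowMeans(log(r)))

# all permutations of 1..n as an (n!) x n matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- matrix(rest[sub], nrow(sub), n - 1L)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(i, block)
    row <- row + nrow(sub)
  }
  out
}

#' Permutation p-values for rank products
#'
#' Each permutation independently shuffles the rank column of every
#' comparison and recomputes all G rank products; the p-value of a gene is
#' `(1 + #permuted RP anywhere <= observed RP) / (1 + n_perm * G)`, i.e. the
#' expected-false-positives count normalized to a p-value, with a pseudo-count
#' guaranteeing p > 0. With `exhaustive = TRUE` all (G!)^C rank assignments
#' are enumerated instead of sampled (feasible only for tiny G and C).
#'
#' @param rp result of [rank_product()].
#' @param n_perm number of permutations (ignored when exhaustive).
#' @param seed RNG seed.
#' @param exhaustive enumerate all rank assignments instead of sampling.
#' @return List with vectors `p_up`, `p_down`, `p` (two-sided,
#'   `2 * pmin(p_up, p_down)` capped at 1) and the effective permutation
#'   count `n_perm`.
#' @export
rp_pvalues <- function(rp, n_perm = 1000L, seed = 1L, exhaustive = FALSE) {
  G <- nrow(rp$ranks_up)
  C <- ncol(rp$ranks_up)
  logr_up <- log(rp$ranks_up)
  logr_dn <- log(rp$ranks_down)
  if (exhaustive) {
    if (factorial(G)^C > 2e5) stop("exhaustive enumeration infeasible at this size")
    perm1 <- all_permutations(G)
    grid <- as.matrix(do.call(expand.grid,
                              replicate(C, seq_len(nrow(perm1)), simplify = FALSE)))
    B <- nrow(grid)
    draw <- function(b, cc) perm1[grid[b, cc], ]
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    B <- as.integer(n_perm)
    draw <- function(b, cc) sample.int(G)
  }
  pool_up <- numeric(B * G)
  pool_dn <- numeric(B * G)
  fill <- function() {
    for (b in seq_len(B)) {
      s_up <- numeric(G)
      s_dn <- numeric(G)
      for (cc in seq_len(C)) {
        idx <- draw(b, cc)
        s_up <- s_up + logr_up[idx, cc]
        s_dn <- s_dn + logr_dn[idx, cc]
      }
      at <- ((b - 1L) * G + 1L):(b * G)
      pool_up[at] <<- exp(s_up / C)
      pool_dn[at] <<- exp(s_dn / C)
    }
  }
  if (exhaustive) fill() else with_seed(seed, fill())
  pool_up <- sort(pool_up)
  pool_dn <- sort(pool_dn)
  denom <- 1 + as.numeric(B) * G
  p_up <- (1 + findInterval(rp$RP_up, pool_up)) / denom
  p_dn <- (1 + findInterval(rp$RP_down, pool_dn)) / denom
  list(p_up = p_up, p_down = p_dn,
       p = pmin(1, 2 * pmin(p_up, p_dn)), n_perm = B)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, in [0,1], elementwise >= p).
#'
#' @param p numeric vector of p-values in [0,1].
#' @return Adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Run the full differential-expression stage for one contrast
#'
#' @param expr an [expression_matrix()].
#' @param contrast a [contrast()].
#' @param n_perm permutations for the rank-product p-values.
#' @param max_pairs cap on unpaired sample pairs.
#' @param seed RNG seed (pair subsample and permutations).
#' @param pairing pairing scheme for unpaired contrasts, see
#'   [pairwise_comparisons()].
#' @return A `DifferentialResult` data.frame with columns gene, RP_up,
#'   RP_down, p_up, p_down, p, FDR, direction, effect.
#' @export
diffexp <- function(expr, contrast, n_perm = 1000L, max_pairs = 30L,
                    seed = 1L, pairing = "disjoint") {
  cmp <- pairwise_comparisons(expr, contrast, max_pairs = max_pairs,
                              seed = derive_seed(seed, "pairs"),
                              pairing = pairing)
  rp <- rank_product(cmp)
  pv <- rp_pvalues(rp, n_perm = n_perm, seed = derive_seed(seed, "rp_perm"))
  effect <- rowMeans(cmp)
  res <- data.frame(
    gene = rownames(cmp),
    RP_up = unname(rp$RP_up), RP_down = unname(rp$RP_down),
    p_up = pv$p_up, p_down = pv$p_down, p = pv$p,
    FDR = bh_adjust(pv$p),
    direction = ifelse(effect >= 0, "up", "down"),
    effect = effect,
    stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- contrast$label
  attr(res, "n_perm") <- pv$n_perm
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Write a differential result as TSV (with a provenance header)
#' @param res a `DifferentialResult`.
#' @param path output path.
#' @export
write_diffexp <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast=%s n_perm=%d fdr=BH",
                     attr(res, "contrast"), attr(res, "n_perm")), con)
  write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
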