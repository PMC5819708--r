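# Gene-set over-representation for modules.
#
# Each module is tested against every annotation term it overlaps, with the
# hypergeometric upper tail on the harmonized-network gene universe;
# adjusted p-values are Benjamini-Hochberg within module. A module counts as
# functionally significant when at least one term reaches adjusted p < 0.05
# with at least two module genes in the overlap.

#' Hypergeometric over-representation p-value
#'
#' Probability of drawing at least `x` genes of a term of size `K` when
#' sampling `n` genes (the module) from a universe of `N`:
#' `p = sum_{i=x..min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param x overlap count.
#' @param n module size.
#' @param K term size.
#' @param N universe size.
#' @return Upper-tail probability.
#' @export
hypergeom_overrep <- function(x, n, K, N) {
  stopifnot(x >= 0, x <= min(n, K), min(n, K) <= N)
  if (x == 0) return(1)
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of annotation terms in one module
#'
#' One hypergeometric test per term with a non-empty overlap; BH adjustment
#' across the tested terms of the module.
#'
#' @param module character vector of module genes (subset of `universe`).
#' @param sets a `GeneSetCollection`.
#' @param universe character vector: the gene universe (normally the genes
#'   of the harmonized network).
#' @return data.frame with term, term_name, overlap, term_size, module_size,
#'   universe_size, p, adj_p, genes (semicolon-joined overlap), ordered by p.
#' @export
enrich_module <- function(module, sets, universe) {
  module <- intersect(module, universe)
  if (length(setdiff(module, universe))) stop("module not contained in universe")
  N <- length(universe)
  n <- length(module)
  rows <- lapply(names(sets$sets), function(id) {
    term_genes <- intersect(sets$sets[[id]], universe)
    ov <- intersect(module, term_genes)
    if (!length(ov)) return(NULL)
    data.frame(
      term = id,
      term_name = unname(sets$names[id]),
      overlap = length(ov), term_size = length(term_genes),
      module_size = n, universe_size = N,
      p = hypergeom_overrep(length(ov), n, length(term_genes), N),
      genes = paste(sort(ov), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(term = character(), term_name = character(),
                      overlap = integer(), term_size = integer(),
                      module_size = integer(), universe_size = integer(),
                      p = numeric(), adj_p = numeric(), genes = character()))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[order(out$p, out$term), c("term", "term_name", "overlap", "term_size",
                                "module_size", "universe_size", "p", "adj_p",
                                "genes")]
}

#' Functional-significance filter for modules
#'
#' A module passes when at least one of its terms has BH-adjusted p < 0.05
#' and an overlap of at least two module genes.
#'
#' @param enrichment data.frame from [enrich_module()] (columns `adj_p`,
#'   `overlap`).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_overlap minimal overlap (default 2).
#' @return Logical scalar verdict.
#' @export
functional_filter <- function(enrichment, alpha = 0.05, min_overlap = 2L) {
  if (!nrow(enrichment)) return(FALSE)
  any(enrichment$adj_p < alpha & enrichment$overlap >= min_overlap)
}

#' Enrich and filter every module of a ModuleSet
#'
#' @param modules a `ModuleSet`.
#' @param sets a `GeneSetCollection`.
#' @param universe gene universe.
#' @inheritParams functional_filter
#' @return List with `table` (combined enrichment data.frame with a `module`
#'   column and per-row verdict) and `functional` (logical per module).
#' @export
enrich_modules <- function(modules, sets, universe, alpha = 0.05,
                           min_overlap = 2L) {
  tabs <- lapply(seq_along(modules$modules), function(i) {
    t1 <- enrich_module(modules$modules[[i]], sets, universe)
    if (nrow(t1)) t1 <- cbind(module = sprintf("M%02d", i), t1)
    t1
  })
  functional <- vapply(tabs, functional_filter, logical(1L),
                       alpha = alpha, min_overlap = min_overlap)
  tab <- do.call(rbind, tabs[vapply(tabs, nrow, integer(1L)) > 0])
  if (is.null(tab)) {
    tab <- data.frame(module = character(), term = character(),
                      term_name = character(), overlap = integer(),
                      term_size = integer(), module_size = integer(),
                      universe_size = integer(), p = numeric(),
                      adj_p = numeric(), genes = character())
  }
  tab$functional <- if (nrow(tab)) functional[match(tab$module,
                                                    sprintf("M%02d", seq_along(functional)))]
                    else logical()
  list(table = tab, functional = functional)
}
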