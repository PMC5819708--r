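# Insulated heat diffusion on an interaction network.
#
# Heat placed on a node spreads along interactions by a random walk that
# restarts with probability beta, so a fraction of every node's heat stays
# "insulated" near its source. The stationary exchange is described by the
# diffusion operator F = beta * (I - (1 - beta) * W)^-1 with W the
# column-normalized walk matrix; F is column-stochastic, so diffusion
# conserves each node's heat exactly.

#' Heat scores from FDR-adjusted differential expression
#'
#' Genes are heated by how significant their differential expression is:
#' `h = -log10(max(FDR, cap))`. The cap keeps heat finite for extremely
#' small FDR values.
#'
#' @param diff a `DifferentialResult` (or any data.frame with columns
#'   `gene` and `FDR`).
#' @param cap lower cap on FDR (default 1e-10, i.e. maximal heat 10).
#' @return Named numeric vector of non-negative heat scores.
#' @export
heat_from_fdr <- function(diff, cap = 1e-10) {
  stopifnot(all(diff$FDR > 0 & diff$FDR <= 1))
  setNames(-log10(pmax(diff$FDR, cap)), diff$gene)
}

#' Build the insulated diffusion operator of a network
#'
#' Isolated nodes are removed first (recorded in the result); the walk
#' matrix W divides each node's outgoing heat equally among its neighbours,
#' and the operator is the dense solve
#' `F = beta * (I - (1 - beta) * W)^-1`. Every column of F sums to 1.
#'
#' @param net an [interaction_network()].
#' @param beta restart probability in (0,1); 0.4 is the standard choice for
#'   protein-interaction networks.
#' @return Object of class `DiffusionOperator`: list with `F` (dense matrix,
#'   dimnames = retained genes), `beta`, `nodes`, `n_isolated`.
#' @export
build_diffusion <- function(net, beta = 0.4) {
  stopifnot(beta > 0, beta < 1)
  deg <- table(factor(as.vector(net$edges), levels = net$nodes))
  keep <- names(deg)[deg > 0]
  n_iso <- length(net$nodes) - length(keep)
  if (!length(keep)) stop("network is empty after removing isolated nodes")
  n <- length(keep)
  idx <- setNames(seq_len(n), keep)
  W <- matrix(0, n, n, dimnames = list(keep, keep))
  i <- idx[net$edges[, 1L]]
  j <- idx[net$edges[, 2L]]
  W[cbind(i, j)] <- 1
  W[cbind(j, i)] <- 1
  W <- sweep(W, 2L, colSums(W), "/")        # column-stochastic
  Fmat <- beta * solve(diag(n) - (1 - beta) * W)
  structure(list(F = Fmat, beta = beta, nodes = keep, n_isolated = n_iso),
            class = "DiffusionOperator")
}

#' @export
print.DiffusionOperator <- function(x, ...) {
  cat(sprintf("DiffusionOperator: %d nodes, beta=%.2f (%d isolated removed)\n",
              length(x$nodes), x$beta, x$n_isolated))
  invisible(x)
}

#' Exchanged-heat matrix
#'
#' `E = F %*% diag(h)`: entry (i, j) is the amount of node j's heat that
#' ends up at node i. Column j sums to `h_j` (heat conservation). Genes
#' missing from the heat vector are given zero heat.
#'
#' @param op a [build_diffusion()] result.
#' @param heat named non-negative heat vector.
#' @return Dense matrix E with the operator's dimnames.
#' @export
exchanged_heat <- function(op, heat) {
  h <- rep(0, length(op$nodes))
  names(h) <- op$nodes
  common <- intersect(names(heat), op$nodes)
  h[common] <- heat[common]
  if (any(!is.finite(h)) || any(h < 0)) stop("heat must be finite and non-negative")
  E <- op$F * rep(h, each = length(h))      # column scaling
  attr(E, "heat") <- h
  E
}
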