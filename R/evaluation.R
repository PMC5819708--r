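# Module evaluation against independent phenotype data.
#
# A module's transcriptional activity is summarized by the first three
# principal components of its standardized expression submatrix (its
# eigengenes); associations of those components -- or of single genes --
# with clinical, metabolomic and redox variables are screened with Kendall
# tau-b and the dual rule |rho| >= 0.4 and p < 0.05.

#' Module eigengenes
#'
#' Genes are standardized to zero mean, unit variance across samples
#' (zero-variance genes are dropped with a warning); the principal
#' components of the resulting samples x genes matrix are the module's
#' eigengenes. The sign of each component is fixed so that its correlation
#' with the mean standardized module profile is non-negative, making
#' downstream correlation signs reproducible.
#'
#' @param submatrix numeric matrix, samples in rows, module genes in
#'   columns (or genes x samples with `genes_in_rows = TRUE`).
#' @param n_components number of components to keep (default 3).
#' @param genes_in_rows set when the matrix is oriented genes x samples.
#' @return Object of class `EigengeneSummary`: `scores` (samples x
#'   components), `var_frac`, `cum_var_frac`, `n_genes`.
#' @export
module_eigengenes <- function(submatrix, n_components = 3L,
                              genes_in_rows = FALSE) {
  x <- as.matrix(submatrix)
  if (genes_in_rows) x <- t(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from module")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!ncol(x)) stop("all module genes have zero variance")
  xs <- scale(x)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  total_var <- sum(pc$sdev^2)
  var_frac <- (pc$sdev^2 / total_var)[seq_len(k)]
  mean_profile <- rowMeans(xs)
  for (j in seq_len(k)) {
    r <- suppressWarnings(cor(scores[, j], mean_profile))
    if (!is.na(r) && r < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, var_frac = var_frac,
                 cum_var_frac = cumsum(var_frac), n_genes = ncol(x)),
            class = "EigengeneSummary")
}

# two-sided exact Kendall p by enumerating all n! orderings of y
# (a permutation test on S = concordant - discordant; valid with ties)
kendall_exact_p <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  P <- all_permutations(n)
  prs <- utils::combn(n, 2L)
  S <- numeric(nrow(P))
  for (q in seq_len(ncol(prs))) {
    i <- prs[1L, q]; j <- prs[2L, q]
    S <- S + sx[i, j] * sy[cbind(P[, i], P[, j])]
  }
  s_obs <- sum(sx[upper.tri(sx)] * sy[upper.tri(sy)])
  mean(abs(S) >= abs(s_obs) - 1e-9)
}

#' Kendall tau-b with two-sided p-value
#'
#' Tie-corrected tau-b. The p-value uses the tie-corrected normal
#' approximation for n >= 10 and exact enumeration of all orderings below
#' that.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @return List with `rho`, `p`, `n`.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  S <- sum(sx[up] * sy[up])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) stop("a variable is constant; tau-b undefined")
  rho <- S / den
  if (n < 10L) {
    p <- kendall_exact_p(x, y)
  } else {
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v0 <- n * (n - 1) * (2 * n + 5)
    v1 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v2 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(rho = rho, p = min(1, p), n = n)
}

#' Association selection rule
#'
#' The dual screening rule used throughout the evaluation: an association is
#' selected when `|rho| >= 0.4` and `p < 0.05`.
#'
#' @param rho Kendall tau-b.
#' @param p two-sided p-value.
#' @param rho_min,alpha thresholds.
#' @return Logical.
#' @export
association_selected <- function(rho, p, rho_min = 0.4, alpha = 0.05) {
  abs(rho) >= rho_min & p < alpha
}

#' Screen module eigengenes (or genes) against phenotype variables
#'
#' One Kendall correlation per (component, variable) pair -- or per
#' (gene, variable) pair when `profiles` is a plain matrix of gene profiles.
#' Missing phenotype values are handled pairwise-complete; the number of
#' pairs used is reported per association. Raw p drives selection (the dual
#' |rho|/p rule); BH-adjusted p across the screen is reported alongside.
#'
#' @param profiles either a named list of `EigengeneSummary` objects (keyed
#'   by module id) or a numeric matrix with one column per gene profile
#'   (rows = samples, aligned with `pheno`).
#' @param pheno numeric matrix or data.frame of phenotype variables, rows
#'   aligned with the profile rows.
#' @param rho_min,alpha selection thresholds (defaults 0.4, 0.05).
#' @return data.frame of class `AssociationResult`: level, module,
#'   component, variable, rho, p, FDR, n, selected.
#' @export
associate <- function(profiles, pheno, rho_min = 0.4, alpha = 0.05) {
  pheno <- as.data.frame(pheno)
  cols <- if (is.list(profiles) && !is.data.frame(profiles) &&
              !is.matrix(profiles)) {
    unlist(lapply(names(profiles), function(m) {
      sc <- profiles[[m]]$scores
      setNames(lapply(seq_len(ncol(sc)), function(j) sc[, j]),
               paste(m, colnames(sc), sep = "\r"))
    }), recursive = FALSE)
  } else {
    pm <- as.matrix(profiles)
    setNames(lapply(seq_len(ncol(pm)), function(j) pm[, j]),
             paste("gene", colnames(pm), sep = "\r"))
  }
  rows <- list()
  for (nm in names(cols)) {
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1L]]
    for (v in names(pheno)) {
      kt <- tryCatch(kendall_tau_b(cols[[nm]], pheno[[v]]),
                     error = function(e) NULL)
      if (is.null(kt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        level = if (parts[1L] == "gene") "gene" else paste0("module-", parts[2L]),
        module = if (parts[1L] == "gene") NA_character_ else parts[1L],
        component = if (parts[1L] == "gene") parts[2L] else parts[2L],
        variable = v, rho = kt$rho, p = kt$p, n = kt$n,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    out <- data.frame(level = character(), module = character(),
                      component = character(), variable = character(),
                      rho = numeric(), p = numeric(), n = integer(),
                      FDR = numeric(), selected = logical())
  } else {
    out <- do.call(rbind, rows)
    out$FDR <- bh_adjust(out$p)
    out$selected <- association_selected(out$rho, out$p, rho_min, alpha)
  }
  class(out) <- c("AssociationResult", "data.frame")
  out
}
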