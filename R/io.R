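#' @importFrom utils read.csv read.delim write.csv write.table
#' @importFrom stats p.adjust phyper pnorm prcomp cor sd quantile median setNames rnorm runif var
NULL

# ---- ExpressionMatrix ------------------------------------------------------

#' Construct an expression matrix with sample metadata
#'
#' The central expression container: a genes x samples matrix of log2
#' intensities plus per-sample metadata (group, timepoint, subject). All
#' downstream stages (contrasts, heat scores, eigengenes) consume this type.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   must carry gene symbols and sample ids.
#' @param metadata data.frame with columns `sample`, `group` (factor-like,
#'   e.g. COPD/healthy), `timepoint` (pre/post) and `subject`; one row per
#'   sample of `values`.
#' @return An object of class `ExpressionMatrix` (list with `values`,
#'   `genes`, `samples`, `metadata`).
#' @export
expression_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(genes)) stop("duplicate gene symbols in expression matrix")
  if (anyDuplicated(samples)) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(values))) stop("expression values must be finite")
  metadata <- as.data.frame(metadata)
  req <- c("sample", "group", "timepoint", "subject")
  if (!all(req %in% names(metadata))) {
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  }
  missing_md <- setdiff(samples, metadata$sample)
  if (length(missing_md)) {
    stop("samples absent from metadata: ", paste(missing_md, collapse = ", "))
  }
  metadata <- metadata[match(samples, metadata$sample), req, drop = FALSE]
  if (anyNA(metadata)) stop("metadata has missing fields for some samples")
  rownames(metadata) <- NULL
  structure(
    list(values = values, genes = genes, samples = samples, metadata = metadata),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (%s)\n",
    length(x$genes), length(x$samples),
    paste(sprintf("%s=%d", names(table(x$metadata$group)), table(x$metadata$group)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' Expression values are a tab-separated matrix (first column probe or gene
#' ids, header row of sample ids); metadata is a CSV with columns
#' sample, group, timepoint, subject. When a probe-to-gene map is supplied,
#' probes are collapsed to genes by keeping, per gene, the probe with the
#' highest mean intensity across all samples (ties broken lexicographically
#' by probe id).
#'
#' @param path path to the TSV expression matrix.
#' @param metadata_path path to the metadata CSV.
#' @param probe_map optional path to a two-column TSV (probe, gene) used to
#'   collapse probes; when `NULL` row ids are taken as gene symbols.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path, probe_map = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression matrix needs an id column plus samples")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in expression matrix")
  rownames(vals) <- ids
  if (anyDuplicated(ids) && is.null(probe_map)) {
    stop("duplicate row ids without a probe map")
  }
  if (!is.null(probe_map)) {
    pm <- read.delim(probe_map, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(pm) < 2L) stop("probe map must have two columns: probe, gene")
    vals <- collapse_probes(vals, setNames(as.character(pm[[2L]]),
                                           as.character(pm[[1L]])))
  }
  md <- read.csv(metadata_path, stringsAsFactors = FALSE)
  expression_matrix(vals, md)
}

#' Collapse probe-level rows to genes
#'
#' Keeps, for each gene, the probe with the highest mean intensity across all
#' samples; ties are broken lexicographically by probe id. Probes absent from
#' the map are dropped.
#'
#' @param vals numeric matrix with probe rownames.
#' @param map named character vector probe -> gene symbol.
#' @return Numeric matrix with gene rownames; never more rows than `vals`.
#' @export
collapse_probes <- function(vals, map) {
  keep <- rownames(vals) %in% names(map)
  vals <- vals[keep, , drop = FALSE]
  if (!nrow(vals)) stop("no probes matched the probe map")
  gene <- unname(map[rownames(vals)])
  m <- rowMeans(vals)
  ord <- order(gene, -m, rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  gene <- gene[ord]
  sel <- !duplicated(gene)
  out <- vals[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out[order(rownames(out)), , drop = FALSE]
}

#' Write an expression matrix (and optionally its metadata) back to disk
#' @param expr an [expression_matrix()].
#' @param path TSV path for the value matrix.
#' @param metadata_path optional CSV path for the metadata.
#' @export
write_expression <- function(expr, path, metadata_path = NULL) {
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    write.csv(expr$metadata, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(expr)
}

# ---- InteractionNetwork ----------------------------------------------------

#' Construct an undirected interaction network
#'
#' @param edges two-column character matrix or data.frame of gene-symbol
#'   pairs. Self-loops are dropped (with a message) and duplicate edges
#'   (either orientation) are collapsed.
#' @param name identifier of the source interactome.
#' @param nodes optional character vector of additional isolated nodes.
#' @return Object of class `InteractionNetwork` with `name`, `edges`
#'   (two-column character matrix, pair-sorted), `nodes`.
#' @export
interaction_network <- function(edges, name = "network", nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  n_loops <- 0L
  if (nrow(edges)) {
    loops <- edges[, 1L] == edges[, 2L]
    n_loops <- sum(loops)
    edges <- edges[!loops, , drop = FALSE]
    if (nrow(edges)) {
      swap <- edges[, 1L] > edges[, 2L]
      edges[swap, ] <- edges[swap, c(2L, 1L)]
      edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r")), ,
                     drop = FALSE]
    }
  }
  if (n_loops) nh_log("%s: dropped %d self-loop(s)", name, n_loops)
  all_nodes <- sort(unique(c(as.vector(edges), nodes)))
  structure(list(name = name, edges = edges, nodes = all_nodes),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a protein-protein interaction network from an edge list
#'
#' Each non-comment line holds two whitespace- or tab-separated gene symbols.
#' Lines starting with `#` are ignored. Duplicate edges and self-loops are
#' removed.
#'
#' @param path path to the edge-list file.
#' @param name network identifier (defaults to the file name).
#' @return An [interaction_network()].
#' @export
read_network <- function(path, name = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty network file: ", path)
    return(interaction_network(matrix(character(), 0L, 2L), name = name))
  }
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge line %d in %s: expected 2 tokens, got %d",
                 which(keep)[bad[1L]], path, lengths(toks)[bad[1L]]))
  }
  interaction_network(do.call(rbind, toks), name = name)
}

#' Write a network as a two-column edge list
#' @param net an [interaction_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(net)
}

#' Convert an InteractionNetwork to an igraph object
#' @param net an [interaction_network()].
#' @return An undirected `igraph` graph over `net$nodes`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

# ---- GeneSetCollection -----------------------------------------------------

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `term id`,
#' `description`, then one or more gene symbols. Genes repeated within a line
#' are stored once; a duplicated term id is an error.
#'
#' @param path path to the GMT file.
#' @return Object of class `GeneSetCollection`: list with `sets` (named list
#'   of gene vectors), `names` (term descriptions) and `universe` (all genes
#'   appearing in any set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has %d fields; at least 3 required",
                 short[1L], lengths(fields)[short[1L]]))
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term id in GMT: ", ids[duplicated(ids)][1L])
  }
  descs <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- ids
  gene_set_collection(sets, setNames(descs, ids))
}

#' Construct a gene-set collection
#' @param sets named list of character gene vectors (each non-empty).
#' @param names optional named character vector of term descriptions.
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  if (any(lengths(sets) == 0L)) stop("empty gene set")
  if (is.null(names)) names <- setNames(base::names(sets), base::names(sets))
  structure(list(sets = sets, names = names,
                 universe = sort(unique(unlist(sets, use.names = FALSE)))),
            class = "GeneSetCollection")
}

#' Write a gene-set collection in GMT format
#' @param gsc a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, unname(gsc$names[id]), gsc$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(gsc)
}

# ---- PhenotypeTable --------------------------------------------------------

#' Read a phenotype table
#'
#' CSV keyed by subject id, optionally with a `timepoint` column, followed by
#' named numeric clinical/metabolomic/redox variables. Missing values are
#' retained and handled pairwise-complete at correlation time.
#'
#' @param path path to the CSV.
#' @return A data.frame of class `PhenotypeTable` with attribute
#'   `variables` naming the numeric measurement columns.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) stop("phenotype table needs a 'subject' column")
  key <- intersect(c("subject", "timepoint"), names(df))
  vars <- setdiff(names(df), key)
  for (v in vars) {
    if (!is.numeric(df[[v]])) stop("phenotype variable not numeric: ", v)
  }
  attr(df, "variables") <- vars
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

# ---- Contrast --------------------------------------------------------------

#' Define a differential contrast
#'
#' Two designs are supported: `two-class-unpaired` compares the samples
#' selected for class A against those of class B (e.g. COPD vs healthy at the
#' pre-training timepoint); `paired` compares post vs pre within subjects, so
#' the two selectors must cover the same subjects.
#'
#' @param label contrast label; the study's three contrasts are
#'   `COPD-DE` (disease effect), `COPD-TE` and `Healthy-TE` (training
#'   effects), but any label is accepted.
#' @param design `"two-class-unpaired"` or `"paired"`.
#' @param a,b character vectors of sample ids for class A / class B (for
#'   paired designs: post samples in `a`, pre samples in `b`).
#' @param metadata the sample metadata of the expression matrix, used to
#'   check the selectors.
#' @return An object of class `Contrast`.
#' @export
contrast <- function(label, design = c("two-class-unpaired", "paired"),
                     a, b, metadata) {
  design <- match.arg(design)
  stopifnot(is.character(a), is.character(b))
  unknown <- setdiff(c(a, b), metadata$sample)
  if (length(unknown)) {
    stop("contrast selectors name unknown samples: ",
         paste(unknown, collapse = ", "))
  }
  if (design == "paired") {
    sub_a <- metadata$subject[match(a, metadata$sample)]
    sub_b <- metadata$subject[match(b, metadata$sample)]
    if (anyDuplicated(sub_a) || anyDuplicated(sub_b) ||
        !setequal(sub_a, sub_b)) {
      stop("paired design requires a subject bijection between selectors")
    }
    if (length(a) < 3L) stop("need at least 3 subject pairs")
    # align b to a by subject
    b <- b[match(sub_a, sub_b)]
  } else {
    if (length(a) < 3L || length(b) < 3L) {
      stop("need at least 3 samples per side")
    }
  }
  structure(list(label = label, design = design, a = a, b = b),
            class = "Contrast")
}

#' Build the study's standard contrast from metadata
#'
#' Convenience constructor for the three canonical contrasts: `COPD-DE`
#' (COPD vs healthy, pre-training), `COPD-TE` and `Healthy-TE` (post vs pre
#' within group).
#'
#' @param label one of `"COPD-DE"`, `"COPD-TE"`, `"Healthy-TE"`.
#' @param metadata sample metadata with group/timepoint/subject columns.
#' @return A [contrast()].
#' @export
standard_contrast <- function(label, metadata) {
  md <- metadata
  pick <- function(g, t) md$sample[md$group == g & md$timepoint == t]
  switch(label,
    "COPD-DE" = contrast(label, "two-class-unpaired",
                         a = pick("COPD", "pre"), b = pick("healthy", "pre"),
                         metadata = md),
    "COPD-TE" = contrast(label, "paired",
                         a = pick("COPD", "post"), b = pick("COPD", "pre"),
                         metadata = md),
    "Healthy-TE" = contrast(label, "paired",
                            a = pick("healthy", "post"),
                            b = pick("healthy", "pre"), metadata = md),
    stop("unknown standard contrast: ", label)
  )
}

# ---- harmonization ---------------------------------------------------------

#' Harmonize an expression matrix with one or more networks
#'
#' Module discovery operates on genes present both on the array and in each
#' interactome: every network is reduced to the subgraph induced by the
#' measured genes. The operation is idempotent.
#'
#' @param expr an [expression_matrix()].
#' @param nets a list of [interaction_network()] objects (or a single one).
#' @return A list with `expr` (unchanged), `nets` (induced networks) and
#'   `report` (data.frame of node/edge counts retained and dropped per
#'   network).
#' @export
harmonize <- function(expr, nets) {
  if (inherits(nets, "InteractionNetwork")) nets <- list(nets)
  genes <- expr$genes
  out <- vector("list", length(nets))
  rep_rows <- vector("list", length(nets))
  for (i in seq_along(nets)) {
    net <- nets[[i]]
    keep_edge <- net$edges[, 1L] %in% genes & net$edges[, 2L] %in% genes
    kept_nodes <- intersect(net$nodes, genes)
    induced <- interaction_network(net$edges[keep_edge, , drop = FALSE],
                                   name = net$name)
    if (!length(induced$nodes)) {
      warning("network '", net$name, "' shares no genes with the expression matrix")
    }
    out[[i]] <- induced
    rep_rows[[i]] <- data.frame(
      network = net$name,
      nodes_in = length(net$nodes),
      nodes_kept = length(induced$nodes),
      nodes_dropped = length(net$nodes) - length(kept_nodes),
      edges_in = nrow(net$edges),
      edges_kept = nrow(induced$edges),
      stringsAsFactors = FALSE
    )
  }
  list(expr = expr, nets = out, report = do.call(rbind, rep_rows))
}
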