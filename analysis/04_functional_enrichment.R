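#!/usr/bin/env Rscript
# Step 4 -- functional characterization of the consensus modules.
#
# Each consensus module is tested for over-represented annotation terms
# (hypergeometric upper tail on the network gene universe, BH within
# module); a module is functionally significant when at least one term
# reaches adjusted p < 0.05 with at least two module genes. In the
# synthetic study the generated GMT contains one term per planted module
# plus random sets, so functionally significant modules should be exactly
# the recovered planted ones.

library(netheat)

dir <- "results/synthetic/disease-effect"
expr <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "metadata.csv"))
nets <- lapply(Sys.glob(file.path(dir, "network_*.txt")), read_network)
gmt <- read_gmt(file.path(dir, "gene_sets.gmt"))

mods_tab <- read.delim("results/modules/consensus_COPD_DE.tsv")
modules <- split(mods_tab$gene, mods_tab$module)
ms <- structure(list(modules = unname(modules),
                     mean_heat = rep(NA_real_, length(modules)),
                     delta = NA_real_, min_size = 3L, provenance = list(),
                     component_sizes = lengths(modules),
                     significant = rep(TRUE, length(modules))),
                class = "ModuleSet")

universe <- sort(unique(unlist(lapply(harmonize(expr, nets)$nets,
                                      `[[`, "nodes"))))
enr <- enrich_modules(ms, gmt, universe)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(enr$table, "results/enrichment/enrichment_COPD_DE.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (i in seq_along(modules)) {
  top <- enr$table[enr$table$module == names(modules)[i], ][1, ]
  message(sprintf(
    "%s (%d genes): functionally significant = %s; top term %s (overlap %s, adj p %.2g)",
    names(modules)[i], length(modules[[i]]), enr$functional[i],
    top$term, top$overlap, top$adj_p
  ))
}
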