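#!/usr/bin/env Rscript
# Step 5 -- evaluating modules against independent phenotype data.
#
# Module transcriptional activity is summarized by the first three
# eigengenes (principal components of the standardized module submatrix);
# associations with the phenotype variables are screened by Kendall tau-b
# with the dual rule |rho| >= 0.4 and p < 0.05. In the disease-effect study
# the first planted module is coupled to the VO2-peak-like variable at
# population tau 0.5, so its PC1 should be selected; the remaining
# variables are noise and should not be.

library(netheat)
suppressPackageStartupMessages(library(ggplot2))

dir <- "results/synthetic/disease-effect"
expr <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "metadata.csv"))
pheno <- read_phenotypes(file.path(dir, "phenotypes.csv"))
mods_tab <- read.delim("results/modules/consensus_COPD_DE.tsv")
modules <- split(mods_tab$gene, mods_tab$module)

md <- expr$metadata
pre <- md$sample[md$timepoint == "pre"]
eig <- lapply(modules, function(m) {
  suppressWarnings(module_eigengenes(expr$values[m, pre, drop = FALSE],
                                     genes_in_rows = TRUE))
})
ph <- as.data.frame(pheno)
ph <- ph[ph$timepoint == "pre", ]
ph <- ph[match(md$subject[match(pre, md$sample)], ph$subject), ]
assoc <- associate(eig, ph[, attr(pheno, "variables")])

dir.create("results/associations", showWarnings = FALSE, recursive = TRUE)
write.table(assoc, "results/associations/associations_COPD_DE.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- assoc[assoc$selected, ]
message(sprintf("%d of %d associations selected (|rho| >= 0.4, p < 0.05):",
                nrow(sel), nrow(assoc)))
for (i in seq_len(nrow(sel))) {
  message(sprintf("  %s %s ~ %s: rho = %.2f, p = %.3g, n = %d",
                  sel$module[i], sel$component[i], sel$variable[i],
                  sel$rho[i], sel$p[i], sel$n[i]))
}

mean_var3 <- mean(vapply(eig, function(e) {
  e$cum_var_frac[min(3, length(e$cum_var_frac))]
}, numeric(1)))
message(sprintf(
  "first three eigengenes explain on average %.0f%% of module variability",
  100 * mean_var3
))

# association map (modules x variables, selected cells marked)
assoc$cell <- paste(assoc$module, assoc$component)
p1 <- ggplot(assoc, aes(variable, cell, fill = rho)) +
  geom_tile() +
  geom_text(aes(label = ifelse(selected, "*", "")), size = 5) +
  scale_fill_gradient2(limits = c(-1, 1)) +
  labs(x = NULL, y = NULL, fill = "Kendall rho",
       title = "Module eigengene vs phenotype associations (pre-training)") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 45, hjust = 1))
ggsave("results/associations/association_map.pdf", p1, width = 7, height = 5)

# scatter of the strongest selected association, groups coloured
if (nrow(sel)) {
  best <- sel[which.max(abs(sel$rho)), ]
  df <- data.frame(
    score = eig[[best$module]]$scores[, best$component],
    value = ph[[best$variable]],
    group = md$group[match(pre, md$sample)]
  )
  p2 <- ggplot(df, aes(score, value, colour = group)) +
    geom_point(size = 2) +
    geom_smooth(method = "lm", se = FALSE, colour = "grey40",
                linewidth = 0.5) +
    labs(x = paste(best$module, best$component), y = best$variable,
         title = sprintf("rho = %.2f, p = %.3g", best$rho, best$p)) +
    theme_classic()
  ggsave("results/associations/top_association.pdf", p2, width = 5,
         height = 4)
}
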