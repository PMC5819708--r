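# netheat

Network-module analysis of small-cohort transcriptome studies: rank-product
differential expression, insulated heat-diffusion module discovery on
protein–protein interaction (PPI) networks with permutation significance and
multi-network consensus, gene-set functional filtering, and eigengene /
Kendall evaluation of modules against independent phenotype data.

The motivating setting is skeletal-muscle dysfunction in COPD: fifteen
patients and twelve healthy sedentary controls profiled before and after an
endurance-training program, with three differential conditions — the disease
effect at baseline (COPD-DE) and the training effects within each group
(COPD-TE, Healthy-TE). With cohorts this small, per-gene statistics are
noisy; the package looks instead for *modules*, connected network
neighbourhoods of coordinated transcriptional change, and then asks whether
their activity tracks independent clinical, metabolomic and redox
measurements.

## The method in brief

1. **Differential expression.** Per contrast, the rank product
   `RP_g = (∏_c r_gc)^(1/C)` over replicate comparisons (average ranks on
   ties), with permutation p-values from the pooled null
   `p_g = (1 + #{permuted RP ≤ RP_g}) / (1 + B·G)` and Benjamini–Hochberg
   FDR.
2. **Heat diffusion.** Heat `h_g = −log10(max(FDR_g, 1e−10))` spreads over
   each interactome by a random walk with restart `β = 0.4`:
   `F = β (I − (1−β) W)⁻¹` with `W` the column-normalised walk matrix; `F`
   is column-stochastic, so heat is conserved. The exchanged-heat matrix is
   `E = F · diag(h)`.
3. **Modules.** Thresholding `E ≥ δ` gives a directed graph whose strongly
   connected components (size ≥ 3) are modules. δ is swept over a geometric
   grid anchored at a permutation-selected background scale; module
   count/size significance comes from heat-label permutations; the majority
   consensus over all (network × δ) runs yields the final modules.
4. **Functional filter.** Hypergeometric over-representation against a GMT
   term collection (BH within module); a module is functionally significant
   iff some term has adjusted p < 0.05 and ≥ 2 module genes.
5. **Evaluation.** Module activity = first three eigengenes (PCs of the
   standardized module submatrix); associations with phenotype variables by
   Kendall tau-b, selected when `|rho| ≥ 0.4` and `p < 0.05` (post−pre
   differentials for training contrasts).

A fully seeded synthetic-study generator (scale-free interactome, planted
near-clique modules, phenotypes coupled to module activity at a target
Kendall tau) provides ground truth for every stage; see the methods
vignette `vignettes/network-module-discovery.Rmd` for the model, parameter
defaults and design rationale.

## Worked example

The `analysis/` scripts run the whole study on a generated dataset
(`seed = 7`). Step 1 writes the synthetic study; steps 2–5 print, among
other things:

```
COPD-DE: 1000 genes, 36 at FDR < 0.05, 52 at FDR < 0.25
consensus: 4 module(s) of sizes [6, 9, 11, 11]
planted module 1 (size 9): best Jaccard 0.82
planted module 2 (size 6): best Jaccard 1.00
planted module 3 (size 10): best Jaccard 0.91
planted module 4 (size 7): best Jaccard 0.78
M01 (6 genes): functionally significant = TRUE; top term PM:002 (overlap 6, adj p 7.3e-15)
4 of 84 associations selected (|rho| >= 0.4, p < 0.05):
  M01 PC1 ~ VO2_peak: rho = 0.54, p = 6.84e-05, n = 27
  ...
first three eigengenes explain on average 91% of module variability
```

Reading this: the disease contrast concentrates its FDR tail on the 30
planted genes; module discovery returns exactly four consensus modules that
recover the four planted modules (Jaccard 0.78–1.00); each is functionally
significant for its own planted term; and the eigengene screen selects the
PC1–VO2-peak associations at n = 27 — the planted coupling (population
Kendall tau 0.5) plus the disease-driven modules that separate the groups —
while none of the six noise variables is selected.

The same machinery is available programmatically:

```r
library(netheat)
st  <- synth_generate("disease-effect", seed = 7)
res <- run_condition(st$expr, st$nets, st$gmt, st$pheno, "COPD-DE", seed = 7)
module_recovery(res$consensus, st$truth$planted)
subset(res$associations, selected)
```

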