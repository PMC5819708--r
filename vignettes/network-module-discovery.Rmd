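---
title: "Heat-diffusion network modules from rank-product differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-diffusion network modules from rank-product differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netheat)
options(netheat.quiet = TRUE)
```

## The problem

Skeletal-muscle dysfunction in chronic obstructive pulmonary disease (COPD)
is not driven by a single gene but by coordinated shifts of interacting
proteins. With a small cohort (here, fifteen patients and twelve sedentary
healthy controls, sampled before and after an endurance-training program),
per-gene statistics are noisy and pathway-level signal is easy to miss.
`netheat` implements a network strategy for this setting: per-gene
differential-expression evidence is treated as *heat* placed on the nodes of
a protein--protein interaction (PPI) network, heat spreads to interaction
partners by an insulated random walk, and *network modules* -- connected
sets of genes that persistently exchange heat -- are extracted, tested
against permutation nulls, reconciled across several interactomes,
functionally filtered with gene-set over-representation, and finally
evaluated against independent clinical, metabolomic and redox measurements.

Because the original cohort's microarrays are not publicly deposited, the
package ships a fully specified synthetic-study generator with planted
ground truth; every stage of the pipeline is verified against it.

## Differential expression: the rank product

For each contrast (disease effect: COPD vs healthy at baseline; training
effects: post vs pre within each group) we use the rank product, a
non-parametric statistic suited to noisy, small-n designs. Within each
replicate comparison the genes are ranked by log2 ratio -- ascending for
down-regulation, descending for up-regulation, average ranks on ties -- and
a gene's statistic is the geometric mean of its ranks:
$RP_g = \left(\prod_c r_{gc}\right)^{1/C} \in [1, G]$.

**Comparisons.** Paired contrasts use one post&minus;pre difference vector
per subject. For unpaired contrasts the classical recipe forms all
$n_A \times n_B$ sample pairs; because those pairs share samples, their
rank columns are correlated, and the permutation null below (which shuffles
columns independently) then *understates* the tails -- we measured dozens of
pure-noise genes at $p \le 10^{-3}$ where one is expected. The default is
therefore a seeded random *disjoint* pairing: $\min(n_A, n_B)$ comparisons
in which no sample is reused, which are mutually independent and exactly
calibrated under the shuffle null. The all-pairs construction remains
available (`pairing = "all"`, capped at `max_pairs = 30`) for comparison
with the classical recipe.

**Significance.** Each of `n_perm = 1000` permutations independently
shuffles the rank column of every comparison and recomputes all $G$ rank
products; the pooled construction
$p_g = \bigl(1 + \#\{\text{permuted } RP \le RP_g\}\bigr) / (1 + B\,G)$
is the expected-false-positives count normalised to a p-value, with a
pseudo-count keeping $p > 0$ so that $-\log_{10}$ heat stays finite. The
two-sided summary $p = \min(1,\, 2\min(p_{up}, p_{down}))$ is deliberately
conservative: a gene cannot be extreme in both directions, so mass stacks
at 1; uniformity under the null holds for the directional p-values (mean
Kolmogorov--Smirnov distance $\approx 0.03$ at $G = 500$), and that is what
the test suite asserts. FDR is Benjamini--Hochberg.

## Heat diffusion and module extraction

Heat is $h_g = -\log_{10}(\max(\mathrm{FDR}_g, 10^{-10}))$; the cap bounds
heat at 10 for arbitrarily small FDR. With $W$ the column-normalised walk
matrix of the (harmonized, isolated-nodes-removed) network and restart
probability $\beta = 0.4$ -- the standard choice for PPI networks -- the
insulated diffusion operator is

$$F = \beta\,\bigl(I - (1-\beta) W\bigr)^{-1},$$

a column-stochastic matrix (each column sums to 1 within $10^{-10}$:
diffusion conserves heat). The exchanged-heat matrix is
$E = F\,\mathrm{diag}(h)$; entry $(i, j)$ is the amount of $j$'s heat
arriving at $i$. Thresholding ($E_{ij} \ge \delta$, $i \ne j$) gives a
directed graph whose strongly connected components of size $\ge$
`min_size = 3` are the modules: gene sets whose members all exchange at
least $\delta$ heat along directed cycles. The dense solve is exact and
fast at the scales used here ($\le$ a few thousand nodes); an iterative
solver is unnecessary.

**Choosing $\delta$, and why a sweep.** The permutation heuristic shuffles
heat over nodes and finds, by bisection over the sorted distinct entries of
the permuted $E$, the minimal $\delta$ at which the largest component has
size $\le l_{max} = 10$; the median over 20 permutations estimates the
*background* exchange scale. A single threshold at that scale, however,
lets distinct hot neighbourhoods chain together through one- or two-gene
"warm corridors" (we observed all four planted modules of a synthetic study
merged into one 48-node component), while a single larger threshold
fragments true modules. Since raising $\delta$ only ever refines modules (a
monotone hierarchy), the pipeline extracts modules at a geometric grid of
`n_delta = 7` thresholds spanning the background scale up to past the point
where the observed components become small, and defers the choice to the
consensus step. This mirrors the consensus procedure of the published
heat-diffusion method, which likewise combines runs across interactomes
*and* thresholds.

**Significance of counts and sizes.** For each run, `sig_perm = 99` heat
permutations are re-thresholded (one shared permutation pass serves the
whole grid) and tabulated as $X_k$, the number of components of size
$\ge k$, for $k = 2 \ldots k_{max}$;
$p_k = (1 + \#\{\text{perm}: \text{count}_k \ge X_k\})/(1 + B)$. A module
is significant when $p_k < 0.05$ for some $k$ up to its size. Note the
attainability constraint: with $B$ permutations the smallest possible $p$
is $1/(B+1)$, so $B$ must exceed 19 for the 0.05 flag to be reachable at
all.

**Consensus.** Two genes are linked once per (network, $\delta$) run in
which they share a significant module; edges supported by a majority of
runs are kept and the connected components of size $\ge 3$ are the
consensus modules, annotated with their supporting networks. Pairs inside a
genuine module co-occur at almost every resolution; corridor pairs co-occur
only at the lowest thresholds and are voted out. With a single run per
network this reduces exactly to the majority-across-networks rule.

## Functional filter and phenotype evaluation

Each consensus module is tested against every annotation term it overlaps
(hypergeometric upper tail; universe = genes of the harmonized networks,
since modules can only contain network genes; `universe = "array"`
switches to the full array). BH adjustment is within module, matching the
per-module statement of the filter: a module is *functionally significant*
iff some term has adjusted $p < 0.05$ and at least two module genes in the
overlap.

Module activity is summarised by the first three principal components
("eigengenes") of the gene-standardized module submatrix; standardization
is used because array intensities have gene-specific scales. Each
component's sign is fixed so that it correlates non-negatively with the
mean standardized module profile, making downstream correlation signs
reproducible. Associations between components (or single genes) and
phenotype variables use Kendall tau-b with tie correction --
pairwise-complete on missing data, exact enumeration of all $n!$ orderings
below $n = 10$ and the tie-corrected normal approximation otherwise -- and
the screening rule $|\rho| \ge 0.4$ and $p < 0.05$. The rule is applied on
raw p-values (as stated); BH-adjusted values are reported alongside for
transparency. For training contrasts, per-subject post&minus;pre
differentials of both eigengene scores and phenotype variables are
correlated.

## The synthetic-study generator

The generator emulates the study design so that every stage has ground
truth:

* **Interactome**: preferential attachment (`m = 2` edges per node,
  1000 genes), giving the heavy-tailed degree distribution of real PPI
  networks; two perturbed variants (5% of unprotected edges rewired)
  emulate multiple curated interactomes, and never touch planted edges.
* **Planted modules**: connected subgraphs grown by seeded BFS, pairwise
  separated by $\ge 3$ hops (two adjacent "distinct" modules would form a
  single heat-coherent region -- an ill-posed truth) and densified to
  near-cliques (`p_edge = 0.8`), the topology of protein complexes and the
  structure a diffusion method is designed to detect. The disease preset
  plants four modules of sizes 6--10 with a 2.0 log2-unit effect on the
  COPD group.
* **Expression**: baseline $\sim N(7, 1)$ per gene, subject effect
  $SD = 0.3$, i.i.d. noise $SD = 0.5$ (log2 scale), plus *diffuse* weak
  per-gene group and training effects ($SD = 0.15$) on every gene. The
  diffuse term matters: real contrasts show a continuum of small
  fold-changes, and without it every background gene has FDR $\approx 1$,
  zero heat, and no background exchange scale exists for the $\delta$
  heuristic to estimate.
* **Phenotypes**: one row per (subject, timepoint). A coupled variable is a
  monotone function of the planted module's mean standardized expression
  plus Gaussian noise whose SD is calibrated by bisection on a large
  common-random-numbers sample so the population Kendall tau matches the
  target (tau has no convenient closed form under noise; bisection is
  directly verifiable). Uncoupled variables are pure noise.

What the generator does **not** emulate: probe-level artifacts, batch
effects, realistic metabolite covariance beyond the specified couplings, or
biased/incomplete interactome curation. Passing tests therefore demonstrate
the pipeline's statistical behaviour under its own model of the data, not
performance on any particular real cohort.

## Problem sizes and numerical choices

The verification suite runs the full pipeline on 20 seeded disease-effect
studies and 20 global-null studies at 1000 genes, three networks and the
study's sample sizes, plus enumeration- and closed-form oracles at tiny
sizes; these scales were chosen so a complete desk-scale replication
finishes in minutes while keeping the planted-module recovery and
false-positive rates statistically meaningful. Other numerical notes:

* ties in probe collapsing break lexicographically by probe id, making the
  collapse deterministic;
* the rank-product pseudo-count and heat cap jointly bound heat in
  $[0, 10]$;
* degenerate inputs (empty networks after harmonization, all-zero heat,
  zero-variance genes in a module) produce empty results or explicit
  errors, never silent misbehaviour;
* every stochastic stage derives its seed from the master seed and a stage
  tag, so whole-study reruns are byte-identical and single stages can be
  reproduced in isolation.

## Known limitations

The method inherits the assumptions of its inputs: protein activity is
modelled by transcript abundance; interactome coverage bounds what modules
can be seen; heat permutation preserves topology but not the degree--heat
correlation (full network-permutation nulls are out of scope for runtime
reasons); and the association screen uses the stated raw dual threshold, so
its family-wise behaviour across many modules and variables should be
judged with the reported FDR column in hand.
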