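#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic studies.
#
# Three preset scenarios stand in for the trial data: a disease-effect study
# (four transcriptionally active modules planted on the interactome of COPD
# muscle, with a VO2-peak-like variable coupled to the first module), a
# healthy-training study, and a global-null study with no planted structure.
# Every file written here is a plain-text input for the downstream steps.

library(netheat)

seed <- 7L
out_root <- "results/synthetic"

for (preset in c("disease-effect", "training-effect-healthy", "global-null")) {
  st <- synth_generate(preset, seed = seed)
  dir <- file.path(out_root, preset)
  paths <- write_synthetic_study(st, dir)
  n_planted <- length(st$truth$planted)
  message(sprintf(
    "%s: %d genes x %d samples, %d networks, %d planted module(s) -> %s",
    preset, length(st$expr$genes), length(st$expr$samples),
    length(st$nets), n_planted, dir
  ))
}

message("Study conditions: 15 COPD / 12 healthy subjects, pre/post training,")
message("1000 genes on a preferential-attachment interactome (m = 2).")
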