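#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the complete synthetic study: a modular 250-protein interactome
# (10 blocks of 25; within-block edge probability 0.25, between 0.01;
# confidence scores uniform on [0.9, 1]), a 20-protein disease signature
# planted inside one module, four drug targets placed one hop from the
# signature, a one-to-one ortholog layer to a 500-gene "swine" expression
# study (4 samples per group, 1.5 log2-unit shifts on the signature genes,
# gene variances from a scaled inverse-chi-square prior with d0 = 4,
# s0sq = 0.05), and writes everything as plain-text exchange files plus a
# JSON truth sidecar.

library(remodnet)

seed <- 2026
dir.create("results", showWarnings = FALSE)

ds <- gen_pipeline_dataset(seed = seed)
paths <- write_pipeline_dataset(ds, "results/data")

cat("simulated study written to results/data/\n")
cat(sprintf("  interactome: %d proteins, %d interactions\n",
            length(ds$interactome$nodes), nrow(ds$interactome$interactions)))
cat(sprintf("  signature: %d proteins in block %s; %d drug targets at 1 hop\n",
            length(ds$signature), ds$interactome$block_of[[ds$signature[1]]],
            length(ds$targets)))
cat(sprintf("  expression: %d genes x %d samples, %d planted differential\n",
            nrow(ds$expression$matrix$values),
            ncol(ds$expression$matrix$values), length(ds$de_genes)))
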