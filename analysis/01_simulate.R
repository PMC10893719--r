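#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates the synthetic IgAN-like microarray cohort the whole analysis
# runs on: 90 cases carrying 3 planted molecular subtypes + 12 controls,
# 2000 genes on the log2 scale, a 40-gene shared disease signature, one
# 60-gene block per subtype, 2 batches. Writes the expression matrix,
# sample annotation, and the ground truth needed by later stages.

suppressPackageStartupMessages(library(igansubtypes))

seed <- 1L
outdir <- "results/01_cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cf <- sim_config(n_case = 90, n_ctrl = 12, seed = stage_seed(seed, "simulate"))
cohort <- generate_cohort(cf)

write_expression_tsv(cohort$expr, file.path(outdir, "expression_raw.tsv"))
write.table(cohort$annotation, file.path(outdir, "annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(true_de_genes = cohort$truth$true_de_genes,
       true_global_de = cohort$truth$true_global_de,
       trait_loadings = lapply(cohort$truth$trait_loadings, as.list),
       true_subtype = cohort$truth$true_subtype),
  file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d genes x %d samples (%d cases / %d controls)\n",
            nrow(cohort$expr), ncol(cohort$expr), cf$n_case, cf$n_ctrl))
cat(sprintf("planted: %d-gene shared block + 3 x %d-gene subtype blocks\n",
            cf$n_global_de, cf$n_de_per_subtype))
cat(sprintf("subtype sizes: %s\n",
            paste(table(cohort$truth$true_subtype), collapse = " / ")))
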