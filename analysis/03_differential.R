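#!/usr/bin/env Rscript
# Stage 3 — global differential expression screen.
#
# Welch t per gene, BH adjustment, thresholds adjusted p < 0.05 and
# |log2FC| > 1.7. The passing genes are the disease signature used as the
# feature set for subtype discovery and the classifier.

suppressPackageStartupMessages(library(igansubtypes))

expr <- read_expression_tsv("results/02_preprocessed/expression_adjusted.tsv")
ann <- read.delim("results/01_cohort/annotation.tsv")
truth <- jsonlite::read_json("results/01_cohort/ground_truth.json",
                             simplifyVector = TRUE)
outdir <- "results/03_degs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

degs <- two_group_degs(expr, ann$group, levels = c("case", "control"),
                       alpha = 0.05, lfc = 1.7)
write.table(degs, file.path(outdir, "global_degs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- c(unlist(truth$true_de_genes), truth$true_global_de)
cat(sprintf("global DEGs: %d (%d up, %d down)\n", nrow(degs),
            sum(degs$direction == "up"), sum(degs$direction == "down")))
cat(sprintf("planted-gene recall: %.3f; false positives: %d\n",
            mean(planted %in% degs$gene_id),
            length(setdiff(degs$gene_id, planted))))
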