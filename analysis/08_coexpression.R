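#!/usr/bin/env Rscript
# Stage 8 — weighted co-expression network on the case samples.
#
# Top-25% variance filter, soft threshold by scale-free fit, unsigned
# adjacency, TOM, static-cut module detection (min 30 genes), eigengene
# merging at correlation 0.75, module-subtype correlation, and MM/GS hub
# genes (|MM| > 0.7, |GS| > 0.2).

suppressPackageStartupMessages(library(igansubtypes))

expr <- read_expression_tsv("results/02_preprocessed/expression_adjusted.tsv")
labels_df <- read.delim("results/04_subtypes/subtype_labels.tsv")
outdir <- "results/08_coexpression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

labels_df <- labels_df[!is.na(labels_df$final), ]
labels <- setNames(labels_df$final, labels_df$sample_id)
x <- variance_filter(expr[, names(labels)], top_frac = 0.25)
cat(sprintf("network genes: %d (top 25%% by variance)\n", nrow(x)))

st <- pick_soft_threshold(x)
cat(sprintf("soft threshold beta = %d (scale-free fit %.3f)\n",
            st$beta, st$fit$r2[st$fit$power == st$beta]))
write.table(st$fit, file.path(outdir, "soft_threshold_fit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tom <- tom_transform(adjacency_matrix(x, st$beta))
mods0 <- detect_modules(tom, min_module_size = 30)
merged <- merge_modules(x, mods0, cut_height = 0.25)
cat(sprintf("modules: %d detected, %d after merging at eigengene cor 0.75\n",
            merged$n_initial, merged$n_merged))
write.table(data.frame(gene_id = names(merged$modules),
                       module = unname(merged$modules)),
            file.path(outdir, "modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

indicators <- sapply(sort(unique(labels)), function(s) as.numeric(labels == s))
colnames(indicators) <- paste0("subtype", sort(unique(labels)))
mt <- module_trait_correlation(merged$eigengenes, indicators)
mt_tab <- data.frame(module = rownames(mt$r), round(mt$r, 3),
                     check.names = FALSE)
write.table(mt_tab, file.path(outdir, "module_subtype_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (m in rownames(mt$r)) {
  j <- which.max(abs(mt$r[m, ]))
  cat(sprintf("module %s (n=%d): strongest with %s (r = %.2f, p = %.2e)\n",
              m, sum(merged$modules == m), colnames(mt$r)[j],
              mt$r[m, j], mt$p[m, j]))
}

hubs <- mm_gs_hubs(x, merged$modules, merged$eigengenes, indicators[, 1])
write.table(hubs, file.path(outdir, "hubs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("hub genes (|MM| > 0.7 & |GS| > 0.2 vs subtype 1): %d\n",
            sum(hubs$hub)))
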