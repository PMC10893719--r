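#!/usr/bin/env Rscript
# Stage 5 — single-sample random-forest subtype classifier.
#
# 3:1 stratified split, OOB-driven grid tuning over (mtry, ntree),
# held-out accuracy and one-vs-rest AUCs, plus 5-fold cross-validation
# (full retuning per fold).

suppressPackageStartupMessages(library(igansubtypes))

seed <- 1L
expr <- read_expression_tsv("results/02_preprocessed/expression_adjusted.tsv")
degs <- read.delim("results/03_degs/global_degs.tsv")
labels_df <- read.delim("results/04_subtypes/subtype_labels.tsv")
outdir <- "results/05_classifier"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

labels_df <- labels_df[!is.na(labels_df$final), ]
labels <- setNames(labels_df$final, labels_df$sample_id)
x <- t(expr[degs$gene_id, names(labels)])
y <- factor(labels)

sp <- split_train_test(names(labels), labels, ratio = 0.75,
                       seed = stage_seed(seed, "split"))
fit <- tune_forest(x[sp$train, ], y[match(sp$train, names(labels))],
                   seed = stage_seed(seed, "tune"))
ev <- evaluate_classifier(fit$model, x[sp$test, ],
                          y[match(sp$test, names(labels))])
cv <- cross_validate(x, y, folds = 5, seed = stage_seed(seed, "cv"))

report <- data.frame(
  metric = c("test_accuracy", paste0("auc_subtype", names(ev$per_class_auc)),
             "macro_auc", "oob_error", "cv_accuracy", "mtry", "ntree"),
  value = c(ev$accuracy, ev$per_class_auc, ev$macro_auc, fit$oob_error,
            cv$cv_accuracy, fit$mtry, fit$ntree))
write.table(report, file.path(outdir, "classifier_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

preds <- predict_subtype(fit$model, expr[, names(labels)])
write.table(preds, file.path(outdir, "predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("tuned forest: mtry=%d ntree=%d, OOB error %.3f\n",
            fit$mtry, fit$ntree, fit$oob_error))
cat(sprintf("held-out accuracy %.3f; per-class AUC %s; macro %.3f\n",
            ev$accuracy, paste(round(ev$per_class_auc, 3), collapse = "/"),
            ev$macro_auc))
cat(sprintf("5-fold CV accuracy %.3f\n", cv$cv_accuracy))
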