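#' Pipeline run configuration
#'
#' Bundles every stage's parameters with the study's defaults: global DEG
#' thresholds (adjusted p < 0.05, |log2FC| > 1.7), per-subtype thresholds
#' (0.01, 2), (0.01, 1.5), (0.01, 1.2), 3:1 train/test split, 5-fold CV,
#' top-25% variance filter, scale-free R^2 target 0.9, minimum module size
#' 30, eigengene merge cut 0.25, hub thresholds |MM| > 0.7 and |GS| > 0.2.
#'
#' @param sim a [sim_config()] (the cohort; the pipeline is simulation-fed)
#' @param k number of subtypes, or "auto" for [select_k()]
#' @param alpha,lfc global DEG thresholds
#' @param subtype_alpha,subtype_lfc per-subtype DEG thresholds (recycled to
#'   k)
#' @param split_ratio,cv_folds classifier protocol
#' @param n_resample,sample_frac consensus-clustering parameters
#' @param top_frac,r2_target,min_module_size,merge_cut,mm_thr,gs_thr
#'   co-expression parameters
#' @param n_cell_types,n_mixtures,mixture_noise_sd deconvolution stage
#' @param stages which stages to run; dependencies are validated (e.g. the
#'   classifier needs subtype labels)
#' @param seed global seed; per-stage seeds derive from it via
#'   [stage_seed()]
#' @return a `run_config` list
#' @export
run_config <- function(sim = sim_config(), k = "auto",
                       alpha = 0.05, lfc = 1.7,
                       subtype_alpha = c(0.01, 0.01, 0.01),
                       subtype_lfc = c(2, 1.5, 1.2),
                       split_ratio = 0.75, cv_folds = 5,
                       n_resample = 100, sample_frac = 0.8,
                       top_frac = 0.25, r2_target = 0.9,
                       min_module_size = 30, merge_cut = 0.25,
                       mm_thr = 0.7, gs_thr = 0.2,
                       n_cell_types = 5, n_mixtures = 50,
                       mixture_noise_sd = 0.1,
                       stages = c("differential", "subtyping", "classifier",
                                  "subtype_degs", "pathway", "traits",
                                  "coexpression", "deconvolution",
                                  "enrichment"),
                       seed = 1L) {
  cf <- structure(as.list(environment()), class = "run_config")
  deps <- list(subtyping = c(differential = "global DEG features"),
               classifier = c(subtyping = "subtype labels"),
               subtype_degs = c(subtyping = "subtype labels"),
               pathway = c(subtyping = "subtype labels"),
               traits = c(subtype_degs = "subtype-specific genes"),
               coexpression = c(subtyping = "subtype labels"),
               enrichment = c(subtyping = "subtype labels",
                              pathway = "gene sets"))
  for (st in intersect(names(deps), stages)) {
    need <- deps[[st]]
    missing <- setdiff(names(need), stages)
    if (length(missing)) {
      stop(sprintf("%s requires %s", st, need[[missing[1]]]))
    }
  }
  cf
}

#' Run the full subtyping analysis on a simulated cohort
#'
#' Executes, in dependency order: cohort simulation, batch adjustment,
#' global DEG screen, subtype discovery (three clusterers + 2-of-3 vote,
#' optionally with automatic k selection), single-sample random-forest
#' classifier (split / tune / evaluate / cross-validate), subtype-vs-rest
#' DEGs and subtype-specific genes, pathway activity scores with ANOVA,
#' gene-trait correlation, co-expression modules with hubs, and
#' immune-fraction deconvolution with group tests. Unassigned samples are
#' excluded from classifier training and subtype contrasts.
#'
#' @param config a [run_config()]
#' @param outdir optional directory; when given, every stage table is
#'   written as TSV plus a JSON manifest with parameters, seed and file
#'   hashes
#' @return named list of stage results
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cf <- config
  on <- function(s) s %in% cf$stages
  res <- list(config = cf)

  # --- simulate ---------------------------------------------------------
  sim <- unclass(cf$sim)
  sim$seed <- stage_seed(cf$seed, "simulate")
  cohort <- generate_cohort(do.call(sim_config, sim))
  res$cohort <- cohort

  # --- preprocess -------------------------------------------------------
  expr <- adjust_batches(cohort$expr, cohort$annotation)
  res$expr <- expr
  ann <- cohort$annotation

  # --- global DEGs ------------------------------------------------------
  if (on("differential")) {
  degs <- two_group_degs(expr, ann$group, levels = c("case", "control"),
                         alpha = cf$alpha, lfc = cf$lfc)
  if (nrow(degs) < 2) stop("stage differential: fewer than 2 global DEGs")
  res$global_degs <- degs
  }

  # --- subtype discovery ------------------------------------------------
  if (on("subtyping")) {
  case_ids <- ann$sample_id[ann$group == "case"]
  expr_deg_cases <- expr[degs$gene_id, case_ids, drop = FALSE]
  if (identical(cf$k, "auto")) {
    ksel <- select_k(expr_deg_cases, n_resample = cf$n_resample,
                     sample_frac = cf$sample_frac,
                     seed = stage_seed(cf$seed, "select_k"))
    res$k_selection <- ksel
    k <- ksel$k
  } else {
    k <- as.integer(cf$k)
  }
  res$k <- k
  disc <- discover_subtypes(expr_deg_cases, k, n_resample = cf$n_resample,
                            sample_frac = cf$sample_frac,
                            seed = stage_seed(cf$seed, "subtype"))
  res$subtypes <- disc
  assigned <- disc$assignment[!is.na(disc$assignment$final), ]
  labels <- stats::setNames(assigned$final, assigned$sample_id)
  }

  # --- classifier -------------------------------------------------------
  if (on("classifier")) {
  if (any(table(labels) < max(2, cf$cv_folds))) {
    stop("stage classifier: a subtype is too small to train on")
  }
  sp <- split_train_test(names(labels), labels, ratio = cf$split_ratio,
                         seed = stage_seed(cf$seed, "split"))
  x_all <- t(expr[degs$gene_id, names(labels), drop = FALSE])
  y_all <- factor(labels)
  tuned <- tune_forest(x_all[sp$train, , drop = FALSE],
                       y_all[match(sp$train, names(labels))],
                       seed = stage_seed(cf$seed, "tune"))
  ev <- evaluate_classifier(tuned$model, x_all[sp$test, , drop = FALSE],
                            y_all[match(sp$test, names(labels))])
  cv <- cross_validate(x_all, y_all, folds = cf$cv_folds,
                       seed = stage_seed(cf$seed, "cv"))
  res$classifier <- list(split = sp, tuned = tuned, evaluation = ev, cv = cv,
                         report = list(accuracy = ev$accuracy,
                                       per_class_auc = ev$per_class_auc,
                                       macro_auc = ev$macro_auc,
                                       oob_error = tuned$oob_error,
                                       cv_accuracy = cv$cv_accuracy,
                                       chosen_mtry = tuned$mtry,
                                       chosen_ntree = tuned$ntree))
  }

  # --- subtype DEGs + specific genes -----------------------------------
  expr_cases <- if (on("subtyping")) expr[, names(labels), drop = FALSE]
  if (on("subtype_degs")) {
  sub_alpha <- rep_len(cf$subtype_alpha, k)
  sub_lfc <- rep_len(cf$subtype_lfc, k)
  sub_degs <- lapply(seq_len(k), function(s) {
    subtype_vs_rest_degs(expr_cases, labels, s,
                         alpha = sub_alpha[s], lfc = sub_lfc[s])
  })
  names(sub_degs) <- paste0("subtype", seq_len(k))
  res$subtype_degs <- sub_degs
  res$subtype_specific <- lapply(sub_degs, subtype_specific_genes,
                                 global_degs = degs)
  }

  # --- pathway activity -------------------------------------------------
  if (on("pathway")) {
  sets <- generate_gene_sets(cohort$truth, rownames(expr),
                             seed = stage_seed(cf$seed, "gene_sets"))
  res$gene_sets <- sets
  res$activity <- activity_table(expr, ann, labels, sets)
  }

  # --- gene-trait correlation ------------------------------------------
  if (on("traits")) {
  traits <- generate_traits(cohort$truth, expr, ann,
                            seed = stage_seed(cf$seed, "traits"))
  res$traits <- traits
  spec_genes <- unique(unlist(lapply(res$subtype_specific, `[[`, "gene_id")))
  if (length(spec_genes) >= 2) {
    tr_case <- traits[match(colnames(expr_cases), traits$sample_id), ]
    res$trait_correlation <- lapply(
      stats::setNames(nm = setdiff(names(tr_case), "sample_id")),
      function(tn) gene_trait_correlation(expr_cases, tr_case[[tn]], spec_genes))
  }
  }

  # --- co-expression ----------------------------------------------------
  if (on("coexpression")) {
  expr_net <- variance_filter(expr_cases, cf$top_frac)
  st <- pick_soft_threshold(expr_net, r2_target = cf$r2_target)
  adj <- adjacency_matrix(expr_net, st$beta)
  tom <- tom_transform(adj)
  mods0 <- detect_modules(tom, cf$min_module_size)
  merged <- merge_modules(expr_net, mods0, cf$merge_cut)
  indicators <- sapply(sort(unique(labels)), function(s) as.numeric(labels == s))
  colnames(indicators) <- paste0("subtype", sort(unique(labels)))
  mt <- module_trait_correlation(merged$eigengenes, indicators)
  hubs <- mm_gs_hubs(expr_net, merged$modules, merged$eigengenes,
                     indicators[, 1], mm_thr = cf$mm_thr, gs_thr = cf$gs_thr)
  res$coexpression <- list(beta = st$beta, fit = st$fit,
                           modules_initial = mods0, merged = merged,
                           module_trait = mt, hubs = hubs)
  }

  # --- deconvolution ----------------------------------------------------
  if (on("deconvolution")) {
  set.seed(stage_seed(cf$seed, "signature"))
  sig <- matrix(stats::rgamma(200 * cf$n_cell_types, shape = 2, rate = 0.5),
                200, cf$n_cell_types,
                dimnames = list(sprintf("sg%03d", 1:200),
                                paste0("cell", seq_len(cf$n_cell_types))))
  mix <- generate_mixtures(cf$n_mixtures, sig, noise_sd = cf$mixture_noise_sd,
                           seed = stage_seed(cf$seed, "mixtures"))
  est <- estimate_fractions(mix$bulk, sig)
  n_ctrl_mix <- ceiling(cf$n_mixtures / 4)
  mix_groups <- c(rep("control", n_ctrl_mix),
                  rep_len(paste0("subtype", seq_len(k)),
                          cf$n_mixtures - n_ctrl_mix))
  res$deconvolution <- list(
    signature = sig, true_fractions = mix$fractions, estimated = est,
    mae = mean(abs(est - mix$fractions)),
    tests = compare_fractions(est, mix_groups),
    correlations = fraction_correlations(est))
  }

  # --- enrichment -------------------------------------------------------
  if (on("enrichment")) {
  # ranking statistic: subtype-1-vs-rest log2FC over all genes
  in1 <- labels == 1
  ranked <- rowMeans(expr_cases[, in1, drop = FALSE]) -
    rowMeans(expr_cases[, !in1, drop = FALSE])
  res$enrichment <- list(
    ora = ora_collection(degs$gene_id, sets, rownames(expr)),
    gsea_subtype1 = gsea_preranked(ranked, sets[["signal_subtype1"]],
                                   n_perm = 500,
                                   seed = stage_seed(cf$seed, "gsea")))
  }

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# serialize the main stage tables + a manifest
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_expression_tsv(res$expr, file.path(outdir, "expression.tsv"))
  wt(res$cohort$annotation, "annotation.tsv")
  wt(res$global_degs, "global_degs.tsv")
  wt(res$subtypes$assignment, "subtype_labels.tsv")
  wt(res$activity, "pathway_activity.tsv")
  if (!is.null(res$coexpression)) {
    wt(data.frame(gene_id = names(res$coexpression$merged$modules),
                  module = unname(res$coexpression$merged$modules)),
       "modules.tsv")
    wt(res$coexpression$hubs, "hubs.tsv")
  }
  if (!is.null(res$deconvolution)) {
    wt(data.frame(sample_id = rownames(res$deconvolution$estimated),
                  res$deconvolution$estimated, check.names = FALSE),
       "cell_fractions.tsv")
  }
  if (!is.null(res$gene_sets)) {
    write_gmt(res$gene_sets, file.path(outdir, "gene_sets.gmt"))
  }
  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    parameters = res$config[setdiff(names(res$config), "sim")],
    sim = unclass(res$config$sim),
    seed = res$config$seed,
    k = res$k,
    hashes = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
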