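#' Expression-bias pathway activity score
#'
#' For each pathway gene g: z_g = (mean over cases - mean over controls) /
#' SD over controls; the activity score is the mean of |z_g| over the set's
#' genes present in the matrix. Genes absent from the matrix are skipped
#' and counted. A control SD below the floor is floored with a warning.
#'
#' @param expr gene x sample log2 matrix
#' @param case_ids,control_ids column ids of the two groups (>= 2 controls)
#' @param gene_set character vector of gene ids
#' @return list(score, n_genes_used, n_genes_skipped, z = named |z| vector)
#' @export
activity_score <- function(expr, case_ids, control_ids, gene_set) {
  if (length(control_ids) < 2) stop("need >= 2 controls")
  genes <- intersect(unique(gene_set), rownames(expr))
  if (length(genes) == 0) stop("gene set does not intersect the matrix")
  ctrl <- expr[genes, control_ids, drop = FALSE]
  cse <- expr[genes, case_ids, drop = FALSE]
  sd_ctrl <- apply(ctrl, 1, stats::sd)
  if (any(sd_ctrl < SD_FLOOR)) {
    warning(sprintf("%d control SD(s) floored at %g", sum(sd_ctrl < SD_FLOOR),
                    SD_FLOOR), call. = FALSE)
    sd_ctrl <- pmax(sd_ctrl, SD_FLOOR)
  }
  z <- abs((rowMeans(cse) - rowMeans(ctrl)) / sd_ctrl)
  list(score = mean(z), n_genes_used = length(genes),
       n_genes_skipped = length(unique(gene_set)) - length(genes),
       z = z)
}

#' One-way ANOVA over per-gene pathway deviations grouped by subtype
#'
#' The observational unit is the per-gene |z| value of one pathway computed
#' within one subtype (the only reading of a cross-subtype activity ANOVA
#' that has replication; the study aggregates to a single score per subtype
#' before testing, which admits no test). Classic equal-variance one-way
#' ANOVA.
#'
#' @param values numeric vector of per-gene |z| values
#' @param groups subtype labels aligned to `values` (>= 2 groups, >= 2
#'   values per group)
#' @return list(F, p, df)
#' @export
score_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 values")
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Per-subtype activity scores for a gene-set collection
#'
#' Convenience wrapper: computes [activity_score()] for every (pathway,
#' subtype) pair — cases restricted to one subtype vs all controls — and
#' the cross-subtype ANOVA per pathway.
#'
#' @param expr gene x sample matrix
#' @param annotation cohort annotation (group column)
#' @param subtypes named subtype labels for case samples (NA = unassigned,
#'   dropped)
#' @param gene_sets named list of gene-id vectors
#' @return data.frame: pathway, subtype, score, n_genes_used, F, p (ANOVA
#'   repeated per pathway row)
#' @export
activity_table <- function(expr, annotation, subtypes, gene_sets) {
  control_ids <- annotation$sample_id[annotation$group == "control"]
  subtypes <- subtypes[!is.na(subtypes)]
  levels_s <- sort(unique(subtypes))
  rows <- list()
  for (pw in names(gene_sets)) {
    zs <- list()
    for (s in levels_s) {
      ids <- names(subtypes)[subtypes == s]
      sc <- activity_score(expr, ids, control_ids, gene_sets[[pw]])
      zs[[as.character(s)]] <- sc$z
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = pw, subtype = s, score = sc$score,
        n_genes_used = sc$n_genes_used, stringsAsFactors = FALSE)
    }
    av <- score_anova(unlist(zs, use.names = FALSE),
                      rep(names(zs), lengths(zs)))
    take <- (length(rows) - length(levels_s) + 1):length(rows)
    for (i in take) { rows[[i]]$F <- av$F; rows[[i]]$p <- av$p }
  }
  do.call(rbind, rows)
}
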