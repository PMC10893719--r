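#' Two-group differential expression (Welch t)
#'
#' Per gene: log2 fold change as the difference of group means (the data
#' are already log2), two-sided Welch two-sample t p-value, and
#' Benjamini-Hochberg adjustment over all tested genes. Only genes passing
#' both the adjusted-p and |log2FC| cutoffs are returned, sorted by p
#' (ties broken by gene_id).
#'
#' @param expr gene x sample log2 matrix
#' @param groups two-level label vector over the columns; `group1` is the
#'   first level in `levels` (log2fc = mean(group1) - mean(group2))
#' @param levels character(2), the (group1, group2) level names
#' @param alpha adjusted-p cutoff
#' @param lfc |log2FC| cutoff
#' @return data.frame: gene_id, log2fc, p, adj_p, direction (up/down)
#' @export
two_group_degs <- function(expr, groups, levels = NULL,
                           alpha = 0.05, lfc = 1.7) {
  if (is.null(levels)) levels <- unique(as.character(groups))
  if (length(levels) != 2) stop("exactly two groups required")
  i1 <- which(groups == levels[1])
  i2 <- which(groups == levels[2])
  if (length(i1) < 2 || length(i2) < 2) stop("each group needs >= 2 samples")
  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(pmax(se2, SD_FLOOR^2))
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  df[!is.finite(df)] <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  adj_p <- bh_adjust(p)
  res <- data.frame(gene_id = rownames(expr), log2fc = m1 - m2,
                    p = p, adj_p = adj_p,
                    direction = ifelse(m1 - m2 > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  res <- res[res$adj_p < alpha & abs(res$log2fc) > lfc, , drop = FALSE]
  res <- res[order(res$p, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Subtype-vs-rest differential expression
#'
#' [two_group_degs()] with groups = (target subtype, all other subtypes);
#' log2fc is target minus rest. Per-subtype thresholds are chosen by the
#' caller (the study used (0.01, 2), (0.01, 1.5), (0.01, 1.2) for its three
#' subtypes).
#'
#' @param expr gene x sample matrix restricted to subtyped case samples
#' @param subtype_labels per-column subtype labels
#' @param target_subtype the subtype contrasted against the rest
#' @param alpha adjusted-p cutoff
#' @param lfc |log2FC| cutoff
#' @return data.frame as [two_group_degs()]
#' @export
subtype_vs_rest_degs <- function(expr, subtype_labels, target_subtype,
                                 alpha = 0.01, lfc = 2) {
  if (!target_subtype %in% subtype_labels) {
    stop(sprintf("unknown subtype: %s", target_subtype))
  }
  grp <- ifelse(subtype_labels == target_subtype, "target", "rest")
  two_group_degs(expr, grp, levels = c("target", "rest"),
                 alpha = alpha, lfc = lfc)
}

#' Subtype-specific genes by the intersection rule
#'
#' Intersects the global case-vs-control DEG list with a subtype-vs-rest
#' DEG list on gene_id; direction is taken from the subtype contrast.
#'
#' @param global_degs data.frame from [two_group_degs()]
#' @param subtype_degs data.frame from [subtype_vs_rest_degs()]
#' @return data.frame: gene_id, direction (from the subtype contrast),
#'   log2fc_global, log2fc_subtype
#' @export
subtype_specific_genes <- function(global_degs, subtype_degs) {
  common <- intersect(global_degs$gene_id, subtype_degs$gene_id)
  sub <- subtype_degs[match(common, subtype_degs$gene_id), ]
  glob <- global_degs[match(common, global_degs$gene_id), ]
  data.frame(gene_id = common,
             direction = sub$direction,
             log2fc_global = glob$log2fc,
             log2fc_subtype = sub$log2fc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-trait Pearson correlation
#'
#' Pearson correlation of each gene's expression with a clinical trait
#' over paired samples, two-sided t-based p, BH adjustment over the gene
#' subset, significance flag at adj_p < 0.05.
#'
#' @param expr gene x sample matrix
#' @param trait numeric trait values aligned to the matrix columns
#' @param genes gene subset to test (default: all rows)
#' @return data.frame: gene_id, r, p, adj_p, significant
#' @export
gene_trait_correlation <- function(expr, trait, genes = rownames(expr)) {
  if (length(trait) != ncol(expr)) stop("trait length must match samples")
  if (stats::sd(trait) < SD_FLOOR) stop("constant trait")
  if (ncol(expr) < 3) stop("need >= 3 paired observations")
  genes <- intersect(genes, rownames(expr))
  n <- length(trait)
  r <- as.numeric(stats::cor(t(expr[genes, , drop = FALSE]), trait))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  adj_p <- bh_adjust(p)
  data.frame(gene_id = genes, r = r, p = p, adj_p = adj_p,
             significant = adj_p < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}
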