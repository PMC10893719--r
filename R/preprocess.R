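#' Collapse probe-level values to gene level
#'
#' Microarray probe handling: probes annotated to no gene or to more than
#' one gene are dropped; for each remaining gene the per-sample expression
#' is the median over its probes. Gene order follows first appearance in
#' the probe map.
#'
#' @param probe_matrix probe x sample numeric matrix with probe rownames
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`; may
#'   be partial and many-to-many
#' @return gene x sample matrix
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(probe_matrix), ]
  # drop probes hitting more than one distinct gene
  n_genes_per_probe <- tapply(map$gene_id, map$probe_id,
                              function(g) length(unique(g)))
  multi <- names(n_genes_per_probe)[n_genes_per_probe > 1]
  map <- unique(map[!(map$probe_id %in% multi), c("probe_id", "gene_id")])
  if (nrow(map) == 0) stop("no annotatable probes")
  gene_order <- unique(map$gene_id)
  out <- matrix(NA_real_, length(gene_order), ncol(probe_matrix),
                dimnames = list(gene_order, colnames(probe_matrix)))
  for (g in gene_order) {
    probes <- map$probe_id[map$gene_id == g]
    sub <- probe_matrix[probes, , drop = FALSE]
    out[g, ] <- apply(sub, 2, stats::median)
  }
  out
}

#' Location-scale batch adjustment
#'
#' Per gene and batch, centers and scales values to the batch mean/SD, then
#' restores the gene's pooled mean and pooled SD, removing additive and
#' multiplicative batch effects exactly. Single-batch input is returned
#' unchanged. Zero within-batch variance is guarded by an SD floor.
#'
#' @param expr gene x sample matrix
#' @param annotation data.frame with `sample_id` and `batch` matching the
#'   matrix columns
#' @return adjusted matrix, same dimensions
#' @export
adjust_batches <- function(expr, annotation) {
  batch <- annotation$batch[match(colnames(expr), annotation$sample_id)]
  if (anyNA(batch)) stop("annotation does not cover all samples")
  batches <- unique(batch)
  if (length(batches) < 2) return(expr)
  if (any(table(batch) < 2)) stop("each batch needs >= 2 samples")
  out <- expr
  pooled_mean <- rowMeans(expr)
  pooled_sd <- apply(expr, 1, stats::sd)
  pooled_sd <- pmax(pooled_sd, SD_FLOOR)
  for (b in batches) {
    cols <- which(batch == b)
    m <- rowMeans(expr[, cols, drop = FALSE])
    s <- apply(expr[, cols, drop = FALSE], 1, stats::sd)
    if (any(s < SD_FLOOR)) {
      warning(sprintf("%d gene(s) with near-zero variance in batch %s; SD floored",
                      sum(s < SD_FLOOR), b), call. = FALSE)
      s <- pmax(s, SD_FLOOR)
    }
    out[, cols] <- (expr[, cols, drop = FALSE] - m) / s * pooled_sd + pooled_mean
  }
  out
}

#' Per-gene z-score standardization
#'
#' Scales each gene row to mean 0, sample SD 1 (n-1 denominator). Constant
#' rows are floored to all zeros with a warning. Idempotent.
#'
#' @param expr gene x sample matrix
#' @return standardized matrix
#' @export
zscore_genes <- function(expr) {
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  if (any(!is.finite(s)) || any(s < SD_FLOOR)) {
    warning(sprintf("%d constant gene row(s); SD floored",
                    sum(!is.finite(s) | s < SD_FLOOR)), call. = FALSE)
    s <- pmax(s, SD_FLOOR)
  }
  out <- (expr - m) / s
  # floored rows become numerically huge-but-centered; zero them outright
  flat <- which(s <= SD_FLOOR)
  if (length(flat)) out[flat, ] <- 0
  out
}
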