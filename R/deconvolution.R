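#' Estimate immune-cell fractions by constrained least squares
#'
#' Per sample, solves nonnegative least squares of the bulk expression
#' vector (over genes shared with the signature) against the signature
#' columns, then renormalizes the coefficients to the unit simplex. An
#' all-zero solution falls back to a uniform vector with a warning.
#'
#' @param bulk gene x sample expression matrix
#' @param signature nonnegative gene x cell-type reference matrix
#' @return sample x cell-type matrix; rows sum to 1, entries >= 0
#' @export
estimate_fractions <- function(bulk, signature) {
  shared <- intersect(rownames(bulk), rownames(signature))
  if (length(shared) < ncol(signature)) {
    stop("fewer shared genes than cell types")
  }
  S <- as.matrix(signature[shared, , drop = FALSE])
  B <- as.matrix(bulk[shared, , drop = FALSE])
  out <- matrix(0, ncol(B), ncol(S),
                dimnames = list(colnames(B), colnames(S)))
  for (j in seq_len(ncol(B))) {
    w <- pracma::lsqnonneg(S, B[, j])$x
    if (sum(w) <= 0) {
      warning(sprintf("all-zero NNLS solution for sample %s; uniform fallback",
                      colnames(B)[j]), call. = FALSE)
      w <- rep(1 / ncol(S), ncol(S))
    }
    out[j, ] <- w / sum(w)
  }
  out
}

#' Compare cell fractions across groups
#'
#' Per cell type: Kruskal-Wallis across all groups plus a Wilcoxon
#' rank-sum test of each non-control group against the control group.
#' BH adjustment within each test family; star bins at
#' 0.05/0.01/0.001/0.0001.
#'
#' @param fractions sample x cell-type matrix
#' @param groups per-sample group labels
#' @param control the control level name (default "control")
#' @return list(kruskal = data.frame(cell_type, p, adj_p, stars),
#'   pairwise = data.frame(cell_type, group, p, adj_p, stars))
#' @export
compare_fractions <- function(fractions, groups, control = "control") {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group not present")
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  cells <- colnames(fractions)
  kw_p <- vapply(cells, function(ct) {
    stats::kruskal.test(fractions[, ct], factor(groups))$p.value
  }, 0)
  kw <- data.frame(cell_type = cells, p = kw_p, adj_p = bh_adjust(kw_p),
                   stringsAsFactors = FALSE, row.names = NULL)
  kw$stars <- as.character(p_stars(kw$adj_p))

  others <- setdiff(unique(groups), control)
  pw <- expand.grid(cell_type = cells, group = others,
                    stringsAsFactors = FALSE)
  pw$p <- mapply(function(ct, g) {
    suppressWarnings(stats::wilcox.test(
      fractions[groups == g, ct], fractions[groups == control, ct],
      exact = NULL, correct = TRUE)$p.value)
  }, pw$cell_type, pw$group)
  pw$adj_p <- bh_adjust(pw$p)
  pw$stars <- as.character(p_stars(pw$adj_p))
  list(kruskal = kw, pairwise = pw)
}

#' Pairwise correlations between cell-type fractions
#'
#' Pearson r with two-sided t-based p for every cell-type pair; symmetric
#' matrices, unit diagonal on r. Constant columns are reported with r = 0,
#' p = 1 and a warning.
#'
#' @param fractions sample x cell-type matrix (>= 3 samples)
#' @return list(r, p) cell x cell matrices
#' @export
fraction_correlations <- function(fractions) {
  n <- nrow(fractions)
  if (n < 3) stop("need >= 3 samples")
  sds <- apply(fractions, 2, stats::sd)
  const <- sds < SD_FLOOR
  if (any(const)) {
    warning(sprintf("constant cell-type column(s): %s; pairs set to r = 0, p = 1",
                    paste(colnames(fractions)[const], collapse = ", ")),
            call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(fractions))
  r[const, ] <- 0; r[, const] <- 0
  diag(r) <- 1
  rt <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  tstat <- rt * sqrt((n - 2) / (1 - rt^2))
  p <- matrix(2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE),
              nrow(r), ncol(r), dimnames = dimnames(r))
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 0
  list(r = r, p = p)
}
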