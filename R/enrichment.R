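#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability P(X >= overlap) of drawing at
#' least the observed overlap between a query gene list and a gene set,
#' given the universe. Fold enrichment is (overlap/|query|) /
#' (|set in universe|/|universe|). BH adjustment across a collection is the
#' caller's job (via [bh_adjust()]).
#'
#' @param query character vector, subset of `universe`
#' @param gene_set character vector (intersected with the universe)
#' @param universe character vector of all testable genes
#' @return list(overlap, p, fold_enrichment, set_size, query_size)
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0 || length(query) == 0) stop("empty universe or query")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  set_u <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(query, set_u))
  N <- length(universe); K <- length(set_u); n <- length(query)
  # P(X >= overlap) with X ~ Hypergeometric(N, K, n)
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K > 0) (overlap / n) / (K / N) else NA_real_
  list(overlap = overlap, p = p, fold_enrichment = fold,
       set_size = K, query_size = n)
}

#' Pre-ranked GSEA enrichment score and permutation p-value
#'
#' Weighted Kolmogorov-Smirnov walk down a ranking (scores sorted
#' descending): set hits advance the running sum by |score|^weight
#' (normalized to sum 1 over hits), misses retreat by 1/(N - set size).
#' ES is the extremum of the walk. Significance by gene-label permutation:
#' random same-size sets, sign-matched p, NES = ES / mean |same-sign
#' permutation ES|.
#'
#' @param scores named numeric vector (names = gene ids); any order, ranked
#'   internally by decreasing score
#' @param gene_set character vector of gene ids
#' @param weight exponent on |score| for hit increments (0 = classic KS)
#' @param n_perm number of permutations (0 = ES only)
#' @param seed integer RNG seed
#' @return list(ES, NES, p, running = the walk over the ranking, hits)
#' @export
gsea_preranked <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = 1L) {
  if (is.null(names(scores))) stop("scores must be named by gene id")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, names(scores), decreasing = c(TRUE, FALSE),
               method = "radix")
  scores <- scores[ord]
  hits <- names(scores) %in% gene_set
  if (!any(hits)) stop("gene set does not intersect the ranking")
  if (all(hits)) stop("gene set covers the whole ranking")

  walk <- function(h) {
    inc <- abs(scores)^weight * h
    inc <- if (sum(inc) == 0) h / sum(h) else inc / sum(inc)
    cumsum(inc - (!h) / (length(scores) - sum(h)))
  }
  walk_es <- function(h) { r <- walk(h); unname(r[which.max(abs(r))]) }
  running <- walk(hits)
  es <- unname(running[which.max(abs(running))])

  nes <- NA_real_; pval <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    n <- length(scores); m <- sum(hits)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      h <- logical(n); h[sample.int(n, m)] <- TRUE
      walk_es(h)
    }, 0)
    same_sign <- perm_es[sign(perm_es) == sign(es)]
    if (length(same_sign) > 0) {
      pval <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      nes <- es / mean(abs(same_sign))
    } else {
      pval <- 1 / (1 + n_perm)
    }
  }
  list(ES = es, NES = nes, p = pval, running = running,
       hits = names(scores)[hits])
}

#' ORA over a gene-set collection with BH adjustment
#'
#' @param query character query gene list
#' @param gene_sets named list of gene-id vectors
#' @param universe character universe
#' @return data.frame: set, overlap, set_size, fold_enrichment, p, adj_p
#' @export
ora_collection <- function(query, gene_sets, universe) {
  res <- lapply(gene_sets, ora_test, query = query, universe = universe)
  out <- data.frame(set = names(gene_sets),
                    overlap = vapply(res, `[[`, 0, "overlap"),
                    set_size = vapply(res, `[[`, 0, "set_size"),
                    fold_enrichment = vapply(res, `[[`, 0, "fold_enrichment"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- bh_adjust(out$p)
  out
}
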