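#' Hierarchical clustering labels
#'
#' Euclidean distance + Ward (ward.D2) linkage, tree cut to exactly k
#' groups. The feature space is expected to be the global DEG expression
#' submatrix (genes x samples); samples are the columns.
#'
#' @param expr_subset feature x sample matrix
#' @param k number of clusters
#' @param linkage hclust method (default ward.D2)
#' @return integer labels named by sample id
#' @export
hierarchical_labels <- function(expr_subset, k, linkage = "ward.D2") {
  n <- ncol(expr_subset)
  if (k > n) stop("k exceeds sample count")
  d <- stats::dist(t(expr_subset))
  hc <- stats::hclust(d, method = linkage)
  stats::cutree(hc, k = k)
}

#' k-medoids (PAM) clustering labels
#'
#' Partitioning around medoids (BUILD + SWAP to a local optimum) on
#' Euclidean distance via [cluster::pam()]. PAM is deterministic; `seed`
#' is accepted for interface stability across the three clusterers and
#' does not change the output.
#'
#' @inheritParams hierarchical_labels
#' @param seed ignored (PAM is deterministic); kept for a uniform calling
#'   convention
#' @return integer labels named by sample id
#' @export
medoid_labels <- function(expr_subset, k, seed = 1L) {
  n <- ncol(expr_subset)
  if (k > n) stop("k exceeds sample count")
  fit <- cluster::pam(t(expr_subset), k = k, metric = "euclidean",
                      cluster.only = FALSE)
  fit$clustering
}

#' Monti-style consensus clustering
#'
#' Repeatedly subsamples `ceiling(sample_frac * n)` samples without
#' replacement, clusters each draw hierarchically at k, and records for
#' every sample pair the proportion of co-sampled draws in which they
#' co-clustered. Final labels come from hierarchical clustering (average
#' linkage) of the 1 - consensus distance cut at k. Pairs never co-sampled
#' get consensus 0 with a warning.
#'
#' @inheritParams hierarchical_labels
#' @param n_resample number of subsampling iterations (>= 2)
#' @param sample_frac fraction of samples drawn per iteration
#' @param seed integer RNG seed
#' @return list(consensus = sample x sample matrix, labels = integer vector)
#' @export
consensus_cluster <- function(expr_subset, k, n_resample = 100,
                              sample_frac = 0.8, seed = 1L) {
  n <- ncol(expr_subset)
  if (k > n) stop("k exceeds sample count")
  if (n_resample < 2) stop("n_resample must be >= 2")
  set.seed(seed)
  ids <- colnames(expr_subset)
  m <- ceiling(sample_frac * n)
  co_clust <- matrix(0, n, n)
  co_samp <- matrix(0, n, n)
  for (b in seq_len(n_resample)) {
    take <- sort(sample.int(n, m))
    lab <- hierarchical_labels(expr_subset[, take, drop = FALSE], k)
    ind <- outer(lab, lab, "==") * 1
    co_clust[take, take] <- co_clust[take, take] + ind
    co_samp[take, take] <- co_samp[take, take] + 1
  }
  never <- co_samp == 0
  if (any(never[upper.tri(never)])) {
    warning(sprintf("%d sample pair(s) never co-sampled; consensus set to 0",
                    sum(never[upper.tri(never)])), call. = FALSE)
  }
  consensus <- ifelse(co_samp > 0, co_clust / pmax(co_samp, 1), 0)
  diag(consensus) <- 1
  consensus <- (consensus + t(consensus)) / 2
  dimnames(consensus) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  labels <- stats::cutree(hc, k = k)
  list(consensus = consensus, labels = labels)
}

#' Select the number of subtypes by three criteria
#'
#' Runs the gap statistic (uniform reference over each feature's observed
#' range, B reference sets, firstSEmax rule, hierarchical base clusterer),
#' the mean-silhouette maximizer over PAM labels, and the consensus-CDF
#' relative-area-change maximizer, over `k_range`. Returns each method's k
#' and the majority value; errors if all three disagree.
#'
#' @param expr_subset feature x sample matrix
#' @param k_range integer candidate range (default 2:10)
#' @param B gap-statistic reference sets
#' @param n_resample,sample_frac consensus-clustering parameters
#' @param cdf_delta_min smallest relative consensus-CDF area increase still
#'   counted as a real additional cluster
#' @param methods which criteria to run (default all three); the returned
#'   k is the single method's answer or the majority over those run
#' @param seed integer RNG seed
#' @return list(k, per_method, diagnostics)
#' @export
select_k <- function(expr_subset, k_range = 2:10, B = 50,
                     n_resample = 100, sample_frac = 0.8,
                     cdf_delta_min = 0.1,
                     methods = c("gap", "silhouette", "cdf"), seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- ncol(expr_subset)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop("k_range must lie within [2, n_samples - 1]")
  }
  x <- t(expr_subset)
  per_method <- c()
  diagnostics <- list()

  if ("gap" %in% methods) {
  # gap statistic on hierarchical labels, uniform-over-ranges reference
  set.seed(stage_seed(seed, "gap"))
  hfun <- function(x, k) list(cluster = stats::cutree(
    stats::hclust(stats::dist(x), method = "ward.D2"), k = k))
  gap_fit <- cluster::clusGap(x, FUNcluster = hfun, K.max = max(k_range),
                              B = B, spaceH0 = "original", verbose = FALSE)
  tab <- gap_fit$Tab[k_range, , drop = FALSE]
  per_method["gap"] <- k_range[cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                                              method = "firstSEmax")]
  diagnostics$gap_table <- gap_fit$Tab
  }

  if ("silhouette" %in% methods) {
  # mean silhouette over PAM labels
  d <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    lab <- medoid_labels(expr_subset, k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, 0)
  per_method["silhouette"] <- k_range[which.max(sil)]
  diagnostics$silhouette <- sil
  }

  # consensus-CDF area criterion: the area under the CDF of consensus
  # entries grows with k; the chosen k is the largest one whose relative
  # area increase is still substantial (>= cdf_delta_min), i.e. the elbow
  # of the delta-area curve, after which adding clusters only fragments
  # stable groups
  if ("cdf" %in% methods) {
  areas <- vapply(k_range, function(k) {
    cc <- consensus_cluster(expr_subset, k, n_resample = n_resample,
                            sample_frac = sample_frac,
                            seed = stage_seed(seed, paste0("cdf", k)))
    v <- cc$consensus[upper.tri(cc$consensus)]
    mean(1 - v)   # area under the empirical CDF over [0, 1]
  }, 0)
  delta <- c(areas[1], diff(areas) / pmax(areas[-length(areas)], 1e-12))
  big <- which(delta >= cdf_delta_min)
  per_method["cdf"] <- if (length(big)) k_range[max(big)]
                       else k_range[which.max(delta)]
  diagnostics$cdf_area <- areas
  diagnostics$cdf_delta <- delta
  }

  counts <- table(per_method)
  if (length(methods) > 1 && max(counts) < 2) {
    stop("no majority k; fix k explicitly")
  }
  k <- as.integer(names(counts)[which.max(counts)])
  list(k = k, per_method = per_method, diagnostics = diagnostics)
}

# O(k^3) Hungarian algorithm (potentials / augmenting-path form) for the
# minimum-cost assignment of a square cost matrix. Returns, for each row,
# the assigned column.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # 1-based port with a dummy column at index n+1 used as the free slot
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

#' Harmonize cluster labelings against a reference
#'
#' Relabels each non-reference label vector by the label permutation that
#' maximizes agreement with the reference, found by Hungarian assignment on
#' the k x k contingency table. Needed to make cross-algorithm label votes
#' well-defined: cluster ids are arbitrary per algorithm.
#'
#' @param label_vectors list of equal-length label vectors with the same k
#' @param reference_index which vector is the reference (unchanged)
#' @return list of aligned integer label vectors (labels 1..k)
#' @export
harmonize_labels <- function(label_vectors, reference_index = 1L) {
  ks <- vapply(label_vectors, function(l) length(unique(l)), 0L)
  if (length(unique(ks)) != 1) stop("label vectors have differing k")
  lens <- vapply(label_vectors, length, 0L)
  if (length(unique(lens)) != 1) stop("label vectors have differing length")
  ref <- label_vectors[[reference_index]]
  ref_levels <- sort(unique(ref))
  k <- length(ref_levels)
  ref_int <- match(ref, ref_levels)
  out <- vector("list", length(label_vectors))
  for (i in seq_along(label_vectors)) {
    if (i == reference_index) { out[[i]] <- ref_int; next }
    lab <- label_vectors[[i]]
    levels_i <- sort(unique(lab))
    lab_int <- match(lab, levels_i)
    tab <- matrix(0, k, k)
    for (s in seq_along(lab_int)) {
      tab[lab_int[s], ref_int[s]] <- tab[lab_int[s], ref_int[s]] + 1
    }
    perm <- hungarian_assign(-tab)   # maximize agreement
    out[[i]] <- perm[lab_int]
  }
  names(out) <- names(label_vectors)
  out
}

#' Two-of-three consensus vote over harmonized labelings
#'
#' A sample receives a final subtype label iff at least two of the three
#' aligned algorithm labels agree; otherwise it is UNASSIGNED (NA). The
#' per-algorithm provenance is retained.
#'
#' @param aligned_vectors list of exactly 3 harmonized label vectors
#'   (order: hierarchical, medoid, consensus by convention)
#' @param sample_ids optional sample identifiers
#' @return data.frame: sample_id, hier, medoid, consensus, final (NA =
#'   unassigned)
#' @export
vote_consensus <- function(aligned_vectors, sample_ids = NULL) {
  if (length(aligned_vectors) != 3) stop("exactly 3 label vectors required")
  a <- aligned_vectors[[1]]; b <- aligned_vectors[[2]]; c_ <- aligned_vectors[[3]]
  n <- length(a)
  if (is.null(sample_ids)) {
    sample_ids <- names(a)
    if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  }
  final <- rep(NA_integer_, n)
  final[a == b | a == c_] <- a[a == b | a == c_]
  only_bc <- is.na(final) & b == c_
  final[only_bc] <- b[only_bc]
  data.frame(sample_id = sample_ids, hier = a, medoid = b, consensus = c_,
             final = final, stringsAsFactors = FALSE, row.names = NULL)
}

#' Full subtype-discovery step
#'
#' Runs the three clusterers on the DEG expression submatrix of case
#' samples, harmonizes labels against the consensus-clustering labels (the
#' most stable of the three), and applies the 2-of-3 vote.
#'
#' @param expr_degs global-DEG x case-sample matrix
#' @param k number of subtypes
#' @param n_resample,sample_frac consensus-clustering parameters
#' @param seed integer RNG seed
#' @return list(assignment = data.frame from [vote_consensus()],
#'   consensus = consensus matrix)
#' @export
discover_subtypes <- function(expr_degs, k, n_resample = 100,
                              sample_frac = 0.8, seed = 1L) {
  hier <- hierarchical_labels(expr_degs, k)
  med <- medoid_labels(expr_degs, k, seed = stage_seed(seed, "pam"))
  cc <- consensus_cluster(expr_degs, k, n_resample = n_resample,
                          sample_frac = sample_frac,
                          seed = stage_seed(seed, "consensus"))
  aligned <- harmonize_labels(list(hier = hier, medoid = med,
                                   consensus = cc$labels),
                              reference_index = 3L)
  assignment <- vote_consensus(aligned, sample_ids = colnames(expr_degs))
  n_un <- sum(is.na(assignment$final))
  if (n_un > 0) {
    message(sprintf("%d of %d samples unassigned by the 2-of-3 vote",
                    n_un, nrow(assignment)))
  }
  list(assignment = assignment, consensus = cc$consensus)
}
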