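test_that("hierarchical_labels partitions separable clouds exactly", {
  x <- make_clouds(2, 15, seed = 1)
  lab <- hierarchical_labels(x, 2)
  expect_equal(adjusted_rand_index(lab, attr(x, "cloud")), 1)
  expect_equal(length(unique(hierarchical_labels(x, 1))), 1)
  expect_equal(length(unique(hierarchical_labels(x, ncol(x)))), ncol(x))
  expect_error(hierarchical_labels(x, ncol(x) + 1), "exceeds")
})

test_that("medoid_labels recovers clouds and beats random partitions", {
  x <- make_clouds(3, 12, seed = 2)
  lab <- medoid_labels(x, 3)
  expect_equal(adjusted_rand_index(lab, attr(x, "cloud")), 1)

  # duplicated samples share a label
  xd <- cbind(x, x)
  colnames(xd) <- paste0("s", seq_len(ncol(xd)))
  labd <- medoid_labels(xd, 3)
  expect_equal(labd[1:ncol(x)], labd[ncol(x) + 1:ncol(x)],
               ignore_attr = TRUE)

  # objective sanity: within-cluster distance <= random assignments
  d <- as.matrix(stats::dist(t(x)))
  wss <- function(l) sum(vapply(unique(l), function(g) {
    idx <- which(l == g)
    m <- idx[which.min(colSums(d[idx, idx, drop = FALSE]))]
    sum(d[idx, m])
  }, 0))
  set.seed(3)
  rand <- replicate(100, wss(sample(1:3, ncol(x), replace = TRUE)))
  expect_true(all(wss(lab) <= rand))
})

test_that("consensus_cluster is crisp on separable data and structurally valid", {
  x <- make_clouds(3, 10, seed = 4)
  cc <- consensus_cluster(x, 3, n_resample = 50, seed = 5)
  expect_true(isSymmetric(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, ncol(x)))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  # perfectly separable: entries exactly 0 or 1, within-cloud 1
  expect_true(all(cc$consensus %in% c(0, 1)))
  cl <- attr(x, "cloud")
  same <- outer(cl, cl, "==")
  expect_true(all(cc$consensus[same] == 1))
  expect_equal(adjusted_rand_index(cc$labels, cl), 1)
  expect_error(consensus_cluster(x, 3, n_resample = 1), ">= 2")
})

test_that("full subsampling with a deterministic clusterer reproduces co-membership", {
  x <- make_clouds(2, 8, seed = 6)
  cc <- consensus_cluster(x, 2, n_resample = 10, sample_frac = 1, seed = 7)
  base <- hierarchical_labels(x, 2)
  expect_equal(unname(cc$consensus),
               unname(outer(base, base, "==") * 1))
})

test_that("select_k finds the planted k and honors trivial ranges", {
  co <- generate_cohort(sim_config(n_case = 60, n_ctrl = 10, n_genes = 600,
                                   n_de_per_subtype = 40, n_global_de = 20,
                                   seed = 8))
  expr <- adjust_batches(co$expr, co$annotation)
  degs <- two_group_degs(expr, co$annotation$group,
                         levels = c("case", "control"))
  x <- expr[degs$gene_id, co$annotation$group == "case"]
  ks <- select_k(x, k_range = 2:6, B = 25, n_resample = 50, seed = 9)
  expect_equal(unname(ks$per_method), c(3, 3, 3))
  expect_equal(ks$k, 3)

  ks2 <- select_k(x, k_range = c(2, 2), B = 10, n_resample = 20, seed = 9)
  expect_equal(ks2$k, 2)
  expect_error(select_k(x, k_range = 1:3), "k_range")
})

test_that("gap statistic does not invent clusters in a single cloud", {
  picks <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- matrix(stats::rnorm(10 * 40), 10, 40,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:40)))
    ks <- suppressWarnings(select_k(x, k_range = 2:6, B = 25,
                                    methods = "gap", seed = seed))
    ks$per_method[["gap"]]
  }, 0)
  # firstSEmax on null data settles on the smallest admissible k
  expect_gte(sum(picks == 2), 8)
})

test_that("harmonize_labels matches the exhaustive-permutation oracle", {
  # permuted copy of the reference is recovered exactly
  ref <- rep(1:3, times = c(5, 7, 8))
  perm_ref <- c(2L, 3L, 1L)[ref]
  out <- harmonize_labels(list(ref, perm_ref), reference_index = 1)
  expect_equal(out[[2]], ref)

  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    n <- sample(10:40, 1)
    a <- sample(seq_len(k), n, replace = TRUE)
    b <- sample(seq_len(k), n, replace = TRUE)
    # every label must appear (same-k contract)
    a[seq_len(k)] <- seq_len(k); b[seq_len(k)] <- seq_len(k)
    out <- harmonize_labels(list(a, b), reference_index = 1)
    expect_equal(mean(out[[2]] == out[[1]]),
                 best_agreement_bruteforce(b, a, k))
  }
  expect_error(harmonize_labels(list(c(1, 2), c(1, 1))), "differing k")
})

test_that("random labels agree with a reference at the 1/k rate", {
  set.seed(12)
  agree <- replicate(1000, {
    ref <- sample(1:3, 30, replace = TRUE)
    mean(sample(1:3, 30, replace = TRUE) == ref)
  })
  expect_lt(abs(mean(agree) - 1 / 3), 0.01)
})

test_that("vote_consensus applies the 2-of-3 rule", {
  out <- vote_consensus(list(c(1L, 1L, 2L), c(1L, 2L, 2L), c(2L, 3L, 2L)))
  expect_equal(out$final, c(1L, NA, 2L))
  out2 <- vote_consensus(list(2L, 2L, 2L))
  expect_equal(out2$final, 2L)
  expect_error(vote_consensus(list(1L, 1L)), "exactly 3")
})

test_that("subtype discovery is invariant to sample order", {
  co <- generate_cohort(sim_config(n_case = 45, n_ctrl = 8, n_genes = 400,
                                   n_de_per_subtype = 30, n_global_de = 15,
                                   seed = 13))
  expr <- adjust_batches(co$expr, co$annotation)
  degs <- two_group_degs(expr, co$annotation$group,
                         levels = c("case", "control"))
  x <- expr[degs$gene_id, co$annotation$group == "case"]
  set.seed(14)
  perm <- sample(ncol(x))
  d1 <- discover_subtypes(x, 3, n_resample = 40, seed = 15)
  d2 <- discover_subtypes(x[, perm], 3, n_resample = 40, seed = 15)
  f1 <- stats::setNames(d1$assignment$final, d1$assignment$sample_id)
  f2 <- stats::setNames(d2$assignment$final, d2$assignment$sample_id)
  expect_equal(adjusted_rand_index(f1, f2[names(f1)]), 1)
})
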