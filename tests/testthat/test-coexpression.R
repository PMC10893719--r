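# planted two-block expression: block genes share a latent profile
make_block_expr <- function(block_sizes = c(50, 50), n_noise = 0, n = 40,
                            load = 2, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n_genes <- sum(block_sizes) + n_noise
  x <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
  start <- 0
  for (b in seq_along(block_sizes)) {
    latent <- stats::rnorm(n)
    rows <- start + seq_len(block_sizes[b])
    x[rows, ] <- x[rows, ] + load * matrix(latent, length(rows), n,
                                           byrow = TRUE)
    start <- start + block_sizes[b]
  }
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n)))
  attr(x, "block") <- rep(c(seq_along(block_sizes), 0),
                          c(block_sizes, n_noise))
  x
}

test_that("variance_filter keeps the top-variance genes", {
  set.seed(2)
  x <- matrix(stats::rnorm(100 * 20), 100, 20,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:20)))
  expect_equal(nrow(variance_filter(x, 0.25)), 25)
  expect_equal(variance_filter(x, 1), x)
  # injected high-variance block always retained
  x[1:10, ] <- x[1:10, ] * sqrt(10)
  expect_true(all(sprintf("g%03d", 1:10) %in% rownames(variance_filter(x, 0.25))))
  expect_error(variance_filter(x, 0), "top_frac")
})

test_that("adjacency at beta = 1 is the absolute correlation matrix", {
  x <- make_block_expr(c(10, 10), n = 15, seed = 3)
  a <- adjacency_matrix(x, 1)
  expect_equal(a, abs(stats::cor(t(x))), tolerance = 1e-12)
  a3 <- adjacency_matrix(x, 3)
  expect_equal(a3[1, 2], abs(stats::cor(x[1, ], x[2, ]))^3)
  expect_error(adjacency_matrix(x, 0), "positive")
})

test_that("tom_transform matches the brute-force oracle and the closed form", {
  # isolated perfect pair: TOM = 1
  a <- diag(3)
  a[1, 2] <- a[2, 1] <- 1
  tom <- tom_transform(a)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[1, 3], 0)

  for (seed in 1:20) {
    n <- sample(5:10, 1)
    a <- random_adjacency(n, seed = seed)
    tom <- tom_transform(a)
    expect_lt(max(abs(tom - tom_bruteforce(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }

  expect_equal(unname(tom_transform(diag(4))), diag(4))
  bad <- random_adjacency(4); bad[1, 2] <- 0.9; bad[2, 1] <- 0.1
  expect_error(tom_transform(bad), "symmetric")
})

test_that("pick_soft_threshold reaches the scale-free target on factor-structured cohorts", {
  co <- generate_cohort(sim_config(n_case = 90, n_ctrl = 12, n_genes = 500,
                                   n_de_per_subtype = 10, n_global_de = 10,
                                   n_factors = 5, seed = 4))
  cases <- co$annotation$group == "case"
  bg <- setdiff(rownames(co$expr),
                c(unlist(co$truth$true_de_genes), co$truth$true_global_de))
  st <- pick_soft_threshold(co$expr[bg, cases])
  expect_gte(st$fit$r2[st$fit$power == st$beta], 0.9)
  expect_equal(nrow(st$fit), 20)

  # degenerate range: single candidate power
  st1 <- suppressWarnings(pick_soft_threshold(co$expr[bg[1:100], cases],
                                              powers = 3))
  expect_equal(st1$beta, 3)
  expect_equal(nrow(st1$fit), 1)
})

test_that("detect_modules recovers planted blocks and ignores gene order", {
  x <- make_block_expr(c(50, 50), n = 40, load = 2, seed = 5)
  tom <- tom_transform(adjacency_matrix(x, 6))
  mods <- detect_modules(tom, min_module_size = 30)
  non_grey <- setdiff(unique(mods), "grey")
  expect_length(non_grey, 2)
  block <- attr(x, "block")
  for (b in 1:2) {
    labs <- mods[block == b]
    expect_equal(length(unique(labs)), 1)   # block-pure
    expect_false(unique(labs) == "grey")
  }

  # permuted gene order: identical partition up to labels
  set.seed(6)
  perm <- sample(nrow(tom))
  mods_p <- detect_modules(tom[perm, perm], min_module_size = 30)
  expect_equal(adjusted_rand_index(mods_p[rownames(tom)], mods), 1)

  expect_warning(all_grey <- detect_modules(tom[1:10, 1:10],
                                            min_module_size = 30),
                 "all grey")
  expect_true(all(all_grey == "grey"))
})

test_that("module_eigengene is unit-variance, sign-fixed, and PC1-optimal", {
  x <- make_block_expr(c(20), n = 30, load = 3, seed = 7)
  e <- module_eigengene(x, rownames(x))
  expect_equal(stats::sd(e), 1, tolerance = 1e-9)
  z <- zscore_genes(x)
  expect_gte(stats::cor(e, colMeans(z)), 0)

  # module of identical genes: eigengene is that standardized profile
  xx <- matrix(rep(stats::rnorm(15), each = 4), 4, 15,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:15)))
  e2 <- module_eigengene(xx, rownames(xx))
  prof <- (xx[1, ] - mean(xx[1, ])) / stats::sd(xx[1, ])
  expect_equal(unname(e2), unname(prof), tolerance = 1e-9)

  # PC1 variance share >= any single standardized gene's share (1/p)
  set.seed(8)
  y <- matrix(stats::rnorm(200), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  sv <- svd(zscore_genes(y))
  expect_gte(sv$d[1]^2 / sum(sv$d^2), 1 / 10)

  expect_error(module_eigengene(x, rownames(x)[1]), ">= 2 genes")
})

test_that("merge_modules joins correlated modules and never splits", {
  # two halves of one block: eigengenes correlate ~ 1 -> merged
  x <- make_block_expr(c(60), n = 40, load = 3, noise_sd = 0.5, seed = 9)
  mods <- stats::setNames(rep(c("blue", "brown"), each = 30), rownames(x))
  merged <- merge_modules(x, mods, cut_height = 0.25)
  expect_equal(merged$n_merged, 1)
  expect_lte(merged$n_merged, merged$n_initial)

  # independent blocks stay apart
  x2 <- make_block_expr(c(40, 40), n = 40, load = 3, noise_sd = 0.5, seed = 10)
  mods2 <- stats::setNames(rep(c("blue", "brown"), each = 40), rownames(x2))
  merged2 <- merge_modules(x2, mods2, cut_height = 0.25)
  expect_equal(merged2$n_merged, 2)

  # monotonicity across random initial partitions of a structured cohort
  for (seed in 1:3) {
    x3 <- make_block_expr(c(30, 30, 30), n = 30, load = 2, seed = 20 + seed)
    set.seed(seed)
    k0 <- sample(3:6, 1)
    labs <- stats::setNames(
      sample(c("blue", "brown", "red", "green", "yellow", "black")[1:k0],
             nrow(x3), replace = TRUE), rownames(x3))
    m <- merge_modules(x3, labs, cut_height = 0.25)
    expect_lte(m$n_merged, length(unique(labs)))
  }
})

test_that("module_trait_correlation and hub calling behave per contract", {
  x <- make_block_expr(c(30, 30), n = 50, load = 3, noise_sd = 0.5, seed = 11)
  mods <- stats::setNames(rep(c("blue", "brown"), each = 30), rownames(x))
  me <- module_eigengenes(x, mods)

  # eigengene against itself: coefficient exactly 1
  mt <- module_trait_correlation(me, cbind(self = me["blue", ]))
  expect_equal(mt$r["blue", "self"], 1)
  expect_error(module_trait_correlation(me, cbind(const = rep(1, 50))),
               "constant trait")

  # independent random trait: |coefficient| small at n = 50 (Fisher bound)
  set.seed(12)
  mt2 <- module_trait_correlation(me, cbind(noise = stats::rnorm(50)))
  expect_lt(max(abs(mt2$r)), 3 / sqrt(50 - 3) + 0.1)

  trait <- me["blue", ]
  hubs <- mm_gs_hubs(x, mods, me, trait, mm_thr = 0.7, gs_thr = 0.2)
  # blue-module genes track their eigengene (high MM) and the trait (GS)
  expect_true(any(hubs$hub[hubs$module == "blue"]))
  # gate: thresholds at (0, 0) admit everything with nonzero correlations
  hubs0 <- mm_gs_hubs(x, mods, me, trait, mm_thr = 0, gs_thr = 0)
  expect_true(all(hubs0$hub))
  # gate: a gene orthogonal to the trait is never a hub
  hubs_gate <- mm_gs_hubs(x, mods, me, trait, mm_thr = 0, gs_thr = 1)
  expect_false(any(hubs_gate$hub))
})
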