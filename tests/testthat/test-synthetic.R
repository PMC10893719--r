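test_that("generate_cohort is deterministic and respects its contracts", {
  cf <- sim_config(n_case = 30, n_ctrl = 8, n_genes = 300,
                   n_de_per_subtype = 20, n_global_de = 15, seed = 7)
  a <- generate_cohort(cf)
  b <- generate_cohort(cf)
  expect_identical(a$expr, b$expr)
  expect_identical(a$annotation, b$annotation)
  expect_equal(dim(a$expr), c(300, 38))
  expect_setequal(unique(a$annotation$group), c("case", "control"))

  # per-subtype DE sets disjoint from each other and the global block
  blocks <- a$truth$true_de_genes
  expect_length(intersect(blocks[[1]], blocks[[2]]), 0)
  expect_length(intersect(unlist(blocks), a$truth$true_global_de), 0)

  expect_error(generate_cohort(sim_config(n_genes = 50, n_de_per_subtype = 20,
                                          n_global_de = 10)),
               "DE blocks exceed gene count")
})

test_that("effect_size = 0 plants no group difference", {
  cf <- sim_config(n_case = 20, n_ctrl = 20, n_genes = 100,
                   n_de_per_subtype = 10, n_global_de = 10, effect_size = 0,
                   noise_sd = 0, batch_shift_sd = 0, n_batches = 1, seed = 3)
  co <- generate_cohort(cf)
  # with all noise off, every sample equals the baseline mean vector
  expect_lt(max(abs(co$expr - co$expr[, 1])), 1e-12)
})

test_that("largest-remainder allocation is deterministic and exact", {
  expect_identical(allocate_largest_remainder(90, rep(1 / 3, 3)),
                   c(30L, 30L, 30L))
  expect_identical(allocate_largest_remainder(10, c(0.55, 0.45)), c(6L, 4L))
  expect_identical(allocate_largest_remainder(7, c(0.5, 0.25, 0.25)),
                   c(3L, 2L, 2L))
  set.seed(1)
  for (i in 1:20) {
    p <- stats::rexp(4); p <- p / sum(p)
    n <- sample(5:200, 1)
    a <- allocate_largest_remainder(n, p)
    expect_identical(sum(a), as.integer(n))
    expect_true(all(abs(a - n * p) < 1))
  }
  co <- generate_cohort(sim_config(n_case = 90, n_ctrl = 12, n_genes = 300,
                                   n_de_per_subtype = 10, n_global_de = 10))
  expect_identical(unname(table(co$truth$true_subtype)),
                   table(rep(1:3, each = 30)) |> unname())
})

test_that("generate_gene_sets builds signal and clean null sets", {
  co <- generate_cohort(sim_config(n_case = 30, n_ctrl = 8, n_genes = 500,
                                   n_de_per_subtype = 20, n_global_de = 10,
                                   seed = 2))
  sets <- generate_gene_sets(co$truth, rownames(co$expr), n_null_sets = 5,
                             set_size = 30, seed = 9)
  expect_length(sets, 8)
  de_all <- c(unlist(co$truth$true_de_genes), co$truth$true_global_de)
  for (j in 1:5) {
    expect_length(intersect(sets[[paste0("null_set", j)]], de_all), 0)
  }
  for (s in 1:3) {
    block <- co$truth$true_de_genes[[s]]
    frac <- length(intersect(sets[[paste0("signal_subtype", s)]], block)) /
      length(block)
    expect_gte(frac, 0.8)
  }
  expect_identical(sets, generate_gene_sets(co$truth, rownames(co$expr),
                                            n_null_sets = 5, set_size = 30,
                                            seed = 9))
  expect_error(generate_gene_sets(co$truth, rownames(co$expr),
                                  n_null_sets = 50, set_size = 30),
               "not enough non-DE genes")
})

test_that("generate_mixtures puts fractions on the simplex and is exact at zero noise", {
  set.seed(4)
  sig <- matrix(stats::rgamma(100 * 4, 2, 0.5), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:4)))
  mix <- generate_mixtures(25, sig, noise_sd = 0, seed = 5)
  expect_true(all(abs(rowSums(mix$fractions) - 1) < 1e-9))
  expect_true(all(mix$fractions >= 0))
  # reconstruct: bulk must equal signature %*% fractions exactly
  expect_lt(max(abs(mix$bulk - sig %*% t(mix$fractions))), 1e-12)
  # noise-free recovery through the estimator
  est <- estimate_fractions(mix$bulk, sig)
  expect_lt(max(abs(est - mix$fractions)), 1e-6)
  expect_error(generate_mixtures(5, sig, noise_sd = -1), "nonnegative")
  expect_error(generate_mixtures(5, sig[, 1, drop = FALSE]), ">= 2")
})

test_that("generate_traits is linear in the loaded genes", {
  co <- generate_cohort(sim_config(n_case = 40, n_ctrl = 8, n_genes = 200,
                                   n_de_per_subtype = 10, n_global_de = 10,
                                   seed = 6))
  g1 <- co$truth$true_de_genes[[1]][1]
  truth <- co$truth
  truth$trait_loadings <- list(eGFR_like = stats::setNames(1, g1),
                               proteinuria_like = stats::setNames(-1, g1))
  tr <- generate_traits(truth, co$expr, co$annotation, noise_sd = 0, seed = 1)
  case_ids <- co$annotation$sample_id[co$annotation$group == "case"]
  expect_equal(stats::cor(tr$eGFR_like, co$expr[g1, case_ids]), 1)
  expect_equal(stats::cor(tr$proteinuria_like, co$expr[g1, case_ids]), -1)

  truth$trait_loadings <- list(eGFR_like = stats::setNames(1, "nope"))
  expect_error(generate_traits(truth, co$expr, co$annotation), "nope")
})

test_that("trait signal vanishes as noise dominates", {
  # 1000 Monte-Carlo draws of cor(gene, gene + huge noise) at n = 100
  set.seed(8)
  rs <- replicate(1000, {
    g <- stats::rnorm(100)
    stats::cor(g, g + stats::rnorm(100, sd = 100))
  })
  expect_lt(mean(abs(rs)), 0.1)
})
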