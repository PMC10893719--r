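test_that("bh_adjust matches hand arithmetic and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(10)
  for (i in 1:200) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  # monotone on sorted input
  p <- sort(stats::runif(100))
  expect_true(all(diff(bh_adjust(p)) >= 0))
})

test_that("two_group_degs recovers planted genes with zero false positives", {
  tg <- make_two_group(n_genes = 200, n_de = 50, effect = 3, noise_sd = 0.5,
                       seed = 21)
  res <- two_group_degs(tg$expr, tg$groups, levels = c("a", "b"),
                        alpha = 0.05, lfc = 1.7)
  expect_setequal(res$gene_id, tg$de_genes)
  expect_true(all(res$direction == "up"))
  expect_true(all(res$adj_p >= res$p))
  expect_true(!is.unsorted(res$p))

  # unsatisfiable cutoff
  expect_equal(nrow(two_group_degs(tg$expr, tg$groups, levels = c("a", "b"),
                                   lfc = Inf)), 0)
  # null gene (equal means) never returned: effect 0 everywhere
  tg0 <- make_two_group(n_de = 0, seed = 22)
  expect_equal(nrow(two_group_degs(tg0$expr, tg0$groups,
                                   levels = c("a", "b"))), 0)
  expect_error(two_group_degs(tg$expr[, 1:31],
                              c(rep("a", 30), "b"), levels = c("a", "b")),
               ">= 2 samples")
})

test_that("two_group_degs is antisymmetric under label swap", {
  tg <- make_two_group(n_genes = 100, n_de = 30, seed = 23)
  up <- two_group_degs(tg$expr, tg$groups, levels = c("a", "b"),
                       alpha = 1, lfc = 0)
  dn <- two_group_degs(tg$expr, tg$groups, levels = c("b", "a"),
                       alpha = 1, lfc = 0)
  dn <- dn[match(up$gene_id, dn$gene_id), ]
  expect_equal(up$log2fc, -dn$log2fc, tolerance = 1e-12)
  expect_equal(up$p, dn$p, tolerance = 1e-12)
})

test_that("subtype_vs_rest_degs recovers a planted block and is null-calibrated", {
  co <- generate_cohort(sim_config(n_case = 90, n_ctrl = 12, n_genes = 500,
                                   n_de_per_subtype = 30, n_global_de = 20,
                                   seed = 31))
  expr <- adjust_batches(co$expr, co$annotation)
  cases <- co$annotation$group == "case"
  labels <- co$truth$true_subtype
  res <- subtype_vs_rest_degs(expr[, cases], labels, 1, alpha = 0.01, lfc = 2)
  expect_true(all(co$truth$true_de_genes[[1]] %in% res$gene_id))
  planted <- c(unlist(co$truth$true_de_genes), co$truth$true_global_de)
  expect_length(setdiff(res$gene_id, planted), 0)

  # k = 2 reduces to two_group_degs
  two <- labels[labels %in% 1:2]
  sub <- expr[, cases][, labels %in% 1:2]
  expect_equal(
    subtype_vs_rest_degs(sub, two, 1, alpha = 1, lfc = 0),
    two_group_degs(sub, ifelse(two == 1, "target", "rest"),
                   levels = c("target", "rest"), alpha = 1, lfc = 0))

  expect_error(subtype_vs_rest_degs(sub, two, 9), "unknown subtype")

  # permuted labels: essentially nothing passes lfc = 2
  set.seed(32)
  n_pass <- replicate(20, {
    perm <- sample(labels)
    nrow(subtype_vs_rest_degs(expr[, cases], perm, 1, alpha = 0.01, lfc = 2))
  })
  expect_lt(mean(n_pass), 1)
})

test_that("subtype_specific_genes is plain intersection with subtype direction", {
  g <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(2, -2, 2),
                  p = 0.001, adj_p = 0.001, direction = c("up", "down", "up"))
  s <- data.frame(gene_id = c("B", "C", "D"), log2fc = c(3, -3, 3),
                  p = 0.001, adj_p = 0.001, direction = c("up", "down", "up"))
  out <- subtype_specific_genes(g, s)
  expect_setequal(out$gene_id, c("B", "C"))
  expect_equal(out$direction[out$gene_id == "C"], "down")  # subtype contrast
  expect_equal(nrow(subtype_specific_genes(g, s[3, ])), 0)
  # subset case: subtype list contained in global list
  expect_setequal(subtype_specific_genes(g, g[1:2, ])$gene_id, c("A", "B"))
})

test_that("gene_trait_correlation flags loaded genes and respects bounds", {
  set.seed(41)
  expr <- matrix(stats::rnorm(50 * 60), 50, 60,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:60)))
  trait <- expr["g01", ]
  res <- gene_trait_correlation(expr, trait)
  expect_equal(res$r[res$gene_id == "g01"], 1)
  res2 <- gene_trait_correlation(expr, -expr["g02", ])
  expect_equal(res2$r[res2$gene_id == "g02"], -1)
  expect_error(gene_trait_correlation(expr, rep(1, 60)), "constant trait")

  # loaded genes significant, unloaded false-flag rate near alpha
  trait2 <- expr["g01", ] + expr["g02", ]
  res3 <- gene_trait_correlation(expr, trait2)
  expect_true(all(res3$significant[res3$gene_id %in% c("g01", "g02")]))
  # unadjusted p of null genes below 0.05 at most 0.05 + 3 SE
  null_p <- res3$p[!res3$gene_id %in% c("g01", "g02")]
  expect_lte(mean(null_p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(null_p)))
})

test_that("Welch screen is type-I calibrated on null cohorts", {
  ps <- unlist(lapply(1:3, function(seed) {
    co <- generate_cohort(sim_config(n_case = 60, n_ctrl = 12, n_genes = 1000,
                                     effect_size = 0, n_batches = 1,
                                     seed = seed))
    res <- two_group_degs(co$expr, co$annotation$group,
                          levels = c("case", "control"), alpha = 1, lfc = 0)
    res$p
  }))
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / length(ps))
    expect_lt(abs(mean(ps < alpha) - alpha), 3 * se)
  }
})
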