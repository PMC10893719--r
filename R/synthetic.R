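#' Simulation configuration for a synthetic IgAN-like cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults
#' emulate a two-batch microarray cohort of 107 cases and 14 controls with
#' three planted molecular subtypes, a shared case-vs-control DE block, and
#' subtype-specific DE blocks, on the log2 intensity scale.
#'
#' @param n_case number of case (IgAN) samples
#' @param n_ctrl number of control samples
#' @param n_genes number of genes simulated
#' @param k_subtypes number of planted subtypes among cases
#' @param subtype_props subtype mixing proportions (sums to 1)
#' @param n_de_per_subtype genes in each subtype-specific DE block
#' @param n_global_de genes in the DE block shared by all case subtypes
#'   (the global case-vs-control signal)
#' @param effect_size mean shift, log2 units, applied to DE blocks
#' @param noise_sd per-observation Gaussian noise SD, log2 units
#' @param n_batches number of batches (samples split contiguously so each
#'   batch spans cases and controls)
#' @param batch_shift_sd SD of per-gene per-batch offsets, log2 units
#' @param n_factors number of latent expression factors shared by all
#'   samples (heterogeneous per-gene loadings give the cohort the pervasive
#'   low-rank covariance and heavy-tailed connectivity of real expression
#'   data; 0 disables)
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_case = 107, n_ctrl = 14, n_genes = 2000,
                       k_subtypes = 3,
                       subtype_props = rep(1 / k_subtypes, k_subtypes),
                       n_de_per_subtype = 60, n_global_de = 40,
                       effect_size = 3, noise_sd = 1,
                       n_batches = 2, batch_shift_sd = 0.5,
                       n_factors = 0, seed = 1L) {
  counts <- c(n_case = n_case, n_ctrl = n_ctrl, n_genes = n_genes,
              k_subtypes = k_subtypes, n_de_per_subtype = n_de_per_subtype,
              n_batches = n_batches)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("all counts must be positive integers")
  }
  if (n_global_de < 0) stop("n_global_de must be nonnegative")
  if (length(subtype_props) != k_subtypes) {
    stop("subtype_props must have length k_subtypes")
  }
  if (abs(sum(subtype_props) - 1) > 1e-9) stop("subtype_props must sum to 1")
  if (effect_size < 0) stop("effect_size must be nonnegative")
  if (noise_sd < 0 || batch_shift_sd < 0) stop("SDs must be nonnegative")
  if (n_factors < 0) stop("n_factors must be nonnegative")
  structure(list(n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 n_genes = as.integer(n_genes),
                 k_subtypes = as.integer(k_subtypes),
                 subtype_props = subtype_props,
                 n_de_per_subtype = as.integer(n_de_per_subtype),
                 n_global_de = as.integer(n_global_de),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_batches = as.integer(n_batches),
                 batch_shift_sd = batch_shift_sd,
                 n_factors = as.integer(n_factors),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Largest-remainder allocation of n items to proportions
#'
#' Deterministic apportionment: floor each quota, then distribute the
#' remaining items to the largest fractional remainders (ties to the
#' earlier index).
#' @param n total count
#' @param props proportion vector summing to 1
#' @return integer vector summing to `n`
#' @export
allocate_largest_remainder <- function(n, props) {
  quota <- n * props
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    add <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a gene-by-sample log2 expression matrix with baseline gene
#' means drawn N(7, 1.5^2), per-gene per-batch offsets, latent-factor
#' covariance, Gaussian noise, and planted differential expression. Every
#' DE gene (global block and all subtype blocks) is shifted by
#' `+/- effect_size` in all case samples relative to controls — so all
#' planted genes are global case-vs-control DEGs, as in real cohorts where
#' the disease signature carries the subtype structure — and genes of
#' subtype block s receive an additional `+/- effect_size` in that
#' subtype's cases only, making them subtype-vs-rest DEGs as well. Shift
#' directions are drawn once per gene. Cases are allocated to subtypes by
#' largest-remainder rounding of `subtype_props`; cases and controls are
#' each split contiguously into batches so every batch contains both
#' groups.
#'
#' @param config a [sim_config()] object
#' @return list with elements
#'   \item{expr}{n_genes x (n_case + n_ctrl) matrix, log2 scale}
#'   \item{annotation}{data.frame: sample_id, group (case/control), batch,
#'     subtype_true (NA for controls)}
#'   \item{truth}{ground truth: true_subtype, true_de_genes (per-subtype
#'     list), true_global_de, de_signs, pathway_sets (filled by
#'     [generate_gene_sets()]), trait_loadings}
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n_de_total <- cf$n_de_per_subtype * cf$k_subtypes + cf$n_global_de
  if (n_de_total > cf$n_genes) stop("DE blocks exceed gene count")
  set.seed(cf$seed)

  n <- cf$n_case + cf$n_ctrl
  genes <- sprintf("g%04d", seq_len(cf$n_genes))
  samples <- c(sprintf("case%03d", seq_len(cf$n_case)),
               sprintf("ctrl%03d", seq_len(cf$n_ctrl)))
  group <- rep(c("case", "control"), c(cf$n_case, cf$n_ctrl))

  # round-robin batch assignment over the sample order: balances batches
  # across group AND subtype (cases are ordered by subtype, so a contiguous
  # split would confound batch with subtype and the location-scale batch
  # adjustment would distort subtype means)
  batch_case <- (seq_len(cf$n_case) - 1L) %% cf$n_batches + 1L
  batch_ctrl <- (seq_len(cf$n_ctrl) - 1L) %% cf$n_batches + 1L
  batch <- c(batch_case, batch_ctrl)

  sub_counts <- allocate_largest_remainder(cf$n_case, cf$subtype_props)
  true_subtype <- rep(seq_len(cf$k_subtypes), sub_counts)

  # gene blocks: subtype blocks first, then the shared global block
  idx <- seq_len(cf$n_genes)
  sub_blocks <- split(idx[seq_len(cf$n_de_per_subtype * cf$k_subtypes)],
                      rep(seq_len(cf$k_subtypes), each = cf$n_de_per_subtype))
  global_block <- if (cf$n_global_de > 0) {
    idx[cf$n_de_per_subtype * cf$k_subtypes + seq_len(cf$n_global_de)]
  } else integer(0)

  mu <- stats::rnorm(cf$n_genes, mean = 7, sd = 1.5)
  signs <- sample(c(-1, 1), cf$n_genes, replace = TRUE)
  batch_offsets <- matrix(stats::rnorm(cf$n_genes * cf$n_batches,
                                       sd = cf$batch_shift_sd),
                          cf$n_genes, cf$n_batches)

  shift <- matrix(0, cf$n_genes, n)
  case_cols <- seq_len(cf$n_case)
  if (cf$effect_size > 0) {
    all_de <- c(unlist(sub_blocks, use.names = FALSE), global_block)
    # shared case-vs-control shift on every planted DE gene
    shift[all_de, case_cols] <- cf$effect_size * signs[all_de]
    # extra own-subtype shift on the subtype blocks
    for (s in seq_len(cf$k_subtypes)) {
      cols <- case_cols[true_subtype == s]
      shift[sub_blocks[[s]], cols] <- shift[sub_blocks[[s]], cols] +
        cf$effect_size * signs[sub_blocks[[s]]]
    }
  }

  expr <- mu + batch_offsets[, batch] + shift +
    matrix(stats::rnorm(cf$n_genes * n, sd = cf$noise_sd), cf$n_genes, n)
  if (cf$n_factors > 0) {
    # latent background co-expression: factors load only on non-DE genes
    # (the disease signature stays orthogonal to background covariance);
    # per-gene loading scales ~ Gamma(0.8, 2.5) so a heavy-tailed minority
    # of high-loading hub genes yields approximately scale-free connectivity
    bg <- setdiff(idx, c(unlist(sub_blocks, use.names = FALSE), global_block))
    loading_scale <- stats::rgamma(length(bg), shape = 0.8, rate = 2.5)
    loadings <- matrix(stats::rnorm(length(bg) * cf$n_factors),
                       length(bg), cf$n_factors) * loading_scale
    factor_scores <- matrix(stats::rnorm(cf$n_factors * n), cf$n_factors, n)
    expr[bg, ] <- expr[bg, ] + loadings %*% factor_scores
  }
  dimnames(expr) <- list(genes, samples)

  annotation <- data.frame(
    sample_id = samples, group = group, batch = batch,
    subtype_true = c(true_subtype, rep(NA_integer_, cf$n_ctrl)),
    stringsAsFactors = FALSE)

  true_de_genes <- lapply(sub_blocks, function(b) genes[b])
  names(true_de_genes) <- paste0("subtype", seq_len(cf$k_subtypes))

  # clinical-trait loadings, aligned with each gene's planted shift
  # direction so the trait tracks disease activity: eGFR-like declines
  # with subtype-1 activity, proteinuria-like rises with subtype-2's
  g_egfr <- true_de_genes[[1]][1:2]
  g_prot <- true_de_genes[[min(2, cf$k_subtypes)]][1:2]
  trait_loadings <- list(
    eGFR_like = stats::setNames(-signs[match(g_egfr, genes)], g_egfr),
    proteinuria_like = stats::setNames(signs[match(g_prot, genes)], g_prot))

  truth <- list(true_subtype = true_subtype,
                true_de_genes = true_de_genes,
                true_global_de = genes[global_block],
                de_signs = stats::setNames(signs, genes),
                pathway_sets = NULL,
                trait_loadings = trait_loadings)
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Generate gene sets anchored to the planted DE blocks
#'
#' One "signal" pathway per subtype containing at least 80% of that
#' subtype's true DE genes (padded with random non-DE genes up to
#' `set_size`), plus `n_null_sets` sets drawn uniformly from non-DE genes.
#'
#' @param truth ground truth from [generate_cohort()]
#' @param gene_ids the full gene universe (rownames of the matrix)
#' @param n_null_sets number of null gene sets
#' @param set_size size of every set
#' @param seed integer RNG seed
#' @return named list of gene-id vectors (a GeneSetCollection)
#' @export
generate_gene_sets <- function(truth, gene_ids, n_null_sets = 5,
                               set_size = 50, seed = 1L) {
  if (set_size > length(gene_ids)) stop("set_size exceeds gene count")
  set.seed(seed)
  de_all <- unique(c(unlist(truth$true_de_genes), truth$true_global_de))
  non_de <- setdiff(gene_ids, de_all)
  if (length(non_de) < n_null_sets * set_size) {
    stop("not enough non-DE genes for null sets")
  }
  sets <- list()
  for (s in seq_along(truth$true_de_genes)) {
    block <- truth$true_de_genes[[s]]
    n_sig <- max(ceiling(0.8 * length(block)), min(length(block), set_size))
    n_sig <- min(n_sig, set_size, length(block))
    members <- sample(block, n_sig)
    if (n_sig < set_size) {
      members <- c(members, sample(non_de, set_size - n_sig))
    }
    sets[[paste0("signal_subtype", s)]] <- members
  }
  pool <- sample(non_de)
  for (j in seq_len(n_null_sets)) {
    sets[[paste0("null_set", j)]] <- pool[(j - 1) * set_size + seq_len(set_size)]
  }
  sets
}

#' Generate noisy bulk mixtures from a cell-type signature
#'
#' Draws per-sample cell fractions from a flat Dirichlet, forms bulk
#' profiles as signature x fraction plus Gaussian noise clipped at zero,
#' and returns the true fractions.
#'
#' @param n_samples number of bulk samples
#' @param signature nonnegative gene x cell-type matrix, >= 2 cell types
#' @param noise_sd Gaussian noise SD added to the bulk profiles
#' @param seed integer RNG seed
#' @return list(bulk = gene x sample matrix, fractions = sample x cell-type
#'   matrix with unit row sums)
#' @export
generate_mixtures <- function(n_samples, signature, noise_sd = 0.1, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (ncol(signature) < 2) stop("signature needs >= 2 cell types")
  if (any(signature < 0)) stop("signature must be nonnegative")
  set.seed(seed)
  k <- ncol(signature)
  # flat Dirichlet via normalized Exp(1)
  raw <- matrix(stats::rexp(n_samples * k), n_samples, k)
  fractions <- raw / rowSums(raw)
  colnames(fractions) <- colnames(signature)
  rownames(fractions) <- sprintf("mix%03d", seq_len(n_samples))
  bulk <- signature %*% t(fractions)
  if (noise_sd > 0) {
    bulk <- bulk + matrix(stats::rnorm(length(bulk), sd = noise_sd),
                          nrow(bulk), ncol(bulk))
    bulk[bulk < 0] <- 0
  }
  colnames(bulk) <- rownames(fractions)
  list(bulk = bulk, fractions = fractions)
}

#' Generate synthetic clinical traits linked to planted genes
#'
#' Each trait value (cases only) is a linear combination of the loaded
#' genes' expression plus Gaussian noise. Emulates renal traits such as
#' eGFR and proteinuria that track subtype-specific expression.
#'
#' @param truth ground truth holding `trait_loadings` (trait -> named
#'   coefficient vector over gene ids)
#' @param expr the cohort expression matrix
#' @param annotation the cohort annotation (traits are generated for cases)
#' @param noise_sd Gaussian noise SD on the trait scale
#' @param seed integer RNG seed
#' @return data.frame: sample_id plus one column per trait
#' @export
generate_traits <- function(truth, expr, annotation, noise_sd = 0.5, seed = 1L) {
  if (length(truth$trait_loadings) == 0) stop("trait_loadings is empty")
  set.seed(seed)
  case_ids <- annotation$sample_id[annotation$group == "case"]
  out <- data.frame(sample_id = case_ids, stringsAsFactors = FALSE)
  for (trait in names(truth$trait_loadings)) {
    load <- truth$trait_loadings[[trait]]
    missing <- setdiff(names(load), rownames(expr))
    if (length(missing)) {
      stop(sprintf("loaded gene absent from matrix: %s",
                   paste(missing, collapse = ", ")))
    }
    vals <- as.numeric(t(expr[names(load), case_ids, drop = FALSE]) %*% load)
    out[[trait]] <- vals + stats::rnorm(length(case_ids), sd = noise_sd)
  }
  out
}
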