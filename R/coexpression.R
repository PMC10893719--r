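# Weighted co-expression network analysis: unsigned adjacency
# a_ij = |cor(x_i, x_j)|^beta, topological overlap, static-cut module
# detection, eigengenes, merging, module-trait correlation, MM/GS hubs.

#' Keep the top-variance fraction of genes
#'
#' Retains `ceiling(top_frac * n_genes)` genes with the largest sample
#' variance (ties broken by gene id).
#'
#' @param expr gene x sample matrix
#' @param top_frac fraction in (0, 1]
#' @return row-subset matrix
#' @export
variance_filter <- function(expr, top_frac = 0.25) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  v <- apply(expr, 1, stats::var)
  keep <- ceiling(top_frac * nrow(expr))
  ord <- order(-v, rownames(expr), method = "radix")
  expr[sort(ord[seq_len(keep)]), , drop = FALSE]
}

#' Unsigned weighted adjacency
#'
#' a_ij = |cor(x_i, x_j)|^beta over samples; diagonal 1.
#' @param expr gene x sample matrix
#' @param beta positive soft-threshold exponent
#' @return gene x gene adjacency matrix
#' @export
adjacency_matrix <- function(expr, beta) {
  if (beta <= 0) stop("beta must be positive")
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Choose the soft-threshold exponent by scale-free fit
#'
#' For each candidate power the connectivities k_i = sum_j a_ij (j != i)
#' are binned (equal-width bins over the k range); the scale-free fit index
#' is -sign(slope) * R^2 of the regression log10(p(k)) ~ log10(mean k) over
#' nonempty bins, so a power-law (negative-slope) fit scores positively.
#' beta is the smallest power whose index reaches `r2_target`; if none
#' does, the argmax is returned with a warning.
#'
#' @param expr gene x sample matrix
#' @param powers candidate integer powers
#' @param r2_target scale-free R^2 target
#' @param n_bins connectivity histogram bins
#' @return list(beta, fit = data.frame(power, r2, slope, mean_k))
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.9,
                                n_bins = 10) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  cors <- abs(stats::cor(t(expr)))
  diag(cors) <- 0
  fit <- data.frame(power = powers, r2 = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(cors^powers[i])
    fit$mean_k[i] <- mean(k)
    if (stats::sd(k) < SD_FLOOR) next   # constant connectivity: skip power
    bins <- cut(k, breaks = n_bins)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
    if (sum(ok) < 3) next
    lm_fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    slope <- unname(stats::coef(lm_fit)[2])
    r2 <- summary(lm_fit)$r.squared
    fit$slope[i] <- slope
    fit$r2[i] <- -sign(slope) * r2
  }
  ok_idx <- which(!is.na(fit$r2) & fit$r2 >= r2_target)
  if (length(ok_idx)) {
    beta <- powers[min(ok_idx)]
  } else {
    warning(sprintf("no power reached scale-free R^2 >= %g; using argmax",
                    r2_target), call. = FALSE)
    beta <- powers[which.max(fit$r2)]
  }
  list(beta = beta, fit = fit)
}

#' Topological overlap matrix
#'
#' Standard unsigned TOM: TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij) for i != j, with L_ij = sum_{u != i,j} a_iu a_uj and k_i =
#' sum_{u != i} a_iu; diagonal set to 1.
#'
#' @param adjacency symmetric gene x gene matrix with entries in [0, 1]
#' @return TOM matrix, same dimensions
#' @export
tom_transform <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0                      # work with off-diagonal terms
  L <- a %*% a                      # (AA)_ij = sum_u a_iu a_uj, u != i,j ok
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# deterministic module color palette, assigned by size rank
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue",
                   "darkred", "darkgreen", "darkturquoise", "darkgrey",
                   "orange", "darkorange", "white", "skyblue", "saddlebrown",
                   "steelblue", "paleturquoise", "violet", "darkolivegreen",
                   "darkmagenta")

color_by_size <- function(labels) {
  sizes <- sort(table(labels[labels != 0]), decreasing = TRUE)
  pal <- c(MODULE_COLORS, paste0("module", seq_len(max(0,
            length(sizes) - length(MODULE_COLORS)))))
  map <- stats::setNames(pal[seq_along(sizes)], names(sizes))
  out <- rep("grey", length(labels))
  assigned <- labels != 0
  out[assigned] <- map[as.character(labels[assigned])]
  stats::setNames(out, names(labels))
}

#' Detect co-expression modules by a best static tree cut
#'
#' Average-linkage hierarchical clustering on 1 - TOM; among all candidate
#' cut heights, the one producing the most branches of size >=
#' `min_module_size` is chosen (lowest such height on ties). Undersized
#' branches are labeled "grey" (unassigned). Module colors are assigned
#' deterministically by size rank.
#'
#' @param tom TOM matrix
#' @param min_module_size minimum genes per module
#' @return named character vector gene -> module color ("grey" =
#'   unassigned)
#' @export
detect_modules <- function(tom, min_module_size = 30) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all grey", call. = FALSE)
    return(stats::setNames(rep("grey", n), genes))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  heights <- sort(unique(hc$height))
  # evaluate cuts just below each merge height
  cuts <- stats::cutree(hc, h = heights - 1e-10)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  n_admissible <- apply(cuts, 2, function(lab) {
    sum(table(lab) >= min_module_size)
  })
  # among count-maximizing heights take the highest: lower ties keep only
  # tight module cores and strand peripheral members in grey
  best <- max(which(n_admissible == max(n_admissible)))
  lab <- cuts[, best]
  sizes <- table(lab)
  lab[lab %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  out <- color_by_size(stats::setNames(lab, genes))
  out
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix,
#' scaled to unit sample variance, sign fixed so its correlation with the
#' module's mean standardized profile is nonnegative.
#'
#' @param expr gene x sample matrix
#' @param module_genes gene ids of one module (>= 2)
#' @return numeric per-sample eigengene, unit variance
#' @export
module_eigengene <- function(expr, module_genes) {
  genes <- intersect(module_genes, rownames(expr))
  if (length(genes) < 2) stop("module needs >= 2 genes in the matrix")
  x <- zscore_genes(expr[genes, , drop = FALSE])
  sv <- svd(x, nu = 0, nv = 1)
  if (sv$d[1] < 1e-12) stop("rank-0 module submatrix")
  e <- sv$v[, 1]
  e <- e / stats::sd(e)
  mean_profile <- colMeans(x)
  if (stats::cor(e, mean_profile) < 0) e <- -e
  stats::setNames(e, colnames(expr))
}

#' Eigengenes for every non-grey module
#'
#' @param expr gene x sample matrix
#' @param modules gene -> module color vector
#' @return module x sample matrix of eigengenes
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  if (length(mods) == 0) stop("no non-grey modules")
  do.call(rbind, lapply(stats::setNames(mods, mods), function(m) {
    module_eigengene(expr, names(modules)[modules == m])
  }))
}

#' Merge similar modules by eigengene correlation
#'
#' Average-linkage clustering of module eigengenes on 1 - correlation;
#' branches below `cut_height` (i.e. eigengene correlation above
#' 1 - cut_height) are merged, eigengenes recomputed, iterating until
#' stable. Never increases the module count.
#'
#' @param expr gene x sample matrix
#' @param modules gene -> module color vector
#' @param cut_height merge height on the 1 - cor scale (0.25 merges
#'   modules correlated above 0.75)
#' @return list(modules = relabeled vector, eigengenes = matrix,
#'   n_initial, n_merged)
#' @export
merge_modules <- function(expr, modules, cut_height = 0.25) {
  n_initial <- length(setdiff(unique(modules), "grey"))
  repeat {
    mods <- setdiff(unique(modules), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, modules)
    d <- 1 - stats::cor(t(me))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- stats::cutree(hc, h = cut_height)
    if (max(groups) == length(mods)) break    # nothing to merge
    for (g in unique(groups)) {
      members <- names(groups)[groups == g]
      if (length(members) > 1) {
        modules[modules %in% members] <- members[1]
      }
    }
    # recolor by size so labels stay canonical
    lab_int <- match(modules, setdiff(unique(modules), "grey"))
    lab_int[is.na(lab_int)] <- 0L
    modules <- color_by_size(stats::setNames(lab_int, names(modules)))
  }
  mods <- setdiff(unique(modules), "grey")
  me <- if (length(mods)) module_eigengenes(expr, modules) else NULL
  list(modules = modules, eigengenes = me,
       n_initial = n_initial, n_merged = length(mods))
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait column
#' (subtype traits should be one-vs-rest indicators), with two-sided
#' t-based p-values.
#'
#' @param eigengenes module x sample matrix
#' @param traits sample x trait numeric matrix/data.frame
#' @return list(r = module x trait, p = module x trait)
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (any(apply(traits, 2, stats::sd) < SD_FLOOR)) stop("constant trait")
  n <- ncol(eigengenes)
  stopifnot(nrow(traits) == n)
  r <- stats::cor(t(eigengenes), traits)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

#' Module membership / gene significance hub genes
#'
#' MM(g, M) = cor(x_g, eigengene of M); GS(g) = cor(x_g, trait). A gene is
#' a hub of its own module iff |MM| > mm_thr and |GS| > gs_thr (strict).
#'
#' @param expr gene x sample matrix
#' @param modules gene -> module color vector
#' @param eigengenes module x sample matrix
#' @param trait numeric per-sample trait (e.g. a subtype indicator)
#' @param mm_thr,gs_thr hub thresholds
#' @return data.frame: gene_id, module, mm, gs, hub
#' @export
mm_gs_hubs <- function(expr, modules, eigengenes, trait,
                       mm_thr = 0.7, gs_thr = 0.2) {
  genes <- names(modules)[modules != "grey"]
  x <- t(expr[genes, , drop = FALSE])
  gs <- as.numeric(stats::cor(x, trait))
  mm <- vapply(seq_along(genes), function(i) {
    stats::cor(x[, i], eigengenes[modules[genes[i]], ])
  }, 0)
  data.frame(gene_id = genes, module = unname(modules[genes]),
             mm = mm, gs = gs,
             hub = abs(mm) > mm_thr & abs(gs) > gs_thr,
             stringsAsFactors = FALSE, row.names = NULL)
}
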