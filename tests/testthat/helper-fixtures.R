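# shared fixtures, all built in code

# k well-separated Gaussian clouds in `p` dimensions; returns features x
# samples with cloud ids as an attribute
make_clouds <- function(k, n_per, p = 10, sep = 10, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * p), k, p) * 0
  for (i in seq_len(k)) centers[i, ((i - 1) %% p) + 1] <- sep * i
  x <- do.call(cbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(p * n_per, mean = centers[i, ], sd = sd), p, n_per)
  }))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  rownames(x) <- paste0("f", seq_len(p))
  attr(x, "cloud") <- rep(seq_len(k), each = n_per)
  x
}

# two-group planted DE matrix: first `n_de` genes shifted by `effect` in
# group 1; returns list(expr, groups, de_genes)
make_two_group <- function(n_genes = 200, n_de = 50, n1 = 30, n2 = 30,
                           effect = 3, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  expr <- matrix(stats::rnorm(n_genes * (n1 + n2), mean = 7, sd = noise_sd),
                 n_genes, n1 + n2,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n1 + n2))))
  expr[seq_len(n_de), seq_len(n1)] <- expr[seq_len(n_de), seq_len(n1)] + effect
  list(expr = expr, groups = rep(c("a", "b"), c(n1, n2)),
       de_genes = rownames(expr)[seq_len(n_de)])
}

# random symmetric adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# brute-force TOM by triple loop (independent oracle)
tom_bruteforce <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# exhaustive best label permutation (oracle for Hungarian alignment):
# returns the maximum achievable agreement with the reference
best_agreement_bruteforce <- function(lab, ref, k) {
  perms <- gtools_permutations(k)
  best <- -Inf
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, ][lab] == ref))
  }
  best
}

# all permutations of 1..k without external packages
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- (1:k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
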