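#' @keywords internal
"_PACKAGE"

# Floor applied to standard deviations before division; keeps degenerate
# (near-constant) rows in the matrix instead of dropping them.
SD_FLOOR <- 1e-8

#' Sample standard deviation with a floor
#'
#' Returns `max(sd(x), SD_FLOOR)` (n-1 denominator). Emits a warning naming
#' `context` when the floor engages, so degenerate rows are logged rather
#' than silently rescaled.
#' @param x numeric vector
#' @param context label used in the warning
#' @return a positive scalar
#' @keywords internal
floored_sd <- function(x, context = "value") {
  s <- stats::sd(x)
  if (!is.finite(s) || s < SD_FLOOR) {
    warning(sprintf("standard deviation of %s floored at %g", context, SD_FLOOR),
            call. = FALSE)
    s <- SD_FLOOR
  }
  s
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (global seed, stage name) to a 31-bit seed so
#' pipeline stages can be rerun independently yet reproducibly.
#' @param seed integer global seed
#' @param stage character stage name
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Read / write an expression matrix as TSV
#'
#' Rows are genes (first column `gene_id`), remaining columns are samples.
#' @param path file path
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param expr gene-by-sample numeric matrix
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member gene ids.
#' @param path file path
#' @return named list of character vectors; names are set names, the
#'   `description` attribute holds per-set descriptions
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "description") <- vapply(fields, `[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @param description optional per-set description vector
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description")
    if (is.null(description)) description <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' monotonicity enforcement; output is in the input order.
#' @param p numeric vector of p-values in [0, 1]
#' @return adjusted p-values, same length and order as `p`
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' @param a,b label vectors of equal length
#' @return scalar in [-1, 1], 1 for identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# significance star bins used in fraction comparison tables
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}
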