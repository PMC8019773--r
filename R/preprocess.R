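#' Log-transform and standardize an expression matrix
#'
#' Applies `log2(x + 1)` elementwise (skipped when `transform = FALSE`, for
#' data already on a log/standardized scale) and then standardizes every gene
#' row to mean 0, standard deviation 1 (sample SD, `n - 1` denominator).
#' Genes with zero variance cannot be standardized and are dropped with a
#' warning.
#'
#' @param expr Expression tibble (`gene_id` + one column per sample).
#' @param transform Apply the `log2(x + 1)` transform first (requires all
#'   values `>= 0`); default `TRUE`.
#' @return Standardized expression tibble, possibly with fewer genes.
#' @export
log2_standardize <- function(expr, transform = TRUE) {
  m <- expr_matrix(expr)
  if (transform) {
    if (any(m < 0)) abort("negative values: raw intensities must be >= 0")
    m <- log2(m + 1)
  }
  sds <- apply(m, 1, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warn(sprintf("dropping %d zero-variance gene(s): %s", sum(zero),
                 paste(head(rownames(m)[zero], 5), collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
    sds <- sds[!zero]
  }
  if (nrow(m) == 0L) abort("no genes left after dropping zero-variance rows")
  m <- (m - rowMeans(m)) / sds
  as_expr_tbl(m)
}

#' Sure-independence-screening dimension
#'
#' The number of features retained by sure independence screening,
#' `d = floor(2 n / log(n))` with a base-10 logarithm by default. For a
#' cohort of n = 149 this gives d = 137.
#'
#' @param n Sample count (`>= 2`).
#' @param log_base 10 (default) or `exp(1)`.
#' @param max_genes Optional cap (the number of available genes).
#' @return A positive integer.
#' @export
sis_dimension <- function(n, log_base = 10, max_genes = NULL) {
  if (n < 2) abort("sis_dimension needs n >= 2")
  d <- floor(2 * n / log(n, base = log_base))
  if (!is.null(max_genes)) d <- min(d, max_genes)
  as.integer(max(1L, d))
}

#' Sure independence screening of genes against a binary outcome
#'
#' Ranks genes by marginal utility — the absolute two-sample (pooled) t
#' statistic between outcome groups, which on standardized data orders genes
#' identically to the absolute marginal Pearson correlation with the
#' outcome — and keeps the top `d`. Ties are broken by gene order in the
#' input.
#'
#' @param expr Standardized expression tibble.
#' @param phenotypes Phenotype tibble with 0/1 `outcome`.
#' @param d Number of genes to keep; default `sis_dimension(n)` capped at the
#'   gene count.
#' @param log_base Base of the logarithm in the default `d` rule.
#' @return A tibble `rank`, `gene_id`, `statistic` (the |t| utility),
#'   ordered by decreasing utility.
#' @export
sis_screen <- function(expr, phenotypes, d = NULL, log_base = 10) {
  x <- analysis_matrix(expr, phenotypes)   # samples x genes
  y <- phenotypes$outcome
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")
  n <- nrow(x)
  if (is.null(d)) d <- sis_dimension(n, log_base, max_genes = ncol(x))
  d <- min(as.integer(d), ncol(x))
  if (d < 1L) abort("d must be >= 1")
  tt <- abs(two_sample_t(x, y))
  ord <- order(-tt, seq_along(tt))[seq_len(d)]
  tibble(rank = seq_len(d), gene_id = colnames(x)[ord], statistic = tt[ord])
}

# vectorized pooled two-sample t over the columns of a samples x genes matrix
two_sample_t <- function(x, y) {
  g1 <- x[y == 1L, , drop = FALSE]
  g0 <- x[y == 0L, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- colSums((g1 - rep(m1, each = n1))^2)
  v0 <- colSums((g0 - rep(m0, each = n0))^2)
  sp <- sqrt((v1 + v0) / (n1 + n0 - 2))
  (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0))
}
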