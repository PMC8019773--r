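#' SAM moderated d statistics
#'
#' Per-gene SAM statistic `d = (mean_poor - mean_good) / (s + s0)` where `s`
#' is the pooled standard error of the group mean difference and `s0` the
#' variance-stabilizing fudge factor. The good-outcome group is the control,
#' so positive `d` means elevated in the poor-outcome group.
#'
#' @param x Genes x samples numeric matrix (standardized expression).
#' @param y 0/1 outcome per sample (1 = poor), at least 2 per class.
#' @param s0 Fudge factor (`>= 0`).
#' @return A tibble: `gene_id`, `d`, `s`, `mean_diff`.
#' @export
sam_d_statistics <- function(x, y, s0 = 0) {
  y <- as.integer(y)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    abort("each class needs at least 2 samples")
  }
  st <- sam_num_se(x, y)
  tibble(gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
         d = st$num / (st$s + s0), s = st$s, mean_diff = st$num)
}

# numerator (poor - good mean difference) and pooled SE per gene row
sam_num_se <- function(x, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  m1 <- rowMeans(x[, y == 1L, drop = FALSE])
  m0 <- rowMeans(x[, y == 0L, drop = FALSE])
  ss1 <- rowSums((x[, y == 1L, drop = FALSE] - m1)^2)
  ss0 <- rowSums((x[, y == 0L, drop = FALSE] - m0)^2)
  s <- sqrt((1 / n1 + 1 / n0) * (ss1 + ss0) / (n1 + n0 - 2))
  list(num = m1 - m0, s = s)
}

#' Choose the SAM fudge factor s0
#'
#' Searches the percentiles 0, 5, ..., 100 of the per-gene standard errors
#' and picks the candidate minimizing the coefficient of variation of the
#' median absolute d statistic across standard-error quantile bins, so the
#' d statistic's spread is made as independent of the gene's variance as
#' possible. Deterministic given its inputs.
#'
#' @param num Per-gene mean differences (d numerators).
#' @param s Per-gene pooled standard errors (`>= 20` genes).
#' @return The chosen `s0 >= 0`.
#' @export
choose_s0 <- function(num, s) {
  if (length(s) < 20L) abort("need at least 20 genes for stable s0 selection")
  if (max(s) - min(s) < 1e-12) return(0)
  cands <- unique(quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE))
  n_bins <- max(2L, min(100L, length(s) %/% 10L))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv_of <- function(s0) {
    d <- num / (s + s0)
    mads <- vapply(split(abs(d), bins), median, numeric(1))
    if (mean(mads) == 0) return(Inf)
    sd(mads) / mean(mads)
  }
  cvs <- vapply(cands, cv_of, numeric(1))
  cands[which.min(cvs)]
}

#' SAM differential expression with permutation q-values
#'
#' Computes moderated d statistics on the observed labels, fixes `s0` from
#' the observed data, rebuilds the null by permuting the outcome labels
#' `n_perm` times (exact enumeration when fewer distinct permutations
#' exist), and assigns each gene an FDR-style q-value: the median number of
#' null |d| values at or above that gene's |d|, divided by the observed
#' count at or above it, clipped to `[0, 1]` and monotonized so q never
#' increases with |d|. Genes with `q < threshold` are called differentially
#' expressed.
#'
#' @param expr Expression tibble (standardized) or genes x samples matrix.
#' @param phenotypes Phenotype tibble with 0/1 `outcome` (or a 0/1 vector
#'   when `expr` is a matrix).
#' @param n_perm Number of label permutations (default 1000, minimum 100).
#' @param threshold q-value call threshold (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return A `sam_result` tibble — `gene_id`, `d`, `s`, `q`, `direction`
#'   (`up` = elevated in the poor group), `called` — ordered calls-first by
#'   decreasing |d|, with attributes `s0`, `n_perm`, `threshold`.
#' @export
sam <- function(expr, phenotypes, n_perm = 1000L, threshold = 0.05,
                seed = 1L) {
  if (is.data.frame(expr)) {
    x <- expr_matrix(expr)
    y <- as.integer(phenotypes$outcome)
    x <- x[, phenotypes$sample_id, drop = FALSE]
  } else {
    x <- as.matrix(expr)
    y <- as.integer(phenotypes)
  }
  n <- length(y)
  n1 <- sum(y == 1L)
  if (n_perm < 100L) abort("n_perm must be >= 100")
  n_distinct_perm <- choose(n, n1)
  exact <- is.finite(n_distinct_perm) && n_distinct_perm <= n_perm
  if (exact) {
    inform(sprintf(
      "only %d distinct label permutations; using exact enumeration",
      n_distinct_perm))
    perms <- utils::combn(n, n1)
    ymat <- matrix(0L, n, ncol(perms))
    for (b in seq_len(ncol(perms))) ymat[perms[, b], b] <- 1L
  } else {
    ymat <- with_stage_seed(seed, "sam_perm",
                            replicate(n_perm, sample(y)))
  }

  obs <- sam_d_statistics(x, y, s0 = 0)
  st <- sam_num_se(x, y)
  s0 <- choose_s0(st$num, st$s)
  d_obs <- st$num / (st$s + s0)

  # all-permutation d statistics via matrix products (counts are preserved
  # by permutation, so the group sizes are constants)
  n0 <- n - n1
  x2 <- x^2
  sum1 <- x %*% ymat
  sum0 <- rowSums(x) - sum1
  m1 <- sum1 / n1
  m0 <- sum0 / n0
  sq1 <- x2 %*% ymat
  sq0 <- rowSums(x2) - sq1
  ss <- (sq1 - n1 * m1^2) + (sq0 - n0 * m0^2)
  s_perm <- sqrt((1 / n1 + 1 / n0) * ss / (n - 2))
  d_perm <- (m1 - m0) / (s_perm + s0)

  abs_obs <- abs(d_obs)
  obs_count <- vapply(abs_obs, function(v) sum(abs_obs >= v), numeric(1))
  null_counts <- apply(abs(d_perm), 2, function(col) {
    sc <- sort(col)
    length(sc) - findInterval(abs_obs, sc, left.open = TRUE)
  })
  med_null <- apply(matrix(null_counts, nrow = length(abs_obs)), 1, median)
  q <- pmin(1, med_null / obs_count)

  # monotonize: a larger |d| must never have a larger q
  ord <- order(-abs_obs)
  q[ord] <- cummax(q[ord])

  out <- tibble(
    gene_id = obs$gene_id,
    d = d_obs, s = st$s, q = q,
    direction = ifelse(st$num > 0, "up", "down"),
    called = q < threshold
  ) %>%
    arrange(desc(.data$called), desc(abs(.data$d)))
  attr(out, "s0") <- s0
  attr(out, "n_perm") <- ncol(ymat)
  attr(out, "threshold") <- threshold
  class(out) <- c("sam_result", class(out))
  out
}

#' @method print sam_result
#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf(
    "SAM differential expression: %d/%d genes called at q < %g (s0 = %.4g, %d permutations); %d up, %d down among calls\n",
    sum(x$called), nrow(x), attr(x, "threshold"), attr(x, "s0"),
    attr(x, "n_perm"), sum(x$called & x$direction == "up"),
    sum(x$called & x$direction == "down")))
  NextMethod()
}

#' Plot SAM observed-vs-expected d statistics
#'
#' @param object A `sam_result`.
#' @param ... Unused.
#' @return A ggplot of the ranked |d| values colored by call status.
#' @export
autoplot.sam_result <- function(object, ...) {
  df <- object %>%
    arrange(desc(abs(.data$d))) %>%
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, abs(.data$d),
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Rank by |d|", y = "|d|",
                  title = "SAM moderated statistics") +
    ggplot2::theme_minimal()
}
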