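#' Pooled two-sample t statistic from group summaries
#'
#' The pooled-variance two-sample t test computed from per-group mean, SD
#' and n (the form used for baseline-characteristics tables):
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2))`, df = `n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 First group summary (`sd1 > 0`, `n1 >= 2`).
#' @param mean2,sd2,n2 Second group summary.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided).
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) abort("group SDs must be > 0")
  if (n1 < 2 || n2 < 2) abort("group sizes must be >= 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  t_stat <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble(t = t_stat, df = as.integer(df), p = 2 * pt(-abs(t_stat), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square,
#' `sum((O - E)^2 / E)` with expected counts from the marginal products.
#'
#' @param counts 2x2 matrix of non-negative integer counts with all
#'   marginals positive.
#' @return A one-row tibble: `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) abort("counts must be a 2x2 matrix")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("a zero marginal makes the chi-square undefined")
  }
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - e)^2 / e)
  tibble(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Descriptive-statistics table from printed group summaries
#'
#' Recomputes the test-statistic column of a baseline-characteristics table
#' from per-row group summaries: continuous rows (`type = "continuous"`,
#' columns mean1/sd1/n1/mean2/sd2/n2) get the pooled t; categorical rows
#' (`type = "categorical"`, columns a/b/c/d as the 2x2 cell counts) get the
#' uncorrected Pearson chi-square.
#'
#' @param summaries Data frame with columns `characteristic`, `type`, and
#'   the per-type summary columns described above.
#' @return A tibble: `characteristic`, `statistic` (t or chi2), `df`, `p`.
#' @export
table_one <- function(summaries) {
  stopifnot(all(c("characteristic", "type") %in% names(summaries)))
  purrr::pmap(summaries, function(characteristic, type, ...) {
    v <- list(...)
    if (type == "continuous") {
      res <- pooled_t(v$mean1, v$sd1, v$n1, v$mean2, v$sd2, v$n2)
      tibble(characteristic = characteristic, statistic = res$t,
             df = res$df, p = res$p)
    } else if (type == "categorical") {
      res <- chi2_2x2(matrix(c(v$a, v$c, v$b, v$d), 2))
      tibble(characteristic = characteristic, statistic = res$chi2,
             df = res$df, p = res$p)
    } else {
      abort(paste0("unknown row type: ", type))
    }
  }) %>% list_rbind()
}
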