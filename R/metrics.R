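#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, with ties counted one half (midranks).
#'
#' @param y_true 0/1 truth (1 = poor outcome).
#' @param scores Continuous scores, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

mcc_counts <- function(tp, fp, tn, fn) {
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Confusion-matrix and ranking metrics for one prediction
#'
#' Computes the eight benchmarking metrics with the poor outcome as the
#' positive class: sensitivity, specificity, AUC, accuracy, Youden index
#' (`Se + Sp - 1`), F-measure (positive class), Matthews correlation
#' coefficient, and G-means (`sqrt(Se * Sp)`). MCC is 0 when a confusion
#' marginal is empty; F is 0 when precision and sensitivity are both 0.
#'
#' @param y_true 0/1 truth.
#' @param labels 0/1 predicted labels.
#' @param scores Continuous scores for AUC (default `labels`).
#' @return A one-row tibble: `se, sp, auc, acc, youden, f_measure, mcc,
#'   g_means`.
#' @export
confusion_metrics <- function(y_true, labels, scores = labels) {
  y_true <- as.integer(y_true)
  labels <- as.integer(labels)
  if (length(unique(y_true)) < 2L) abort("y_true must contain both classes")
  tp <- sum(y_true == 1L & labels == 1L)
  fp <- sum(y_true == 0L & labels == 1L)
  tn <- sum(y_true == 0L & labels == 0L)
  fn <- sum(y_true == 1L & labels == 0L)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / length(y_true)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f <- if (prec + se == 0) 0 else 2 * prec * se / (prec + se)
  tibble(
    se = se, sp = sp,
    auc = auc_rank(y_true, scores),
    acc = acc,
    youden = se + sp - 1,
    f_measure = f,
    mcc = mcc_counts(tp, fp, tn, fn),
    g_means = sqrt(se * sp)
  )
}

#' Stratified train/test split indices
#'
#' Splits `1..n` into a training part of total size `ceiling(fraction * n)`
#' and the remaining test part, stratifying by outcome so each class is
#' split as close to the ratio as rounding allows (largest-remainder
#' allocation). For n = 149 at 80:20 this yields 120 training and 29 test
#' samples.
#'
#' @param y 0/1 outcome vector (length n >= 5).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param stratify Stratify by class (default `TRUE`); plain splitting
#'   otherwise.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_indices <- function(y, train_fraction = 0.8, stratify = TRUE) {
  n <- length(y)
  if (n < 5) abort("need at least 5 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  target <- as.integer(ceiling(train_fraction * n))
  if (!stratify) {
    tr <- sort(sample.int(n, target))
    return(list(train = tr, test = setdiff(seq_len(n), tr)))
  }
  y <- as.integer(y)
  if (min(table(y)) < 2) abort("each class needs at least 2 members to split")
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(c) sum(y == c), integer(1))
  base <- floor(train_fraction * sizes)
  rem <- train_fraction * sizes - base
  extra <- target - sum(base)
  if (extra > 0) {
    give <- order(-rem)[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  tr <- unlist(lapply(seq_along(classes), function(i) {
    idx <- which(y == classes[i])
    sample(idx, base[i])
  }))
  tr <- sort(tr)
  list(train = tr, test = setdiff(seq_len(n), tr))
}
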