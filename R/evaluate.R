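#' Repeated stratified-holdout benchmarking of the classifier panel
#'
#' The cohort is repeatedly partitioned into 80:20 training/test sets
#' (stratified by outcome); on every repeat each requested model is fitted
#' on the training part and scored on the held-out part, and the eight
#' metrics of [confusion_metrics()] are recorded. The GA-KPLS model
#' re-optimizes its bandwidth within every training split. Summary rows are
#' arithmetic means over repeats; per-repeat AUC values are retained for the
#' Dunnett comparison.
#'
#' @param x Samples x features matrix (screened, standardized).
#' @param y 0/1 outcome (1 = poor).
#' @param models Character vector among `"ga_kpls"`, `"lasso"`, `"ridge"`,
#'   `"svm"`, `"rf"`, `"logit"`.
#' @param n_repeats Number of random splits (default 1000).
#' @param train_fraction Training fraction (default 0.8).
#' @param stratify Stratify splits by outcome (default `TRUE`).
#' @param n_components KPLS component count (default 3).
#' @param ga A [ga_config()] for the per-repeat bandwidth search.
#' @param baselines A [baseline_config()].
#' @param screen_within_split Optional integer `d`: re-run sure independence
#'   screening (|t| utility) inside every training split, keeping the top
#'   `d` features there, for a leakage-free protocol; default `NULL` uses
#'   `x` as given (screened once up front).
#' @param seed Master seed; every repeat derives its own child seed.
#' @return An object of class `repeat_table`: `metrics` (per repeat x
#'   model), `summary` (per-model means in the conventional column order)
#'   and `auc` (per-repeat AUC, long format).
#' @export
repeated_evaluation <- function(x, y,
                                models = c("ga_kpls", "lasso", "ridge",
                                           "svm", "rf", "logit"),
                                n_repeats = 1000L, train_fraction = 0.8,
                                stratify = TRUE, n_components = 3L,
                                ga = ga_config(), baselines = baseline_config(),
                                screen_within_split = NULL, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  if (n_repeats < 1L) abort("n_repeats must be >= 1")
  x <- as.matrix(x)
  y <- as.integer(y)
  rows <- vector("list", n_repeats * length(models))
  k <- 0L
  for (r in seq_len(n_repeats)) {
    rseed <- stage_seed(seed, paste0("repeat_", r))
    sp <- with_stage_seed(rseed, "split", {
      fails <- 0L
      repeat {
        s <- split_indices(y, train_fraction, stratify = stratify)
        if (length(unique(y[s$test])) == 2L &&
            length(unique(y[s$train])) == 2L) break
        fails <- fails + 1L
        if (fails > 100L) abort("over 100 consecutive degenerate splits")
        inform("degenerate split (single-class part); resplitting")
      }
      s
    })
    xtr <- x[sp$train, , drop = FALSE]
    xte <- x[sp$test, , drop = FALSE]
    ytr <- y[sp$train]
    yte <- y[sp$test]
    if (!is.null(screen_within_split)) {
      tt <- abs(two_sample_t(xtr, ytr))
      keep <- order(-tt, seq_along(tt))[seq_len(min(screen_within_split,
                                                    ncol(xtr)))]
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    for (m in models) {
      pred <- fit_one_model(m, xtr, ytr, xte, n_components, ga, baselines,
                            rseed)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(
        tibble(repeat_id = r, model = m),
        confusion_metrics(yte, pred$label, pred$score)
      )
    }
  }
  metrics <- list_rbind(rows)
  metric_cols <- c("se", "sp", "auc", "acc", "youden", "f_measure", "mcc",
                   "g_means")
  summary <- metrics %>%
    group_by(.data$model) %>%
    summarise(across(all_of(metric_cols), mean), .groups = "drop") %>%
    mutate(model = factor(.data$model, levels = models)) %>%
    arrange(.data$model) %>%
    mutate(model = as.character(.data$model))
  structure(list(
    metrics = metrics, summary = summary,
    auc = metrics %>% select("repeat_id", "model", "auc"),
    models = models, n_repeats = n_repeats
  ), class = "repeat_table")
}

fit_one_model <- function(m, xtr, ytr, xte, n_components, ga, baselines,
                          rseed) {
  if (m == "ga_kpls") {
    gcfg <- ga
    gcfg$seed <- stage_seed(rseed, "ga_seed")
    res <- optimize_sigma(xtr, ytr, n_components = n_components, config = gcfg)
    fit <- kpls(xtr, ytr, sigma = res$best_sigma, n_components = n_components)
    predict(fit, xte)
  } else {
    bcfg <- baselines
    bcfg$seed <- stage_seed(rseed, "baseline_seed")
    fit_predict_baseline(m, xtr, ytr, xte, bcfg)
  }
}

#' @method print repeat_table
#' @export
print.repeat_table <- function(x, ...) {
  cat(sprintf("Repeated-holdout benchmark: %d repeats x %d model(s)\n",
              x$n_repeats, length(x$models)))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' @export
tidy.repeat_table <- function(x, ...) x$metrics

#' @export
glance.repeat_table <- function(x, ...) x$summary

#' Boxplot of per-repeat AUC by model
#'
#' @param object A `repeat_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeat_table <- function(object, ...) {
  ggplot2::ggplot(object$auc,
                  ggplot2::aes(factor(.data$model, levels = object$models),
                               .data$auc)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = "Held-out AUC over repeated 80:20 splits") +
    ggplot2::theme_minimal()
}

#' ANOVA plus Dunnett many-to-one comparison of per-repeat AUC
#'
#' One-way ANOVA of AUC on model, followed by Dunnett's multiple-comparison
#' test of every model against the control (single-step adjustment under
#' the equicorrelated multivariate-t reference distribution, seeded so the
#' quantile integration is reproducible).
#'
#' @param auc Long tibble with columns `model` and `auc` (e.g. the `auc`
#'   element of a `repeat_table`).
#' @param control Control model name (default `"ga_kpls"`).
#' @param seed Seed for the multivariate-t integration.
#' @return A tibble with one row per non-control model: `model`,
#'   `estimate` (mean AUC difference vs control), `p_adj`, `significant`
#'   (at 0.05); the ANOVA F statistic and p-value are attached as
#'   attributes `anova_f` and `anova_p`.
#' @export
dunnett_compare <- function(auc, control = "ga_kpls", seed = 1L) {
  if (!control %in% auc$model) abort(paste0("control model absent: ", control))
  if (dplyr::n_distinct(auc$model) < 2L) abort("need at least 2 models")
  df <- data.frame(
    auc = auc$auc,
    model = stats::relevel(factor(auc$model), ref = control)
  )
  if (min(table(df$model)) < 3L) abort("need at least 3 repeats per model")
  fit <- aov(auc ~ model, data = df)
  an <- summary(fit)[[1]]
  with_stage_seed(seed, "dunnett", {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(model = "Dunnett"))
    sm <- summary(gl)
  })
  out <- tibble(
    model = sub(paste0(" - ", control, "$"), "", names(sm$test$coefficients)),
    estimate = as.numeric(sm$test$coefficients),
    p_adj = as.numeric(sm$test$pvalues)
  ) %>%
    mutate(significant = .data$p_adj < 0.05)
  attr(out, "anova_f") <- an[["F value"]][1]
  attr(out, "anova_p") <- an[["Pr(>F)"]][1]
  out
}
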