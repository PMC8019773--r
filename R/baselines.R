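#' Baseline-classifier configuration
#'
#' Tuning contracts for the five comparison classifiers: penalized logistic
#' LASSO and ridge with lambda chosen by 10-fold cross-validation over a
#' 100-value log-spaced grid (four decades below lambda_max); RBF-kernel SVM
#' at library defaults (`gamma = 1/p`); random forest with 500 trees and
#' `mtry = floor(sqrt(p))`; unpenalized logistic regression with a
#' negligible-ridge fallback (lambda = 1e-8) when separation prevents
#' convergence.
#'
#' @param lambda_grid_size Lambda grid length for LASSO/ridge (default 100).
#' @param cv_folds Cross-validation folds for lambda (default 10).
#' @param rf_n_trees Random-forest tree count (default 500).
#' @param lambda Optional explicit lambda grid overriding the automatic one.
#' @param seed Integer seed (folds, bootstrap, SVM internals).
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(lambda_grid_size = 100L, cv_folds = 10L,
                            rf_n_trees = 500L, lambda = NULL, seed = 1L) {
  stopifnot(lambda_grid_size >= 2 || !is.null(lambda), cv_folds >= 3)
  structure(list(
    lambda_grid_size = as.integer(lambda_grid_size),
    cv_folds = as.integer(cv_folds), rf_n_trees = as.integer(rf_n_trees),
    lambda = lambda, seed = as.integer(seed)
  ), class = "baseline_config")
}

#' Fit a baseline classifier and score a test set
#'
#' @param method One of `"lasso"`, `"ridge"`, `"svm"`, `"rf"`, `"logit"`.
#' @param x_train,x_test Samples x features matrices.
#' @param y_train 0/1 training outcome (both classes required).
#' @param config A [baseline_config()].
#' @return A tibble with continuous `score` (probability or vote fraction
#'   for the poor class) and 0/1 `label` (thresholded at 0.5).
#' @export
fit_predict_baseline <- function(method, x_train, y_train, x_test,
                                 config = baseline_config()) {
  method <- match.arg(method, c("lasso", "ridge", "svm", "rf", "logit"))
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  y_train <- as.integer(y_train)
  if (length(unique(y_train)) < 2L) abort("y_train must contain both classes")
  with_stage_seed(config$seed, paste0("baseline_", method), {
    switch(method,
      lasso = glmnet_baseline(x_train, y_train, x_test, config, alpha = 1),
      ridge = glmnet_baseline(x_train, y_train, x_test, config, alpha = 0),
      svm = svm_baseline(x_train, y_train, x_test),
      rf = rf_baseline(x_train, y_train, x_test, config),
      logit = logit_baseline(x_train, y_train, x_test)
    )
  })
}

glmnet_baseline <- function(x_train, y_train, x_test, config, alpha) {
  lam <- config$lambda %||%
    lambda_grid(x_train, y_train, alpha, config$lambda_grid_size)
  if (length(lam) == 1L) {
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                          alpha = alpha, lambda = lam)
    score <- as.numeric(predict(fit, x_test, type = "response", s = lam))
  } else {
    foldid <- stratified_folds(y_train, config$cv_folds)
    cv <- glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                            alpha = alpha, lambda = lam, foldid = foldid,
                            type.measure = "deviance")
    score <- as.numeric(predict(cv, x_test, type = "response",
                                s = "lambda.min"))
  }
  tibble(score = score, label = as.integer(score >= 0.5))
}

# log-spaced grid from lambda_max (smallest lambda zeroing all LASSO
# coefficients on standardized features) down four decades; ridge reuses the
# LASSO lambda_max scaled up by the conventional factor of 1000
lambda_grid <- function(x, y, alpha, size) {
  n <- nrow(x)
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / n
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  if (alpha == 0) lmax <- lmax * 1000
  exp(seq(log(lmax), log(lmax) - 4 * log(10), length.out = size))
}

svm_baseline <- function(x_train, y_train, x_test) {
  fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                    kernel = "radial", probability = TRUE, scale = FALSE)
  pr <- predict(fit, x_test, probability = TRUE)
  score <- attr(pr, "probabilities")[, "1"]
  tibble(score = as.numeric(score), label = as.integer(score >= 0.5))
}

rf_baseline <- function(x_train, y_train, x_test, config) {
  fit <- randomForest::randomForest(
    x_train, factor(y_train, levels = c(0, 1)),
    ntree = config$rf_n_trees, mtry = max(1L, floor(sqrt(ncol(x_train)))))
  votes <- predict(fit, x_test, type = "prob")[, "1"]
  labels <- as.integer(as.character(predict(fit, x_test, type = "response")))
  tibble(score = as.numeric(votes), label = labels)
}

logit_baseline <- function(x_train, y_train, x_test) {
  df_tr <- as.data.frame(x_train)
  names(df_tr) <- paste0("V", seq_len(ncol(x_train)))
  df_tr$.y <- y_train
  df_te <- as.data.frame(x_test)
  names(df_te) <- paste0("V", seq_len(ncol(x_test)))
  score <- tryCatch({
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = df_tr, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) stop("logit did not converge")
    if (separated || any(fit$fitted.values < 1e-8) ||
        any(fit$fitted.values > 1 - 1e-8)) {
      stop("complete separation in logit")
    }
    suppressWarnings(as.numeric(predict(fit, df_te, type = "response")))
  }, error = function(e) {
    inform(paste0("logit fallback to negligible ridge (1e-8): ",
                  conditionMessage(e)))
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                          alpha = 0, lambda = 1e-8)
    as.numeric(predict(fit, x_test, type = "response", s = 1e-8))
  })
  tibble(score = score, label = as.integer(score >= 0.5))
}
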