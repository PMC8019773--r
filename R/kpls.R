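#' Gaussian (RBF) kernel matrix
#'
#' `K(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 sigma^2))` between the rows of
#' `a` and the rows of `b`.
#'
#' @param a m x p numeric matrix (rows are observations).
#' @param b k x p numeric matrix (defaults to `a`).
#' @param sigma Kernel bandwidth, `> 0`.
#' @return An m x k kernel matrix with entries in `(0, 1]`.
#' @export
gaussian_kernel <- function(a, b = a, sigma) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) abort("feature-count mismatch between a and b")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("sigma must be a positive scalar")
  }
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Center a training kernel matrix in feature space
#'
#' `Kc = (I - J/n) K (I - J/n)` with `J` the all-ones matrix, so that the
#' implicit feature vectors are mean-centered; every row and column of the
#' result sums to zero.
#'
#' @param k Symmetric n x n kernel matrix.
#' @return List with `kc` (centered kernel), `row_means` and `grand_mean`
#'   (training statistics needed to center test kernels consistently).
#' @export
center_train_kernel <- function(k) {
  if (nrow(k) != ncol(k)) abort("training kernel must be square")
  rm_ <- colMeans(k)
  gm <- mean(k)
  kc <- k - outer(rowMeans(k), rep(1, ncol(k))) -
    outer(rep(1, nrow(k)), rm_) + gm
  list(kc = kc, row_means = rm_, grand_mean = gm)
}

#' Center a test kernel with training statistics
#'
#' Applies the training-derived feature-space centering
#' `Kc_test = (K_test - 1 r')(I - J/n)` where `r` holds the training-kernel
#' row means; equivalently, subtracts test-row means and training-column
#' means and adds back the training grand mean.
#'
#' @param k_test m x n kernel between test and training points.
#' @param train_stats List with `row_means` and `grand_mean` from
#'   [center_train_kernel()].
#' @return Centered m x n test kernel.
#' @export
center_test_kernel <- function(k_test, train_stats) {
  r <- train_stats$row_means
  if (ncol(k_test) != length(r)) {
    abort("test kernel column count must equal the training sample count")
  }
  k_test - outer(rowMeans(k_test), rep(1, ncol(k_test))) -
    outer(rep(1, nrow(k_test)), r) + train_stats$grand_mean
}

#' Fit kernel PLS components on a centered kernel (low level)
#'
#' Dual NIPALS extraction for a univariate 0/1 response: per component,
#' the score `t` is the (normalized) image of the current response under the
#' deflated kernel; both the kernel (two-sided, `(I - t t') K (I - t t')`)
#' and the response are then deflated. Dual regression coefficients
#' `alpha = U (T' K U)^{-1} T' y` map a centered kernel row to a predicted
#' response.
#'
#' @param kc Centered n x n training kernel ([center_train_kernel()]).
#' @param y Numeric response coded 0/1 (centered internally).
#' @param n_components Number of components to extract (`<= n - 1`).
#' @param threshold Decision cut on the predicted response (default 0.5).
#' @return An object of class `kpls_fit` with dual coefficients, scores,
#'   the response mean and the decision threshold.
#' @export
fit_kpls <- function(kc, y, n_components = 3L, threshold = 0.5) {
  n <- length(y)
  if (nrow(kc) != n || ncol(kc) != n) abort("kernel/response size mismatch")
  if (var(y) == 0) abort("response has zero variance")
  if (n_components > n - 1L) abort("n_components must be <= n_train - 1")
  ybar <- mean(y)
  yc <- y - ybar
  kd <- kc
  yd <- yc
  tt <- matrix(0, n, 0)
  uu <- matrix(0, n, 0)
  for (a in seq_len(n_components)) {
    u <- yd / sqrt(sum(yd^2))
    t_a <- kd %*% u
    nt <- sqrt(sum(t_a^2))
    if (!is.finite(nt) || nt < 1e-10) {
      warn(sprintf("component %d has negligible score norm; stopping at %d components",
                   a, a - 1L))
      break
    }
    t_a <- t_a / nt
    tt <- cbind(tt, t_a)
    uu <- cbind(uu, u)
    proj <- diag(n) - tcrossprod(t_a)
    kd <- proj %*% kd %*% proj
    yd <- yd - t_a %*% crossprod(t_a, yd)
  }
  a_used <- ncol(tt)
  alpha <- if (a_used > 0) {
    uu %*% solve(crossprod(tt, kc %*% uu), crossprod(tt, yc))
  } else {
    matrix(0, n, 1)
  }
  fitted <- as.numeric(kc %*% alpha + ybar)
  structure(list(
    alpha = alpha, scores = tt, ybar = ybar, threshold = threshold,
    n_components = a_used, fitted = fitted,
    train_r2 = 1 - sum((y - fitted)^2) / sum(yc^2)
  ), class = "kpls_fit")
}

#' Predict from kernel PLS dual coefficients (low level)
#'
#' @param model A `kpls_fit` from [fit_kpls()].
#' @param kc_test Centered m x n test kernel ([center_test_kernel()]).
#' @return A tibble with continuous `score` (predicted response, used for
#'   AUC) and 0/1 `label` (`score >= threshold`).
#' @export
predict_kpls <- function(model, kc_test) {
  if (ncol(kc_test) != nrow(model$alpha)) {
    abort("test kernel column count must equal the training sample count")
  }
  score <- as.numeric(kc_test %*% model$alpha + model$ybar)
  tibble(score = score, label = as.integer(score >= model$threshold))
}

#' Gaussian-kernel PLS classifier
#'
#' User-facing wrapper: builds the Gaussian kernel on the training samples,
#' centers it in feature space, extracts `n_components` dual PLS components
#' against the 0/1 outcome and stores everything needed to score new
#' samples. `sigma` defaults to the median pairwise Euclidean distance of
#' the training rows (the median heuristic).
#'
#' @param x Samples x features matrix or data frame.
#' @param y 0/1 outcome (1 = poor outcome, the positive class).
#' @param sigma Gaussian bandwidth; default median pairwise distance.
#' @param n_components Number of PLS components (default 3).
#' @param threshold Decision threshold on the predicted response (default
#'   0.5 for 0/1 coding).
#' @return An object of class `kpls` with a [predict()] method.
#' @export
kpls <- function(x, y, sigma = NULL, n_components = 3L, threshold = 0.5) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(sigma)) sigma <- median_heuristic(x)
  k <- gaussian_kernel(x, sigma = sigma)
  cs <- center_train_kernel(k)
  fit <- fit_kpls(cs$kc, y, n_components = n_components, threshold = threshold)
  structure(list(
    fit = fit, x_train = x, sigma = sigma,
    train_stats = cs[c("row_means", "grand_mean")],
    y = y
  ), class = "kpls")
}

#' Median pairwise-distance bandwidth heuristic
#'
#' @param x Samples x features matrix.
#' @return Median Euclidean distance between distinct rows.
#' @export
median_heuristic <- function(x) {
  d <- as.numeric(dist(as.matrix(x)))
  m <- median(d)
  if (!is.finite(m) || m <= 0) abort("zero pairwise distances: degenerate data")
  m
}

#' @rdname kpls
#' @param object,newdata A fitted `kpls` model and a samples x features
#'   matrix of new observations (same feature order as training).
#' @param ... Unused.
#' @export
predict.kpls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  k_test <- gaussian_kernel(newdata, object$x_train, object$sigma)
  kc_test <- center_test_kernel(k_test, object$train_stats)
  predict_kpls(object$fit, kc_test)
}

#' @method print kpls
#' @export
print.kpls <- function(x, ...) {
  cat(sprintf(
    "Gaussian-kernel PLS classifier: %d training samples, sigma = %.4g, %d component(s), training R^2 = %.3f\n",
    nrow(x$x_train), x$sigma, x$fit$n_components, x$fit$train_r2))
  invisible(x)
}

#' @export
tidy.kpls <- function(x, ...) {
  tt <- x$fit$scores
  if (ncol(tt) == 0) return(tibble(component = integer(), ss_scores = double()))
  tibble(component = seq_len(ncol(tt)),
         ss_scores = colSums(tt^2))
}

#' @export
glance.kpls <- function(x, ...) {
  tibble(sigma = x$sigma, n_components = x$fit$n_components,
         threshold = x$fit$threshold, train_r2 = x$fit$train_r2,
         n_train = nrow(x$x_train))
}
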