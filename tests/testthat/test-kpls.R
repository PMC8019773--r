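test_that("gaussian kernel matches its closed form and limits", {
  x <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  expect_equal(gaussian_kernel(x, sigma = 1)[1, 1], 1)
  # squared distance 2 equals 2 sigma^2 at sigma = 1 -> exp(-1)
  expect_equal(gaussian_kernel(x, sigma = 1)[1, 2], exp(-1), tolerance = 1e-12)
  set.seed(1)
  b <- matrix(runif(20), 5)
  expect_true(all(abs(gaussian_kernel(b, sigma = 1e8) - 1) < 1e-6))
  k <- gaussian_kernel(b, sigma = 0.7)
  expect_equal(k, t(k))
  expect_true(all(k > 0 & k <= 1))
  expect_error(gaussian_kernel(b, sigma = 0), "positive")
  expect_error(gaussian_kernel(b, matrix(1, 2, 5), sigma = 1), "mismatch")
})

test_that("kernel centering zeroes margins and fixes already-centered data", {
  expect_true(all(abs(center_train_kernel(matrix(1, 4, 4))$kc) < 1e-12))
  set.seed(2)
  a <- matrix(rnorm(36), 6)
  k <- a %*% t(a)
  kc <- center_train_kernel(k)$kc
  expect_true(all(abs(rowSums(kc)) < 1e-8))
  expect_true(all(abs(colSums(kc)) < 1e-8))
  # linear kernel of column-centered X is already centered
  xc <- scale(matrix(rnorm(40), 8), scale = FALSE)
  klin <- tcrossprod(xc)
  expect_equal(center_train_kernel(klin)$kc, klin, tolerance = 1e-10)
  expect_error(center_train_kernel(matrix(1, 2, 3)), "square")
})

test_that("test-kernel centering is consistent with training centering", {
  set.seed(3)
  x <- matrix(rnorm(50), 10)
  k <- gaussian_kernel(x, sigma = 2)
  cs <- center_train_kernel(k)
  # feeding training rows back through the test path reproduces Kc rows
  kc_test <- center_test_kernel(k, cs)
  expect_equal(kc_test, cs$kc, tolerance = 1e-10)
  # all-ones kernels center to zero; single-row shape is preserved
  ones <- center_train_kernel(matrix(1, 10, 10))
  expect_true(all(abs(center_test_kernel(matrix(1, 1, 10), ones)) < 1e-12))
  one_row <- center_test_kernel(k[1, , drop = FALSE], cs)
  expect_identical(dim(one_row), c(1L, 10L))
  expect_error(center_test_kernel(k[, 1:3], cs), "column count")
})

test_that("dual KPLS reproduces the independent Krylov projection oracle", {
  set.seed(4)
  for (case in 1:3) {
    n <- sample(15:30, 1)
    p <- sample(4:10, 1)
    x <- scale(matrix(rnorm(n * p), n), scale = FALSE)
    y <- rnorm(n)
    kc <- center_train_kernel(tcrossprod(x))$kc
    for (a in 1:3) {
      fit <- fit_kpls(kc, y, n_components = a)
      expect_equal(fit$fitted, krylov_fitted(kc, y, a), tolerance = 1e-6)
    }
  }
})

test_that("component scores are orthogonal and training R2 is monotone", {
  set.seed(5)
  x <- matrix(rnorm(25 * 6), 25)
  y <- as.numeric(rowSums(x[, 1:2]) > 0)
  kc <- center_train_kernel(gaussian_kernel(x, sigma = 2))$kc
  fit <- fit_kpls(kc, y, n_components = 5)
  g <- crossprod(fit$scores)
  expect_true(all(abs(g - diag(diag(g))) < 1e-8))
  r2 <- vapply(1:5, function(a) fit_kpls(kc, y, a)$train_r2, numeric(1))
  expect_true(all(diff(r2) > -1e-10))
  expect_error(fit_kpls(kc, rep(1, 25), 2), "zero variance")
  expect_error(fit_kpls(kc, y, 25), "n_train - 1")
})

test_that("zero components predict the training response mean", {
  set.seed(6)
  x <- matrix(rnorm(40), 10)
  y <- rep(c(0, 1), 5)
  kc <- center_train_kernel(gaussian_kernel(x, sigma = 1))$kc
  fit <- fit_kpls(kc, y, n_components = 0)
  expect_true(all(abs(fit$fitted - mean(y)) < 1e-12))
})

test_that("a separable two-cluster problem is solved with one component", {
  d <- make_clusters(n_per = 10, dist = 20, sd = 0.5)
  fit <- kpls(d$x, d$y, sigma = 2, n_components = 1)
  pr <- predict(fit, d$x)
  expect_identical(pr$label, d$y)
  # a point equidistant from both clusters scores near the decision midpoint
  mid <- matrix(10, 1, 2)
  expect_lt(abs(predict(fit, mid)$score - 0.5), 0.1)
  # an absurdly low threshold labels everything positive
  fit_lo <- kpls(d$x, d$y, sigma = 2, n_components = 1, threshold = -1e9)
  expect_true(all(predict(fit_lo, d$x)$label == 1L))
})

test_that("predictions are invariant to training sample permutation", {
  d <- make_ring(40, seed = 12)
  test_x <- make_ring(20, seed = 13)$x
  fit <- kpls(d$x, d$y, sigma = 1, n_components = 3)
  set.seed(14)
  perm <- sample(length(d$y))
  fit_p <- kpls(d$x[perm, ], d$y[perm], sigma = 1, n_components = 3)
  expect_equal(predict(fit, test_x)$score, predict(fit_p, test_x)$score,
               tolerance = 1e-8)
})

test_that("radial KPLS beats logistic regression on spherical boundaries", {
  aucs <- vapply(1:50, function(s) {
    co <- simulate_cohort(synth_config(
      n_samples = 400, n_genes = 8, n_de_genes = 0, signal = "nonlinear",
      seed = 500 + s))
    d <- cohort_xy(co)
    set.seed(s)
    sp <- split_indices(d$y, 0.8)
    fit <- kpls(d$x[sp$train, ], d$y[sp$train])
    a_k <- auc_rank(d$y[sp$test], predict(fit, d$x[sp$test, ])$score)
    pl <- fit_predict_baseline("logit", d$x[sp$train, ], d$y[sp$train],
                               d$x[sp$test, ])
    a_k - auc_rank(d$y[sp$test], pl$score)
  }, numeric(1))
  expect_lt(stats::wilcox.test(aucs, alternative = "greater")$p.value, 0.01)
})
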