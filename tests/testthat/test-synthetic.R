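test_that("cohort dimensions, outcome counts and determinism hold", {
  cfg <- synth_config(n_genes = 200, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(dim(co$expression), c(200L, 150L))
  expect_equal(nrow(co$phenotypes), 149L)
  expect_true(all(co$phenotypes$outcome %in% 0:1))
  expect_equal(nrow(co$truth$de_genes), 116L)
  expect_equal(sum(co$truth$de_genes$direction == "up"), round(116 * 70 / 116))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$expression, co2$expression)
  expect_identical(co$phenotypes, co2$phenotypes)
})

test_that("with no planted genes the two-sample t statistics are null", {
  co <- simulate_cohort(synth_config(
    n_samples = 149, n_genes = 2000, n_de_genes = 0, seed = 2))
  d <- cohort_xy(co)
  tt <- kplsrisk:::two_sample_t(d$x, d$y)
  tol <- 3 / sqrt(2000)
  expect_lt(abs(mean(tt)), tol)
  expect_lt(abs(var(tt) - 1), 3 * tol)
})

test_that("planted effect sizes are realized at the configured magnitude", {
  co <- simulate_cohort(synth_config(
    n_samples = 1000, prevalence_poor = 0.5, n_genes = 60, n_de_genes = 20,
    effect_size = 2, seed = 3))
  d <- cohort_xy(co)
  x1 <- d$x[d$y == 1, , drop = FALSE]
  x0 <- d$x[d$y == 0, , drop = FALSE]
  smd <- (colMeans(x1) - colMeans(x0)) /
    sqrt((apply(x1, 2, var) + apply(x0, 2, var)) / 2)
  truth <- co$truth$de_genes
  signed <- ifelse(truth$direction == "up", 2, -2)
  expect_true(all(abs(smd[truth$gene_id] - signed) < 0.2))
})

test_that("permuting outcomes destroys the planted signal", {
  co <- simulate_cohort(synth_config(
    n_samples = 200, n_genes = 300, n_de_genes = 50, effect_size = 1.5,
    seed = 4))
  d <- cohort_xy(co)
  planted <- co$truth$de_genes$gene_id
  t_obs <- abs(kplsrisk:::two_sample_t(d$x, d$y))
  set.seed(11)
  t_perm <- abs(kplsrisk:::two_sample_t(d$x, sample(d$y)))
  expect_gt(mean(t_obs[planted]), 4)          # strong under true labels
  expect_lt(mean(t_perm[planted]), 2)         # null-like after permutation
  expect_lt(max(t_perm[planted]), 5)
})

test_that("nonlinear cohorts defeat linear rules but not radial kernels", {
  co <- simulate_cohort(synth_config(
    n_samples = 400, n_genes = 10, n_de_genes = 0, signal = "nonlinear",
    seed = 5))
  d <- cohort_xy(co)
  set.seed(21)
  sp <- split_indices(d$y, 0.8)
  fit <- kpls(d$x[sp$train, ], d$y[sp$train])
  auc_k <- auc_rank(d$y[sp$test], predict(fit, d$x[sp$test, ])$score)
  pl <- fit_predict_baseline("logit", d$x[sp$train, ], d$y[sp$train],
                             d$x[sp$test, ])
  auc_l <- auc_rank(d$y[sp$test], pl$score)
  expect_gt(auc_k, auc_l + 0.15)
})

test_that("poor-outcome survival is stochastically shorter and censoring is calibrated", {
  co <- simulate_cohort(synth_config(
    n_samples = 2000, n_genes = 5, n_de_genes = 0, censor_rate = 0.25,
    seed = 6))
  ph <- co$phenotypes
  expect_lt(median(ph$time[ph$outcome == 1]), median(ph$time[ph$outcome == 0]))
  expect_lt(abs(mean(ph$event == 0) - 0.25), 0.05)
})

test_that("raw-intensity mode emits non-negative values recoverable by log2", {
  co <- simulate_cohort(synth_config(
    n_samples = 30, n_genes = 40, n_de_genes = 5, raw_intensities = TRUE,
    seed = 7))
  m <- as.matrix(co$expression[-1])
  expect_true(all(m >= 0))
  std <- log2_standardize(co$expression, transform = TRUE)
  sm <- as.matrix(std[-1])
  expect_true(all(abs(rowMeans(sm)) < 1e-10))
  expect_true(all(abs(apply(sm, 1, sd) - 1) < 1e-10))
})
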