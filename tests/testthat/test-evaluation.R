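test_that("confusion metrics match a hand-computed table", {
  # TP=3, FN=1, TN=5, FP=1
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  lab <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(y, lab)
  expect_equal(m$se, 0.75)
  expect_equal(m$sp, 5 / 6, tolerance = 1e-4)
  expect_equal(m$acc, 0.8)
  expect_equal(m$mcc, 14 / 24, tolerance = 1e-12)
  expect_equal(m$youden, m$se + m$sp - 1, tolerance = 1e-12)
  expect_equal(m$g_means, sqrt(m$se * m$sp), tolerance = 1e-12)

  perfect <- confusion_metrics(y, y, scores = y)
  expect_true(all(abs(unlist(perfect) - 1) < 1e-12))
  expect_error(confusion_metrics(rep(1, 5), rep(1, 5)), "both classes")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(1)
  for (i in 1:25) {
    y <- rbinom(40, 1, 0.3)
    if (length(unique(y)) < 2) next
    lab <- rbinom(40, 1, 0.5)
    sc <- runif(40)
    m <- confusion_metrics(y, lab, sc)
    expect_equal(m$youden, m$se + m$sp - 1, tolerance = 1e-12)
    expect_equal(m$g_means, sqrt(m$se * m$sp), tolerance = 1e-12)
    counts <- table(factor(y, 0:1), factor(lab, 0:1))
    expect_equal(m$acc, sum(diag(counts)) / sum(counts), tolerance = 1e-12)
  }
})

test_that("rank AUC equals exhaustive pair enumeration with tie midranks", {
  expect_equal(auc_rank(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auc_rank(c(1, 1, 0, 0), c(3, 2, 1, 0)), 1)
  expect_equal(auc_rank(c(1, 0, 1, 0), rep(1, 4)), 0.5)
  set.seed(2)
  y <- rbinom(30, 1, 0.4)
  s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # many ties
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                       ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(auc_rank(y, s), brute, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auc_rank(y, exp(3 * s)), auc_rank(y, s), tolerance = 1e-12)
  expect_error(auc_rank(rep(1, 4), 1:4), "both classes")
})

test_that("stratified 80:20 splits have the expected sizes and partition", {
  set.seed(3)
  y149 <- c(rep(1, 42), rep(0, 107))
  sp <- split_indices(y149, 0.8)
  expect_equal(length(sp$train), 120L)
  expect_equal(length(sp$test), 29L)
  expect_identical(sort(c(sp$train, sp$test)), 1:149)
  # class-wise allocation close to the ratio
  expect_equal(sum(y149[sp$train] == 1), 34L)
  sp10 <- split_indices(rep(0:1, 5), 0.8)
  expect_equal(c(length(sp10$train), length(sp10$test)), c(8L, 2L))
  expect_error(split_indices(c(1, rep(0, 9)), 0.8), "at least 2 members")
  expect_error(split_indices(rep(0:1, 5), 1.2), "train_fraction")
})

test_that("repeated evaluation reproduces and satisfies mean identities", {
  co <- make_tiny_cohort(seed = 20, n_genes = 15, n = 40, n_de = 5)
  d <- cohort_xy(co)
  ev <- suppressMessages(repeated_evaluation(
    d$x, d$y, models = c("ga_kpls", "logit"), n_repeats = 5,
    ga = quiet_ga(pop = 6, gens = 4, patience = 2), seed = 21))
  ev2 <- suppressMessages(repeated_evaluation(
    d$x, d$y, models = c("ga_kpls", "logit"), n_repeats = 5,
    ga = quiet_ga(pop = 6, gens = 4, patience = 2), seed = 21))
  expect_identical(ev$metrics, ev2$metrics)
  expect_equal(nrow(ev$metrics), 10L)
  sm <- ev$summary
  expect_equal(sm$youden, sm$se + sm$sp - 1, tolerance = 1e-12)
  expect_setequal(unique(ev$auc$model), c("ga_kpls", "logit"))
})

test_that("within-split screening keeps the protocol leakage-free but runs", {
  co <- simulate_cohort(synth_config(
    n_samples = 60, n_genes = 80, n_de_genes = 10, effect_size = 2,
    prevalence_poor = 0.4, seed = 22))
  d <- cohort_xy(co)
  ev <- suppressMessages(repeated_evaluation(
    d$x, d$y, models = "lasso", n_repeats = 3,
    screen_within_split = 20, seed = 23))
  expect_equal(nrow(ev$metrics), 3L)
  expect_true(all(ev$metrics$auc >= 0 & ev$metrics$auc <= 1))
})

test_that("Dunnett comparison reduces to the t test and orders sensibly", {
  set.seed(4)
  base <- rnorm(40, 0.8, 0.05)
  # identical AUC columns: F = 0, adjusted p = 1
  same <- tibble::tibble(
    model = rep(c("ga_kpls", "svm", "rf"), each = 40),
    auc = rep(base, 3))
  res0 <- dunnett_compare(same, "ga_kpls")
  expect_lt(attr(res0, "anova_f"), 1e-20)
  expect_true(all(res0$p_adj > 0.999))

  # two groups: Dunnett equals the pooled two-sample t test
  two <- tibble::tibble(
    model = rep(c("ga_kpls", "svm"), each = 40),
    auc = c(base, rnorm(40, 0.75, 0.05)))
  res2 <- dunnett_compare(two, "ga_kpls", seed = 5)
  tp <- t.test(auc ~ model, data = two, var.equal = TRUE)$p.value
  expect_equal(res2$p_adj, tp, tolerance = 0.005)

  # an absurdly shifted control is significant against everything,
  # and adjusted p-values never undercut the unadjusted t test
  three <- tibble::tibble(
    model = rep(c("ga_kpls", "svm", "rf"), each = 40),
    auc = c(base + 10 * 0.05 * 10, rnorm(40, 0.75, 0.05),
            rnorm(40, 0.7, 0.05)))
  res3 <- dunnett_compare(three, "ga_kpls", seed = 6)
  expect_true(all(res3$p_adj < 1e-6))
  for (m in c("svm", "rf")) {
    sub <- three[three$model %in% c("ga_kpls", m), ]
    praw <- t.test(auc ~ model, data = sub, var.equal = TRUE)$p.value
    expect_gte(res3$p_adj[res3$model == m] + 5e-4, praw)
  }
  expect_error(dunnett_compare(two, "nope"), "control model absent")
})
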