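test_that("SAM d statistics match the closed form on constructed data", {
  # one gene: group means 1 vs 0, both sample SDs exactly 1, n = 50 + 50
  mk <- function(n, mean, sd) {
    v <- scale(rnorm(n))          # exact mean 0, sd 1
    as.numeric(v * sd + mean)
  }
  set.seed(1)
  x <- matrix(c(mk(50, 1, 1), mk(50, 0, 1)), nrow = 1)
  y <- rep(c(1L, 0L), each = 50)
  res <- sam_d_statistics(x, y, s0 = 0)
  expect_equal(res$d, 1 / sqrt(2 / 50), tolerance = 1e-12)  # = 5
  expect_equal(res$d, 5, tolerance = 1e-12)

  # equal group means give d = 0; sign always tracks the mean difference
  x2 <- rbind(x, c(mk(50, 2, 1), mk(50, 2, 1)))
  res2 <- sam_d_statistics(x2, y)
  expect_equal(res2$d[2], 0, tolerance = 1e-12)
  set.seed(2)
  x3 <- matrix(rnorm(30 * 20), 30)
  res3 <- sam_d_statistics(x3, rep(0:1, 10))
  expect_true(all(sign(res3$d) == sign(res3$mean_diff) | res3$d == 0))
  expect_error(sam_d_statistics(x3, c(1L, rep(0L, 19))), "at least 2")
})

test_that("the fudge factor search is stable and degenerates to zero", {
  expect_equal(choose_s0(rnorm(30), rep(0.5, 30)), 0)
  set.seed(3)
  num <- rnorm(200)
  s <- runif(200, 0.1, 1)
  s0 <- choose_s0(num, s)
  expect_gte(s0, 0)
  expect_lte(s0, max(s))
  # homoscedastic null data: downstream calls are insensitive to s0 within
  # one percentile step of the search grid
  co <- simulate_cohort(synth_config(
    n_samples = 80, n_genes = 150, n_de_genes = 0, censor_rate = 0, seed = 4))
  x <- t(as.matrix(co$expression[-1]))
  st <- kplsrisk:::sam_num_se(t(x), co$phenotypes$outcome)
  s0_null <- choose_s0(st$num, st$s)
  for (shift in c(-0.05, 0.05)) {
    q <- quantile(st$s, max(0, min(1, ecdf(st$s)(s0_null) + shift)))
    d_alt <- st$num / (st$s + q)
    d_chosen <- st$num / (st$s + s0_null)
    expect_identical(order(-abs(d_alt))[1:10], order(-abs(d_chosen))[1:10])
  }
})

test_that("q-values are calibrated on pure-null cohorts", {
  fp <- vapply(1:20, function(s) {
    co <- simulate_cohort(synth_config(
      n_samples = 60, n_genes = 137, n_de_genes = 0, censor_rate = 0,
      seed = 1000 + s))
    x <- t(as.matrix(co$expression[-1]))
    rownames(x) <- colnames(co$expression)[-1]
    res <- sam(t(x), co$phenotypes$outcome, n_perm = 150, seed = s)
    mean(res$called)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
})

test_that("planted differential expression is recovered with directions", {
  co <- simulate_cohort(synth_config(
    n_samples = 149, n_genes = 137, n_de_genes = 116, effect_size = 1.5,
    seed = 11))
  res <- sam(co$expression, co$phenotypes, n_perm = 300, seed = 12)
  truth <- co$truth$de_genes
  called <- res$gene_id[res$called]
  expect_gte(mean(truth$gene_id %in% called), 0.8)
  joined <- merge(res[res$called, ], truth, by = "gene_id")
  expect_true(all(joined$direction.x == joined$direction.y))
  # determinism
  res2 <- sam(co$expression, co$phenotypes, n_perm = 300, seed = 12)
  expect_identical(res$q, res2$q)
})

test_that("q-values are proper, monotone in |d|, and vanish under permutation", {
  co <- simulate_cohort(synth_config(
    n_samples = 100, n_genes = 120, n_de_genes = 30, effect_size = 1.5,
    prevalence_poor = 0.4, seed = 13))
  res <- sam(co$expression, co$phenotypes, n_perm = 200, seed = 14)
  expect_true(all(res$q >= 0 & res$q <= 1))
  ord <- order(-abs(res$d))
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # tightening the threshold shrinks the call set
  strict <- sam(co$expression, co$phenotypes, n_perm = 200, threshold = 0.01,
                seed = 14)
  expect_lte(sum(strict$called), sum(res$called))
  expect_true(all(strict$gene_id[strict$called] %in% res$gene_id[res$called]))
  # permuting outcomes destroys the planted calls
  ph_perm <- co$phenotypes
  set.seed(15)
  ph_perm$outcome <- sample(ph_perm$outcome)
  res_perm <- sam(co$expression, ph_perm, n_perm = 200, seed = 16)
  expect_lte(sum(res_perm$called), 0.05 * nrow(res_perm) + 2)
})
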