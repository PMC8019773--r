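# Shared fixtures, all generated in code under fixed seeds.

# concentric-ring binary data: class 1 inside, class 0 on an outer ring;
# radially separable, never linearly separable
make_ring <- function(n = 60, seed = 7, r_in = 0.5, r_out = 2, sd = 0.1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  r <- ifelse(y == 1, r_in, r_out) + rnorm(n, 0, sd)
  th <- runif(n, 0, 2 * pi)
  list(x = cbind(r * cos(th), r * sin(th)), y = y)
}

# two well-separated Gaussian clusters (distance >> within-cluster spread)
make_clusters <- function(n_per = 10, seed = 3, dist = 20, sd = 0.5, p = 2) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per * p, 0, sd), n_per),
    matrix(rnorm(n_per * p, dist, sd), n_per)
  )
  list(x = x, y = rep(0:1, each = n_per))
}

# Independent oracle for PLS1 fitted values: the least-squares projection of
# the centered response onto the Krylov basis {K y, K^2 y, ..., K^a y}
# (PLS1 is conjugate gradients on the normal equations). Uses lm(), not the
# dual NIPALS path under test.
krylov_fitted <- function(kc, y, a) {
  yc <- y - mean(y)
  basis <- sapply(seq_len(a), function(i) {
    v <- yc
    for (j in seq_len(i)) v <- kc %*% v
    v
  })
  fit <- lm.fit(as.matrix(basis), yc)
  as.numeric(fit$fitted.values) + mean(y)
}

# small expression tibble + phenotype pair for IO-level tests
make_tiny_cohort <- function(seed = 1, n_genes = 30, n = 20, n_de = 5,
                             effect = 2) {
  simulate_cohort(synth_config(
    n_samples = n, n_genes = n_genes, n_de_genes = n_de,
    effect_size = effect, prevalence_poor = 0.4, censor_rate = 0.2,
    seed = seed
  ))
}

# matrix of samples x genes plus outcome, from a cohort
cohort_xy <- function(cohort) {
  x <- t(as.matrix(cohort$expression[-1]))
  colnames(x) <- cohort$expression$gene_id
  list(x = x[cohort$phenotypes$sample_id, , drop = FALSE],
       y = cohort$phenotypes$outcome)
}

quiet_ga <- function(seed = 1, pop = 10, gens = 15, patience = 5) {
  ga_config(population_size = pop, n_generations = gens, patience = patience,
            seed = seed)
}
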