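# kplsrisk

Survival risk stratification of clinical gene-expression cohorts with a
genetic-algorithm-tuned Gaussian-kernel partial least squares (GA-KPLS)
classifier.

## What this package does, and for whom

Clinicians and statisticians working with syndromes such as heart failure
with preserved ejection fraction (HFpEF) need to split patients into
good- and poor-outcome groups (e.g., 3-year survival) from expression
profiles, where the gene–outcome relationship may be nonlinear and the
feature count dwarfs the cohort size. `kplsrisk` provides the full
analysis as composable, pipe-friendly R functions:

- **Preprocessing & screening** — `log2(x+1)` transform, per-gene
  standardization, and sure independence screening keeping
  `d = floor(2n / log10 n)` genes (137 for n = 149) ranked by the
  absolute two-sample t statistic.
- **GA-KPLS classifier** — the Gaussian kernel
  `K(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 sigma^2))` with feature-space
  centering and dual NIPALS component extraction; the bandwidth `sigma` is
  tuned by a real-coded genetic algorithm whose fitness is
  cross-validated MCC.
- **Benchmark panel** — LASSO, ridge (penalized logistic, lambda by
  10-fold CV over a 100-value grid), RBF SVM, random forest, and plain
  logistic regression, evaluated over repeated stratified 80:20 holdouts
  (1,000 repeats by default) with Se, Sp, AUC, ACC, Youden, F-measure,
  MCC, G-means, and ANOVA + Dunnett comparison of per-repeat AUC.
- **Differential expression** — SAM moderated d statistics with a
  data-driven fudge factor `s0` and permutation FDR q-values (q < 0.05).
- **Survival** — Kaplan-Meier stratification of actual vs predicted risk
  groups with log-rank tests.
- **Synthetic cohorts** — `simulate_cohort()` generates expression,
  outcomes and censored survival with planted differential expression and
  an optional nonlinear (spherical) decision boundary, since the
  motivating cohort type is access-restricted.
- **Cohort statistics** — pooled two-sample t and uncorrected Pearson
  chi-square for baseline-characteristics tables computed from published
  group summaries.

## Worked example

```r
library(kplsrisk)

co <- simulate_cohort(synth_config(n_genes = 500, seed = 1))
co
#> Synthetic cohort: 500 genes x 149 samples; 37 poor / 112 good; 116 DE genes (linear signal)

std      <- log2_standardize(co$expression, transform = FALSE)
screened <- sis_screen(std, co$phenotypes)    # d = floor(2*149/log10 149) = 137
head(screened, 3)
#>    rank gene_id statistic
#> 1     1 G0100        8.39
#> 2     2 G0003        7.77
#> 3     3 G0023        7.72

x <- t(as.matrix(std[-1])); colnames(x) <- std$gene_id
x <- x[co$phenotypes$sample_id, screened$gene_id]
y <- co$phenotypes$outcome

set.seed(1)
sp <- split_indices(y, 0.8)                   # 120 train / 29 test
ga <- optimize_sigma(x[sp$train, ], y[sp$train],
                     config = ga_config(population_size = 10,
                                        n_generations = 15, patience = 5,
                                        seed = 1))
ga
#> GA bandwidth search: best sigma = 163.7 (fitness 1.0000, 34 evaluations, 5 generation(s))

fit  <- kpls(x[sp$train, ], y[sp$train], sigma = ga$best_sigma)
pred <- predict(fit, x[sp$test, ])
confusion_metrics(y[sp$test], pred$label, pred$score)
#>      se    sp   auc   acc youden f_measure   mcc g_means
#> 1     1     1     1     1      1         1     1       1

deg <- sam(co$expression[co$expression$gene_id %in% screened$gene_id, ],
           co$phenotypes, n_perm = 300, seed = 1)
deg
#> SAM differential expression: 136/137 genes called at q < 0.05
#> (s0 = 0.2028, 300 permutations); 79 up, 57 down among calls

km_stratify(co$phenotypes[sp$test, ], predicted = pred$label)
#> actual groups:    log-rank chi2 = 10.446, p = 0.00123
#> predicted groups: log-rank chi2 = 10.446, p = 0.00123
```

Reading the output: the planted signal (116 differentially expressed
genes at standardized effect 1.0) is strong enough that the screened
classifier separates the held-out samples perfectly, and the predicted
risk groups reproduce the survival separation of the true groups exactly.
Note the SAM call count (136 of 137) exceeds the 116 planted genes: the
screened set was *selected* for large |t|, so post-selection inference on
it is optimistic — the expected behavior when differential expression is
run downstream of screening. On unscreened cohorts the q-values are
calibrated (the test suite checks a false-call rate <= 0.05 under the
null).

`run_pipeline(pipeline_config(...))` sequences all of the above and
writes `metrics.csv`, `auc_by_repeat.csv`, `deg.tsv`, `km_logrank.json`,
`screened_genes.tsv` and a `run_log.txt` recording every resolved
parameter; the same configuration and master seed reproduce every output
byte-for-byte. A thin command-line wrapper lives at
`inst/scripts/kplsrisk-cli.R`.

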