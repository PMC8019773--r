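#' Pipeline configuration
#'
#' Assembles and validates the parameters of the full risk-stratification
#' pipeline: preprocessing and screening, the repeated-holdout protocol
#' (80:20, 1,000 repeats by default), the model panel, SAM differential
#' expression (q < 0.05) and Kaplan-Meier stratification. One master seed
#' deterministically spawns per-stage child seeds (keyed by stage name) so
#' any stage can be re-run in isolation.
#'
#' @param seed Master integer seed.
#' @param n_repeats Holdout repeats (default 1000, `>= 1`).
#' @param train_fraction Training fraction in (0, 1) (default 0.8).
#' @param models Model panel; any of `"ga_kpls"`, `"lasso"`, `"ridge"`,
#'   `"svm"`, `"rf"`, `"logit"` (unknown names are rejected).
#' @param sis_log_base 10 (default) or `exp(1)` in the screening-dimension
#'   rule `d = floor(2n / log(n))`.
#' @param q_threshold SAM call threshold (default 0.05).
#' @param n_perm SAM permutations (default 1000).
#' @param n_components KPLS components (default 3).
#' @param stratify Stratified splits (default `TRUE`).
#' @param screen_within_split Screen inside each training split instead of
#'   once up front (default `FALSE`).
#' @param raw_input Input expression is raw intensities needing log2(x+1)
#'   (default `FALSE`: already on the log/standardized scale).
#' @param ga A [ga_config()].
#' @param synth A [synth_config()] used when no input paths are given.
#' @param baselines A [baseline_config()].
#' @param expression_path,phenotype_path Optional input files (TSV/CSV); if
#'   `NULL` a synthetic cohort is generated.
#' @param out_dir Output directory (default `"kplsrisk-output"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_repeats = 1000L,
                            train_fraction = 0.8,
                            models = c("ga_kpls", "lasso", "ridge", "svm",
                                       "rf", "logit"),
                            sis_log_base = 10, q_threshold = 0.05,
                            n_perm = 1000L, n_components = 3L,
                            stratify = TRUE, screen_within_split = FALSE,
                            raw_input = FALSE, ga = ga_config(),
                            synth = synth_config(),
                            baselines = baseline_config(),
                            expression_path = NULL, phenotype_path = NULL,
                            out_dir = "kplsrisk-output") {
  known <- c("ga_kpls", "lasso", "ridge", "svm", "rf", "logit")
  bad <- setdiff(models, known)
  if (length(bad)) abort(paste0("unknown model name: ",
                                paste(bad, collapse = ", ")))
  if (n_repeats < 1L) abort("n_repeats must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort("q_threshold must be in (0, 1)")
  }
  if (!isTRUE(all.equal(sis_log_base, 10)) &&
      !isTRUE(all.equal(sis_log_base, exp(1)))) {
    abort("sis_log_base must be 10 or e")
  }
  structure(list(
    seed = as.integer(seed), n_repeats = as.integer(n_repeats),
    train_fraction = train_fraction, models = models,
    sis_log_base = sis_log_base, q_threshold = q_threshold,
    n_perm = as.integer(n_perm), n_components = as.integer(n_components),
    stratify = stratify, screen_within_split = screen_within_split,
    raw_input = raw_input, ga = ga, synth = synth, baselines = baselines,
    expression_path = expression_path, phenotype_path = phenotype_path,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' `ga`, `synth` and `baselines` blocks mirror [ga_config()],
#' [synth_config()] and [baseline_config()]. Unknown keys and unknown model
#' names are rejected at load time.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(args, fn, name) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) abort(paste0("unknown ", name, " key: ",
                                  paste(bad, collapse = ", ")))
    do.call(fn, args)
  }
  for (nm in intersect(c("ga", "synth", "baselines"), names(raw))) {
    fn <- switch(nm, ga = ga_config, synth = synth_config,
                 baselines = baseline_config)
    raw[[nm]] <- build(raw[[nm]], fn, nm)
  }
  build(raw, pipeline_config, "pipeline")
}

#' Run the full risk-stratification pipeline
#'
#' Sequences data loading (or synthesis), preprocessing and screening, the
#' repeated-holdout benchmark with the ANOVA + Dunnett comparison, SAM
#' differential expression on the screened genes, and Kaplan-Meier
#' stratification of actual versus predicted risk groups (predictions from
#' one 80:20 split). All stages derive their seeds from the master seed, so
#' a rerun with the same configuration reproduces every output exactly.
#'
#' Files written to `out_dir`: `metrics.csv` (per-model summary),
#' `auc_by_repeat.csv`, `deg.tsv`, `km_logrank.json`, `screened_genes.tsv`,
#' `ga_trace.csv` and `run_log.txt` (every resolved parameter).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `evaluation`, `comparison`, `deg`, `km`,
#'   `screen`, `cohort` and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- stage("data", {
    if (is.null(config$expression_path)) {
      sc <- config$synth
      sc$seed <- stage_seed(config$seed, "synth")
      simulate_cohort(sc)
    } else {
      expr <- read_expression(config$expression_path)
      ph <- read_phenotypes(config$phenotype_path, expr)
      list(expression = expr, phenotypes = ph, truth = NULL)
    }
  })

  std <- stage("preprocess", {
    log2_standardize(cohort$expression,
                     transform = config$raw_input ||
                       isTRUE(cohort$truth$config$raw_intensities))
  })

  n <- nrow(cohort$phenotypes)
  d <- sis_dimension(n, config$sis_log_base, max_genes = nrow(std))
  screen <- stage("screen", {
    sis_screen(std, cohort$phenotypes, d = d,
               log_base = config$sis_log_base)
  })
  x_all <- analysis_matrix(std, cohort$phenotypes)
  x_screened <- x_all[, screen$gene_id, drop = FALSE]
  y <- cohort$phenotypes$outcome

  evaluation <- stage("evaluate", {
    repeated_evaluation(
      if (config$screen_within_split) x_all else x_screened, y,
      models = config$models, n_repeats = config$n_repeats,
      train_fraction = config$train_fraction, stratify = config$stratify,
      n_components = config$n_components, ga = config$ga,
      baselines = config$baselines,
      screen_within_split = if (config$screen_within_split) d else NULL,
      seed = stage_seed(config$seed, "evaluate"))
  })

  comparison <- stage("compare", {
    if (length(config$models) >= 2 && config$n_repeats >= 3 &&
        "ga_kpls" %in% config$models) {
      dunnett_compare(evaluation$auc, control = "ga_kpls",
                      seed = stage_seed(config$seed, "dunnett"))
    } else NULL
  })

  deg <- stage("deg", {
    sam(as_expr_tbl(t(x_screened)), cohort$phenotypes,
        n_perm = config$n_perm, threshold = config$q_threshold,
        seed = stage_seed(config$seed, "sam"))
  })

  km <- stage("km", {
    sp <- with_stage_seed(config$seed, "km_split",
                          split_indices(y, config$train_fraction,
                                        config$stratify))
    gcfg <- config$ga
    gcfg$seed <- stage_seed(config$seed, "km_ga")
    res <- optimize_sigma(x_screened[sp$train, , drop = FALSE], y[sp$train],
                          n_components = config$n_components, config = gcfg)
    fit <- kpls(x_screened[sp$train, , drop = FALSE], y[sp$train],
                sigma = res$best_sigma, n_components = config$n_components)
    pred <- predict(fit, x_screened[sp$test, , drop = FALSE])
    km_stratify(cohort$phenotypes[sp$test, ], predicted = pred$label)
  })

  paths <- stage("write", {
    write_pipeline_outputs(config, cohort, screen, evaluation, comparison,
                           deg, km, d)
  })

  invisible(list(cohort = cohort, screen = screen, evaluation = evaluation,
                 comparison = comparison, deg = deg, km = km, paths = paths))
}

signif_cols <- function(df, digits = 6) {
  mutate(df, across(dplyr::where(is.numeric), ~ signif(.x, digits)))
}

write_pipeline_outputs <- function(config, cohort, screen, evaluation,
                                   comparison, deg, km, d) {
  out <- config$out_dir
  p <- list(
    metrics = file.path(out, "metrics.csv"),
    auc = file.path(out, "auc_by_repeat.csv"),
    deg = file.path(out, "deg.tsv"),
    km = file.path(out, "km_logrank.json"),
    screen = file.path(out, "screened_genes.tsv"),
    log = file.path(out, "run_log.txt")
  )
  readr::write_csv(signif_cols(evaluation$summary), p$metrics,
                   progress = FALSE)
  auc_wide <- tidyr::pivot_wider(evaluation$auc, names_from = "model",
                                 values_from = "auc")
  readr::write_csv(signif_cols(auc_wide), p$auc, progress = FALSE)
  readr::write_tsv(signif_cols(as_tibble(deg)), p$deg, progress = FALSE)
  readr::write_tsv(signif_cols(screen), p$screen, progress = FALSE)
  km_json <- list(
    tests = km$tests,
    curves = split(km$curves[c("group", "time", "survival")],
                   km$curves$panel),
    dunnett = if (!is.null(comparison)) {
      list(anova_f = attr(comparison, "anova_f"),
           anova_p = attr(comparison, "anova_p"),
           comparisons = comparison)
    } else NULL
  )
  jsonlite::write_json(km_json, p$km, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(
    paste0("kplsrisk run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("master seed: ", config$seed),
    paste0("screening dimension d: ", d),
    "resolved configuration:",
    utils::capture.output(utils::str(unclass(config), give.attr = FALSE))
  ), p$log)
  p
}
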