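#' Genetic-algorithm configuration for bandwidth tuning
#'
#' Controls [optimize_sigma()]. Chromosomes are real-valued base-10
#' logarithms of multipliers of the median pairwise distance of the training
#' rows, so the search range is scale-free.
#'
#' @param population_size Number of chromosomes (default 20).
#' @param n_generations Maximum generations (default 50).
#' @param sigma_log10_range Search interval on the log10-multiplier scale
#'   (default `c(-2, 3)`).
#' @param crossover_rate Probability a selected pair is blended (default 0.8).
#' @param mutation_rate Per-chromosome mutation probability (default 0.1).
#' @param mutation_sd Gaussian mutation SD on the log10 scale (default 0.25).
#' @param tournament_size Tournament selection size (default 2).
#' @param elitism Number of elites copied unchanged (default 1).
#' @param cv_folds Stratified cross-validation folds for the fitness
#'   (default 5).
#' @param fitness_metric `"mcc"` (default), `"accuracy"` or `"auc"`.
#' @param patience Stop after this many generations without best-fitness
#'   improvement (default 10).
#' @param seed Integer seed for the GA's own randomness.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 20L, n_generations = 50L,
                      sigma_log10_range = c(-2, 3), crossover_rate = 0.8,
                      mutation_rate = 0.1, mutation_sd = 0.25,
                      tournament_size = 2L, elitism = 1L, cv_folds = 5L,
                      fitness_metric = c("mcc", "accuracy", "auc"),
                      patience = 10L, seed = 1L) {
  fitness_metric <- match.arg(fitness_metric)
  stopifnot(population_size >= 2, n_generations >= 1, cv_folds >= 2,
            elitism < population_size, length(sigma_log10_range) == 2,
            sigma_log10_range[1] < sigma_log10_range[2])
  structure(list(
    population_size = as.integer(population_size),
    n_generations = as.integer(n_generations),
    sigma_log10_range = sigma_log10_range,
    crossover_rate = crossover_rate, mutation_rate = mutation_rate,
    mutation_sd = mutation_sd, tournament_size = as.integer(tournament_size),
    elitism = as.integer(elitism), cv_folds = as.integer(cv_folds),
    fitness_metric = fitness_metric, patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "ga_config")
}

# stratified fold assignment; every fold gets members of both classes
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# CV fitness of one bandwidth: mean metric over stratified folds. The full
# pairwise squared-distance matrix is precomputed once per optimize_sigma
# call, so each evaluation is just an exp() and the PLS algebra.
cv_fitness_fun <- function(x, y, folds, n_components, threshold, metric) {
  d2full <- as.matrix(dist(x))^2
  k_fold <- max(folds)
  function(sigma) {
    kfull <- exp(-d2full / (2 * sigma^2))
    vals <- vapply(seq_len(k_fold), function(f) {
      tr <- folds != f
      te <- !tr
      cs <- center_train_kernel(kfull[tr, tr, drop = FALSE])
      # extreme candidate bandwidths legitimately truncate the component
      # extraction; that is part of the fitness landscape, not a fault
      fit <- suppressWarnings(
        fit_kpls(cs$kc, y[tr], n_components = min(n_components, sum(tr) - 1L),
                 threshold = threshold))
      kc_te <- center_test_kernel(kfull[te, tr, drop = FALSE], cs)
      pr <- predict_kpls(fit, kc_te)
      metric_value(y[te], pr$label, pr$score, metric)
    }, numeric(1))
    mean(vals)
  }
}

metric_value <- function(y_true, labels, scores, metric) {
  switch(metric,
    mcc = mcc_counts(sum(y_true == 1 & labels == 1),
                     sum(y_true == 0 & labels == 1),
                     sum(y_true == 0 & labels == 0),
                     sum(y_true == 1 & labels == 0)),
    accuracy = mean(y_true == labels),
    auc = if (length(unique(y_true)) < 2) 0.5 else auc_rank(y_true, scores)
  )
}

#' Tune the Gaussian bandwidth with a genetic algorithm
#'
#' Real-valued GA over `log10` multipliers of the median pairwise distance:
#' tournament selection, arithmetic (blend) crossover, Gaussian mutation on
#' the log scale with clipping into the search range, and elitism. Fitness
#' of a chromosome is the mean cross-validated classification metric
#' (default MCC) of a KPLS fit at that bandwidth over stratified folds; the
#' fold assignment is fixed once per call so fitness is a deterministic
#' function of the chromosome.
#'
#' @param x Samples x features training matrix.
#' @param y 0/1 training outcome.
#' @param n_components,threshold KPLS settings (see [kpls()]).
#' @param config A [ga_config()].
#' @return An object of class `ga_result`: `best_sigma` (original scale),
#'   `best_fitness`, per-generation `history` tibble (best, mean), and the
#'   number of distinct fitness `evaluations`.
#' @export
optimize_sigma <- function(x, y, n_components = 3L, threshold = 0.5,
                           config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  med <- median_heuristic(x)
  lo <- config$sigma_log10_range[1]
  hi <- config$sigma_log10_range[2]
  with_stage_seed(config$seed, "ga", {
    folds <- stratified_folds(y, config$cv_folds)
    fitness <- cv_fitness_fun(x, y, folds, n_components, threshold,
                              config$fitness_metric)
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    eval_chrom <- function(g) {
      key <- sprintf("%.12g", g)
      if (!is.null(cache[[key]])) return(cache[[key]])
      n_eval <<- n_eval + 1L
      val <- fitness(med * 10^g)
      cache[[key]] <- val
      val
    }
    pop <- runif(config$population_size, lo, hi)
    fit <- vapply(pop, eval_chrom, numeric(1))
    history <- tibble(generation = integer(), best = double(), mean = double())
    best_g <- pop[which.max(fit)]
    best_f <- max(fit)
    stall <- 0L
    for (gen in seq_len(config$n_generations)) {
      ord <- order(-fit)
      elites <- pop[ord][seq_len(config$elitism)]
      children <- numeric(0)
      while (length(children) < config$population_size - config$elitism) {
        p1 <- tournament(pop, fit, config$tournament_size)
        p2 <- tournament(pop, fit, config$tournament_size)
        if (runif(1) < config$crossover_rate) {
          w <- runif(1)
          c1 <- w * p1 + (1 - w) * p2
          c2 <- (1 - w) * p1 + w * p2
        } else {
          c1 <- p1; c2 <- p2
        }
        children <- c(children, c1, c2)
      }
      children <- children[seq_len(config$population_size - config$elitism)]
      mut <- runif(length(children)) < config$mutation_rate
      children[mut] <- children[mut] + rnorm(sum(mut), 0, config$mutation_sd)
      children <- pmin(pmax(children, lo), hi)
      pop <- c(elites, children)
      fit <- vapply(pop, eval_chrom, numeric(1))
      gen_best <- max(fit)
      if (gen_best > best_f + 1e-12) {
        best_f <- gen_best
        best_g <- pop[which.max(fit)]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- bind_rows(history, tibble(
        generation = gen, best = best_f, mean = mean(fit)))
      if (stall >= config$patience) break
    }
    structure(list(
      best_sigma = med * 10^best_g, best_fitness = best_f,
      best_log10_multiplier = best_g, median_distance = med,
      history = history, evaluations = n_eval, config = config
    ), class = "ga_result")
  })
}

tournament <- function(pop, fit, k) {
  idx <- sample.int(length(pop), k, replace = TRUE)
  pop[idx[which.max(fit[idx])]]
}

#' @method print ga_result
#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "GA bandwidth search: best sigma = %.4g (fitness %.4f, %d evaluations, %d generation(s))\n",
    x$best_sigma, x$best_fitness, x$evaluations, nrow(x$history)))
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) x$history

#' @export
glance.ga_result <- function(x, ...) {
  tibble(best_sigma = x$best_sigma, best_fitness = x$best_fitness,
         evaluations = x$evaluations, generations = nrow(x$history))
}

#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "CV fitness",
                  title = "GA convergence for the Gaussian bandwidth") +
    ggplot2::theme_minimal()
}
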