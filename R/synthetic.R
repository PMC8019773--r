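#' Synthetic-cohort configuration
#'
#' Builds the parameter set for [simulate_cohort()]. Defaults emulate a
#' moderately sized clinical expression cohort: 149 samples with a 28.19%
#' poor-outcome prevalence, 2,000 genes of which 116 are differentially
#' expressed between outcome groups with a 70:46 up:down split, and
#' group-dependent exponential survival with independent uniform censoring.
#'
#' @param n_samples Number of samples (default 149).
#' @param n_genes Number of genes (default 2000).
#' @param prevalence_poor Probability a sample has the poor outcome
#'   (default 0.2819; poor outcome is the positive class).
#' @param n_de_genes Number of differentially expressed genes (default 116).
#' @param effect_size Standardized mean shift of DE genes in the poor group,
#'   in units of `noise_sd` (default 1.0).
#' @param up_fraction Fraction of DE genes up-regulated in the poor group
#'   (default 70/116).
#' @param signal `"linear"` (mean shifts only) or `"nonlinear"` (a latent
#'   radial subset additionally carries a spherical class boundary that no
#'   linear rule can match).
#' @param n_latent Size of the latent radial subset in nonlinear mode
#'   (default 4; clamped to 2..5).
#' @param nonlinear_radius Radius (in `noise_sd` units) around the shifted
#'   poor-class center containing ~95% of poor-class latent mass (default 1.5).
#' @param noise_sd Residual standard deviation of expression values
#'   (default 1.0).
#' @param censor_rate Target overall censoring proportion in `[0, 1)`
#'   (default 0.2).
#' @param surv_scale_good,surv_scale_poor Mean survival times (years) of the
#'   two groups; poor must be shorter (defaults 8 and 1.5).
#' @param raw_intensities If `TRUE`, emit positive raw-scale intensities
#'   (`2^(latent + 5) - 1`) so the log2(x+1) preprocessing path is exercised;
#'   default emits values already on the standardized latent scale.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 149L, n_genes = 2000L,
                         prevalence_poor = 0.2819, n_de_genes = 116L,
                         effect_size = 1.0, up_fraction = 70 / 116,
                         signal = c("linear", "nonlinear"), n_latent = 4L,
                         nonlinear_radius = 1.5, noise_sd = 1.0,
                         censor_rate = 0.2, surv_scale_good = 8,
                         surv_scale_poor = 1.5, raw_intensities = FALSE,
                         seed = 1L) {
  signal <- match.arg(signal)
  stopifnot(n_samples >= 2, n_genes >= 1, n_de_genes >= 0,
            prevalence_poor > 0, prevalence_poor < 1,
            effect_size > 0, noise_sd > 0, nonlinear_radius > 0,
            censor_rate >= 0, censor_rate < 1,
            surv_scale_good > 0, surv_scale_poor > 0)
  if (n_de_genes > n_genes) abort("n_de_genes must not exceed n_genes")
  if (surv_scale_poor >= surv_scale_good) {
    abort("surv_scale_poor must be smaller than surv_scale_good")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    prevalence_poor = prevalence_poor, n_de_genes = as.integer(n_de_genes),
    effect_size = effect_size, up_fraction = up_fraction, signal = signal,
    n_latent = max(2L, min(5L, as.integer(n_latent))),
    nonlinear_radius = nonlinear_radius, noise_sd = noise_sd,
    censor_rate = censor_rate, surv_scale_good = surv_scale_good,
    surv_scale_poor = surv_scale_poor, raw_intensities = raw_intensities,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Simulate a gene-expression cohort with planted outcomes
#'
#' Draws binary outcomes `Bernoulli(prevalence_poor)`, i.i.d. Gaussian
#' expression for non-DE genes, mean-shifted DE genes
#' (`+/- effect_size * noise_sd` in the poor group, up:down per
#' `up_fraction`), optional nonlinear structure (see below), and
#' group-dependent exponential survival times with independent uniform
#' censoring calibrated to `censor_rate`.
#'
#' In nonlinear mode a latent subset of the up-regulated DE genes carries a
#' spherical class boundary: poor-class latent vectors are concentrated
#' (within `nonlinear_radius`) around the shifted center while good-class
#' vectors are dispersed, so the Bayes rule is radial and no linear
#' classifier attains it, while each latent gene still shows a marginal mean
#' shift and survives marginal screening.
#'
#' @param config A [synth_config()].
#' @return A list of class `cohort` with elements `expression` (tibble,
#'   genes in rows), `phenotypes` (tibble: sample_id, outcome, time, event)
#'   and `truth` (planted DE gene ids with directions, latent subset, and a
#'   description of the Bayes rule).
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_stage_seed(cfg$seed, "simulate", {
    y <- draw_outcomes(cfg$n_samples, cfg$prevalence_poor)
    n <- cfg$n_samples
    p <- cfg$n_genes
    gene_ids <- sprintf("G%04d", seq_len(p))
    sample_ids <- sprintf("S%03d", seq_len(n))

    # latent standardized-scale expression, genes x samples
    x <- matrix(rnorm(p * n, 0, cfg$noise_sd), nrow = p,
                dimnames = list(gene_ids, sample_ids))
    n_up <- if (cfg$n_de_genes > 0) round(cfg$up_fraction * cfg$n_de_genes) else 0L
    de_idx <- seq_len(cfg$n_de_genes)
    direction <- rep(c(1, -1), c(n_up, cfg$n_de_genes - n_up))
    shift <- cfg$effect_size * cfg$noise_sd
    if (cfg$n_de_genes > 0) {
      x[de_idx, y == 1L] <- x[de_idx, y == 1L] + direction * shift
    }

    latent_idx <- integer(0)
    if (cfg$signal == "nonlinear") {
      k <- cfg$n_latent
      latent_idx <- if (n_up >= k) seq_len(k) else seq_len(min(k, p))
      center <- if (length(latent_idx) && all(latent_idx %in% de_idx)) {
        direction[latent_idx] * shift
      } else {
        rep(0, length(latent_idx))
      }
      # poor-class latent mass concentrated within nonlinear_radius of the
      # center: sd chosen so the 95% chi-square ball has that radius
      sd_poor <- cfg$nonlinear_radius * cfg$noise_sd /
        sqrt(qchisq(0.95, length(latent_idx)))
      n_poor <- sum(y == 1L)
      x[latent_idx, y == 1L] <- center +
        matrix(rnorm(length(latent_idx) * n_poor, 0, sd_poor),
               nrow = length(latent_idx))
      x[latent_idx, y == 0L] <- matrix(
        rnorm(length(latent_idx) * sum(y == 0L), 0, cfg$noise_sd),
        nrow = length(latent_idx))
    }

    if (cfg$raw_intensities) {
      x <- pmax(2^(x + 5) - 1, 0)
    }

    surv <- draw_survival(y, cfg)
    expression <- as_expr_tbl(x)
    phenotypes <- tibble(
      sample_id = sample_ids,
      outcome = y,
      time = surv$time,
      event = surv$event
    )
    truth <- list(
      de_genes = tibble(
        gene_id = gene_ids[de_idx],
        direction = ifelse(direction > 0, "up", "down")
      ),
      latent_genes = gene_ids[latent_idx],
      signal = cfg$signal,
      bayes_rule = if (cfg$signal == "nonlinear") {
        paste0("poor iff latent vector lies inside the sphere of radius ~",
               signif(cfg$nonlinear_radius, 3),
               " * noise_sd around the shifted center (spherical boundary)")
      } else {
        "linear in the DE genes (Gaussian shift model)"
      },
      config = cfg
    )
    structure(list(expression = expression, phenotypes = phenotypes,
                   truth = truth), class = "cohort")
  })
}

draw_outcomes <- function(n, prevalence) {
  y <- rbinom(n, 1L, prevalence)
  if (length(unique(y)) < 2L) {
    y <- rbinom(n, 1L, prevalence)
    if (length(unique(y)) < 2L) {
      abort("realized outcome draw has an empty class (after one resample)")
    }
  }
  y
}

draw_survival <- function(y, cfg) {
  n <- length(y)
  scale <- ifelse(y == 1L, cfg$surv_scale_poor, cfg$surv_scale_good)
  t_true <- rexp(n, rate = 1 / scale)
  if (cfg$censor_rate <= 0) {
    return(list(time = t_true, event = rep(1L, n)))
  }
  cmax <- calibrate_censoring(cfg)
  cens <- runif(n, 0, cmax)
  list(time = pmin(t_true, cens), event = as.integer(t_true <= cens))
}

# c_max of the Uniform(0, c_max) censoring time such that the expected
# censoring proportion over the outcome mixture equals censor_rate
calibrate_censoring <- function(cfg) {
  pcens <- function(cmax) {
    one <- function(mu) mu / cmax * (1 - exp(-cmax / mu))
    cfg$prevalence_poor * one(cfg$surv_scale_poor) +
      (1 - cfg$prevalence_poor) * one(cfg$surv_scale_good)
  }
  uniroot(function(cm) pcens(cm) - cfg$censor_rate,
          interval = c(1e-6, 1e4 * cfg$surv_scale_good), tol = 1e-8)$root
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d genes x %d samples; %d poor / %d good; %d DE genes (%s signal)\n",
    nrow(x$expression), ncol(x$expression) - 1L,
    sum(x$phenotypes$outcome == 1L), sum(x$phenotypes$outcome == 0L),
    nrow(x$truth$de_genes), x$truth$signal
  ))
  invisible(x)
}
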