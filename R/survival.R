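#' Kaplan-Meier survival curve(s)
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` per
#' group, via the standard survival machinery. Censored records contribute
#' at-risk time only; ties at an event time keep censored subjects at risk
#' through that time.
#'
#' @param records Data frame with columns `time` (non-negative), `event`
#'   (0/1) and optionally `group`.
#' @return A tibble of step coordinates: `group`, `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
km_curve <- function(records) {
  if (any(records$time < 0)) abort("negative survival time")
  if (nrow(records) < 1L) abort("need at least one record")
  has_group <- "group" %in% names(records) &&
    length(unique(records$group)) > 1L
  f <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  s <- summary(f, censored = TRUE)
  grp <- if (has_group) {
    sub("^group=", "", as.character(s$strata))
  } else {
    rep("all", length(s$time))
  }
  tibble(group = grp, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, survival = s$surv)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom
#' comparing the survival experience of two groups over the pooled event
#' times.
#'
#' @param records Data frame with columns `time`, `event`, `group` (exactly
#'   two groups, at least one event overall).
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
logrank <- function(records) {
  groups <- unique(records$group)
  if (length(groups) != 2L) abort("log-rank needs exactly two groups")
  if (sum(records$event) < 1L) abort("log-rank needs at least one event")
  d <- survival::survdiff(survival::Surv(time, event) ~ group,
                          data = records)
  tibble(statistic = d$chisq, df = 1L,
         p = pchisq(d$chisq, 1, lower.tail = FALSE))
}

#' Kaplan-Meier stratification of actual vs predicted risk groups
#'
#' Convenience wrapper producing the two-panel comparison: the survival
#' split by the true outcome groups, and by a classifier's predicted
#' groups, each with its log-rank test.
#'
#' @param phenotypes Phenotype tibble (`outcome`, `time`, `event`).
#' @param predicted Optional 0/1 predicted outcome for the same samples.
#' @return A list of class `km_strata`: `curves` (tibble with a `panel`
#'   column), `tests` (log-rank per panel).
#' @export
km_stratify <- function(phenotypes, predicted = NULL) {
  lab <- function(v) ifelse(v == 1, "poor", "good")
  actual <- phenotypes %>%
    mutate(group = lab(.data$outcome)) %>%
    select("time", "event", "group")
  panels <- list(actual = actual)
  if (!is.null(predicted)) {
    panels$predicted <- actual %>% mutate(group = lab(predicted))
  }
  curves <- imap(panels, function(df, nm) {
    km_curve(df) %>% mutate(panel = nm)
  }) %>% list_rbind()
  tests <- imap(panels, function(df, nm) {
    logrank(df) %>% mutate(panel = nm)
  }) %>% list_rbind()
  structure(list(curves = curves, tests = tests), class = "km_strata")
}

#' @method print km_strata
#' @export
print.km_strata <- function(x, ...) {
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("%s groups: log-rank chi2 = %.3f, p = %.3g\n",
                x$tests$panel[i], x$tests$statistic[i], x$tests$p[i]))
  }
  invisible(x)
}

#' @export
tidy.km_strata <- function(x, ...) x$curves

#' @export
glance.km_strata <- function(x, ...) x$tests

#' Kaplan-Meier step plot
#'
#' @param object A `km_strata`.
#' @param ... Unused.
#' @return A ggplot (one facet per panel).
#' @export
autoplot.km_strata <- function(object, ...) {
  df <- object$curves %>%
    group_by(.data$panel, .data$group) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0, survival = 1),
      .x
    )) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability",
                  title = "Kaplan-Meier risk-group stratification") +
    ggplot2::theme_minimal()
}
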