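#' Read a gene-expression matrix from TSV
#'
#' Expression files are tab-separated with gene identifiers in the first
#' column and one column per sample (header row carries the sample ids).
#' Genes are rows, samples are columns, matching the usual heatmap
#' orientation; analysis functions transpose to samples-by-genes internally.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort("empty expression file: need at least one gene and one sample")
  }
  names(raw)[1] <- "gene_id"
  if (anyDuplicated(raw$gene_id)) {
    dup <- unique(raw$gene_id[duplicated(raw$gene_id)])
    abort(paste0("duplicate gene id: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort("duplicate sample ids in header")
  }
  body <- raw[-1]
  num <- suppressWarnings(lapply(body, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(body[[j]]))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric expression value '%s' at gene %s, sample %s",
        body[[j]][bad[1]], raw$gene_id[bad[1]], names(body)[j]
      ))
    }
  }
  out <- tibble(gene_id = raw$gene_id)
  out[names(body)] <- num
  inform(sprintf("read expression matrix: %d genes x %d samples",
                 nrow(out), ncol(out) - 1L))
  out
}

#' Write a gene-expression matrix to TSV
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "gene_id")
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' The file must have columns `sample_id`, `outcome` (one of `"good"` or
#' `"poor"`), `time` (non-negative follow-up, years) and `event` (0/1 death
#' indicator). Poor outcome is the positive (minority) class and is coded 1.
#'
#' @param path Path to a CSV file.
#' @param expr Optional expression tibble; if supplied, sample ids must match
#'   exactly (an error lists any id present on one side only).
#' @return A tibble with columns `sample_id`, `outcome` (integer, poor = 1),
#'   `time`, `event`.
#' @export
read_phenotypes <- function(path, expr = NULL) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  ph <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    outcome = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer()
  ), progress = FALSE)
  need <- c("sample_id", "outcome", "time", "event")
  miss <- setdiff(need, names(ph))
  if (length(miss)) abort(paste0("phenotype file missing columns: ",
                                 paste(miss, collapse = ", ")))
  bad <- setdiff(unique(ph$outcome), c("good", "poor"))
  if (length(bad)) abort(paste0("unrecognized outcome value: ",
                                paste(bad, collapse = ", ")))
  if (any(ph$time < 0, na.rm = TRUE)) abort("negative survival time")
  if (!all(ph$event %in% c(0L, 1L))) abort("event must be 0 or 1")
  if (anyDuplicated(ph$sample_id)) abort("duplicate sample id in phenotypes")
  out <- ph %>%
    mutate(outcome = as.integer(.data$outcome == "poor")) %>%
    select(all_of(need))
  if (!is.null(expr)) check_sample_match(expr, out)
  out
}

#' Write a phenotype table to CSV
#'
#' @param phenotypes Phenotype tibble (`outcome` coded 0/1 or good/poor).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  ph <- phenotypes
  if (is.numeric(ph$outcome)) {
    ph$outcome <- ifelse(ph$outcome == 1, "poor", "good")
  }
  readr::write_csv(ph, path, progress = FALSE)
  invisible(path)
}

check_sample_match <- function(expr, phenotypes) {
  es <- names(expr)[-1]
  ps <- phenotypes$sample_id
  only_e <- setdiff(es, ps)
  only_p <- setdiff(ps, es)
  if (length(only_e) || length(only_p)) {
    abort(paste0(
      "sample ids do not match between expression and phenotypes;",
      if (length(only_e)) paste0(" expression only: ",
                                 paste(only_e, collapse = ", ")) else "",
      if (length(only_p)) paste0(" phenotypes only: ",
                                 paste(only_p, collapse = ", ")) else ""
    ))
  }
  invisible(TRUE)
}

# genes x samples numeric matrix from an expression tibble
expr_matrix <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

# expression tibble from a genes x samples matrix
as_expr_tbl <- function(m) {
  out <- tibble(gene_id = rownames(m))
  out[colnames(m)] <- as.data.frame(m)
  out
}

# samples x genes matrix aligned to the phenotype table order
analysis_matrix <- function(expr, phenotypes) {
  check_sample_match(expr, phenotypes)
  m <- t(expr_matrix(expr))
  m[phenotypes$sample_id, , drop = FALSE]
}
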