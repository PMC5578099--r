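# Exon-level CV screening.
#
# After normalization, exons detected in every library are screened by the
# coefficient of variation (CV = SD / mean) of their counts across subjects.
# Exons in the lowest tail of the CV distribution, expressed within a
# practical working range of counts, are the reference-gene candidates.

#' Keep robustly detected exons
#'
#' An exon is robustly detected when it has at least one count in every
#' library (minimum value across libraries > 0). Row order is preserved.
#'
#' @param counts Wide count tibble.
#' @return The filtered count tibble (possibly zero rows).
#' @export
filter_robust <- function(counts) {
  m <- counts_to_matrix(counts)
  keep <- apply(m, 1, min) > 0
  if (!any(keep)) {
    inform("No exon is robustly detected (every exon has a zero count).")
  }
  counts[keep, , drop = FALSE]
}

#' Per-exon mean, SD and CV across subjects
#'
#' Technical replicates of the same subject are averaged first (the
#' default), then the mean, sample SD (n - 1 denominator) and CV = SD/mean
#' are computed across subjects. With `average_replicates = FALSE` the
#' statistics are computed across libraries directly.
#'
#' @param counts Wide count tibble (typically robust-filtered and
#'   RUV-normalized).
#' @param design Sample design tibble covering every library.
#' @param gene_map Optional tibble with columns `exon_id`, `gene_id`.
#' @param average_replicates Average technical replicates per subject before
#'   computing statistics?
#' @return A tibble with columns `exon_id`, optionally `gene_id`, `mean`,
#'   `sd`, `cv` (fraction; `NA` when the mean is zero).
#' @examples
#' counts <- tibble::tibble(exon_id = "e1", A = 1, B = 2, C = 3)
#' design <- tibble::tibble(library_id = c("A", "B", "C"),
#'                          subject_id = c("s1", "s2", "s3"),
#'                          replicate_group = c("s1", "s2", "s3"),
#'                          outcome = c("sPTB", "TB", "TB"))
#' exon_stats(counts, design)
#' @export
exon_stats <- function(counts, design, gene_map = NULL,
                       average_replicates = TRUE) {
  m <- counts_to_matrix(counts)
  check_design(design, colnames(m))
  if (average_replicates) {
    subj <- design$subject_id[match(colnames(m), design$library_id)]
    if (anyNA(subj)) abort("Design must assign every library to a subject.")
    m <- vapply(
      split(seq_len(ncol(m)), subj),
      function(idx) rowMeans(m[, idx, drop = FALSE]),
      numeric(nrow(m))
    )
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- tibble(
    exon_id = as.character(counts[[1]]),
    mean = unname(mu),
    sd = unname(s),
    cv = ifelse(mu > 0, s / mu, NA_real_)
  )
  if (anyNA(out$cv)) {
    warn("CV undefined (mean = 0) for some exons; flagged as NA.")
  }
  if (!is.null(gene_map)) {
    out <- left_join(out, gene_map, by = "exon_id") %>%
      select("exon_id", "gene_id", dplyr::everything())
  }
  out
}

#' Select exons with CV below a percentile of the CV distribution
#'
#' The percentile is computed by linear interpolation of order statistics at
#' zero-based index `p/100 * (n - 1)` (the default quantile convention in
#' most statistical software); exons strictly below the realized cutoff are
#' returned, sorted by ascending CV.
#'
#' @param stats An [exon_stats()] tibble with defined `cv` values.
#' @param percentile Percentile in (0, 100); default 10.
#' @return A `candidate_panel`: the selected rows of `stats` sorted by `cv`,
#'   with attributes `percentile`, `cv_cutoff` and (once shortlisted)
#'   `level_range`.
#' @export
select_low_cv <- function(stats, percentile = 10) {
  if (percentile <= 0 || percentile > 100) {
    abort("percentile must lie in (0, 100].")
  }
  cv <- stats$cv
  if (length(cv) == 0 || anyNA(cv)) {
    abort("All exons must have a defined CV (drop mean-zero exons first).")
  }
  cutoff <- quantile(cv, percentile / 100, type = 7, names = FALSE)
  out <- stats %>% filter(.data$cv < cutoff) %>% arrange(.data$cv)
  new_candidate_panel(out, percentile = percentile, cv_cutoff = cutoff,
                      level_range = NULL)
}

new_candidate_panel <- function(tbl, percentile, cv_cutoff, level_range) {
  structure(
    tbl,
    percentile = percentile,
    cv_cutoff = cv_cutoff,
    level_range = level_range,
    class = c("candidate_panel", class(tibble()))
  )
}

#' Shortlist candidates by mean expression level
#'
#' Retains panel members whose mean normalized count lies in
#' `[min_level, max_level]` (inclusive), so that candidate reference genes
#' are expressed within a few orders of magnitude of typical target
#' transcripts. Ordering by CV is preserved.
#'
#' @param panel A [select_low_cv()] panel.
#' @param min_level,max_level Inclusive mean-count bounds (defaults 5 and
#'   500).
#' @return A `candidate_panel` with the `level_range` attribute set.
#' @export
shortlist_by_level <- function(panel, min_level = 5, max_level = 500) {
  if (min_level > max_level) abort("min_level must not exceed max_level.")
  out <- panel %>%
    filter(.data$mean >= min_level, .data$mean <= max_level)
  new_candidate_panel(
    out,
    percentile = attr(panel, "percentile"),
    cv_cutoff = attr(panel, "cv_cutoff"),
    level_range = c(min_level, max_level)
  )
}

#' Association between mean level and CV
#'
#' Spearman rank correlation (with two-sided t-approximation p-value)
#' between per-exon mean and CV: a near-zero value indicates the CV screen
#' is not simply picking an expression stratum.
#'
#' @param stats An [exon_stats()] tibble (>= 3 exons, defined CV).
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
mean_cv_association <- function(stats) {
  ok <- !is.na(stats$cv)
  spearman_cor(stats$mean[ok], stats$cv[ok])
}

#' One exon per gene: the lowest-CV exon
#'
#' For each gene, reports the exon with the smallest CV; ties are broken by
#' lexicographically smallest exon ID.
#'
#' @param stats An [exon_stats()] tibble with `gene_id` populated.
#' @return One row per gene, ordered by `gene_id`.
#' @export
per_gene_best_exon <- function(stats) {
  if (!"gene_id" %in% names(stats)) {
    abort("`gene_id` must be populated (supply gene_map to exon_stats()).")
  }
  stats %>%
    arrange(.data$gene_id, .data$cv, .data$exon_id) %>%
    group_by(.data$gene_id) %>%
    dplyr::slice(1) %>%
    ungroup()
}

#' Format a CV as a percentage
#'
#' Convenience for reporting: `100 * sd / mean`, rounded to `digits`
#' decimal places (default whole percent).
#'
#' @param mean,sd Numeric vectors of summary statistics.
#' @param digits Decimal places of the percentage.
#' @return Numeric vector of CV percentages.
#' @examples
#' cv_pct(mean = 1.3, sd = 0.52)  # 40
#' @export
cv_pct <- function(mean, sd, digits = 0) {
  round(100 * sd / mean, digits)
}

#' Scatter plot of exon CV against mean level
#'
#' Log10 axes; candidates (if a panel is supplied) are highlighted.
#'
#' @param stats An [exon_stats()] tibble.
#' @param panel Optional [select_low_cv()] panel to highlight.
#' @return A ggplot object.
#' @export
plot_mean_cv <- function(stats, panel = NULL) {
  dat <- stats %>%
    filter(!is.na(.data$cv), .data$mean > 0, .data$cv > 0) %>%
    mutate(candidate = if (is.null(panel)) FALSE else .data$exon_id %in% panel$exon_id)
  ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data$mean),
                                    y = log10(100 * .data$cv),
                                    colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "darkorange")) +
    ggplot2::labs(x = "log10 mean normalized counts", y = "log10 CV%",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}
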