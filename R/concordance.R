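# Subset concordance of stability rankings.
#
# Stability values estimated in one batch of samples are only useful if
# they transfer to future batches. The check: split the cohort into two
# outcome-balanced subsets, rank the candidate genes in each with both
# stability methods, and compare the rankings (absolute rank differences
# and the Spearman correlation of the stability values).

#' Stratified two-subset partition of a sample design
#'
#' Samples are split within each outcome group as evenly as possible; when
#' a group has an odd count, subset 1 receives the extra sample. The split
#' is random but fully determined by `seed`.
#'
#' @param design Tibble with `sample_id` (or `library_id`) and `outcome`
#'   columns; each outcome group needs >= 2 samples.
#' @param seed Integer seed.
#' @return The design tibble with an added integer `subset` column (1/2).
#' @export
partition_samples <- function(design, seed) {
  key <- if ("sample_id" %in% names(design)) "sample_id" else "library_id"
  if (!all(c(key, "outcome") %in% names(design))) {
    abort("Design needs `sample_id` (or `library_id`) and `outcome` columns.")
  }
  sizes <- table(design$outcome)
  if (length(sizes) == 0 || any(sizes < 2)) {
    abort("Each outcome group needs at least 2 samples.")
  }
  rng <- local_rng(seed)
  design %>%
    group_by(.data$outcome) %>%
    mutate(subset = {
      n_here <- dplyr::n()
      n1 <- ceiling(n_here / 2)
      assignment <- rep(2L, n_here)
      assignment[sample.int(n_here, n1)] <- 1L
      assignment
    }) %>%
    ungroup()
}

#' Rank-difference table between two stability vectors
#'
#' Both vectors are ranked ascending (most stable = rank 1; ties broken by
#' gene name so ranks are a strict 1..N permutation) and compared per gene.
#'
#' @param stab1,stab2 Named numeric vectors of stability values (same gene
#'   set), or two-column tibbles (`gene`, value).
#' @return A tibble with columns `gene`, `rank1`, `rank2`, `abs_diff` and
#'   attributes `total` (sum of absolute differences) and `spearman`
#'   (one-row tibble from [spearman_cor()] on the rank vectors).
#' @examples
#' s1 <- c(a = 0.2, b = 0.5, c = 0.3)
#' s2 <- c(a = 0.25, b = 0.45, c = 0.35)
#' rank_difference_table(s1, s2)
#' @export
rank_difference_table <- function(stab1, stab2) {
  as_named <- function(s) {
    if (is.data.frame(s)) setNames(s[[2]], s[[1]]) else s
  }
  s1 <- as_named(stab1)
  s2 <- as_named(stab2)
  if (!setequal(names(s1), names(s2))) {
    abort(paste0(
      "Gene sets differ: ",
      paste(union(setdiff(names(s1), names(s2)),
                  setdiff(names(s2), names(s1))), collapse = ", ")
    ))
  }
  genes <- sort(names(s1))
  strict_rank <- function(s) {
    ord <- order(s[genes], genes)
    r <- integer(length(genes))
    r[ord] <- seq_along(genes)
    setNames(r, genes)
  }
  r1 <- strict_rank(s1)
  r2 <- strict_rank(s2)
  out <- tibble(
    gene = genes,
    rank1 = unname(r1),
    rank2 = unname(r2),
    abs_diff = abs(unname(r1) - unname(r2))
  )
  attr(out, "total") <- sum(out$abs_diff)
  attr(out, "spearman") <- spearman_cor(out$rank1, out$rank2)
  out
}

#' Two-subset concordance of geNorm and model-based stability
#'
#' Partitions the cohort ([partition_samples()]), runs both stability
#' methods on each subset's relative quantities, and tabulates per-gene
#' ranks, absolute rank differences, totals and Spearman correlations.
#'
#' @param cq Long Cq tibble (see [cq_to_relative_quantity()]).
#' @param design Tibble with `sample_id` and `outcome`.
#' @param seed Integer seed for the partition.
#' @param cutoff geNorm V-series cutoff.
#' @return An object of class `concordance_result`: `table` (per gene and
#'   method: ranks and differences), `totals`, `spearman`, `partition`,
#'   `fits` (the four underlying fits).
#' @export
concordance <- function(cq, design, seed = 1L, cutoff = 0.15) {
  part <- partition_samples(design, seed)
  key <- if ("sample_id" %in% names(part)) "sample_id" else "library_id"

  subset_fit <- function(i) {
    ids <- part[[key]][part$subset == i]
    q <- cq %>%
      filter(.data$sample_id %in% ids) %>%
      cq_to_relative_quantity()
    list(
      genorm = genorm(q, cutoff = cutoff),
      normfinder = normfinder_stability(q, part[part$subset == i, ])
    )
  }
  f1 <- subset_fit(1L)
  f2 <- subset_fit(2L)

  genorm_stab <- function(f) setNames(f$genorm$m$m, f$genorm$m$gene)
  nf_stab <- function(f) {
    setNames(f$normfinder$stability$rho, f$normfinder$stability$gene)
  }
  # geNorm rank differences use the stepwise exclusion order (final pair
  # resolved by M), matching how the software reports rankings.
  genorm_rank_values <- function(f) {
    r <- f$genorm$rank
    m <- setNames(f$genorm$m$m, f$genorm$m$gene)
    # exclusion rank with the tied final pair separated by M value
    setNames(r[names(m)] + m / (2 * max(m) + 1), names(m))
  }
  tabs <- list(
    geNorm = rank_difference_table(genorm_rank_values(f1), genorm_rank_values(f2)),
    NormFinder = rank_difference_table(nf_stab(f1), nf_stab(f2))
  )
  table <- bind_rows(
    tabs$geNorm %>% mutate(method = "geNorm"),
    tabs$NormFinder %>% mutate(method = "NormFinder")
  ) %>% select("method", dplyr::everything())
  totals <- tibble(
    method = names(tabs),
    total_abs_rank_diff = unname(vapply(tabs, function(t) attr(t, "total"),
                                        numeric(1)))
  )
  spearman <- bind_rows(
    attr(tabs$geNorm, "spearman") %>% mutate(method = "geNorm"),
    attr(tabs$NormFinder, "spearman") %>% mutate(method = "NormFinder")
  ) %>% select("method", dplyr::everything())
  structure(
    list(table = table, totals = totals, spearman = spearman,
         partition = part, fits = list(subset1 = f1, subset2 = f2)),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Two-subset stability concordance\n")
  sizes <- table(x$partition$subset)
  cat("  subset sizes: ", paste(sizes, collapse = " / "), "\n", sep = "")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf(
      "  %-10s total |rank diff| = %d, Spearman r = %.2f (p = %.3g)\n",
      x$totals$method[i], x$totals$total_abs_rank_diff[i],
      x$spearman$r[i], x$spearman$p[i]
    ))
  }
  invisible(x)
}

#' @rdname concordance
#' @param x A `concordance_result` object.
#' @param ... Unused.
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  x$table
}

#' @rdname concordance
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  left_join(x$totals, x$spearman, by = "method")
}

#' @rdname concordance
#' @param object A `concordance_result` object.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(
    x = .data$rank1, y = .data$rank2, label = .data$gene
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(nudge_y = 0.2, size = 3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "rank in subset 1", y = "rank in subset 2") +
    ggplot2::theme_minimal()
}
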