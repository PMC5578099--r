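# geNorm expression-stability analysis.
#
# The stability of a candidate reference gene is the average standard
# deviation of its log2 expression ratio with every other candidate
# (M value); truly stable genes hold a constant ratio with each other
# regardless of the amount of input RNA. Genes are ranked by stepwise
# exclusion of the highest-M gene, normalization factors NF_n are geometric
# means of the top-n genes, and the pairwise variation V_n/n+1 between
# consecutive normalization factors decides how many reference genes are
# enough (V <= 0.15 by convention).

#' Efficiency-corrected relative quantities from Cq values
#'
#' `q = E^(minCq - Cq)` per gene, so the sample with the lowest Cq of each
#' gene is the calibrator (q = 1). Relative quantities are the substrate of
#' both geNorm and the model-based stability estimator.
#'
#' @param cq Long tibble with columns `gene`, `sample_id`, `cq`,
#'   `efficiency` (one row per gene-sample pair; efficiency constant within
#'   gene, in (1, 2.2]).
#' @return A wide tibble: `gene` column plus one positive column per sample.
#' @examples
#' cq <- tibble::tibble(gene = "g", sample_id = c("a", "b", "c"),
#'                      cq = c(20, 21, 22), efficiency = 2)
#' cq_to_relative_quantity(cq)  # 1, 0.5, 0.25
#' @export
cq_to_relative_quantity <- function(cq) {
  req <- c("gene", "sample_id", "cq", "efficiency")
  missing_cols <- setdiff(req, names(cq))
  if (length(missing_cols) > 0) {
    abort(paste0("Cq table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(cq$efficiency <= 1)) abort("PCR efficiencies must be > 1.")
  if (any(cq$efficiency > 2.2)) {
    warn("PCR efficiency above 2.2: check calibration-curve units.")
  }
  if (anyNA(cq$cq) || any(!is.finite(cq$cq))) {
    bad <- cq %>% filter(!is.finite(.data$cq))
    abort(paste0(
      "Missing/non-finite Cq for: ",
      paste(paste0(bad$gene, "/", bad$sample_id), collapse = ", ")
    ))
  }
  dup <- cq %>% dplyr::count(.data$gene, .data$sample_id) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Multiple Cq rows for: ",
      paste(paste0(dup$gene, "/", dup$sample_id), collapse = ", ")
    ))
  }
  genes <- unique(cq$gene)
  samples <- unique(cq$sample_id)
  full <- tidyr::expand_grid(gene = genes, sample_id = samples) %>%
    dplyr::anti_join(cq, by = c("gene", "sample_id"))
  if (nrow(full) > 0) {
    abort(paste0(
      "Missing Cq cell(s): ",
      paste(paste0(full$gene, "/", full$sample_id), collapse = ", ")
    ))
  }
  wide <- cq %>%
    group_by(.data$gene) %>%
    mutate(q = .data$efficiency^(min(.data$cq) - .data$cq)) %>%
    ungroup() %>%
    select("gene", "sample_id", "q") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "q")
  wide
}

#' Pairwise variation between two genes
#'
#' The sample standard deviation (n - 1 denominator) of
#' `log2(q_j / q_k)` across samples; the building block of the M value.
#'
#' @param q Wide relative-quantity tibble (`gene` + sample columns).
#' @param gene_j,gene_k Gene names present in `q`.
#' @return A single non-negative number; symmetric in its gene arguments.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  m <- quantities_to_matrix(q)
  if (ncol(m) < 2) abort("At least 2 samples are required.")
  for (g in c(gene_j, gene_k)) {
    if (!g %in% rownames(m)) abort(paste0("Gene not present: ", g))
  }
  sd(log2(m[gene_j, ] / m[gene_k, ]))
}

m_values <- function(m) {
  # m: gene x sample positive matrix. Average pairwise SD of log2 ratios.
  lg <- log2(m)
  k <- nrow(m)
  v <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      v[j, l] <- v[l, j] <- sd(lg[j, ] - lg[l, ])
    }
  }
  setNames(rowSums(v) / (k - 1), rownames(m))
}

#' geNorm M values for all candidate genes
#'
#' `M_j` is the mean of the pairwise variations of gene `j` with every
#' other candidate; lower M means more stable.
#'
#' @param q Wide relative-quantity tibble (>= 2 genes).
#' @return A tibble with columns `gene`, `m`.
#' @export
stability_m <- function(q) {
  m <- quantities_to_matrix(q)
  if (nrow(m) < 2) abort("At least 2 genes are required to compute M.")
  mv <- m_values(m)
  tibble(gene = names(mv), m = unname(mv))
}

#' Rank genes by stepwise exclusion of the least stable gene
#'
#' Repeatedly removes the gene with the highest M (ties: the
#' lexicographically larger gene name is excluded) and recomputes M on the
#' remainder until two genes are left; the final two genes share the top
#' rank. The full M trajectory is retained.
#'
#' @param q Wide relative-quantity tibble (>= 3 genes).
#' @return A list of class `genorm_ranking`: `ranking` (most to least
#'   stable; first two tied), `rank` (named integer vector, final pair = 1),
#'   `trajectory` (tibble: `round`, `n_genes`, `gene`, `m`, `excluded`).
#' @export
rank_stepwise <- function(q) {
  m <- quantities_to_matrix(q)
  if (nrow(m) < 3) abort("Stepwise ranking needs at least 3 genes.")
  cur <- m
  excluded <- character(0)
  rounds <- list()
  round_i <- 1L
  while (nrow(cur) > 2) {
    mv <- m_values(cur)
    # Highest M leaves; lexicographic tie-break on the gene name.
    worst_m <- max(mv)
    cand <- sort(names(mv)[mv >= worst_m - 1e-15])
    drop_gene <- cand[length(cand)]
    if (length(cand) > 1) {
      inform(paste0("M tie at round ", round_i, "; excluding ", drop_gene, "."))
    }
    rounds[[round_i]] <- tibble(
      round = round_i, n_genes = nrow(cur),
      gene = names(mv), m = unname(mv),
      excluded = names(mv) == drop_gene
    )
    excluded <- c(excluded, drop_gene)
    cur <- cur[setdiff(rownames(cur), drop_gene), , drop = FALSE]
    round_i <- round_i + 1L
  }
  mv <- m_values(cur)
  rounds[[round_i]] <- tibble(
    round = round_i, n_genes = 2L,
    gene = names(mv), m = unname(mv), excluded = FALSE
  )
  final_pair <- sort(rownames(cur))
  ranking <- c(final_pair, rev(excluded))
  rank <- setNames(c(1L, 1L, seq.int(2L, length.out = length(excluded))), ranking)
  structure(
    list(ranking = ranking, rank = rank, trajectory = bind_rows(rounds)),
    class = "genorm_ranking"
  )
}

#' Normalization factor from the top-n reference genes
#'
#' `NF_n(sample)` is the geometric mean of the `n` most stable genes'
#' relative quantities in that sample.
#'
#' @param q Wide relative-quantity tibble.
#' @param genes Genes ordered most to least stable.
#' @param n How many genes to include (1 <= n <= length(genes)).
#' @return A named numeric vector, one positive value per sample.
#' @export
normalization_factor <- function(q, genes, n) {
  m <- quantities_to_matrix(q)
  if (n < 1 || n > length(genes)) {
    abort(paste0("n must be between 1 and ", length(genes), "."))
  }
  use <- genes[seq_len(n)]
  absent <- setdiff(use, rownames(m))
  if (length(absent) > 0) {
    abort(paste0("Gene(s) not present: ", paste(absent, collapse = ", ")))
  }
  apply(m[use, , drop = FALSE], 2, geomean)
}

#' Pairwise variation series between consecutive normalization factors
#'
#' `V_n/n+1` is the sample SD of `log2(NF_n / NF_(n+1))` for
#' `n = 2 .. N - 1`, where genes enter NF in stability order.
#'
#' @param q Wide relative-quantity tibble (>= 3 genes).
#' @param ranking Genes ordered most to least stable (a character vector or
#'   a [rank_stepwise()] result).
#' @return A tibble with columns `n` and `v` (`V_n/n+1`).
#' @export
pairwise_v_series <- function(q, ranking) {
  if (inherits(ranking, "genorm_ranking")) ranking <- ranking$ranking
  m <- quantities_to_matrix(q)
  n_genes <- length(ranking)
  if (n_genes < 3) abort("V series needs at least 3 genes.")
  nf <- lapply(2:n_genes, function(n) normalization_factor(q, ranking, n))
  names(nf) <- 2:n_genes
  v <- vapply(2:(n_genes - 1), function(n) {
    sd(log2(nf[[as.character(n)]] / nf[[as.character(n + 1)]]))
  }, numeric(1))
  tibble(n = 2:(n_genes - 1), v = v)
}

#' Optimal number of reference genes from a V series
#'
#' The smallest `n` whose `V_n/n+1` does not exceed the cutoff (inclusive:
#' V exactly at the cutoff means the added gene has little effect). If no
#' entry passes, the largest available `n + 1` is returned with a warning.
#'
#' @param v A [pairwise_v_series()] tibble or a numeric vector of V values
#'   for `n = 2, 3, ...` in order.
#' @param cutoff Decision threshold (default 0.15).
#' @return An integer >= 2.
#' @examples
#' optimal_n(c(0.15, 0.12))  # 2
#' @export
optimal_n <- function(v, cutoff = 0.15) {
  if (is.data.frame(v)) {
    n_vals <- v$n
    v_vals <- v$v
  } else {
    v_vals <- as.numeric(v)
    n_vals <- seq.int(2L, length.out = length(v_vals))
  }
  if (length(v_vals) == 0) abort("Empty V series.")
  ok <- which(v_vals <= cutoff)
  if (length(ok) == 0) {
    warn(paste0(
      "No V value at or below ", cutoff,
      "; using all ", max(n_vals) + 1L, " genes."
    ))
    return(as.integer(max(n_vals) + 1L))
  }
  as.integer(n_vals[min(ok)])
}

#' Full geNorm analysis
#'
#' Runs stepwise ranking, normalization factors, the V series and the
#' optimal-n decision in one call.
#'
#' @param q Wide relative-quantity tibble (>= 3 genes).
#' @param cutoff V-series decision threshold (default 0.15).
#' @return An object of class `genorm_fit`: `ranking`, `rank`, `m`
#'   (per-gene M at the round each gene was last present), `trajectory`,
#'   `nf` (tibble of NF_n per sample for n = 2..N), `v` (V-series tibble),
#'   `optimal_n`, `cutoff`.
#' @examples
#' sim <- simulate_cq(n_genes = 5, n_samples_per_group = c(6, 6),
#'                    noise_sd = c(0.05, 0.1, 0.2, 0.4, 0.8), seed = 11)
#' fit <- genorm(cq_to_relative_quantity(sim$cq))
#' fit$ranking
#' @export
genorm <- function(q, cutoff = 0.15) {
  ranking <- rank_stepwise(q)
  n_genes <- length(ranking$ranking)
  nf <- purrr::map(2:n_genes, function(nn) {
    nf_n <- normalization_factor(q, ranking$ranking, nn)
    tibble(n = nn, sample_id = names(nf_n), nf = unname(nf_n))
  }) %>% bind_rows()
  v <- pairwise_v_series(q, ranking$ranking)
  # Per-gene M at exclusion time; the final pair keeps its last-round M.
  last_m <- ranking$trajectory %>%
    group_by(.data$gene) %>%
    filter(.data$round == max(.data$round)) %>%
    ungroup() %>%
    select("gene", "m")
  structure(
    list(
      ranking = ranking$ranking,
      rank = ranking$rank,
      m = last_m,
      trajectory = ranking$trajectory,
      nf = nf,
      v = v,
      optimal_n = optimal_n(v, cutoff),
      cutoff = cutoff
    ),
    class = "genorm_fit"
  )
}

#' @export
print.genorm_fit <- function(x, ...) {
  cat("geNorm stability analysis\n")
  cat("  ranking (most to least stable): ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  cat("  optimal number of reference genes:", x$optimal_n,
      sprintf("(cutoff %.2f)\n", x$cutoff))
  invisible(x)
}

#' @rdname genorm
#' @param x A `genorm_fit` object.
#' @param ... Unused.
#' @method tidy genorm_fit
#' @export
tidy.genorm_fit <- function(x, ...) {
  x$m %>%
    mutate(rank = unname(x$rank[.data$gene])) %>%
    arrange(.data$rank, .data$gene)
}

#' @rdname genorm
#' @method glance genorm_fit
#' @export
glance.genorm_fit <- function(x, ...) {
  tibble(
    n_genes = length(x$ranking),
    optimal_n = x$optimal_n,
    cutoff = x$cutoff,
    v_2_3 = x$v$v[x$v$n == 2]
  )
}

#' @rdname genorm
#' @param object A `genorm_fit` object.
#' @method autoplot genorm_fit
#' @export
autoplot.genorm_fit <- function(object, ...) {
  # Average M of the remaining genes per exclusion round, the classic
  # "stepwise exclusion" curve, alongside the V-series bars.
  traj <- object$trajectory %>%
    group_by(.data$round, .data$n_genes) %>%
    summarise(mean_m = mean(.data$m), .groups = "drop")
  p1 <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$n_genes, y = .data$mean_m)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = traj$n_genes) +
    ggplot2::labs(x = "genes remaining", y = "average M") +
    ggplot2::theme_minimal()
  vdat <- object$v %>% mutate(label = paste0("V", .data$n, "/", .data$n + 1))
  p2 <- ggplot2::ggplot(vdat, ggplot2::aes(x = .data$label, y = .data$v)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = NULL, y = "pairwise variation V") +
    ggplot2::theme_minimal()
  list(m_trajectory = p1, v_series = p2)
}
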