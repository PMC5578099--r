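# Model-based stability estimation (NormFinder family).
#
# On log2 relative quantities, each gene's variation is decomposed into an
# intra-group variance (residual noise after removing sample- and
# gene-level effects within the group) and an inter-group difference that
# is shrunk toward zero according to how noisy its estimate is. The
# stability value combines both: genes can look stable within groups yet be
# regulated between outcome groups, and vice versa.

#' Model-based stability values with intra- and inter-group components
#'
#' With two outcome groups (sPTB/TB), for gene `i` in group `g` with
#' `n_g` samples and `k` genes:
#' residuals `r = x - rowmean - colmean + grandmean` within the group give
#' the raw variance `v_ig = sum(r^2) / ((n_g - 1)(1 - 2/k))`; the
#' bias-adjusted intra-group variance is
#' `sigma2_ig = max(v_ig - mean_i(v_ig)/(k - 1), 0)`. The inter-group
#' difference `d_ig` (gene-by-group interaction of the group means) is
#' shrunk by `gamma2_g / (gamma2_g + sigma2_ig/n_g)` where
#' `gamma2_g = max(var_i(d_ig) - mean_i(sigma2_ig/n_g), 0)`. The stability
#' value is `rho_i = mean_g(|d_shrunk_ig| + sqrt(sigma2_ig/n_g))`; with a
#' single group, `rho_i = sqrt(sigma2_i)`. Lower rho = more stable.
#'
#' @param q Wide relative-quantity tibble (`gene` + sample columns,
#'   >= 3 genes).
#' @param design Tibble mapping samples to outcome groups: columns
#'   `sample_id` (or `library_id`) and `outcome` (values sPTB/TB); each
#'   group needs >= 2 samples. Omit or pass a single-group design for the
#'   one-group variant.
#' @return An object of class `normfinder_fit`: `stability` (tibble:
#'   `gene`, `rho`, `rank`), `components` (tibble: `gene`, `group`, `n`,
#'   `sigma2`, `d`, `d_shrunk`), `n_groups`.
#' @examples
#' sim <- simulate_cq(n_genes = 5, n_samples_per_group = c(8, 8),
#'                    noise_sd = c(0.05, 0.1, 0.2, 0.4, 0.8), seed = 5)
#' fit <- normfinder_stability(cq_to_relative_quantity(sim$cq), sim$design)
#' tidy(fit)
#' @export
normfinder_stability <- function(q, design = NULL) {
  m <- quantities_to_matrix(q)
  k <- nrow(m)
  if (k < 3) abort("At least 3 genes are required (variance correction undefined).")
  x <- log2(m)

  if (is.null(design)) {
    grp <- rep("all", ncol(m))
  } else {
    key <- if ("sample_id" %in% names(design)) "sample_id" else "library_id"
    if (!all(c(key, "outcome") %in% names(design))) {
      abort("Design needs `sample_id` (or `library_id`) and `outcome` columns.")
    }
    idx <- match(colnames(m), design[[key]])
    if (anyNA(idx)) {
      abort(paste0(
        "Samples absent from design: ",
        paste(colnames(m)[is.na(idx)], collapse = ", ")
      ))
    }
    grp <- as.character(design$outcome[idx])
  }
  groups <- unique(grp)
  if (length(groups) > 2) abort("At most 2 outcome groups are supported.")
  n_g <- table(grp)
  if (any(n_g < 2)) {
    abort(paste0(
      "Each group needs >= 2 samples; too small: ",
      paste(names(n_g)[n_g < 2], collapse = ", ")
    ))
  }

  # Per-group intra-group variances.
  comp <- purrr::map(groups, function(g) {
    xg <- x[, grp == g, drop = FALSE]
    ng <- ncol(xg)
    r <- xg - rowMeans(xg) -
      matrix(colMeans(xg), k, ng, byrow = TRUE) + mean(xg)
    v <- rowSums(r^2) / ((ng - 1) * (1 - 2 / k))
    sigma2 <- pmax(v - mean(v) / (k - 1), 0)
    tibble(gene = rownames(m), group = g, n = ng, sigma2 = unname(sigma2))
  }) %>% bind_rows()

  if (length(groups) == 1) {
    stab <- comp %>%
      mutate(rho = sqrt(.data$sigma2), d = 0, d_shrunk = 0)
    components <- stab %>% select("gene", "group", "n", "sigma2", "d", "d_shrunk")
    rho <- stab %>% select("gene", "rho")
  } else {
    # Gene-by-group interaction of means: how much gene i's group mean
    # departs from what gene- and group-level effects alone predict.
    d_tbl <- purrr::map(groups, function(g) {
      xg <- x[, grp == g, drop = FALSE]
      tibble(
        gene = rownames(m), group = g,
        d = (rowMeans(xg) - rowMeans(x)) - (mean(xg) - mean(x))
      )
    }) %>% bind_rows()
    comp <- left_join(comp, d_tbl, by = c("gene", "group"))
    comp <- comp %>%
      group_by(.data$group) %>%
      mutate(
        gamma2 = max(var(.data$d) - mean(.data$sigma2 / .data$n), 0),
        # gamma2 = 0 shrinks fully; guard the 0/0 when sigma2 is also 0
        d_shrunk = dplyr::if_else(
          .data$gamma2 + .data$sigma2 / .data$n > 0,
          .data$d * .data$gamma2 / (.data$gamma2 + .data$sigma2 / .data$n),
          0
        )
      ) %>%
      ungroup()
    rho <- comp %>%
      group_by(.data$gene) %>%
      summarise(
        rho = mean(abs(.data$d_shrunk) + sqrt(.data$sigma2 / .data$n)),
        .groups = "drop"
      )
    components <- comp %>% select("gene", "group", "n", "sigma2", "d", "d_shrunk")
  }

  stability <- rho %>%
    arrange(.data$rho, .data$gene) %>%
    mutate(rank = dplyr::row_number()) %>%
    arrange(.data$gene)
  structure(
    list(stability = stability, components = components,
         n_groups = length(groups)),
    class = "normfinder_fit"
  )
}

#' Genes ordered by ascending stability value
#'
#' Ties are broken by lexicographic gene name.
#'
#' @param fit A [normfinder_stability()] result.
#' @return Character vector, most stable first.
#' @export
rank_by_stability <- function(fit) {
  stopifnot(inherits(fit, "normfinder_fit"))
  fit$stability %>% arrange(.data$rank) %>% pull("gene")
}

#' @export
print.normfinder_fit <- function(x, ...) {
  cat("Model-based stability analysis (", x$n_groups, " group",
      if (x$n_groups > 1) "s", ")\n", sep = "")
  ord <- x$stability %>% arrange(.data$rank)
  cat("  ranking: ", paste(ord$gene, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' @rdname normfinder_stability
#' @param x A `normfinder_fit` object.
#' @param ... Unused.
#' @method tidy normfinder_fit
#' @export
tidy.normfinder_fit <- function(x, ...) {
  x$stability %>% arrange(.data$rank)
}

#' @rdname normfinder_stability
#' @method glance normfinder_fit
#' @export
glance.normfinder_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$stability),
    n_groups = x$n_groups,
    most_stable = rank_by_stability(x)[1]
  )
}

#' @rdname normfinder_stability
#' @param object A `normfinder_fit` object.
#' @method autoplot normfinder_fit
#' @export
autoplot.normfinder_fit <- function(object, ...) {
  dat <- object$stability %>% arrange(.data$rho)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$gene, levels = .data$gene), y = .data$rho
  )) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "stability value (lower = more stable)") +
    ggplot2::theme_minimal()
}
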