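# Replicate-based removal of unwanted variation (RUVs).
#
# Technical replicates of the same blood sample share all biology, so any
# systematic difference between them is unwanted (library-level) variation.
# Centering log counts within each replicate group cancels biology for
# every exon; the dominant directions of the centered matrix estimate the
# unwanted-variation loadings, and each library's factor score is obtained
# by least-squares projection of its log counts onto those loadings.

#' Upper-quartile library-size normalization
#'
#' Scales each library so that its upper quartile of positive counts equals
#' the across-library geometric mean of upper quartiles. Relative
#' proportions within a library are unchanged; a pure sequencing-depth
#' difference between two libraries is removed exactly.
#'
#' @param counts Wide count tibble (`exon_id` + one numeric column per
#'   library).
#' @return A count tibble of the same shape with scaled (possibly
#'   fractional) values.
#' @examples
#' counts <- tibble::tibble(exon_id = c("e1", "e2"), A = c(2, 6), B = c(4, 12))
#' library_size_normalize(counts)
#' @export
library_size_normalize <- function(counts) {
  m <- counts_to_matrix(counts)
  uq <- apply(m, 2, function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0) return(NA_real_)
    quantile(pos, 0.75, names = FALSE)
  })
  if (anyNA(uq)) {
    abort(paste0(
      "All-zero library(ies): ",
      paste(colnames(m)[is.na(uq)], collapse = ", ")
    ))
  }
  target <- geomean(uq)
  scaled <- sweep(m, 2, target / uq, "*")
  matrix_to_tbl(scaled, id_column(counts))
}

#' Fit a replicate-based unwanted-variation model
#'
#' On `Y = log(counts + offset)`, columns are centered within each
#' technical-replicate group (per exon), the centered columns are pooled and
#' decomposed by SVD, and the top-`k` left singular vectors become the exon
#' loadings `alpha`. Factor scores `W` for every library are the
#' least-squares projection of its `Y` column onto `alpha`, centered so the
#' average correction across libraries is zero.
#'
#' @param counts Wide count tibble.
#' @param design Sample design tibble (`library_id`, `subject_id`,
#'   `replicate_group`, `outcome`) covering every library.
#' @param k Number of unwanted factors (>= 0).
#' @param offset Pseudocount added before taking logs.
#' @return An object of class `ruv_fit`: list with `k`, `W` (library x k),
#'   `alpha` (k x exon), `offset`, `singular_values` and
#'   `var_explained` (fraction of replicate-centered variance per factor).
#' @examples
#' sim <- simulate_counts(sim_config(n_subjects = 6, n_exons = 80, seed = 2))
#' fit <- fit_ruvs(sim$counts, sim$design, k = 1)
#' glance(fit)
#' @export
fit_ruvs <- function(counts, design, k = 1, offset = 1) {
  m <- counts_to_matrix(counts)
  check_design(design, colnames(m))
  if (k < 0) abort("k must be >= 0.")

  y <- log(m + offset)
  lib_groups <- design$replicate_group[match(colnames(m), design$library_id)]
  groups <- split(seq_len(ncol(m)), lib_groups)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]

  empty_fit <- function(sv = numeric(0)) {
    structure(
      list(
        k = 0L,
        W = matrix(0, nrow = ncol(m), ncol = 0,
                   dimnames = list(colnames(m), NULL)),
        alpha = matrix(0, nrow = 0, ncol = nrow(m),
                       dimnames = list(NULL, rownames(m))),
        offset = offset,
        singular_values = sv,
        var_explained = numeric(0)
      ),
      class = "ruv_fit"
    )
  }
  if (k == 0) return(empty_fit())
  if (length(groups) == 0) {
    abort("k >= 1 requires at least one replicate group with >= 2 libraries.")
  }
  max_k <- min(sum(vapply(groups, length, integer(1)) - 1L), nrow(m))
  if (k > max_k) {
    abort(paste0(
      "k = ", k, " exceeds the admissible rank; maximum admissible k is ",
      max_k, "."
    ))
  }

  centered <- do.call(cbind, lapply(groups, function(idx) {
    y[, idx, drop = FALSE] - rowMeans(y[, idx, drop = FALSE])
  }))
  if (all(abs(centered) < 1e-12)) {
    warn("Replicate libraries are identical: no unwanted variation to estimate.")
    return(empty_fit())
  }

  dec <- svd(centered)
  alpha <- t(dec$u[, seq_len(k), drop = FALSE])   # k x exon, orthonormal rows
  colnames(alpha) <- rownames(m)
  w <- t(y) %*% t(alpha)                          # least squares: alpha orthonormal
  w <- sweep(w, 2, colMeans(w))                   # zero-mean correction
  dimnames(w) <- list(colnames(m), paste0("W", seq_len(k)))
  rownames(alpha) <- paste0("W", seq_len(k))

  sv2 <- dec$d^2
  structure(
    list(
      k = as.integer(k),
      W = w,
      alpha = alpha,
      offset = offset,
      singular_values = dec$d[seq_len(k)],
      var_explained = sv2[seq_len(k)] / sum(sv2)
    ),
    class = "ruv_fit"
  )
}

#' Remove fitted unwanted variation from a count matrix
#'
#' Returns `exp(log(counts + offset) - W %*% alpha) - offset`, clipped at
#' zero. With `k = 0` the input is returned unchanged.
#'
#' @param counts Wide count tibble on the same exon set the model was
#'   fitted on.
#' @param model A [fit_ruvs()] object.
#' @return A normalized count tibble (fractional values allowed).
#' @export
normalize_ruvs <- function(counts, model) {
  stopifnot(inherits(model, "ruv_fit"))
  m <- counts_to_matrix(counts)
  if (model$k == 0) return(counts)
  if (!identical(rownames(m), colnames(model$alpha)) ||
      !identical(colnames(m), rownames(model$W))) {
    abort("Counts do not match the exons/libraries the model was fitted on.")
  }
  y <- log(m + model$offset)
  adj <- y - t(model$W %*% model$alpha)
  out <- pmax(exp(adj) - model$offset, 0)
  matrix_to_tbl(out, id_column(counts))
}

#' Mean within-replicate-group disagreement of log counts
#'
#' The mean absolute deviation of `log(counts + offset)` from the replicate
#' group mean, across exons and replicated libraries. Smaller is better;
#' RUV normalization should reduce it.
#'
#' @inheritParams fit_ruvs
#' @return A single non-negative number.
#' @export
replicate_disagreement <- function(counts, design, offset = 1) {
  m <- counts_to_matrix(counts)
  check_design(design, colnames(m))
  y <- log(m + offset)
  lib_groups <- design$replicate_group[match(colnames(m), design$library_id)]
  groups <- split(seq_len(ncol(m)), lib_groups)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) abort("No replicate group with >= 2 libraries.")
  devs <- lapply(groups, function(idx) {
    abs(y[, idx, drop = FALSE] - rowMeans(y[, idx, drop = FALSE]))
  })
  mean(unlist(devs))
}

#' @export
print.ruv_fit <- function(x, ...) {
  cat("Replicate-based RUV model\n")
  cat("  factors (k):   ", x$k, "\n", sep = "")
  cat("  log pseudocount:", x$offset, "\n")
  if (x$k > 0) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname fit_ruvs
#' @param x A `ruv_fit` object.
#' @param ... Unused.
#' @method tidy ruv_fit
#' @export
tidy.ruv_fit <- function(x, ...) {
  if (x$k == 0) {
    return(tibble(library_id = character(0), factor = integer(0),
                  score = numeric(0)))
  }
  as_tibble(x$W, rownames = "library_id") %>%
    tidyr::pivot_longer(-"library_id", names_to = "factor", values_to = "score") %>%
    mutate(factor = match(.data$factor, unique(.data$factor)))
}

#' @rdname fit_ruvs
#' @method glance ruv_fit
#' @export
glance.ruv_fit <- function(x, ...) {
  tibble(
    k = x$k,
    offset = x$offset,
    total_var_explained = sum(x$var_explained)
  )
}
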