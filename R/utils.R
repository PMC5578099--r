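# Shared representation helpers.
#
# Wide tibbles are the user-facing containers throughout:
#   * counts: first column `exon_id`, one numeric column per library.
#   * relative quantities: first column `gene`, one numeric column per sample.
# Internally both are converted to plain matrices (rows named by the key
# column) for the linear algebra, then back.

id_column <- function(tbl) names(tbl)[1]

#' Convert a wide feature table to a numeric matrix
#'
#' The first column supplies row names; all remaining columns must be
#' numeric. Used internally, exported because it is handy when interfacing
#' with matrix-based tools.
#'
#' @param tbl A wide tibble (first column = feature IDs).
#' @return A numeric matrix with row names from the first column.
#' @export
as_feature_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate ", id_column(tbl), " values: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  vals <- tbl[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric value columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

matrix_to_tbl <- function(m, key) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!key := rownames(m)), out)
  out
}

counts_to_matrix <- function(counts) {
  m <- as_feature_matrix(counts)
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("Count values must be finite and non-negative.")
  }
  m
}

quantities_to_matrix <- function(q) {
  m <- as_feature_matrix(q)
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("Relative quantities must be finite and strictly positive.")
  }
  m
}

check_design <- function(design, library_ids = NULL) {
  req <- c("library_id", "subject_id", "replicate_group", "outcome")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Sample design is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(design$library_id)) {
    abort("Sample design has duplicate library_id entries.")
  }
  bad <- setdiff(unique(design$outcome), c("sPTB", "TB"))
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown outcome label(s): ", paste(bad, collapse = ", "),
      " (allowed: sPTB, TB)"
    ))
  }
  if (!is.null(library_ids)) {
    absent <- setdiff(library_ids, design$library_id)
    if (length(absent) > 0) {
      abort(paste0(
        "Libraries absent from design: ", paste(absent, collapse = ", ")
      ))
    }
  }
  invisible(design)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Spearman rank correlation with the two-sided t approximation for p.
# Shared by the screening and concordance layers.
spearman_rp <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant input: Spearman correlation undefined.")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the Spearman correlation between two numeric vectors (average
#' ranks for ties) and a two-sided p-value from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A one-row tibble with columns `r`, `p` and `n`.
#' @examples
#' spearman_cor(1:6, c(2, 1, 3, 4, 6, 5))
#' @export
spearman_cor <- function(x, y) {
  res <- spearman_rp(x, y)
  tibble(r = res$r, p = res$p, n = length(x))
}
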