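# Independent oracles and small fixture builders used across test files.

# Brute-force M values: explicit double loop over gene pairs on the raw
# matrix, no shared code with the package internals.
oracle_m <- function(qmat) {
  genes <- rownames(qmat)
  out <- numeric(length(genes))
  for (j in seq_along(genes)) {
    vs <- c()
    for (l in seq_along(genes)) {
      if (l == j) next
      vs <- c(vs, sd(log2(qmat[j, ] / qmat[l, ])))
    }
    out[j] <- mean(vs)
  }
  names(out) <- genes
  out
}

# Brute-force stepwise exclusion using oracle_m only.
oracle_stepwise <- function(qmat) {
  remaining <- qmat
  excluded <- character(0)
  while (nrow(remaining) > 2) {
    mv <- oracle_m(remaining)
    worst <- max(mv)
    cand <- sort(names(mv)[mv >= worst - 1e-15])
    drop_gene <- cand[length(cand)]
    excluded <- c(excluded, drop_gene)
    remaining <- remaining[setdiff(rownames(remaining), drop_gene), , drop = FALSE]
  }
  c(sort(rownames(remaining)), rev(excluded))
}

# Random positive relative-quantity matrix as a wide tibble.
random_q <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, sd = 1.5),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  q_tbl(m)
}

# Wide tibble from a gene x sample matrix.
q_tbl <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(m))
}

# Minimal design for a set of libraries, one subject per library.
flat_design <- function(lib_ids, outcome = NULL) {
  if (is.null(outcome)) outcome <- rep_len(c("sPTB", "TB"), length(lib_ids))
  tibble::tibble(
    library_id = lib_ids, subject_id = lib_ids,
    replicate_group = lib_ids, outcome = outcome
  )
}

# Noise ladder used for the stability-recovery study: spacing chosen so
# adjacent genes are roughly equally discriminable by the variance
# estimator at 50 samples per group.
recovery_noise_ladder <- c(0.2, 0.4, 0.6, 0.85, 1.15, 1.5, 1.95, 2.5)
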