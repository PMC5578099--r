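# Synthetic data with known ground truth.
#
# The generator emulates the structure of an exon-level whole-blood RNA-seq
# screen: ~19 subjects sequenced as two technical replicates each, negative
# binomial counts whose means span roughly 1 to 16,000, one or two
# library-level unwanted-variation factors acting multiplicatively on the
# mean, and a subset of "stable" exons with low biological variability.

#' Configuration for the count simulator
#'
#' @param n_subjects Number of blood samples (biological subjects).
#' @param replicates_per_subject Technical replicate libraries per subject.
#' @param n_exons Number of simulated exons.
#' @param mean_count_range Length-2 positive range; exon baseline means are
#'   drawn log-uniformly over it.
#' @param dispersion Negative-binomial size parameter shared by all exons;
#'   larger values approach Poisson noise.
#' @param n_uv_factors Number of library-level unwanted-variation factors.
#' @param stable_fraction Fraction of exons given a small biological
#'   (between-subject) log-SD; these are the true "stable" exons.
#' @param stable_sd,variable_sd_range Between-subject log-normal SD for the
#'   stable exons, and the uniform range it is drawn from for the rest.
#' @param uv_sd Standard deviation of each per-exon unwanted-variation
#'   loading.
#' @param seed Integer seed; all randomness in [simulate_counts()] flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 19,
                       replicates_per_subject = 2,
                       n_exons = 2000,
                       mean_count_range = c(1, 16000),
                       dispersion = 8,
                       n_uv_factors = 1,
                       stable_fraction = 0.1,
                       stable_sd = 0.05,
                       variable_sd_range = c(0.2, 0.8),
                       uv_sd = 0.25,
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    replicates_per_subject = replicates_per_subject,
    n_exons = n_exons,
    mean_count_range = mean_count_range,
    dispersion = dispersion,
    n_uv_factors = n_uv_factors,
    stable_fraction = stable_fraction,
    stable_sd = stable_sd,
    variable_sd_range = variable_sd_range,
    uv_sd = uv_sd,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(paste0("Invalid simulation config: `", field, "` ", msg))
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2) {
    bad("n_subjects", "must be >= 2")
  }
  if (cfg$replicates_per_subject < 1) bad("replicates_per_subject", "must be >= 1")
  if (cfg$n_exons < 2) bad("n_exons", "must be >= 2")
  if (length(cfg$mean_count_range) != 2 || any(cfg$mean_count_range <= 0) ||
      diff(cfg$mean_count_range) < 0) {
    bad("mean_count_range", "must be a positive increasing interval")
  }
  if (cfg$dispersion <= 0) bad("dispersion", "must be > 0")
  if (cfg$n_uv_factors < 0) bad("n_uv_factors", "must be >= 0")
  if (cfg$stable_fraction < 0 || cfg$stable_fraction > 1) {
    bad("stable_fraction", "must be in [0, 1]")
  }
  invisible(cfg)
}

#' Simulate an exon-by-library count matrix with technical replicates
#'
#' Counts are negative binomial around exon-specific means. Each subject has
#' a biological expression level per exon (shared by that subject's
#' technical replicates), while unwanted variation is drawn per library and
#' enters multiplicatively on the mean (`exp(loading * factor)`), matching
#' the factor-analysis model that replicate-based RUV assumes.
#'
#' @param config A [sim_config()].
#' @param uv_loadings Optional `n_exons x n_uv_factors` matrix overriding the
#'   randomly drawn loadings (recycled if a single number).
#' @return A list with elements `counts` (wide tibble, `exon_id` + one
#'   column per library), `design` (tibble: `library_id`, `subject_id`,
#'   `replicate_group`, `outcome`) and `truth` (list recording
#'   `stable_exon_ids`, `uv_factor`, `uv_loadings`, `bio_sd`, `base_mean`).
#' @examples
#' sim <- simulate_counts(sim_config(n_subjects = 4, n_exons = 50, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config = sim_config(), uv_loadings = NULL) {
  validate_sim_config(config)
  rng <- local_rng(config$seed)

  n_lib <- config$n_subjects * config$replicates_per_subject
  exon_ids <- sprintf("ENSE%011d", seq_len(config$n_exons))
  subj_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  lib_ids <- paste0(
    rep(subj_ids, each = config$replicates_per_subject), "_R",
    rep(seq_len(config$replicates_per_subject), config$n_subjects)
  )
  # Alternate outcome labels so both groups are populated.
  outcome <- rep(
    rep_len(c("sPTB", "TB"), config$n_subjects),
    each = config$replicates_per_subject
  )

  base_mean <- exp(runif(
    config$n_exons,
    log(config$mean_count_range[1]), log(config$mean_count_range[2])
  ))
  n_stable <- round(config$stable_fraction * config$n_exons)
  stable_idx <- if (n_stable > 0) {
    sample.int(config$n_exons, n_stable)
  } else {
    integer(0)
  }
  bio_sd <- runif(
    config$n_exons, config$variable_sd_range[1], config$variable_sd_range[2]
  )
  bio_sd[stable_idx] <- config$stable_sd

  # Subject-level biological effects, shared across technical replicates.
  bio <- matrix(
    rnorm(config$n_exons * config$n_subjects, sd = bio_sd),
    nrow = config$n_exons
  )
  log_mu <- log(base_mean) + bio[, rep(seq_len(config$n_subjects),
                                       each = config$replicates_per_subject)]

  if (config$n_uv_factors > 0) {
    uv_factor <- matrix(rnorm(n_lib * config$n_uv_factors), ncol = config$n_uv_factors)
    if (is.null(uv_loadings)) {
      uv_loadings <- matrix(
        rnorm(config$n_exons * config$n_uv_factors, sd = config$uv_sd),
        ncol = config$n_uv_factors
      )
    } else {
      uv_loadings <- matrix(uv_loadings,
                            nrow = config$n_exons, ncol = config$n_uv_factors)
    }
    log_mu <- log_mu + uv_loadings %*% t(uv_factor)
  } else {
    uv_factor <- matrix(numeric(0), nrow = n_lib, ncol = 0)
    uv_loadings <- matrix(numeric(0), nrow = config$n_exons, ncol = 0)
  }

  counts <- matrix(
    rnbinom(config$n_exons * n_lib, size = config$dispersion, mu = exp(log_mu)),
    nrow = config$n_exons, dimnames = list(exon_ids, lib_ids)
  )

  design <- tibble(
    library_id = lib_ids,
    subject_id = rep(subj_ids, each = config$replicates_per_subject),
    replicate_group = rep(subj_ids, each = config$replicates_per_subject),
    outcome = outcome
  )
  truth <- list(
    stable_exon_ids = exon_ids[sort(stable_idx)],
    uv_factor = uv_factor,
    uv_loadings = uv_loadings,
    bio_sd = setNames(bio_sd, exon_ids),
    base_mean = setNames(base_mean, exon_ids)
  )
  list(counts = matrix_to_tbl(counts, "exon_id"), design = design, truth = truth)
}

#' Simulate a Cq table for a two-group qPCR stability study
#'
#' Per-gene Cq values are generated on the quantification-cycle scale from a
#' log2-expression model: an inter-group shift (applied to the second,
#' term-birth group), a shared per-sample offset emulating RNA input-amount
#' variation, and intra-group Gaussian noise. Both the offset and the noise
#' are specified on the log2-expression scale and divided by `log2(E)` per
#' gene, so `noise_sd` is an expression-scale SD regardless of assay
#' efficiency.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Length-2 integer vector: samples in the sPTB
#'   and TB groups.
#' @param noise_sd Per-gene intra-group log2-expression SD (recycled).
#' @param group_shift Per-gene log2 inter-group offset (recycled).
#' @param efficiency Per-gene PCR efficiency in (1, 2.2] (recycled).
#' @param sample_offset_sd SD of the shared per-sample log2 offset.
#' @param base_cq Per-gene baseline Cq (recycled).
#' @param seed Integer seed.
#' @return A list with `cq` (long tibble: `gene`, `sample_id`, `cq`,
#'   `efficiency`), `design` (tibble: `sample_id`, `outcome`) and `truth`
#'   (list with `noise_sd`, `group_shift`, `sample_offset`).
#' @examples
#' sim <- simulate_cq(n_genes = 4, n_samples_per_group = c(5, 5),
#'                    noise_sd = c(0, 0.2, 0.4, 0.8), seed = 3)
#' head(sim$cq)
#' @export
simulate_cq <- function(n_genes,
                        n_samples_per_group = c(17, 15),
                        noise_sd = 0.25,
                        group_shift = 0,
                        efficiency = 2,
                        sample_offset_sd = 0.5,
                        base_cq = 25,
                        seed = 1L) {
  if (any(noise_sd < 0)) abort("All noise_sd must be >= 0.")
  if (any(efficiency <= 1)) abort("All efficiencies must be > 1.")
  if (length(n_samples_per_group) != 2 || any(n_samples_per_group < 1)) {
    abort("n_samples_per_group must give two positive group sizes.")
  }
  rng <- local_rng(seed)

  genes <- sprintf("G%02d", seq_len(n_genes))
  noise_sd <- rep_len(noise_sd, n_genes)
  group_shift <- rep_len(group_shift, n_genes)
  efficiency <- rep_len(efficiency, n_genes)
  base_cq <- rep_len(base_cq, n_genes)

  n_samples <- sum(n_samples_per_group)
  sample_ids <- sprintf("P%02d", seq_len(n_samples))
  outcome <- rep(c("sPTB", "TB"), n_samples_per_group)
  offset <- if (sample_offset_sd > 0) {
    rnorm(n_samples, sd = sample_offset_sd)
  } else {
    rep(0, n_samples)
  }

  rows <- purrr::map(seq_len(n_genes), function(i) {
    le <- log2(efficiency[i])
    shift <- ifelse(outcome == "TB", group_shift[i], 0)
    noise <- if (noise_sd[i] > 0) rnorm(n_samples, sd = noise_sd[i]) else rep(0, n_samples)
    tibble(
      gene = genes[i],
      sample_id = sample_ids,
      cq = base_cq[i] - shift / le - offset / le + noise / le,
      efficiency = efficiency[i]
    )
  })
  cq <- bind_rows(rows)
  design <- tibble(sample_id = sample_ids, outcome = outcome)
  truth <- list(
    noise_sd = setNames(noise_sd, genes),
    group_shift = setNames(group_shift, genes),
    sample_offset = setNames(offset, sample_ids)
  )
  list(cq = cq, design = design, truth = truth)
}

# Seed an isolated RNG stream for the calling function and restore the
# global state on exit.
local_rng <- function(seed, env = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("Invalid simulation config: `seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  withr::defer(
    {
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    },
    envir = env
  )
  set.seed(as.integer(seed))
  invisible(seed)
}
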