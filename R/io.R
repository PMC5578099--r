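# Readers and writers for the pipeline's tabular formats: TSV for count
# matrices (HTSeq-style layout), CSV for sample sheets and Cq exports.

#' Read an exon-by-library count matrix from TSV
#'
#' First column = exon IDs, header = library IDs, all other cells numeric.
#'
#' @param path Path to a tab-separated file.
#' @return A wide count tibble (`exon_id` + one column per library).
#' @export
read_count_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tbl) < 2) abort("Count matrix needs an ID column and >= 1 library.")
  names(tbl)[1] <- "exon_id"
  tbl$exon_id <- as.character(tbl$exon_id)
  if (anyDuplicated(tbl$exon_id)) {
    abort(paste0(
      "Duplicate exon ID(s): ",
      paste(unique(tbl$exon_id[duplicated(tbl$exon_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(names(tbl))) {
    abort("Duplicate library ID(s) in header.")
  }
  for (col in names(tbl)[-1]) {
    if (!is.numeric(tbl[[col]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(tbl[[col]]))))[1]
      abort(paste0(
        "Non-numeric count in column `", col, "`, data row ", bad_row, "."
      ))
    }
  }
  counts_to_matrix(tbl)  # validates non-negativity / finiteness
  tbl
}

#' Write a count matrix to TSV
#'
#' @param counts Wide count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample design sheet from CSV
#'
#' Requires columns `library_id`, `subject_id`, `replicate_group`,
#' `outcome`; outcome values must be `sPTB` or `TB`.
#'
#' @param path Path to a CSV file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  check_design(design)
  design
}

#' Read a Cq table from CSV
#'
#' Requires columns `gene`, `sample_id`, `cq`, `efficiency`; efficiencies
#' must be > 1.
#'
#' @param path Path to a CSV file.
#' @return A long Cq tibble.
#' @export
read_cq <- function(path) {
  cq <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene", "sample_id", "cq", "efficiency")
  missing_cols <- setdiff(req, names(cq))
  if (length(missing_cols) > 0) {
    abort(paste0("Cq file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(cq$efficiency <= 1)) {
    abort("PCR efficiencies must be > 1 (2 = perfect doubling).")
  }
  cq
}

#' Write the full set of pipeline reports
#'
#' Writes `candidates.tsv` (screening panel), `genorm.json` (ranking, M
#' trajectory, V series, optimal n), `normfinder.tsv` (stability values and
#' components), `concordance.tsv`, and `run_metadata.json` (config, seeds,
#' package version). Only components present in `results` are written;
#' numeric columns are serialized unrounded with display-rounded `cv_pct`
#' added where relevant.
#'
#' @param results Named list with any of `panel`, `stats`, `genorm`,
#'   `normfinder`, `concordance`.
#' @param outdir Output directory (created if absent).
#' @param config Optional list recorded in the metadata file.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, outdir, config = list()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)

  if (!is.null(results$panel)) {
    p <- file.path(outdir, "candidates.tsv")
    panel <- as_tibble(results$panel)
    if (nrow(panel) > 0 && all(c("mean", "sd") %in% names(panel))) {
      panel <- panel %>% mutate(cv_pct = cv_pct(.data$mean, .data$sd))
    }
    readr::write_tsv(panel, p)
    add(p)
  }
  if (!is.null(results$genorm)) {
    p <- file.path(outdir, "genorm.json")
    g <- results$genorm
    jsonlite::write_json(
      list(
        ranking = g$ranking,
        m = g$m,
        trajectory = g$trajectory,
        v_series = g$v,
        optimal_n = g$optimal_n,
        cutoff = g$cutoff
      ),
      p, auto_unbox = TRUE, digits = NA
    )
    add(p)
  }
  if (!is.null(results$normfinder)) {
    p <- file.path(outdir, "normfinder.tsv")
    readr::write_tsv(tidy(results$normfinder), p)
    add(p)
  }
  if (!is.null(results$concordance)) {
    p <- file.path(outdir, "concordance.tsv")
    readr::write_tsv(tidy(results$concordance), p)
    add(p)
  }
  meta <- file.path(outdir, "run_metadata.json")
  jsonlite::write_json(
    list(
      package = "refstab",
      version = as.character(utils::packageVersion("refstab")),
      config = config
    ),
    meta, auto_unbox = TRUE, digits = NA
  )
  add(meta)
  invisible(written)
}

#' Run the screening-plus-stability pipeline end to end
#'
#' Upper-quartile depth normalization, replicate-based RUV normalization,
#' robust-detection filtering, per-exon statistics, percentile selection and
#' level shortlisting on the count side; geNorm, model-based stability and
#' two-subset concordance on the Cq side. Either side may be omitted.
#'
#' @param counts,count_design Wide count tibble and its library design
#'   (optional).
#' @param cq,cq_design Long Cq tibble and its sample design (optional).
#' @param k Number of unwanted-variation factors (default 1).
#' @param percentile CV-selection percentile (default 10).
#' @param level_range Inclusive mean-count shortlisting range.
#' @param cutoff geNorm V-series cutoff.
#' @param seed Seed for the concordance partition.
#' @param gene_map Optional `exon_id`/`gene_id` tibble.
#' @param outdir Optional directory; when given, [write_report()] is called.
#' @return Named list with the computed components (`stats`, `panel`,
#'   `genorm`, `normfinder`, `concordance`, `ruv`).
#' @export
run_pipeline <- function(counts = NULL, count_design = NULL,
                         cq = NULL, cq_design = NULL,
                         k = 1, percentile = 10, level_range = c(5, 500),
                         cutoff = 0.15, seed = 1L, gene_map = NULL,
                         outdir = NULL) {
  results <- list()
  if (!is.null(counts)) {
    if (is.null(count_design)) abort("count_design is required with counts.")
    depth_norm <- library_size_normalize(counts)
    ruv <- fit_ruvs(depth_norm, count_design, k = k)
    normalized <- normalize_ruvs(depth_norm, ruv)
    robust <- filter_robust(normalized)
    stats <- exon_stats(robust, count_design, gene_map = gene_map)
    panel <- select_low_cv(stats, percentile = percentile) %>%
      shortlist_by_level(level_range[1], level_range[2])
    results$ruv <- ruv
    results$stats <- stats
    results$panel <- panel
  }
  if (!is.null(cq)) {
    q <- cq_to_relative_quantity(cq)
    results$genorm <- genorm(q, cutoff = cutoff)
    if (!is.null(cq_design)) {
      results$normfinder <- normfinder_stability(q, cq_design)
      results$concordance <- concordance(cq, cq_design, seed = seed,
                                         cutoff = cutoff)
    }
  }
  if (!is.null(outdir)) {
    write_report(results, outdir, config = list(
      k = k, percentile = percentile, level_range = level_range,
      cutoff = cutoff, seed = seed
    ))
  }
  results
}
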