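wide_counts <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(exon_id = sprintf("e%d", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = ~ sprintf("L%d", seq_along(.x)))
  )
}

test_that("robust filtering keeps exactly the exons detected in every library", {
  m <- rbind(c(1, 2, 3, 4),
             c(0, 5, 5, 5),
             c(2, 2, 2, 2),
             c(7, 0, 0, 1),
             c(0.5, 1, 1, 9))
  out <- filter_robust(wide_counts(m))
  expect_equal(out$exon_id, c("e1", "e3", "e5"))
  # all-positive input is the identity
  allpos <- wide_counts(matrix(1:8, 2))
  expect_identical(filter_robust(allpos), allpos)
  # a single zero entry excludes the exon
  onezero <- wide_counts(rbind(c(1, 1), c(1, 0)))
  expect_equal(filter_robust(onezero)$exon_id, "e1")
})

test_that("exon statistics use subject averages and the n-1 denominator", {
  counts <- wide_counts(matrix(c(1, 2, 3), nrow = 1))
  design <- flat_design(c("L1", "L2", "L3"))
  st <- exon_stats(counts, design)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  expect_equal(st$cv, 0.5)
  # constant exon
  stc <- exon_stats(wide_counts(matrix(c(2, 2, 2), nrow = 1)), design)
  expect_equal(stc$sd, 0)
  expect_equal(stc$cv, 0)
})

test_that("technical replicates are averaged per subject before the CV", {
  m <- matrix(c(10, 14, 20, 24, 30, 36), nrow = 1)
  counts <- wide_counts(m)
  design <- tibble::tibble(
    library_id = sprintf("L%d", 1:6),
    subject_id = rep(c("a", "b", "c"), each = 2),
    replicate_group = rep(c("a", "b", "c"), each = 2),
    outcome = rep(c("sPTB", "TB", "TB"), each = 2)
  )
  st <- exon_stats(counts, design)
  expect_equal(st$mean, mean(c(12, 22, 33)))
  expect_equal(st$sd, sd(c(12, 22, 33)))
  # without averaging, all six libraries enter
  st6 <- exon_stats(counts, design, average_replicates = FALSE)
  expect_equal(st6$sd, sd(m[1, ]))
})

test_that("exon statistics are invariant under library column permutation", {
  sim <- simulate_counts(sim_config(n_subjects = 5, n_exons = 30, seed = 14))
  st1 <- exon_stats(sim$counts, sim$design)
  perm <- sim$counts[, c(1, 1 + sample(ncol(sim$counts) - 1))]
  st2 <- exon_stats(perm, sim$design)
  expect_equal(st1, st2)
})

test_that("CV percentages reproduce the printed per-exon summaries", {
  expect_equal(cv_pct(1.3, 0.52), 40)
  expect_equal(cv_pct(85, 6.6), 8)
  expect_equal(cv_pct(0.45, 0.69), 153)
})

test_that("percentile selection interpolates order statistics and is strict", {
  st <- tibble::tibble(exon_id = sprintf("e%02d", 1:20),
                       mean = rep(10, 20), sd = 1:20 / 10, cv = 1:20)
  panel <- select_low_cv(st, percentile = 10)
  expect_equal(attr(panel, "cv_cutoff"), 2.9)
  expect_equal(panel$cv, c(1, 2))
  # all-equal CVs: nothing strictly below the percentile
  ties <- tibble::tibble(exon_id = c("a", "b", "c"), mean = 1, sd = 1, cv = 1)
  expect_equal(nrow(select_low_cv(ties, 10)), 0)
  expect_error(select_low_cv(st, 0), "percentile")
  expect_error(select_low_cv(st, 101), "percentile")
})

test_that("selection is monotone in the percentile and matches a brute-force count", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    cvs <- runif(n)
    st <- tibble::tibble(exon_id = sprintf("e%04d", seq_len(n)),
                         mean = 10, sd = cvs * 10, cv = cvs)
    p1 <- sample(5:50, 1)
    p2 <- p1 + sample(5:40, 1)
    sel1 <- select_low_cv(st, p1)$exon_id
    sel2 <- select_low_cv(st, min(p2, 100))$exon_id
    expect_true(all(sel1 %in% sel2))
    # brute force: count order statistics strictly below the interpolated cut
    srt <- sort(cvs)
    h <- (p1 / 100) * (n - 1)
    cut <- srt[floor(h) + 1] + (h - floor(h)) * (srt[min(floor(h) + 2, n)] - srt[floor(h) + 1])
    expect_equal(length(sel1), sum(cvs < cut))
  }
  # percentile 100 keeps everything except values tied at the maximum
  cvs <- c(0.1, 0.2, 0.3, 0.5, 0.5)
  st <- tibble::tibble(exon_id = letters[1:5], mean = 1, sd = cvs, cv = cvs)
  expect_equal(sort(select_low_cv(st, 100)$exon_id), c("a", "b", "c"))
})

test_that("level shortlisting keeps the stated count range inclusively", {
  st <- tibble::tibble(
    exon_id = c("hi", "mid1", "mid2", "lo", "edge5", "edge500"),
    mean = c(1000, 85, 34, 0.45, 5, 500),
    sd = c(10, 7, 3, 0.69, 1, 10),
    cv = c(0.01, 0.08, 0.09, 1.53, 0.2, 0.02)
  )
  panel <- select_low_cv(st, 99)
  short <- shortlist_by_level(panel)
  expect_setequal(short$exon_id, c("mid1", "mid2", "edge5", "edge500"))
  expect_false("lo" %in% short$exon_id)
  expect_equal(attr(short, "level_range"), c(5, 500))
  expect_error(shortlist_by_level(panel, 10, 5), "min_level")
})

test_that("mean-CV association follows the Spearman closed form", {
  st_up <- tibble::tibble(exon_id = letters[1:5], mean = 1:5,
                          sd = (1:5) * (1:5) / 10, cv = (1:5) / 10)
  expect_equal(mean_cv_association(st_up)$r, 1)
  st_dn <- st_up
  st_dn$cv <- rev(st_dn$cv)
  expect_equal(mean_cv_association(st_dn)$r, -1)
  # two swapped ranks out of 10: r = 1 - 6 * sum(d^2) / (n(n^2-1))
  mean10 <- 1:10
  cv10 <- c(1, 2, 3, 5, 4, 6, 7, 8, 9, 10) / 10
  st10 <- tibble::tibble(exon_id = letters[1:10], mean = mean10,
                         sd = cv10 * mean10, cv = cv10)
  expect_equal(mean_cv_association(st10)$r, 1 - 6 * 2 / (10 * 99))
})

test_that("one exon per gene: minimum CV with a lexicographic tie-break", {
  st <- tibble::tibble(
    exon_id = c("ENSE00001855680", "ENSE00001863979",
                "ENSE00001924900", "ENSE00001942031"),
    gene_id = "DDX17",
    mean = c(1.3, 1.6, 66, 85),
    sd = c(0.52, 0.55, 9.4, 6.6),
    cv = c(0.40, 0.34, 0.14, 0.08)
  )
  expect_equal(per_gene_best_exon(st)$exon_id, "ENSE00001942031")
  tie <- tibble::tibble(
    exon_id = c("b_exon", "a_exon"), gene_id = "G",
    mean = c(1, 1), sd = c(0.1, 0.1), cv = c(0.1, 0.1)
  )
  expect_equal(per_gene_best_exon(tie)$exon_id, "a_exon")
  single <- tibble::tibble(exon_id = "only", gene_id = "G2",
                           mean = 1, sd = 1, cv = 1)
  expect_equal(per_gene_best_exon(single)$exon_id, "only")
})
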