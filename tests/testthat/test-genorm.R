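test_that("relative quantities are efficiency powers of the Cq deficit", {
  cq <- tibble::tibble(gene = "g", sample_id = c("a", "b", "c"),
                       cq = c(20, 21, 22), efficiency = 2)
  q <- cq_to_relative_quantity(cq)
  expect_equal(unlist(q[1, c("a", "b", "c")], use.names = FALSE), c(1, 0.5, 0.25))
  # efficiency 1.9, delta Cq of 1
  cq19 <- tibble::tibble(gene = "g", sample_id = c("a", "b"),
                         cq = c(20, 21), efficiency = 1.9)
  expect_equal(cq_to_relative_quantity(cq19)$b, 1 / 1.9)
  # constant Cq: everything is the calibrator
  cqc <- tibble::tibble(gene = "g", sample_id = c("a", "b"),
                        cq = c(25, 25), efficiency = 2)
  expect_equal(unlist(cq_to_relative_quantity(cqc)[, -1], use.names = FALSE), c(1, 1))
})

test_that("incomplete or invalid Cq tables are rejected with coordinates", {
  cq <- tibble::tibble(gene = c("g1", "g1", "g2"),
                       sample_id = c("a", "b", "a"),
                       cq = c(20, 21, 22), efficiency = 2)
  expect_error(cq_to_relative_quantity(cq), "g2/b")
  bad_e <- tibble::tibble(gene = "g", sample_id = "a", cq = 20, efficiency = 1)
  expect_error(cq_to_relative_quantity(bad_e), "efficienc")
})

test_that("pairwise variation is the SD of log ratios and is symmetric", {
  q <- q_tbl(rbind(g1 = c(1, 1), g2 = c(1, 2)))
  expect_equal(pairwise_variation(q, "g1", "g2"), sd(c(0, -1)))
  # proportional genes have zero variation
  qp <- q_tbl(rbind(g1 = c(1, 2, 4), g2 = c(3, 6, 12)))
  expect_equal(pairwise_variation(qp, "g1", "g2"), 0)
  qr <- random_q(4, 6, seed = 2)
  expect_equal(pairwise_variation(qr, "g01", "g03"),
               pairwise_variation(qr, "g03", "g01"))
})

test_that("M values equal the brute-force pairwise average", {
  q <- random_q(3, 3, seed = 5)
  m <- stability_m(q)
  expect_equal(setNames(m$m, m$gene), oracle_m(as_feature_matrix(q)))
  # two genes: both M equal V12
  q2 <- q_tbl(rbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  m2 <- stability_m(q2)
  expect_equal(m2$m[1], m2$m[2])
  expect_equal(m2$m[1], pairwise_variation(q2, "a", "b"))
  # mutually proportional genes all have M = 0
  base <- c(1, 3, 9)
  qp <- q_tbl(rbind(a = base, b = 2 * base, c = 5 * base))
  expect_equal(stability_m(qp)$m, rep(0, 3))
})

test_that("stepwise exclusion matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    q <- random_q(sample(3:8, 1), sample(3:12, 1), seed = seed + 100)
    fit <- suppressMessages(rank_stepwise(q))
    expect_equal(fit$ranking, oracle_stepwise(as_feature_matrix(q)))
    mm <- stability_m(q)
    expect_equal(setNames(mm$m, mm$gene), oracle_m(as_feature_matrix(q)))
  }
})

test_that("a noisy gene is excluded first and the final pair shares rank 1", {
  base <- c(1, 2, 4, 8, 16, 32)
  set.seed(7)
  noisy <- base * 2^rnorm(6, sd = 1.5)
  q <- q_tbl(rbind(a = base, b = 2 * base, c = 5 * base, z = noisy))
  fit <- rank_stepwise(q)
  expect_equal(fit$ranking[4], "z")
  expect_equal(unname(fit$rank[fit$ranking[1:2]]), c(1L, 1L))
})

test_that("simulated noise ordering is recovered by the stepwise ranking", {
  sim <- simulate_cq(n_genes = 6, n_samples_per_group = c(15, 15),
                     noise_sd = c(0.05, 0.15, 0.3, 0.55, 0.9, 1.5), seed = 42)
  fit <- rank_stepwise(cq_to_relative_quantity(sim$cq))
  expect_equal(sort(fit$ranking[1:2]), c("G01", "G02"))
  expect_equal(fit$ranking[3:6], c("G03", "G04", "G05", "G06"))
})

test_that("normalization factors are geometric means of the top genes", {
  q <- q_tbl(rbind(g1 = c(1, 4), g2 = c(4, 1)))
  expect_equal(unname(normalization_factor(q, c("g1", "g2"), 2)), c(2, 2))
  expect_equal(unname(normalization_factor(q, c("g1", "g2"), 1)),
               unname(unlist(q[q$gene == "g1", -1])))
  # scaling one included gene by c scales NF_n by c^(1/n)
  q3 <- random_q(3, 5, seed = 3)
  nf <- normalization_factor(q3, c("g01", "g02", "g03"), 3)
  q3s <- q3
  q3s[q3s$gene == "g02", -1] <- q3s[q3s$gene == "g02", -1] * 8
  nfs <- normalization_factor(q3s, c("g01", "g02", "g03"), 3)
  expect_equal(nfs, nf * 8^(1 / 3))
  expect_error(normalization_factor(q3, c("g01", "g02", "g03"), 4), "between")
})

test_that("the V series matches a direct SD computation and stays non-negative", {
  q <- random_q(3, 6, seed = 11)
  ranking <- c("g01", "g02", "g03")
  v <- pairwise_v_series(q, ranking)
  nf2 <- normalization_factor(q, ranking, 2)
  nf3 <- normalization_factor(q, ranking, 3)
  expect_equal(v$v[v$n == 2], sd(log2(nf2 / nf3)))
  expect_true(all(v$v >= 0))
  # a gene proportional to NF_n contributes zero pairwise variation
  m <- as_feature_matrix(q)[1:2, ]
  extra <- apply(m, 2, function(x) exp(mean(log(x)))) * 3
  qz <- q_tbl(rbind(m, g04 = extra))
  vz <- pairwise_v_series(qz, c("g01", "g02", "g04"))
  expect_equal(vz$v[vz$n == 2], 0)
})

test_that("the optimal-n rule is inclusive at the cutoff", {
  expect_equal(optimal_n(c(0.15, 0.3)), 2L)
  expect_equal(optimal_n(c(0.2, 0.1)), 3L)
  expect_warning(n <- optimal_n(c(0.3, 0.2)), "No V value")
  expect_equal(n, 4L)
  v_tbl <- tibble::tibble(n = 2:4, v = c(0.21, 0.15, 0.08))
  expect_equal(optimal_n(v_tbl), 3L)
})

test_that("M and V are invariant to per-sample scaling and per-gene calibration", {
  for (seed in 1:10) {
    q <- random_q(5, 8, seed = seed)
    m <- as_feature_matrix(q)
    set.seed(seed + 500)
    sample_scale <- 2^rnorm(ncol(m))
    gene_scale <- 2^rnorm(nrow(m))
    q_scaled <- q_tbl(sweep(sweep(m, 2, sample_scale, "*"), 1, gene_scale, "*"))
    expect_equal(stability_m(q_scaled)$m, stability_m(q)$m, tolerance = 1e-9)
    rk <- c("g01", "g02", "g03", "g04", "g05")
    expect_equal(pairwise_v_series(q_scaled, rk)$v,
                 pairwise_v_series(q, rk)$v, tolerance = 1e-9)
  }
})

test_that("duplicating a gene never increases its M", {
  for (seed in 1:10) {
    q <- random_q(4, 6, seed = seed + 40)
    m <- as_feature_matrix(q)
    m_before <- oracle_m(m)["g02"]
    dup <- rbind(m, g02copy = m["g02", ])
    m_after <- oracle_m(dup)["g02"]
    expect_lte(m_after, m_before + 1e-12)
  }
})

test_that("the full geNorm wrapper assembles consistent components", {
  sim <- simulate_cq(n_genes = 5, n_samples_per_group = c(10, 10),
                     noise_sd = c(0.05, 0.1, 0.3, 0.6, 1.2), seed = 17)
  fit <- genorm(cq_to_relative_quantity(sim$cq))
  expect_s3_class(fit, "genorm_fit")
  expect_equal(sort(unique(fit$nf$n)), 2:5)
  expect_equal(fit$v$n, 2:4)
  expect_gte(fit$optimal_n, 2)
  td <- tidy(fit)
  expect_equal(sort(td$gene), sort(fit$ranking))
  expect_s3_class(autoplot(fit)$v_series, "ggplot")
})
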