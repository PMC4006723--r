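test_that("empirical p-values follow the add-one permutation rule", {
  set.seed(501)
  mask <- iv("chr1", 0, 2e5)
  # feature clustered where the origins are: strong enrichment
  origins <- iv("chr1", seq(0, 19) * 5000 + 100, seq(0, 19) * 5000 + 1100)
  feature <- iv("chr1", seq(0, 19) * 5000, seq(0, 19) * 5000 + 1500)
  res <- enrichment_test(origins, feature, mask, n_intervals = 300,
                         n_reps = 100, seed = 17, feature_label = "toy")
  expect_equal(res$observed_pct, 100)
  expect_equal(res$direction, "enriched")
  expect_gte(res$empirical_p, 1 / 101)
  expect_lt(res$expected_pct, res$observed_pct)

  # feature == whole mask: everything overlaps, nothing is exceptional
  res2 <- enrichment_test(origins, mask, mask, n_intervals = 200,
                          n_reps = 50, seed = 19)
  expect_equal(res2$observed_pct, 100)
  expect_equal(res2$expected_pct, 100)
  expect_equal(res2$direction, "ns")
})

test_that("the null mean matches the analytic hit probability", {
  mask <- iv("chr1", 0, 5e5)
  feature <- iv("chr1", seq(0, 9) * 5e4, seq(0, 9) * 5e4 + 5000)
  origins <- iv("chr1", c(480000, 490000), c(481000, 491000))
  res <- enrichment_test(origins, feature, mask, n_intervals = 2000,
                         n_reps = 50, seed = 23)
  # exclusion footprint is tiny here; compare to the no-exclusion closed form
  p <- uniform_hit_probability(feature, 1000, mask)
  expect_lt(abs(res$expected_pct / 100 - p), 0.01)
})

test_that("strata are reported separately and empty strata are skipped", {
  set.seed(503)
  mask <- iv("chr1", 0, 2e5)
  origins <- random_intervals(60, genome_length = 2e5, max_len = 1000)
  feature <- random_intervals(30, genome_length = 2e5, max_len = 2000)
  strata <- rep(c(1, 2, NA), 20)
  res <- enrichment_test(origins, feature, mask, strata = strata,
                         n_intervals = 100, n_reps = 20, seed = 3)
  expect_equal(sort(as.character(res$stratum)), c("1", "2"))
  expect_equal(res$n, c(20L, 20L))
})

test_that("stratified summaries report means, CIs and densities", {
  origins <- tibble::tibble(
    chrom = "chr1", start = c(0, 5000, 10000, 15000),
    end = c(2000, 7000, 12000, 17000),
    efficiency = c(0.2, 0.4, 0.1, 0.3),
    timing_category = c(1L, 1L, 5L, 5L))
  marks <- list(H2AZ = iv("chr1", c(100, 5100), c(600, 5600)))
  s <- stratified_summary(origins, marks)
  a1 <- s[s$timing_category == 1 & s$pattern == "associated", ]
  expect_equal(a1$n, 2L)
  expect_equal(a1$mean_efficiency, 0.3)
  expect_equal(a1$mean_length, 2000)

  # density: 2 origins in a 1 Mb timing stratum -> 2 per Mb
  timing <- tibble::tibble(chrom = "chr1", start = c(0, 1e6),
                           end = c(1e6, 2e6), mrt = c(0.1, 0.8),
                           timing_category = c(1L, 5L))
  s2 <- stratified_summary(origins, marks, timing = timing)
  expect_true(all(s2$stratum_mb == 1))
  expect_equal(s2$density_per_mb[s2$timing_category == 1 &
                                   s2$pattern == "associated"], 2)
})

test_that("mark-combination patterns partition each stratum", {
  set.seed(509)
  origins <- random_intervals(200, genome_length = 1e6, max_len = 2000)
  origins$efficiency <- runif(200)
  origins$timing_category <- sample(1:6, 200, replace = TRUE)
  marks <- list(
    H4K20me1 = random_intervals(120, genome_length = 1e6, max_len = 3000),
    H3K27me3 = random_intervals(120, genome_length = 1e6, max_len = 3000))
  s <- stratified_summary(origins, marks,
                          combination = c("H4K20me1", "H3K27me3"))
  totals <- tapply(s$n, s$timing_category, sum)
  expect_equal(as.vector(totals),
               as.vector(table(origins$timing_category)))
  expect_error(stratified_summary(origins, marks, combination = "nope"),
               "unknown mark")
})

test_that("the efficiency t-test reproduces a hand-computed Welch t", {
  x <- c(0.20, 0.30, 0.40)  # associated
  y <- c(0.10, 0.15, 0.20)  # not associated
  origins <- tibble::tibble(chrom = "chr1", start = 0:5 * 100,
                            end = 0:5 * 100 + 50,
                            efficiency = c(x, y))
  res <- efficiency_t_test(origins, flag = rep(c(TRUE, FALSE), each = 3))
  sx2 <- var(x) / 3; sy2 <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df_hand <- (sx2 + sy2)^2 / (sx2^2 / 2 + sy2^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$estimate, 0.15)
})
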