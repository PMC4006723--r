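test_that("scan threshold handles the empty-background limit", {
  cfg <- scan_config()
  expect_equal(scan_threshold(noise_model(0, 1), 1e6, cfg), 1L)
  expect_error(scan_config(alpha = 0), "alpha")
  expect_error(scan_config(alpha = 1), "alpha")
  expect_error(noise_model(0.01, 0), "p_geom")
})

test_that("threshold is monotone in the site intensity", {
  cfg <- scan_config()
  taus <- vapply(c(0.002, 0.004, 0.008, 0.016, 0.032),
                 function(l) scan_threshold(noise_model(l, 0.6), 1e6, cfg),
                 integer(1))
  expect_true(all(diff(taus) >= 0))
})

test_that("analytic threshold matches the Monte-Carlo null maximum", {
  # Poisson case (p_geom = 1), 1 Mb scan at alpha = 0.05
  cfg_an <- scan_config(threshold_mode = "analytic")
  cfg_mc <- scan_config(threshold_mode = "monte_carlo", n_sim = 1500)
  nm <- noise_model(0.01, 1)
  t_an <- scan_threshold(nm, 1e6, cfg_an)
  set.seed(101)
  t_mc <- scan_threshold(nm, 1e6, cfg_mc)
  expect_lte(abs(t_an - t_mc), 1)

  # compound case
  nm2 <- noise_model(0.01, 0.6)
  t_an2 <- scan_threshold(nm2, 1e6, cfg_an)
  set.seed(103)
  t_mc2 <- scan_threshold(nm2, 1e6, cfg_mc)
  expect_lte(abs(t_an2 - t_mc2), 1)
})

test_that("window counts equal a brute-force recount", {
  set.seed(107)
  pos <- sort(floor(runif(400, 0, 5e4)))
  profile <- read_start_profile("chr1", pos,
                                count = rgeom(400, 0.5) + 1)
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 5e4)
  cfg <- scan_config(window = 2000, step = 300)
  w <- scan_segment(profile, seg, cfg, tau = 10)
  expect_equal(w$count, bf_window_counts(profile, w))
  expect_equal(w$significant, w$count >= 10)
  expect_true(all(w$end - w$start == 2000))
})

test_that("short segments yield a single clipped window", {
  profile <- read_start_profile("chr1", c(10, 20, 30))
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 500)
  w <- scan_segment(profile, seg, scan_config(), tau = 2)
  expect_equal(nrow(w), 1)
  expect_true(w$clipped)
  expect_equal(w$end - w$start, 500)
  expect_equal(w$count, 3)
})

test_that("overlapping significant windows merge into one origin", {
  profile <- read_start_profile("chr1", rep(c(500, 1500, 2500), c(20, 20, 20)))
  w <- tibble::tibble(chrom = "chr1", start = c(0, 1000), end = c(2000, 3000),
                      count = c(40, 40), tau = 20,
                      significant = TRUE, clipped = FALSE)
  ori <- call_origins(w, profile)
  expect_equal(nrow(ori), 1)
  expect_equal(ori$start, 0)
  expect_equal(ori$end, 3000)
  expect_equal(ori$n_reads, 60)
  expect_equal(ori$efficiency, 60 / 3000)
  expect_equal(ori$source_windows, 2L)

  # isolated significant window keeps exactly the window resolution
  w2 <- w[1, ]
  ori2 <- call_origins(w2, profile)
  expect_equal(ori2$end - ori2$start, 2000)

  expect_equal(nrow(call_origins(w[0, ], profile)), 0)
})

test_that("origin efficiency is reads per bp by definition", {
  profile <- read_start_profile("chr1", floor(seq(0, 1999, length.out = 500)))
  w <- tibble::tibble(chrom = "chr1", start = 0, end = 2000, count = 500,
                      tau = 100, significant = TRUE, clipped = FALSE)
  ori <- call_origins(w, profile)
  expect_equal(ori$efficiency, 0.25)
})

test_that("input-DNA FDR estimate is the SNS-in-input fraction", {
  set.seed(109)
  sns <- random_intervals(100, genome_length = 1e6)
  input <- sns[1:5, ]
  expect_equal(estimate_fdr_vs_input(sns, input), 0.05)
  far <- iv("chr2", 0, 10)
  expect_equal(estimate_fdr_vs_input(sns, far), 0)
  expect_equal(estimate_fdr_vs_input(sns[1:5, ], sns), 1)
  expect_error(estimate_fdr_vs_input(sns[0, ], input), "empty")
})

test_that("detection is deterministic and respects the window resolution", {
  cfg <- tiny_config(seed = 303)
  sim <- simulate_reads(cfg)
  fit1 <- detect_origins(sim$profile, sim$layout)
  fit2 <- detect_origins(sim$profile, sim$layout)
  expect_identical(fit1$origins, fit2$origins)
  expect_true(all(fit1$origins$end - fit1$origins$start >= 2000))
  g <- glance(fit1)
  expect_equal(g$n_origins, nrow(tidy(fit1)))
  expect_s3_class(tidy(fit1), "tbl_df")
})
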