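test_that("bin_reads counts starts per bin and conserves totals", {
  lay <- genome_layout("chr1", 1000)
  p <- read_start_profile("chr1", c(5, 150, 155))
  b <- bin_reads(p, 100, lay)
  expect_equal(b$count[1:3], c(1, 2, 0))
  expect_equal(sum(b$count), 3)

  empty <- read_start_profile(character(), numeric())
  expect_true(all(bin_reads(empty, 100, lay)$count == 0))
  expect_error(bin_reads(p, 0, lay), ">= 1")

  set.seed(5)
  lay2 <- genome_layout("chr1", 1e6)
  pos <- floor(runif(1e5, 0, 1e6))
  p2 <- read_start_profile("chr1", pos)
  expect_equal(sum(bin_reads(p2, 777, lay2)$count), 1e5)
  expect_equal(sum(p2$count), 1e5)
})

test_that("noise estimation recovers the geometric multiplicity parameter", {
  # every site single-read: pure Poisson limit
  p1 <- read_start_profile("chr1", seq(0, 999) * 10)
  nm <- estimate_noise(p1)
  expect_equal(nm$p_geom, 1)

  # all multiplicities 2: moment identity p = 1/2
  p2 <- read_start_profile("chr1", seq(0, 999) * 10, count = 2)
  expect_equal(estimate_noise(p2)$p_geom, 0.5)

  # recovery of p = 0.6 from 1e6 simulated sites
  set.seed(8)
  mult <- rgeom(1e6, 0.6) + 1
  p3 <- read_start_profile("chr1", seq_len(1e6) * 3, count = mult)
  expect_lt(abs(estimate_noise(p3)$p_geom - 0.6), 0.02)

  expect_error(estimate_noise(read_start_profile(character(), numeric())),
               "occupied")
})

test_that("compound Poisson-geometric pmf matches Poisson limit and simulation", {
  # p = 1: plain Poisson
  expect_equal(dcpgeom(0:10, mu = 3, p = 1), dpois(0:10, 3), tolerance = 1e-12)
  expect_equal(pcpgeom(4, mu = 3, p = 1), ppois(3, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # moments against Monte Carlo
  set.seed(13)
  n <- rpois(2e5, 5)
  w <- vapply(n, function(k) sum(rgeom(k, 0.6) + 1), numeric(1))
  pmf <- dcpgeom(0:60, mu = 5, p = 0.6)
  expect_equal(sum(pmf), 1, tolerance = 1e-9)
  emp <- tabulate(w + 1, 61) / length(w)
  expect_lt(max(abs(pmf - emp)), 0.005)
  expect_equal(sum(pmf * 0:60), 5 / 0.6, tolerance = 1e-3)
})

test_that("segmentation finds no changepoint in constant-rate coverage", {
  set.seed(17)
  bins <- tibble::tibble(chrom = "chr1", start = (0:999) * 1000,
                         end = (1:1000) * 1000, count = rpois(1000, 5))
  segs <- segment_coverage(bins)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$lambda_hat, sum(bins$count) / 1e6)
  expect_false(segs$low_coverage)
})

test_that("a clean rate step is localized within +/-2 bins of the truth", {
  # oracle: exhaustive single-changepoint likelihood scan
  set.seed(19)
  counts <- c(rpois(500, 2), rpois(500, 20))
  bins <- tibble::tibble(chrom = "chr1", start = (0:999) * 1000,
                         end = (1:1000) * 1000, count = counts)
  segs <- segment_coverage(bins, min_seg_bins = 5)
  expect_equal(nrow(segs), 2)
  bk <- segs$end[1] / 1000
  # oracle: exhaustive scan of every single-changepoint likelihood
  cx <- cumsum(counts)
  n <- length(counts)
  cost1 <- function(x, m) ifelse(x > 0, 2 * (x - x * log(x / m)), 0)
  tot <- vapply(1:(n - 1), function(s)
    cost1(cx[s], s) + cost1(cx[n] - cx[s], n - s), numeric(1))
  oracle <- which.min(tot)
  expect_equal(bk, oracle)
  expect_lte(abs(bk - 500), 2)
})

test_that("an all-zero chromosome yields a single low-coverage segment", {
  bins <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 100),
    start = rep((0:99) * 1000, 2), end = rep((1:100) * 1000, 2),
    count = c(rpois(100, 10), rep(0, 100)))
  segs <- segment_coverage(bins)
  z <- segs[segs$chrom == "chr2", ]
  expect_equal(nrow(z), 1)
  expect_true(z$low_coverage)
  expect_equal(z$lambda_hat, 0)
})

test_that("segments partition the genome and conserve reads", {
  set.seed(23)
  counts <- c(rpois(300, 3), rpois(200, 30), rpois(300, 8))
  bins <- tibble::tibble(chrom = "chr1", start = (0:799) * 500,
                         end = (1:800) * 500, count = counts)
  segs <- segment_coverage(bins, min_seg_bins = 10)
  expect_equal(segs$start[1], 0)
  expect_equal(segs$end[nrow(segs)], 800 * 500)
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  expect_equal(sum(segs$n_reads), sum(counts))
})

test_that("fixed-K DP equals exhaustive enumeration on tiny instances", {
  set.seed(29)
  for (rep in 1:5) {
    counts <- rpois(40, sample(c(2, 10, 25), 40, replace = TRUE))
    dp <- .dp_segment_cpp(counts, 3L, 1L)
    for (k in 1:3) {
      ex <- segment_exhaustive(counts, k)
      expect_equal(dp$cost[k], ex$cost, tolerance = 1e-9)
      expect_equal(dp$ends[[k]], as.integer(ex$ends))
    }
    # monotone DP property: more segments never fit worse
    expect_true(all(diff(dp$cost) <= 1e-9))
  }
})

test_that("PELT solves the same penalized objective as the DP", {
  set.seed(31)
  counts <- c(rpois(60, 4), rpois(60, 18), rpois(60, 2))
  pen <- 2 * log(length(counts))
  pelt <- .pelt_segment_cpp(counts, pen, 3L)
  dp <- .dp_segment_cpp(counts, 10L, 3L)
  k_best <- which.min(dp$cost + seq_along(dp$cost) * pen)
  expect_equal(pelt, dp$ends[[k_best]])
})
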