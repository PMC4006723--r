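test_that("BED parsing follows the 0-based half-open convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x",
               "chr1\t100\t200\tpeak0\t3\t-", "chr2\t0\t50\tpeak1\t7\t+"),
             path)
  x <- read_bed(path)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(100, 0))
  expect_equal(x$end, c(200, 50))
  expect_equal(x$name, c("peak0", "peak1"))
  expect_equal(x$strand, c("-", "+"))
  expect_equal(x$score, c(3, 7))

  # ragged files keep the common column prefix
  writeLines(c("chr1\t100\t200", "chr2\t0\t50\tpeak1\t7\t+"), path)
  expect_equal(names(read_bed(path)), c("chrom", "start", "end"))

  writeLines(character(), path)
  expect_equal(nrow(read_bed(path)), 0)

  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t0\t10", "chrUn\t5\t6"), path)
  expect_error(read_bed(path, genome_layout("chr1", 1000)), "chrUn")
})

test_that("BED round-trip is lossless for coordinates and names", {
  set.seed(11)
  x <- random_intervals(1000)
  x$name <- sprintf("iv%04d", seq_len(nrow(x)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)

  write_bed(x[0, ], path)
  expect_equal(nrow(read_bed(path)), 0)
  expect_identical(readLines(path), character(0))
})

test_that("interval overlap requires >= 1 shared bp on the same chromosome", {
  expect_true(interval_overlaps(iv("chr1", 100, 200), iv("chr1", 150, 250)))
  expect_false(interval_overlaps(iv("chr1", 100, 200), iv("chr1", 200, 300)))
  expect_false(interval_overlaps(iv("chr1", 100, 200), iv("chr2", 150, 250)))
})

test_that("merge_within clusters by strict edge-to-edge distance", {
  x <- iv("chr1", c(0, 1500), c(1000, 2500))
  m <- merge_within(x, gap = 12000)
  expect_equal(m[c("start", "end")], tibble::tibble(start = 0, end = 2500))

  far <- iv("chr1", c(0, 20000), c(1000, 21000))
  expect_equal(nrow(merge_within(far, gap = 12000)), 2)

  # gap = 0: only strict overlaps merge; half-open abutment stays split
  ab <- iv("chr1", c(0, 100), c(100, 200))
  expect_equal(nrow(merge_within(ab, gap = 0)), 2)
  ov <- iv("chr1", c(0, 50), c(100, 200))
  expect_equal(nrow(merge_within(ov, gap = 0)), 1)

  # exactly-at-gap distance is NOT merged (strict inequality)
  at <- iv("chr1", c(0, 1012), c(12, 1024))
  expect_equal(nrow(merge_within(at, gap = 1000)), 2)
  expect_equal(nrow(merge_within(at, gap = 1001)), 1)
})

test_that("merge_within is idempotent and aggregates read counts", {
  set.seed(21)
  x <- random_intervals(300, genome_length = 5e4)
  x$n_reads <- rpois(300, 20)
  m1 <- merge_within(x, gap = 100)
  m2 <- merge_within(m1, gap = 100)
  expect_equal(m1[c("chrom", "start", "end")], m2[c("chrom", "start", "end")])
  expect_equal(sum(m1$n_reads), sum(x$n_reads))
  expect_equal(m1$efficiency, m1$n_reads / (m1$end - m1$start))
})

test_that("distance_to_nearest matches the exhaustive pairwise scan", {
  expect_equal(distance_to_nearest(iv("chr1", 100, 200),
                                   iv("chr1", 300, 400)), 100)
  expect_equal(distance_to_nearest(iv("chr1", 100, 200),
                                   iv("chr1", 150, 400)), 0)
  expect_error(distance_to_nearest(iv("chr1", 0, 1), iv("chr1", 0, 1)[0, ]),
               "non-empty")

  set.seed(31)
  q <- random_intervals(500, chroms = c("chr1", "chr2", "chr3"))
  s <- random_intervals(200, chroms = c("chr1", "chr2"))
  expect_equal(distance_to_nearest(q, s), bf_nearest(q, s))
})

test_that("overlap fractions agree with O(n*m) brute force", {
  set.seed(41)
  a <- random_intervals(1000, chroms = c("chr1", "chr2"))
  b <- random_intervals(1000, chroms = c("chr1", "chr2"))
  rep <- overlap_report(a, b)
  expect_equal(rep$frac_a_in_b, mean(bf_overlaps_any(a, b)))
  expect_equal(rep$frac_b_in_a, mean(bf_overlaps_any(b, a)))
})

test_that("genome layout and complement behave", {
  expect_error(genome_layout(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_layout("a", 0), "> 0")
  lay <- genome_layout(c("chr1", "chr2"), c(1000, 500))
  gaps <- iv("chr1", c(0, 900), c(100, 1000))
  m <- complement_intervals(gaps, lay)
  expect_equal(m, iv(c("chr1", "chr2"), c(100, 0), c(900, 500)))
  expect_equal(covered_bp(m), 800 + 500)
})
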