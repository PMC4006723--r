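test_that("canonical G4 motifs are found with correct span and strand", {
  hits <- scan_g4(c(s = "GGGAGGGAGGGAGGG"), loop_max = 7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$end, 15)
  expect_equal(hits$strand, "+")

  minus <- scan_g4(c(s = "CCCTCCCTCCCTCCC"), loop_max = 7)
  expect_equal(minus$strand, "-")
  expect_equal(c(minus$start, minus$end), c(0, 15))

  # loop longer than the cap breaks the motif
  none <- scan_g4(c(s = "GGGAAAAAAAAGGGAGGGAGGG"), loop_max = 7)
  expect_equal(nrow(none), 0)

  # N never contributes to a run
  expect_equal(nrow(scan_g4(c(s = "GGNGAGGGAGGGAGGG"), loop_max = 7)), 0)
  expect_error(scan_g4(c(s = "GGGAXGGG")), "non-ACGTN")
})

test_that("greedy matching is non-overlapping and leftmost", {
  # five runs close together: the first four are taken, the fifth alone
  # cannot form a motif
  s <- "GGGAGGGAGGGAGGGAGGG"
  hits <- scan_g4(c(s = s), loop_max = 7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$end, 15)

  # eight runs: exactly two abutting motifs
  s2 <- paste0("GGGAGGGAGGGAGGG", "T", "GGGAGGGAGGGAGGG")
  hits2 <- scan_g4(c(s = s2), loop_max = 7)
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$start, c(0, 16))
})

test_that("scanner agrees exactly with the exhaustive enumerator", {
  set.seed(401)
  bad <- 0
  for (rep in 1:40) {
    s <- random_dna(3000)
    for (L in c(7, 15)) {
      got <- scan_g4(c(chrZ = s), loop_max = L)
      plus <- bf_g4_one_strand(s, "G", L)
      minus <- bf_g4_minus(s, L)
      gp <- got[got$strand == "+", ]
      gm <- got[got$strand == "-", ]
      bad <- bad +
        !identical(as.numeric(gp$start), plus$start) +
        !identical(as.numeric(gp$end), plus$end) +
        !identical(as.numeric(gm$start), minus$start) +
        !identical(as.numeric(gm$end), minus$end)
    }
  }
  expect_equal(bad, 0)
})

test_that("reverse complement swaps the strand of every motif", {
  set.seed(409)
  s <- paste0(random_dna(20000), "GGGAGGGAGGGAGGG", random_dna(2000))
  fwd <- scan_g4(c(x = s), loop_max = 15)
  expect_gt(nrow(fwd), 0)
  rev <- scan_g4(c(x = revcomp(s)), loop_max = 15)
  n <- nchar(s)
  flipped <- tibble::tibble(start = n - rev$end, end = n - rev$start,
                            strand = dplyr::if_else(rev$strand == "+",
                                                    "-", "+"))
  flipped <- flipped[order(flipped$start, flipped$strand), ]
  expect_equal(flipped$start, fwd$start)
  expect_equal(flipped$end, fwd$end)
  expect_equal(flipped$strand, fwd$strand)
})

test_that("g4_density counts motifs in the centered window", {
  origins <- iv("chr1", c(10000, 50000), c(12000, 52000))
  motifs <- tibble::tibble(chrom = "chr1",
                           start = c(11000, 13000, 8600, 49000),
                           end = c(11030, 13030, 8630, 49030),
                           strand = "+")
  d <- g4_density(origins, motifs, window = 5000)
  # origin 1 midpoint 11000: window [8500, 13500) catches 3 motifs;
  # origin 2 midpoint 51000: window [48500, 53500) catches the 4th
  expect_equal(d$g4_count, c(3L, 1L))
  set.seed(419)
  o <- random_intervals(200, genome_length = 1e5)
  m <- random_intervals(300, genome_length = 1e5, max_len = 30)
  mid <- floor((o$start + o$end) / 2)
  win <- iv("chr1", mid - 2500, mid - 2500 + 5000)
  expect_equal(g4_density(o, m, 5000)$g4_count,
               as.integer(rowSums(outer(seq_len(nrow(win)), seq_len(nrow(m)),
                                        function(i, j)
                                          win$start[i] < m$end[j] &
                                          m$start[j] < win$end[i]))))
})

test_that("FASTA input is accepted", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr9 test", "GGGAGGGAGGGAGGG"), path)
  hits <- scan_g4(path, loop_max = 7)
  expect_equal(hits$chrom, "chr9")
  expect_equal(nrow(hits), 1)
})
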