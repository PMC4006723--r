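# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own data paths (GRanges sweeps, regex runs, DP) so that
# agreement is evidence, not tautology.

iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

random_intervals <- function(n, genome_length = 1e5, max_len = 500,
                             chroms = "chr1") {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, genome_length - max_len))
  iv(sample(chroms, n, replace = TRUE), start, start + len)
}

# O(n*m) overlap predicate per query row.
bf_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(query$chrom[i] == subject$chrom &
          query$start[i] < subject$end & subject$start < query$end[i])
  }, logical(1))
}

# exhaustive pairwise edge-to-edge nearest distance (NA off-chromosome)
bf_nearest <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- subject$chrom == query$chrom[i]
    if (!any(same)) return(NA_real_)
    d <- pmax(0, pmax(subject$start[same] - query$end[i],
                      query$start[i] - subject$end[same]))
    min(d)
  }, numeric(1))
}

# per-window read recount straight from positions
bf_window_counts <- function(profile, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- profile$chrom == windows$chrom[i] &
      profile$pos >= windows$start[i] & profile$pos < windows$end[i]
    sum(profile$count[sel])
  }, numeric(1))
}

# Exhaustive G4 enumerator under the documented greedy rule: maximal runs
# located by rle (not regex), all feasible run quadruples enumerated with
# pruning, then leftmost-start / earliest-end non-overlapping selection.
bf_g4_one_strand <- function(s, letter, loop_max, min_run = 3) {
  ch <- strsplit(s, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  sel <- r$values == letter & r$lengths >= min_run
  rs <- (ends - r$lengths)[sel]  # 0-based run starts
  re <- ends[sel]                # half-open run ends
  nr <- length(rs)
  cand <- list()
  if (nr >= 4) {
    for (i in seq_len(nr - 3)) {
      for (j in (i + 1):(nr - 2)) {
        if (rs[j] - re[i] > loop_max) break
        for (k in (j + 1):(nr - 1)) {
          if (rs[k] - re[j] > loop_max) break
          for (l in (k + 1):nr) {
            if (rs[l] - re[k] > loop_max) break
            cand[[length(cand) + 1]] <- c(rs[i], re[l])
          }
        }
      }
    }
  }
  out <- matrix(numeric(0), ncol = 2)
  if (length(cand)) {
    m <- do.call(rbind, cand)
    dimnames(m) <- NULL
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    while (nrow(m) > 0) {
      pick <- m[1, ]
      out <- rbind(out, pick)
      m <- m[m[, 1] >= pick[2], , drop = FALSE]
    }
  }
  tibble::tibble(start = unname(out[, 1]), end = unname(out[, 2]))
}

# minus-strand oracle: enumerate on the reverse complement (the strand's own
# 5'->3' orientation) and map the coordinates back
bf_g4_minus <- function(s, loop_max, min_run = 3) {
  hits <- bf_g4_one_strand(revcomp(s), "G", loop_max, min_run)
  n <- nchar(s)
  tibble::tibble(start = sort(n - hits$end), end = sort(n - hits$start))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# synthetic distance matrix with the planted proximity structure: early
# origins near open marks, mid near H4K20me1 + H3K27me3, late near H3K9me3
planted_distances <- function(n_per_group, near = 1500, far = 25000) {
  marks <- c("H2AZ", "H3K9ac", "H3K4me3", "H4K20me1", "H3K27me3", "H3K9me3")
  near_marks <- list(early = c("H2AZ", "H3K9ac", "H3K4me3", "H4K20me1"),
                     mid = c("H4K20me1", "H3K27me3"),
                     late = "H3K9me3")
  purrr::map_dfr(names(near_marks), function(g) {
    m <- matrix(rexp(n_per_group * 6, 1 / far), n_per_group, 6,
                dimnames = list(NULL, marks))
    for (nm in near_marks[[g]]) {
      m[, nm] <- rexp(n_per_group, 1 / near)
    }
    dplyr::bind_cols(tibble::tibble(group = g), tibble::as_tibble(m))
  })
}

# small synthetic world shared by several tests
tiny_config <- function(seed, ...) {
  simulation_config(genome_length = 1e6, n_origins = 20, origin_fold = 10,
                    timing_domain_size = 2e5, fraction_bin = 5000,
                    seq_length = 5e4, n_g4 = 10, seed = seed, ...)
}
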