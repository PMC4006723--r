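#' Scan sequences for G-quadruplex motifs
#'
#' A G4 motif is four runs of >= 3 consecutive guanines separated by loops of
#' 1 to `loop_max` arbitrary bases (`G3+ N1..L G3+ N1..L G3+ N1..L G3+`) on
#' the plus strand, or the cytosine analog on the minus strand.  Matching is
#' over *maximal* G (resp. C) runs, greedy and leftmost *in the strand's own
#' 5'->3' orientation*: runs are scanned 5'->3', a motif is emitted at the
#' first run from which the next three consecutive runs all satisfy the loop
#' constraint, the motif spans from the start of its first to the end of its
#' fourth run, and scanning resumes after it — so same-strand motifs never
#' overlap (opposite-strand motifs may).  The minus strand is scanned on the
#' reverse complement, which makes the output exactly strand-symmetric under
#' reverse complementation.  `N` never matches a run.
#'
#' @param x Sequences: a named character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param loop_max Maximum loop length (typical choices 7, 15, 20, 30).
#' @param min_run Minimum run length (default 3).
#' @return Stranded interval tibble: `chrom`, `start`, `end`, `strand`,
#'   sorted by (chrom, start, strand).
#' @export
scan_g4 <- function(x, loop_max = 7, min_run = 3) {
  if (loop_max < 1) abort("`loop_max` must be >= 1.")
  if (methods::is(x, "DNAStringSet")) {
    seqs <- setNames(as.character(x), names(x))
  } else if (is.character(x) && length(x) == 1 && file.exists(x) &&
             grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    seqs <- x
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  out <- purrr::map_dfr(names(seqs), function(nm) {
    s <- toupper(seqs[[nm]])
    if (grepl("[^ACGTN]", s)) {
      abort(paste0("sequence ", nm, " contains non-ACGTN characters."))
    }
    srev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    minus <- g4_one_strand(srev, "G", min_run, loop_max)
    n <- nchar(s)
    bind_rows(
      g4_one_strand(s, "G", min_run, loop_max) |>
        mutate(chrom = nm, strand = "+"),
      tibble(start = n - minus$end, end = n - minus$start) |>
        mutate(chrom = nm, strand = "-"))
  })
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character()))
  }
  arrange(out[c("chrom", "start", "end", "strand")],
          .data$chrom, .data$start, .data$strand)
}

# Maximal runs of `letter` (>= min_run), then greedy-leftmost chaining of 4
# consecutive runs with loop gaps in [1, loop_max].
g4_one_strand <- function(s, letter, min_run, loop_max) {
  m <- gregexpr(paste0(letter, "{", min_run, ",}"), s)[[1]]
  empty <- tibble(start = numeric(), end = numeric())
  if (m[1] == -1) return(empty)
  run_start <- as.numeric(m) - 1                     # 0-based
  run_end <- run_start + attr(m, "match.length")     # half-open
  nr <- length(run_start)
  if (nr < 4) return(empty)
  gap_ok <- run_start[-1] - run_end[-nr] <= loop_max # lower bound 1 automatic
  starts <- ends <- numeric(0)
  r <- 1
  while (r <= nr - 3) {
    if (all(gap_ok[r:(r + 2)])) {
      starts <- c(starts, run_start[r])
      ends <- c(ends, run_end[r + 3])
      r <- r + 4
    } else {
      r <- r + 1
    }
  }
  tibble(start = starts, end = ends)
}

#' G4 motif count in a window around each origin
#'
#' Counts motifs overlapping the `window`-bp window centered on the origin
#' midpoint (default 5 kb), the local G4 density used to relate
#' G-quadruplexes to origin efficiency.
#'
#' @param origins Origin tibble.
#' @param motifs G4 motif tibble from [scan_g4()].
#' @param window Window width in bp (> 0).
#' @return `origins` with an added `g4_count` column.
#' @export
g4_density <- function(origins, motifs, window = 5000) {
  if (window <= 0) abort("`window` must be > 0.")
  check_intervals(origins, what = "origins")
  origins$g4_count <- 0L
  if (nrow(origins) == 0 || nrow(motifs) == 0) return(origins)
  mid <- floor((origins$start + origins$end) / 2)
  # centered window; clip the start for coordinate validity without
  # shifting the end
  win <- tibble(chrom = origins$chrom,
                start = pmax(0, mid - floor(window / 2)),
                end = mid - floor(window / 2) + window)
  origins$g4_count <- GenomicRanges::countOverlaps(as_gr(win), as_gr(motifs),
                                                   ignore.strand = TRUE)
  origins
}
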