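#' Pairwise interval overlap predicate
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least 1 bp under the half-open convention: `a.start < b.end && b.start <
#' a.end`.  Strand is always ignored (SNS reads are pooled across strands).
#'
#' @param a,b Interval tibbles of equal length (or length 1, recycled).
#' @return Logical vector.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
#' interval_overlaps(a, b)  # FALSE: half-open abutment
#' @export
interval_overlaps <- function(a, b) {
  check_intervals(a, what = "a"); check_intervals(b, what = "b")
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  a$chrom[idx_a] == b$chrom[idx_b] &
    a$start[idx_a] < b$end[idx_b] &
    b$start[idx_b] < a$end[idx_a]
}

# Logical per query row: does it overlap any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  # disjoint seqlevels are a legitimate "no overlap", not a warning
  suppressWarnings(
    GenomicRanges::countOverlaps(as_gr(query), as_gr(subject),
                                 ignore.strand = TRUE)) > 0
}

#' Cluster intervals closer than a gap into single larger intervals
#'
#' Any two intervals whose edge-to-edge distance is strictly less than `gap`
#' (overlap counts as distance 0) are transitively merged into their union.
#' This is the clustering used to bring origin maps from different methods to
#' a matched resolution (typical gaps: 12000, 6000, 20000 bp).  With
#' `gap = 0` only strictly overlapping intervals merge, so the operation is
#' idempotent on disjoint sets.
#'
#' A numeric `n_reads` column, if present, is summed over merged intervals
#' and `efficiency` (reads per bp) is recomputed over the merged span; the
#' number of source intervals is reported as `n_merged`.  Other annotation
#' columns are dropped (they have no well-defined aggregate).
#'
#' @param x Interval tibble.
#' @param gap Non-negative distance in bp; strict inequality.
#' @return Merged interval tibble sorted by (chrom, start).
#' @export
merge_within <- function(x, gap = 0) {
  check_intervals(x)
  if (!is.numeric(gap) || length(gap) != 1 || gap < 0) {
    abort("`gap` must be a single non-negative number.")
  }
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(),
                                  end = numeric(), n_merged = integer()))
  gr <- as_gr(x)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap, with.revmap = TRUE,
                               ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- gr_tbl(red)
  out$n_merged <- lengths(revmap)
  if ("n_reads" %in% names(x) && is.numeric(x$n_reads)) {
    out$n_reads <- vapply(revmap, function(i) sum(x$n_reads[i]), numeric(1))
    out$efficiency <- out$n_reads / (out$end - out$start)
  }
  out
}

#' Distance from each query interval to its nearest subject interval
#'
#' Edge-to-edge distance in bp on the same chromosome; 0 when the intervals
#' overlap (or abut).  Queries on chromosomes with no subject interval get
#' `NA` (distance undefined).
#'
#' @param query,subject Interval tibbles; `subject` must be non-empty.
#' @return Numeric vector of length `nrow(query)`.
#' @export
distance_to_nearest <- function(query, subject) {
  check_intervals(query, what = "query")
  check_intervals(subject, what = "subject")
  if (nrow(subject) == 0) abort("`subject` must be non-empty.")
  if (nrow(query) == 0) return(numeric(0))
  hit <- suppressWarnings(
    GenomicRanges::distanceToNearest(as_gr(query), as_gr(subject),
                                     ignore.strand = TRUE))
  out <- rep(NA_real_, nrow(query))
  out[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out
}
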