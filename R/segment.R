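#' Segment binned coverage into constant-intensity regions
#'
#' Models the binned read counts of each chromosome as piecewise-constant
#' Poisson and finds the changepoints minimising twice the negative Poisson
#' log-likelihood, in the spirit of penalised-likelihood segmentation models
#' for array-CGH data.  Two solvers share the same objective:
#'
#' * `method = "dp"`: exact dynamic program over a fixed number of segments,
#'   with the number of segments `K <= max_segments` chosen by penalised
#'   selection (`cost_K + K * penalty`);
#' * `method = "pelt"` (default): pruned exact solver of the same linearly
#'   penalised objective, near-linear in the number of bins and provably
#'   identical in optimum when the DP search is not truncated by
#'   `max_segments`.
#'
#' Segmentation is meant to capture *regional* coverage, not individual ~2 kb
#' peaks, so a minimum segment length (default 20 bins) keeps single read
#' pileups from being absorbed as their own segments; the scan statistic,
#' not the segmentation, is what detects peaks.
#'
#' Segments whose rate falls below `low_coverage_frac` times the genome-wide
#' mean intensity are flagged `low_coverage` and are excluded from scanning
#' downstream.
#'
#' @param bins Binned counts from [bin_reads()].
#' @param layout Optional genome layout used to clip the last segment of each
#'   chromosome to the true chromosome end.
#' @param penalty Penalty per additional segment on the -2 log-likelihood
#'   scale; default `2 * log(n_bins)` per chromosome (BIC-style: a rate and a
#'   changepoint per extra segment).
#' @param max_segments Cap on segments per chromosome for `method = "dp"`.
#' @param min_seg_bins Minimum segment length in bins (default 20).
#' @param low_coverage_frac Exclusion floor as a fraction of the genome-wide
#'   mean intensity (default 0.1).
#' @param method `"pelt"` or `"dp"`.
#' @return Tibble of segments: `chrom`, `start`, `end` (bp), `n_bins`,
#'   `n_reads`, `lambda_hat` (reads per bp), `low_coverage`.
#' @export
segment_coverage <- function(bins, layout = NULL, penalty = NULL,
                             max_segments = 50, min_seg_bins = 20,
                             low_coverage_frac = 0.1,
                             method = c("pelt", "dp")) {
  method <- match.arg(method)
  if (nrow(bins) == 0) abort("`bins` is empty.")
  if (max_segments < 1) abort("`max_segments` must be >= 1.")
  bin_size <- bins$end[1] - bins$start[1]
  segs <- purrr::map_dfr(split(bins, bins$chrom), function(b) {
    b <- arrange(b, .data$start)
    n <- nrow(b)
    minlen <- max(1L, min(as.integer(min_seg_bins), n))
    pen <- penalty %||% (2 * log(n))
    if (n <= minlen) {
      ends <- n
    } else if (method == "pelt") {
      ends <- .pelt_segment_cpp(b$count, pen, minlen)
    } else {
      kmax <- max(1L, min(as.integer(max_segments), n %/% minlen))
      dp <- .dp_segment_cpp(b$count, kmax, minlen)
      ok <- which(is.finite(dp$cost))
      k_best <- ok[which.min(dp$cost[ok] + seq_along(dp$cost)[ok] * pen)]
      ends <- dp$ends[[k_best]]
    }
    starts <- c(0L, ends[-length(ends)]) + 1L
    tibble(
      chrom = b$chrom[1],
      start = b$start[starts],
      end = b$end[ends],
      n_bins = ends - starts + 1L,
      n_reads = vapply(seq_along(ends), function(i)
        sum(b$count[starts[i]:ends[i]]), numeric(1))
    )
  })
  if (!is.null(layout)) {
    len <- layout$length[match(segs$chrom, layout$chrom)]
    segs$end <- pmin(segs$end, len)
  }
  segs$lambda_hat <- segs$n_reads / (segs$end - segs$start)
  mean_intensity <- sum(segs$n_reads) / sum(segs$end - segs$start)
  segs$low_coverage <- segs$lambda_hat < low_coverage_frac * mean_intensity
  dplyr::as_tibble(segs)
}

#' Exhaustive fixed-K segmentation (reference oracle)
#'
#' Enumerates every placement of `k - 1` changepoints and returns the best
#' under the same Poisson cost as [segment_coverage()].  Exponential in `k`;
#' intended for verification on tiny inputs only.
#'
#' @param counts Numeric vector of bin counts.
#' @param k Number of segments.
#' @param min_seg_bins Minimum segment length in bins.
#' @return List with `ends` (1-based inclusive segment end indices) and
#'   `cost`.
#' @export
segment_exhaustive <- function(counts, k, min_seg_bins = 1) {
  n <- length(counts)
  if (n > 60) abort("exhaustive segmentation is for tiny instances only.")
  cx <- c(0, cumsum(counts))
  cost1 <- function(i, j) {
    x <- cx[j + 1] - cx[i]
    if (x <= 0) return(0)
    2 * (x - x * log(x / (j - i + 1)))
  }
  if (k == 1) return(list(ends = n, cost = cost1(1, n)))
  best <- list(ends = NULL, cost = Inf)
  for (cp in utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)) {
    ends <- c(cp, n)
    starts <- c(1, cp + 1)
    if (any(ends - starts + 1 < min_seg_bins)) next
    cost <- sum(vapply(seq_len(k), function(i) cost1(starts[i], ends[i]),
                       numeric(1)))
    if (cost < best$cost) best <- list(ends = ends, cost = cost)
  }
  best
}

#' Write coverage segments as BED6+
#'
#' Columns: chrom, start, end, segment id, lambda_hat, strand (`.`),
#' low-coverage flag.
#'
#' @param segments Segment tibble from [segment_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  x <- tibble(chrom = segments$chrom, start = segments$start,
              end = segments$end,
              name = sprintf("seg_%04d", seq_len(nrow(segments))),
              score = signif(segments$lambda_hat, 6), strand = ".",
              low_coverage = as.integer(segments$low_coverage))
  write_bed(x, path)
}
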