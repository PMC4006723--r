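#' Sample random intervals uniformly on a mappable mask
#'
#' Places intervals of the requested lengths uniformly over all allowed start
#' positions of `mask` minus the footprint of `exclude`, rejection-free: for
#' each length, a mask segment long enough to contain the interval is drawn
#' with probability proportional to its number of valid starts, then the
#' start uniformly within it.
#'
#' @param lengths Integer vector of interval lengths (bp).
#' @param mask Interval tibble of mappable regions.
#' @param exclude Optional interval tibble whose footprint sampled intervals
#'   may not overlap.
#' @param seed Optional integer seed (sets the RNG).
#' @return Interval tibble with `nrow = length(lengths)`.
#' @export
sample_intervals <- function(lengths, mask, exclude = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  allowed <- merge_within(mask, gap = 0)[c("chrom", "start", "end")]
  if (!is.null(exclude) && nrow(exclude) > 0) {
    gr <- GenomicRanges::setdiff(as_gr(allowed), as_gr(exclude),
                                 ignore.strand = TRUE)
    allowed <- gr_tbl(gr)
  }
  widths <- allowed$end - allowed$start
  chrom <- character(length(lengths))
  start <- numeric(length(lengths))
  for (len in unique(lengths)) {
    idx <- which(lengths == len)
    nstarts <- pmax(0, widths - len + 1)
    if (sum(nstarts) == 0) {
      abort(paste0("mask too small to place an interval of length ", len, "."))
    }
    seg <- sample.int(nrow(allowed), length(idx), replace = TRUE,
                      prob = nstarts)
    chrom[idx] <- allowed$chrom[seg]
    start[idx] <- allowed$start[seg] + floor(runif(length(idx)) *
                                               nstarts[seg])
  }
  tibble(chrom = chrom, start = start, end = start + lengths)
}

#' Mutual overlap between two origin sets, with a randomization null
#'
#' `frac_a_in_b` is the fraction of A intervals overlapping at least one B
#' interval (>= 1 bp), and symmetrically.  When `mask` is given, the expected
#' fractions under a randomization null are added: `n_sets` sets of random
#' intervals with the exact length multiset of B (resp. A), placed uniformly
#' on the mappable mask excluding B's (resp. A's) own footprint, are overlapped
#' with A (resp. B) and averaged.
#'
#' @param a,b Non-empty interval tibbles on the same genome.
#' @param mask Optional mappability mask enabling the randomization null.
#' @param n_sets Number of random sets (default 50).
#' @param seed Optional seed for the randomization.
#' @return One-row tibble: `n_a`, `n_b`, `frac_a_in_b`, `frac_b_in_a`, and —
#'   with a mask — `expected_a_in_b`, `expected_b_in_a`, `n_randomizations`.
#' @export
overlap_report <- function(a, b, mask = NULL, n_sets = 50, seed = NULL) {
  check_intervals(a, what = "a"); check_intervals(b, what = "b")
  if (nrow(a) == 0 || nrow(b) == 0) abort("`a` and `b` must be non-empty.")
  out <- tibble(n_a = nrow(a), n_b = nrow(b),
                frac_a_in_b = mean(overlaps_any(a, b)),
                frac_b_in_a = mean(overlaps_any(b, a)))
  if (!is.null(mask)) {
    e <- expected_overlap(a, b, mask, n_sets = n_sets, seed = seed)
    out$expected_a_in_b <- e$expected_a_in_b
    out$expected_b_in_a <- e$expected_b_in_a
    out$n_randomizations <- n_sets
  }
  out
}

#' Randomization-expected overlap between two interval sets
#'
#' Estimates how much overlap of A with B is expected by chance:
#' `expected_a_in_b` replaces B with `n_sets` random sets carrying B's exact
#' length multiset, placed uniformly on `mask` minus B's own footprint, and
#' averages the fraction of A overlapping each random set (and symmetrically
#' for `expected_b_in_a`).
#'
#' @inheritParams overlap_report
#' @param mask Mappability mask (required).
#' @return One-row tibble `expected_a_in_b`, `expected_b_in_a`, `n_sets`.
#' @export
expected_overlap <- function(a, b, mask, n_sets = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_side <- function(query, other) {
    lens <- other$end - other$start
    mean(vapply(seq_len(n_sets), function(k) {
      r <- sample_intervals(lens, mask, exclude = other)
      mean(overlaps_any(query, r))
    }, numeric(1)))
  }
  tibble(expected_a_in_b = one_side(a, b),
         expected_b_in_a = one_side(b, a),
         n_sets = n_sets)
}

#' Classify origins as constitutive, common or cell-line specific
#'
#' A focal origin overlapping at least one origin in *every* other set is
#' constitutive; one overlapping no other set is specific; anything else is
#' common.
#'
#' @param sets Named list of >= 2 interval tibbles (one per cell line),
#'   including the focal set.
#' @param focal Name (or index) of the focal set within `sets`.
#' @return The focal tibble with `sharing`
#'   (`constitutive`/`common`/`specific`) and `n_lines` (number of lines the
#'   origin is found in, including its own).
#' @export
classify_sharing <- function(sets, focal) {
  if (length(sets) < 2) abort("need at least 2 sets.")
  if (is.character(focal) && !(focal %in% names(sets))) {
    abort(paste0("focal set '", focal, "' not among `sets`."))
  }
  f <- sets[[focal]]
  others <- sets[-match(focal, if (is.character(focal)) names(sets)
                        else seq_along(sets))]
  hits <- vapply(others, function(s) overlaps_any(f, s),
                 logical(nrow(f)))
  if (nrow(f) == 1) hits <- matrix(hits, nrow = 1)
  n_hit <- rowSums(hits)
  f$n_lines <- as.integer(n_hit + 1)
  f$sharing <- dplyr::case_when(
    n_hit == length(others) ~ "constitutive",
    n_hit == 0 ~ "specific",
    TRUE ~ "common")
  f
}
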