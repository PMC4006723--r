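#' Mean replication timing from six Repli-Seq fractions
#'
#' The MRT of a bin is the signal-weighted mean replication time on a unit S
#' phase, with fraction `i` (1 = earliest) contributing its midpoint weight
#' `w_i = (i - 0.5) / 6`:  `MRT = sum(w_i s_i) / sum(s_i)`.  Bins with zero
#' total signal are undefined (`NA`) and excluded downstream.  MRT therefore
#' lives in `[1/12, 11/12]`; small values are early, large values late.
#'
#' @param fractions Long tibble with columns `chrom`, `start`, `end`,
#'   `fraction` (1..6, 1 = earliest S), `signal` (>= 0); the six fractions
#'   must share the same binning.
#' @param weights Optional fraction weights (default midpoints
#'   `(1:6 - 0.5) / 6`).
#' @return Tibble `chrom`, `start`, `end`, `mrt`, `timing_category`.
#' @export
compute_mrt <- function(fractions, weights = NULL) {
  need <- c("chrom", "start", "end", "fraction", "signal")
  if (!all(need %in% names(fractions))) {
    abort("`fractions` needs columns chrom, start, end, fraction, signal.")
  }
  fr <- sort(unique(fractions$fraction))
  if (!identical(as.integer(fr), 1:6)) {
    abort("exactly 6 fractions (numbered 1..6) are required.")
  }
  if (any(fractions$signal < 0)) abort("fraction signal must be >= 0.")
  weights <- weights %||% ((1:6 - 0.5) / 6)
  counts <- fractions |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(n = dplyr::n(),
              total = sum(.data$signal),
              wsum = sum(weights[.data$fraction] * .data$signal),
              .groups = "drop")
  if (any(counts$n != 6)) {
    abort("mismatched binning: every bin must appear in all 6 fractions.")
  }
  counts |>
    mutate(mrt = ifelse(.data$total > 0, .data$wsum / .data$total, NA_real_),
           timing_category = timing_category(.data$mrt)) |>
    select("chrom", "start", "end", "mrt", "timing_category") |>
    arrange(.data$chrom, .data$start)
}

#' Six timing categories from MRT values
#'
#' Left-closed bins `[0, 1/6), [1/6, 2/6), ..., [5/6, 1]`: categories 1-2 are
#' early, 3-4 mid, 5-6 late S phase.
#'
#' @param mrt Numeric MRT values in `[0, 1]` (NA allowed).
#' @return Integer categories 1..6 (NA preserved).
#' @export
timing_category <- function(mrt) {
  as.integer(pmin(floor(6 * mrt) + 1, 6))
}

#' Label origins with a replication-timing category
#'
#' Each origin receives the MRT of the timing bin containing its midpoint
#' (origins are far smaller than timing bins), the derived category 1..6 and
#' the early/mid/late group.  Origins whose midpoint falls in an undefined
#' bin (or outside the profile) stay unlabeled (`NA`).
#'
#' @param origins Origin tibble.
#' @param profile Timing profile from [compute_mrt()].
#' @return `origins` with added `mrt`, `timing_category`, `timing_group`.
#' @export
assign_timing <- function(origins, profile) {
  check_intervals(origins, what = "origins")
  origins$mrt <- NA_real_
  if (nrow(origins) > 0) {
    mid <- floor((origins$start + origins$end) / 2)
    for (chr in unique(origins$chrom)) {
      sel <- which(origins$chrom == chr)
      p <- dplyr::filter(profile, .data$chrom == chr) |> arrange(.data$start)
      if (nrow(p) == 0) next
      idx <- findInterval(mid[sel], p$start)
      ok <- idx >= 1
      ok[ok] <- mid[sel][ok] < p$end[idx[ok]]
      origins$mrt[sel[ok]] <- p$mrt[idx[ok]]
    }
  }
  origins$timing_category <- timing_category(origins$mrt)
  origins$timing_group <- category_group(origins$timing_category)
  origins
}

#' Assemble six bedGraph tracks into a long fraction tibble
#'
#' @param paths Character vector of 6 bedGraph paths ordered from the
#'   earliest to the latest S-phase fraction.
#' @param layout Optional genome layout for validation.
#' @return Long tibble suitable for [compute_mrt()].
#' @export
read_fractions <- function(paths, layout = NULL) {
  if (length(paths) != 6) abort("exactly 6 fraction files are required.")
  purrr::map_dfr(1:6, function(i) {
    mutate(read_bedgraph(paths[i], layout), fraction = i) |>
      dplyr::rename(signal = "value")
  })
}

#' Export a timing profile as bedGraph
#'
#' Undefined bins are dropped.
#'
#' @param profile Timing profile from [compute_mrt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrt_bedgraph <- function(profile, path) {
  x <- dplyr::filter(profile, !is.na(.data$mrt))
  write_bedgraph(tibble(chrom = x$chrom, start = x$start, end = x$end,
                        value = round(x$mrt, 6)), path)
}
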