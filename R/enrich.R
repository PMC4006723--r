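#' Randomization test of origin association with a genomic feature
#'
#' Compares the observed percentage of origins overlapping a feature track
#' with the percentage expected for random genomic intervals of the origins'
#' average length, sampled uniformly from the mappable mask excluding the
#' origins' own footprint.  Each of `n_reps` replicates samples `n_intervals`
#' intervals and records its overlap percentage; the expected percentage is
#' the null mean and the empirical p-value is `(1 + #more extreme) /
#' (n_reps + 1)` for each one-sided direction.
#'
#' @param origins Origin tibble.
#' @param feature Feature interval tibble (e.g. CGIs, a mark's peaks, G4s).
#' @param mask Mappability mask tibble.
#' @param strata Optional vector (length `nrow(origins)`) of stratum labels,
#'   e.g. timing categories; results are reported per stratum.
#' @param n_intervals Random intervals per replicate.  Default scales the
#'   genome-scale choice of 100,000 intervals per ~3.1 Gb down proportionally
#'   to the mask (floor 500).
#' @param n_reps Number of null replicates (default 1000).
#' @param seed Optional seed.
#' @param feature_label Label for the output (default
#'   `deparse(substitute(feature))`).
#' @param null_strata_fn Optional function mapping an interval tibble to
#'   stratum labels, used to stratify the null the same way as the origins
#'   (e.g. timing lookup for random intervals).  Without it all strata share
#'   one genome-wide null.
#' @param p_threshold Overall significance level for the enriched/depleted
#'   calls (default 0.05, uncorrected across strata); each one-sided
#'   comparison is tested at `p_threshold / 2`.
#' @return Tibble with one row per stratum: `feature`, `stratum`, `n`,
#'   `observed_pct`, `expected_pct`, `empirical_p`, `direction`.
#' @export
enrichment_test <- function(origins, feature, mask, strata = NULL,
                            n_intervals = NULL, n_reps = 1000, seed = NULL,
                            feature_label = NULL, null_strata_fn = NULL,
                            p_threshold = 0.05) {
  feature_label <- feature_label %||% deparse(substitute(feature))
  if (!is.null(seed)) set.seed(seed)
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  check_intervals(origins, what = "origins")
  if (nrow(origins) == 0) abort("`origins` is empty.")
  mask_bp <- covered_bp(mask)
  n_intervals <- n_intervals %||% max(500, round(1e5 * mask_bp / 3.1e9))
  strata <- strata %||% rep("all", nrow(origins))
  avg_len <- max(1, round(mean(origins$end - origins$start)))
  hit <- overlaps_any(origins, feature)

  # hot loop: precompute the allowed start space (mask minus origins) and a
  # findInterval hit tester over the merged, left-expanded feature footprint
  allowed <- gr_tbl(GenomicRanges::setdiff(
    as_gr(merge_within(mask, gap = 0)[c("chrom", "start", "end")]),
    as_gr(origins), ignore.strand = TRUE))
  nstarts <- pmax(0, allowed$end - allowed$start - avg_len + 1)
  if (sum(nstarts) == 0) abort("mask too small for the null intervals.")
  fm <- merge_within(feature, gap = 0)
  fexp <- merge_within(tibble(chrom = fm$chrom,
                              start = pmax(0, fm$start - avg_len + 1),
                              end = fm$end), gap = 1)
  bounds <- split(fexp, fexp$chrom)
  hit_fun <- function(chrom, start) {
    out <- logical(length(start))
    for (chr in names(bounds)) {
      b <- bounds[[chr]]
      sel <- chrom == chr
      out[sel] <- findInterval(start[sel],
                               as.vector(rbind(b$start, b$end))) %% 2 == 1
    }
    out
  }

  # null replicates: one pooled sampling per replicate, optionally stratified
  null_pct <- matrix(NA_real_, n_reps, length(unique(strata[!is.na(strata)])))
  strata_levels <- sort(unique(strata[!is.na(strata)]))
  colnames(null_pct) <- strata_levels
  for (r in seq_len(n_reps)) {
    seg <- sample.int(nrow(allowed), n_intervals, replace = TRUE,
                      prob = nstarts)
    st <- allowed$start[seg] + floor(runif(n_intervals) * nstarts[seg])
    rnd <- tibble(chrom = allowed$chrom[seg], start = st,
                  end = st + avg_len)
    rnd_hit <- hit_fun(rnd$chrom, rnd$start)
    if (is.null(null_strata_fn)) {
      null_pct[r, ] <- 100 * mean(rnd_hit)
    } else {
      rs <- null_strata_fn(rnd)
      for (lv in strata_levels) {
        sel <- !is.na(rs) & rs == lv
        null_pct[r, lv] <- if (any(sel)) 100 * mean(rnd_hit[sel]) else NA
      }
    }
  }
  purrr::map_dfr(strata_levels, function(lv) {
    sel <- !is.na(strata) & strata == lv
    if (!any(sel)) {
      warn(paste0("stratum ", lv, " is empty; skipped."))
      return(NULL)
    }
    obs <- 100 * mean(hit[sel])
    nulls <- null_pct[, lv]
    nulls <- nulls[!is.na(nulls)]
    p_up <- (1 + sum(nulls >= obs)) / (length(nulls) + 1)
    p_down <- (1 + sum(nulls <= obs)) / (length(nulls) + 1)
    # the two one-sided tests share the level (p_threshold / 2 per side) so
    # that an independent feature is called ns with probability
    # ~1 - p_threshold overall
    tibble(feature = feature_label, stratum = lv, n = sum(sel),
           observed_pct = obs, expected_pct = mean(nulls),
           empirical_p = min(p_up, p_down),
           direction = if (p_up < p_threshold / 2) "enriched"
                       else if (p_down < p_threshold / 2) "depleted" else "ns")
  })
}

#' Analytic hit probability of a random interval against a feature track
#'
#' For a random interval of length `len` placed uniformly over the start
#' positions of a single-chromosome mask, the probability of overlapping the
#' feature is the fraction of allowed starts within `len - 1` bp upstream of
#' (or inside) the merged feature footprint.  Used as the closed-form check
#' of the randomization nulls.
#'
#' @param feature Feature tibble on one chromosome.
#' @param len Interval length (bp).
#' @param mask Mask tibble (single contiguous interval).
#' @return Probability in `[0, 1]`.
#' @export
uniform_hit_probability <- function(feature, len, mask) {
  stopifnot(nrow(mask) == 1)
  lo <- mask$start
  hi <- mask$end - len  # last allowed start (inclusive)
  if (hi < lo) abort("mask shorter than the interval.")
  f <- merge_within(feature, gap = 0)
  # starts s with [s, s+len) overlapping [fs, fe): s in [fs - len + 1, fe - 1]
  hit <- tibble(chrom = f$chrom, start = pmax(lo, f$start - len + 1),
                end = pmin(hi + 1, f$end))
  hit <- hit[hit$start < hit$end, ]
  covered_bp(hit) / (hi - lo + 1)
}

#' Stratified origin summaries by timing, CGI status and mark association
#'
#' Summarises origin efficiency, length and density per stratum.  Strata are
#' the timing category crossed (optionally) with CGI overlap and with a mark
#' association pattern: for a single mark, associated vs not; for a pair of
#' marks, `both` / `<mark1> only` / `<mark2> only` / `neither` (the
#' combination-of-marks partition); `"OpenMarks"` may be used as a pseudo-mark
#' meaning association with any of `open_marks`.
#'
#' Density is origins per Mb of the genome assigned to the stratum's timing
#' category (mappable bp of defined timing bins in that category), when a
#' timing profile and mask are supplied.
#'
#' @param origins Origin tibble with `efficiency` and `timing_category`
#'   (see [assign_timing()]).
#' @param marks Named list of mark interval tibbles.
#' @param combination `NULL` (one associated/not breakdown per mark in
#'   `marks`) or a length-1 or length-2 character vector of mark names.
#' @param cgi Optional CGI interval tibble; if given, strata are additionally
#'   split by CGI overlap.
#' @param open_marks Marks whose union defines `"OpenMarks"`.
#' @param timing Optional timing profile (from [compute_mrt()]) for the
#'   density denominator.
#' @param mask Optional mappability mask for the density denominator.
#' @return Tibble with one row per stratum: timing category, optional
#'   `cgi`, `pattern`, `n`, means with 95% normal-approximation half-widths,
#'   and `density_per_mb`.
#' @export
stratified_summary <- function(origins, marks, combination = NULL,
                               cgi = NULL,
                               open_marks = c("H2AZ", "H3K9ac", "H3K4me3"),
                               timing = NULL, mask = NULL) {
  if (!all(c("efficiency", "timing_category") %in% names(origins))) {
    abort("`origins` needs `efficiency` and `timing_category` columns.")
  }
  assoc <- function(mark) {
    if (mark == "OpenMarks") {
      track <- bind_rows(marks[intersect(open_marks, names(marks))])
      if (nrow(track) == 0) abort("no open mark track available.")
    } else {
      if (!mark %in% names(marks)) {
        abort(paste0("unknown mark: ", mark, "."))
      }
      track <- marks[[mark]]
    }
    overlaps_any(origins, track)
  }
  base <- tibble(timing_category = origins$timing_category,
                 efficiency = origins$efficiency,
                 length = origins$end - origins$start)
  if (!is.null(cgi)) base$cgi <- overlaps_any(origins, cgi)
  if (is.null(combination)) {
    long <- purrr::map_dfr(names(marks), function(m) {
      mutate(base, mark = m,
             pattern = ifelse(assoc(m), "associated", "not associated"))
    })
  } else if (length(combination) == 1) {
    long <- mutate(base, mark = combination,
                   pattern = ifelse(assoc(combination), "associated",
                                    "not associated"))
  } else if (length(combination) == 2) {
    a1 <- assoc(combination[1]); a2 <- assoc(combination[2])
    long <- mutate(base, mark = paste(combination, collapse = "+"),
                   pattern = dplyr::case_when(
                     a1 & a2 ~ "both",
                     a1 ~ paste(combination[1], "only"),
                     a2 ~ paste(combination[2], "only"),
                     TRUE ~ "neither"))
  } else {
    abort("`combination` must name one or two marks.")
  }
  denom <- NULL
  if (!is.null(timing)) {
    bins <- dplyr::filter(timing, !is.na(.data$timing_category))
    if (!is.null(mask)) {
      # per-category bp restricted to the mappable mask
      denom <- purrr::map_dfr(sort(unique(bins$timing_category)), function(k) {
        b <- dplyr::filter(bins, .data$timing_category == k)
        g <- GenomicRanges::intersect(as_gr(b), as_gr(mask),
                                      ignore.strand = TRUE)
        tibble(timing_category = k, stratum_mb = sum(IRanges::width(g)) / 1e6)
      })
    } else {
      denom <- bins |>
        group_by(.data$timing_category) |>
        summarise(stratum_mb = sum(.data$end - .data$start) / 1e6,
                  .groups = "drop")
    }
  }
  grp <- c("timing_category", if (!is.null(cgi)) "cgi", "mark", "pattern")
  out <- long |>
    dplyr::filter(!is.na(.data$timing_category)) |>
    group_by(across(all_of(grp))) |>
    summarise(n = dplyr::n(),
              mean_efficiency = mean(.data$efficiency),
              ci_efficiency = 1.96 * sd(.data$efficiency) / sqrt(dplyr::n()),
              mean_length = mean(.data$length),
              ci_length = 1.96 * sd(.data$length) / sqrt(dplyr::n()),
              .groups = "drop")
  if (!is.null(denom)) {
    out <- left_join(out, denom, by = "timing_category") |>
      mutate(density_per_mb = .data$n / .data$stratum_mb)
  }
  out
}

#' Two-sample t-test of origin efficiency by a stratum flag
#'
#' Welch t-test comparing a numeric origin property between flagged and
#' unflagged origins, optionally within groups (e.g. per timing category).
#'
#' @param origins Origin tibble.
#' @param flag Logical vector (length `nrow(origins)`): e.g. mark
#'   association.
#' @param value Column to compare (default `"efficiency"`).
#' @param by Optional grouping vector (e.g. timing categories).
#' @return Tidy tibble: group, group means, `estimate` (difference),
#'   `statistic`, `df`, `p.value`.
#' @export
efficiency_t_test <- function(origins, flag, value = "efficiency",
                              by = NULL) {
  v <- origins[[value]]
  by <- by %||% rep("all", length(v))
  purrr::map_dfr(sort(unique(by[!is.na(by)])), function(g) {
    sel <- !is.na(by) & by == g
    x <- v[sel & flag]; y <- v[sel & !flag]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tt <- stats::t.test(x, y)
    tibble(group = g, mean_flagged = mean(x), mean_unflagged = mean(y),
           estimate = mean(x) - mean(y),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value)
  })
}
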