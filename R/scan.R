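#' Configuration of the sliding-window scan
#'
#' @param window Window size u in bp (default 2000, the SNS fragment-size
#'   resolution of the assay).
#' @param step Step between window starts in bp (default 200, i.e. 10x
#'   overlapping windows; `step = window` gives disjoint tiles).
#' @param alpha Genome-wise false-positive level in (0, 1): the probability,
#'   under the compound-Poisson null, that the richest window anywhere in the
#'   scanned genome is a false positive (default 0.05).
#' @param threshold_mode `"analytic"` (scan-statistic tail approximation) or
#'   `"monte_carlo"` (simulation of the null maximum, the reference mode).
#' @param n_sim Number of null genomes simulated in `"monte_carlo"` mode.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 2000, step = 200, alpha = 0.05,
                        threshold_mode = c("analytic", "monte_carlo"),
                        n_sim = 2000) {
  threshold_mode <- match.arg(threshold_mode)
  if (!(step > 0 && step <= window)) abort("need 0 < step <= window.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  structure(list(window = window, step = step, alpha = alpha,
                 threshold_mode = threshold_mode, n_sim = n_sim),
            class = "scan_config")
}

# Null tail curve of the scan maximum: P(max window count >= tau) for
# tau = 1..nmax over a scanned segment.  Discrete-scan upcrossing
# (declumping) approximation: the max reaches tau iff the first window does,
# or some later window crosses from below; for overlapping windows the
# crossing probability conditions on the stretch shared with the previous
# window.  All component distributions are compound Poisson-geometric
# (Panjer recursion), computed once for the whole curve.
scan_max_tail_curve <- function(nmax, lambda_sites, p_geom, seg_length,
                                window, step) {
  if (lambda_sites <= 0) return(rep(0, nmax))
  u <- min(window, seg_length)
  k <- if (seg_length <= window) 1 else floor((seg_length - window) / step) + 1
  mu_u <- lambda_sites * u
  cdf_u <- cumsum(cpgeom_pmf(nmax, mu_u, p_geom))
  tail_u <- pmax(0, 1 - cdf_u[seq_len(nmax)])  # P(W >= tau), tau = 1..nmax
  if (k == 1) return(tail_u)
  if (step >= u) return(pmin(1, 1 - (1 - tail_u)^k))
  pmf_s <- cpgeom_pmf(nmax - 1, lambda_sites * (u - step), p_geom)
  cdf_a <- cumsum(cpgeom_pmf(nmax, lambda_sites * step, p_geom))
  # crossing at shared count s: old flank <= tau-1-s AND new flank >= tau-s;
  # both flank probabilities involve P(A <= tau-s-1) = cdf_a[tau-s]
  g <- cdf_a[seq_len(nmax)] * (1 - cdf_a[seq_len(nmax)])
  cross <- vapply(seq_len(nmax), function(tau) {
    s <- seq_len(tau) - 1
    sum(pmf_s[s + 1] * g[tau - s])
  }, numeric(1))
  pmin(1, tail_u + (k - 1) * cross)
}

# Scalar wrapper used by tests and by threshold search fallbacks.
scan_max_tail <- function(tau, lambda_sites, p_geom, seg_length, window,
                          step) {
  scan_max_tail_curve(max(tau, 1), lambda_sites, p_geom, seg_length, window,
                      step)[tau]
}

#' Detection threshold for the windowed scan statistic
#'
#' Returns the smallest integer `tau` such that, under the compound-Poisson
#' null (window site count `Poisson(lambda_sites * u)`, per-site multiplicity
#' `Geometric(p_geom)`), the probability that the *maximum* window count over
#' the scanned segment reaches `tau` is at most the segment's share of the
#' genome-wise level: `alpha * segment_length / total_scan_length`.
#'
#' @param noise A `noise_model` (the per-segment site intensity is typically
#'   the segment's `lambda_hat * p_geom`).
#' @param segment_length Length of the scanned segment in bp.
#' @param config A [scan_config()].
#' @param total_scan_length Total scanned bp over all segments (defaults to
#'   `segment_length`, i.e. the whole budget on one segment).
#' @return Integer threshold in reads.
#' @export
scan_threshold <- function(noise, segment_length, config,
                           total_scan_length = segment_length) {
  stopifnot(inherits(noise, "noise_model"), inherits(config, "scan_config"))
  if (segment_length <= 0 || total_scan_length < segment_length) {
    abort("need 0 < segment_length <= total_scan_length.")
  }
  alpha_seg <- config$alpha * segment_length / total_scan_length
  if (noise$lambda_sites <= 0) return(1L)
  if (config$threshold_mode == "monte_carlo") {
    return(mc_scan_threshold(noise$lambda_sites, noise$p_geom, segment_length,
                             config$window, config$step, alpha_seg,
                             config$n_sim))
  }
  mu <- noise$lambda_sites * min(config$window, segment_length)
  nmax <- cpgeom_support(mu, noise$p_geom)
  repeat {
    curve <- scan_max_tail_curve(nmax, noise$lambda_sites, noise$p_geom,
                                 segment_length, config$window, config$step)
    ok <- which(curve <= alpha_seg)
    if (length(ok)) return(as.integer(min(ok)))
    nmax <- nmax * 2L  # extend the support until the level is reachable
  }
}

# Simulate null maxima of the scan and return the smallest tau with
# empirical exceedance <= alpha_seg.  Uses the caller's RNG stream.
mc_scan_threshold <- function(lambda_sites, p_geom, seg_length, window, step,
                              alpha_seg, n_sim) {
  maxes <- mc_scan_maxima(lambda_sites, p_geom, seg_length, window, step,
                          n_sim)
  tab <- tabulate(maxes + 1L, nbins = max(maxes) + 1L)
  tail <- rev(cumsum(rev(tab))) / n_sim  # tail[t+1] = P(max >= t)
  ok <- which(tail <= alpha_seg) - 1L
  if (length(ok) == 0) return(max(maxes) + 1L)
  as.integer(max(1L, min(ok)))
}

mc_scan_maxima <- function(lambda_sites, p_geom, seg_length, window, step,
                           n_sim) {
  u <- min(window, seg_length)
  vapply(seq_len(n_sim), function(i) {
    n <- rpois(1, lambda_sites * seg_length)
    if (n == 0) return(0)
    pos <- runif(n, 0, seg_length)
    w <- rgeom(n, p_geom) + 1
    if (u %% step == 0 && seg_length > u) {
      nb <- ceiling(seg_length / step)
      binned <- as.numeric(tapply(w, factor(floor(pos / step) + 1,
                                            levels = seq_len(nb)),
                                  sum, default = 0))
      m <- u %/% step
      cw <- c(0, cumsum(binned))
      max(cw[(m + 1):(nb + 1)] - cw[1:(nb - m + 1)])
    } else {
      o <- order(pos)
      pos <- pos[o]
      cw <- c(0, cumsum(w[o]))
      starts <- seq(0, max(0, seg_length - u), by = step)
      hi <- findInterval(starts + u, pos)
      lo <- findInterval(starts, pos)
      max(cw[hi + 1] - cw[lo + 1])
    }
  }, numeric(1))
}

#' Score scan windows across one coverage segment
#'
#' Tiles windows of width `config$window` at `config$step` across the
#' segment (plus a final window flush with the segment end when the grid does
#' not reach it), counts the read starts in each, and flags windows with
#' `count >= tau` as significant.  Windows never straddle segment boundaries;
#' a segment shorter than the window yields a single clipped window.
#'
#' @param profile Read-start profile.
#' @param segment One-row segment tibble (`chrom`, `start`, `end`).
#' @param config A [scan_config()].
#' @param tau Integer detection threshold for this segment.
#' @return Tibble of windows: `chrom`, `start`, `end`, `count`, `tau`,
#'   `significant`, `clipped`.
#' @export
scan_segment <- function(profile, segment, config, tau) {
  w <- tile_windows(segment, config)
  w$count <- count_in_intervals(profile, w)
  w$tau <- tau
  w$significant <- w$count >= tau
  w[c("chrom", "start", "end", "count", "tau", "significant", "clipped")]
}

tile_windows <- function(segment, config) {
  u <- config$window
  seg_len <- segment$end - segment$start
  if (seg_len < u) {
    starts <- segment$start
    ends <- segment$end
    clipped <- TRUE
  } else {
    starts <- seq(segment$start, segment$end - u, by = config$step)
    if (max(starts) < segment$end - u) starts <- c(starts, segment$end - u)
    ends <- starts + u
    clipped <- FALSE
  }
  tibble(chrom = segment$chrom, start = starts, end = ends, clipped = clipped)
}

#' Merge significant scan windows into called origins
#'
#' Overlapping or abutting significant windows are merged into maximal runs;
#' each origin spans the union of its windows, its read count is re-counted
#' over that union, and its efficiency is `n_reads / length` (reads per bp) —
#' the sequencing proxy for the fraction of cell cycles in which the origin
#' fires.
#'
#' @param windows Window tibble from [scan_segment()] (one detection run).
#' @param profile The read-start profile the windows were scored on.
#' @return Origin tibble: `chrom`, `start`, `end`, `name`, `n_reads`,
#'   `efficiency`, `source_windows`.
#' @export
call_origins <- function(windows, profile) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), n_reads = numeric(),
                  efficiency = numeric(), source_windows = integer())
  if (nrow(windows) == 0) return(empty)
  sig <- dplyr::filter(windows, .data$significant)
  if (nrow(sig) == 0) return(empty)
  merged <- merge_within(sig[c("chrom", "start", "end")], gap = 1)
  merged$n_reads <- count_in_intervals(profile, merged)
  tibble(chrom = merged$chrom, start = merged$start, end = merged$end,
         name = sprintf("ori_%05d", seq_len(nrow(merged))),
         n_reads = merged$n_reads,
         efficiency = merged$n_reads / (merged$end - merged$start),
         source_windows = merged$n_merged)
}

#' Detect replication origins from a read-start profile
#'
#' The full detection pipeline: bin the profile, segment coverage into
#' constant-intensity regions, estimate the compound-Poisson noise model,
#' derive a per-segment threshold at the genome-wise level `config$alpha`
#' (allocated across segments proportionally to scanned length), scan every
#' non-excluded segment, and merge significant windows into origins.
#'
#' @param profile Read-start profile (see [read_start_profile()]).
#' @param layout Genome layout.
#' @param config A [scan_config()].
#' @param bin_size Bin size in bp for coverage segmentation (default 1000).
#' @param ... Further arguments passed to [segment_coverage()]
#'   (`min_seg_bins`, `penalty`, `low_coverage_frac`, `method`, ...).
#' @return An `origin_scan` object: list with `origins` (tibble), `segments`,
#'   `thresholds`, `noise`, `config`, `layout`.  `tidy()` returns the origin
#'   tibble, `glance()` a one-row run summary.
#' @export
detect_origins <- function(profile, layout, config = scan_config(),
                           bin_size = 1000, ...) {
  bins <- bin_reads(profile, bin_size, layout)
  segments <- segment_coverage(bins, layout = layout, ...)
  noise <- estimate_noise(profile, segments)
  active <- dplyr::filter(segments, !.data$low_coverage)
  if (nrow(active) == 0) abort("every segment is low-coverage; nothing to scan.")
  total <- sum(active$end - active$start)
  windows <- purrr::map_dfr(seq_len(nrow(active)), function(i) {
    seg <- active[i, ]
    seg_noise <- noise_model(lambda_sites = seg$lambda_hat * noise$p_geom,
                             p_geom = noise$p_geom)
    tau <- scan_threshold(seg_noise, seg$end - seg$start, config, total)
    w <- tile_windows(seg, config)
    w$tau <- tau
    w$segment <- i
    w
  })
  windows$count <- count_in_intervals(profile, windows)
  windows$significant <- windows$count >= windows$tau
  windows <- windows[c("chrom", "start", "end", "count", "tau",
                       "significant", "clipped", "segment")]
  thresholds <- windows |>
    group_by(.data$segment) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), tau = .data$tau[1],
              n_windows = dplyr::n(),
              n_significant = sum(.data$significant), .groups = "drop") |>
    mutate(alpha_seg = config$alpha * (.data$end - .data$start) / total)
  origins <- call_origins(windows, profile)
  structure(list(origins = origins, segments = segments,
                 thresholds = thresholds, noise = noise, config = config,
                 layout = layout, total_reads = n_profile_reads(profile)),
            class = "origin_scan")
}

#' @export
print.origin_scan <- function(x, ...) {
  cat(sprintf("origin_scan: %d origins from %s reads\n",
              nrow(x$origins), format(x$total_reads, big.mark = ",")))
  cat(sprintf("  window %d bp, step %d bp, alpha %.3g (%s threshold)\n",
              x$config$window, x$config$step, x$config$alpha,
              x$config$threshold_mode))
  cat(sprintf("  %d segments (%d low-coverage, excluded); p_geom %.3f\n",
              nrow(x$segments), sum(x$segments$low_coverage),
              x$noise$p_geom))
  invisible(x)
}

#' @rdname detect_origins
#' @param x An `origin_scan` object.
#' @export
tidy.origin_scan <- function(x, ...) x$origins

#' @rdname detect_origins
#' @export
glance.origin_scan <- function(x, ...) {
  tibble(n_origins = nrow(x$origins),
         total_reads = x$total_reads,
         genome_bp = sum(x$layout$length),
         scanned_bp = sum(x$thresholds$end - x$thresholds$start),
         n_segments = nrow(x$segments),
         n_low_coverage = sum(x$segments$low_coverage),
         p_geom = x$noise$p_geom,
         lambda_sites = x$noise$lambda_sites,
         mean_origin_length = if (nrow(x$origins)) mean(x$origins$end -
                                                          x$origins$start) else NA_real_,
         origin_bp_fraction = covered_bp(x$origins) / sum(x$layout$length))
}

#' Write called origins as BED6+
#'
#' Columns: chrom, start, end, name, n_reads (score), strand (`.`),
#' efficiency.
#'
#' @param origins Origin tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origins_bed <- function(origins, path) {
  x <- tibble(chrom = origins$chrom, start = origins$start,
              end = origins$end, name = origins$name,
              score = origins$n_reads, strand = ".",
              efficiency = signif(origins$efficiency, 6))
  write_bed(x, path)
}

#' Upper-bound FDR estimate from an input-DNA control
#'
#' The threshold can be calibrated by running the same detection on input
#' DNA: the fraction of SNS origins that are also detected as peaks in the
#' input data over-estimates the false discovery rate, since input peaks are
#' not necessarily false positives.
#'
#' @param sns_origins Origin tibble from the SNS data (non-empty).
#' @param input_origins Peak tibble from the input-DNA data.
#' @return Fraction in `[0, 1]`.
#' @export
estimate_fdr_vs_input <- function(sns_origins, input_origins) {
  check_intervals(sns_origins, what = "sns_origins")
  check_intervals(input_origins, what = "input_origins")
  if (nrow(sns_origins) == 0) abort("`sns_origins` is empty.")
  mean(overlaps_any(sns_origins, input_origins))
}
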