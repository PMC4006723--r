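#' Build a read-start profile from mapped read positions
#'
#' The detection model works on read *starts*: a sparse per-position count of
#' how many reads begin at each genomic position.  Duplicate starts are kept —
#' they are the per-site multiplicities the geometric part of the noise model
#' describes — so positions carry a count rather than being deduplicated.
#'
#' @param chrom Chromosome of each read start (recycled if length 1).
#' @param pos 0-based read-start positions.
#' @param count Optional pre-aggregated counts per position (default 1 each).
#' @return Tibble with columns `chrom`, `pos`, `count` (count >= 1), sorted
#'   by (chrom, pos).
#' @export
read_start_profile <- function(chrom, pos, count = 1) {
  if (length(pos) == 0) {
    return(tibble(chrom = character(), pos = numeric(), count = numeric()))
  }
  x <- tibble(chrom = rep_len(as.character(chrom), length(pos)),
              pos = as.numeric(pos),
              count = rep_len(as.numeric(count), length(pos)))
  if (any(x$pos < 0)) abort("read-start positions must be >= 0.")
  if (any(x$count < 1)) abort("per-position counts must be >= 1.")
  o <- order(x$chrom, x$pos)
  x <- x[o, ]
  new <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$pos[-1] != x$pos[-nrow(x)])
  id <- cumsum(new)
  tibble(chrom = x$chrom[new], pos = x$pos[new],
         count = as.vector(rowsum(x$count, id)))
}

#' Read a read-start profile from a BED-like file
#'
#' Expects one line per read (or per position with a count in the 4th/5th
#' column, as written by the `simulate` subcommand).  For stranded BED6 input
#' the start of `+` reads and `end - 1` of `-` reads is used.
#'
#' @param path BED path.
#' @param layout Optional genome layout for validation.
#' @return Read-start profile tibble.
#' @export
read_starts_bed <- function(path, layout = NULL) {
  x <- read_bed(path, layout = layout)
  if (nrow(x) == 0) return(read_start_profile(character(), numeric()))
  pos <- x$start
  if ("strand" %in% names(x)) {
    pos <- ifelse(x$strand == "-", x$end - 1, x$start)
  }
  count <- 1
  if ("score" %in% names(x) && is.numeric(x$score) && all(x$score >= 1)) {
    count <- x$score
  } else if ("name" %in% names(x) && is.numeric(x$name) && all(x$name >= 1)) {
    count <- x$name
  }
  read_start_profile(x$chrom, pos, count)
}

n_profile_reads <- function(profile) sum(profile$count)

#' Bin a read-start profile into fixed-width bins
#'
#' Counts read starts per `[k*b, (k+1)*b)` bin.  The last bin of each
#' chromosome is padded to a full bin beyond the chromosome end so no read is
#' truncated: the bin totals always conserve the profile total.
#'
#' @param profile Read-start profile (see [read_start_profile()]).
#' @param bin_size Bin width in bp (>= 1).
#' @param layout Genome layout; bins cover every chromosome in it.
#' @return Tibble `chrom`, `start`, `end`, `count` with one row per bin.
#' @export
bin_reads <- function(profile, bin_size, layout) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1) {
    abort("`bin_size` must be a single value >= 1.")
  }
  bin_size <- as.integer(bin_size)
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]
    nb <- ceiling(layout$length[i] / bin_size)
    p <- dplyr::filter(profile, .data$chrom == chr)
    cnt <- numeric(nb)
    if (nrow(p) > 0) {
      if (any(p$pos >= nb * bin_size)) {
        abort(paste0("read position beyond chromosome ", chr, "."))
      }
      idx <- p$pos %/% bin_size + 1
      cnt <- as.numeric(tapply(p$count, factor(idx, levels = seq_len(nb)),
                               sum, default = 0))
    }
    tibble(chrom = chr, start = (seq_len(nb) - 1) * bin_size,
           end = seq_len(nb) * bin_size, count = cnt)
  })
}

# Count reads of `profile` falling in each interval of `x` (half-open).
# Used to score scan windows and re-count merged origins.
count_in_intervals <- function(profile, x) {
  if (nrow(x) == 0) return(numeric(0))
  out <- numeric(nrow(x))
  for (chr in unique(x$chrom)) {
    sel <- which(x$chrom == chr)
    p <- dplyr::filter(profile, .data$chrom == chr) |> arrange(.data$pos)
    if (nrow(p) == 0) next
    cw <- c(0, cumsum(p$count))
    # reads with pos in [start, end): count = #\{pos < end\} - #\{pos < start\}
    hi <- findInterval(x$end[sel] - 0.5, p$pos)
    lo <- findInterval(x$start[sel] - 0.5, p$pos)
    out[sel] <- cw[hi + 1] - cw[lo + 1]
  }
  out
}
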