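#' Describe a genome as an ordered set of chromosomes
#'
#' A genome layout is the coordinate frame every other function works in: an
#' ordered table of chromosome names and lengths.  All intervals handled by
#' oriscan are 0-based, half-open `[start, end)`, the native BED convention.
#'
#' @param chrom Character vector of unique chromosome names, in the order they
#'   should be reported.
#' @param length Integer-ish vector of chromosome lengths in bp (all > 0).
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_layout("chr1", 1e6)
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) abort("chromosome names must be unique.")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be finite and > 0.")
  }
  tibble(chrom = chrom, length = length)
}

#' Read chromosome sizes from a two-column text file
#'
#' @param path Path to a `name<TAB>length` file (the UCSC "chrom.sizes"
#'   format).
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome_layout(x$chrom, x$length)
}

# Validate an interval tibble against a layout (if given).  Returns the tibble
# invisibly so it can be used in pipes; errors carry the offending row.
check_intervals <- function(x, layout = NULL, what = "intervals") {
  if (!is.data.frame(x)) abort(paste0("`", what, "` must be a data frame."))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("`", what, "` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(paste0("invalid interval (need 0 <= start < end) at row ", bad[1],
                 ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]]))
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), layout$chrom)
    if (length(unknown)) {
      abort(paste0("unknown chromosome(s): ", paste(unknown, collapse = ", ")))
    }
    len <- layout$length[match(x$chrom, layout$chrom)]
    over <- which(x$end > len)
    if (length(over)) {
      abort(paste0("interval exceeds chromosome length at row ", over[1],
                   ": ", x$chrom[over[1]], ":", x$start[over[1]], "-",
                   x$end[over[1]]))
    }
  }
  invisible(x)
}

# Interval tibble -> GRanges (0-based half-open -> 1-based closed).
as_gr <- function(x, layout = NULL) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  if (nrow(x) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(strand == ".", "*", strand)
  )
}

# GRanges -> interval tibble (back to 0-based half-open).
gr_tbl <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
  if (any(s != "*")) out$strand <- ifelse(s == "*", ".", s)
  out
}

#' Total bp covered by a set of intervals (after merging overlaps)
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @return Numeric, total covered bp.
#' @export
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(as_gr(x))))
}

#' Complement of a mask within a genome
#'
#' Used to turn a list of unmappable gaps into the mappable mask and vice
#' versa.
#'
#' @param x Interval tibble.
#' @param layout Genome layout.
#' @return Interval tibble covering `layout` minus `x`.
#' @export
complement_intervals <- function(x, layout) {
  check_intervals(x, layout)
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]
    len <- layout$length[i]
    xi <- dplyr::filter(x, .data$chrom == chr) |> dplyr::arrange(.data$start)
    if (nrow(xi) == 0) return(tibble(chrom = chr, start = 0, end = len))
    m <- gr_tbl(GenomicRanges::reduce(as_gr(xi)))
    starts <- c(0, m$end)
    ends <- c(m$start, len)
    keep <- starts < ends
    tibble(chrom = chr, start = starts[keep], end = ends[keep])
  })
}
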