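#' Read a BED (3+) file into an interval tibble
#'
#' Parses BED3/BED6 and wider variants (narrowPeak is BED6+4).  Coordinates
#' are kept in the native 0-based half-open convention.  Columns beyond the
#' first three are preserved: `name`, `score`, `strand` when present, then any
#' extra columns as `V7`, `V8`, ...  `track` and `browser` header lines and
#' `#` comments are skipped.
#'
#' @param path Path to a BED text file.
#' @param layout Optional genome layout; if given, chromosomes and bounds are
#'   validated against it.
#' @param col_names Optional names for columns beyond the sixth.
#' @return Interval tibble in file order.
#' @export
read_bed <- function(path, layout = NULL, col_names = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(paste0("malformed BED line ", lineno[bad], " in ", path,
                 ": fewer than 3 fields."))
  }
  ncol <- min(nf)
  mat <- t(vapply(fields, function(f) f[seq_len(ncol)], character(ncol)))
  if (ncol == 1) mat <- matrix(mat, ncol = 1)
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(paste0("malformed BED line ", lineno[bad[1]], " in ", path,
                 ": non-numeric coordinates."))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    abort(paste0("malformed BED line ", lineno[bad[1]], " in ", path,
                 ": need 0 <= start < end, got start=", start[bad[1]],
                 " end=", end[bad[1]], "."))
  }
  out <- tibble(chrom = mat[, 1], start = start, end = end)
  std <- c("name", "score", "strand")
  extra_idx <- seq_len(ncol)[-(1:3)]
  for (j in extra_idx) {
    nm <- if (j <= 6) std[j - 3] else paste0("V", j)
    if (!is.null(col_names) && j > 6 && (j - 6) <= length(col_names)) {
      nm <- col_names[j - 6]
    }
    col <- mat[, j]
    num <- suppressWarnings(as.numeric(col))
    out[[nm]] <- if (!anyNA(num)) num else col
  }
  check_intervals(out, layout, what = basename(path))
  out
}

#' Write an interval tibble as BED
#'
#' Writes `chrom start end` plus, when present, `name score strand` and any
#' further columns, tab-separated with no header — the inverse of
#' [read_bed()] up to annotation formatting.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  std <- c("chrom", "start", "end", "name", "score", "strand")
  have <- std[std %in% names(x)]
  # BED requires a contiguous prefix of the standard columns; fill gaps.
  cols <- x[intersect(std, names(x))]
  if ("strand" %in% names(cols) && !"score" %in% names(cols)) cols$score <- 0
  if (("score" %in% names(cols) || "strand" %in% names(cols)) &&
      !"name" %in% names(cols)) {
    cols$name <- "."
  }
  cols <- cols[intersect(std, names(cols))]
  extra <- x[setdiff(names(x), std)]
  out <- dplyr::bind_cols(cols, extra)
  fmt <- function(v) {
    if (is.numeric(v)) {
      ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
             format(v, scientific = FALSE, trim = TRUE, digits = 10))
    } else as.character(v)
  }
  body <- do.call(paste, c(lapply(out, fmt), sep = "\t"))
  readr::write_lines(body, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a 4-column `chrom start end value` text file.
#' @param layout Optional genome layout for validation.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, layout = NULL) {
  x <- read_bed(path, layout = layout)
  if (!"name" %in% names(x) || !is.numeric(x$name)) {
    abort(paste0(basename(path), ": bedGraph needs a numeric 4th column."))
  }
  dplyr::rename(x, value = "name")
}

#' Write a bedGraph file
#'
#' @param x Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  write_bed(dplyr::select(x, "chrom", "start", "end", name = "value"), path)
}
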