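#' Configuration of the synthetic SNS-seq world
#'
#' The generator emulates the statistical structure the detection model
#' assumes: read-bearing sites placed by a heterogeneous Poisson process
#' (background intensity `lambda_sites`, multiplied by a fold-enrichment
#' inside planted ~2 kb origins), geometric per-site read multiplicities,
#' mappability gaps that swallow reads, a blocky replication-timing field,
#' chromatin-mark tracks placed around origins with timing-dependent overlap
#' probabilities, and a G4-seeded random sequence.
#'
#' Defaults are the desk-scale world: one 10 Mb chromosome, 200 planted 2 kb
#' origins at 8-fold enrichment over a background of 0.01 sites/bp with
#' geometric success 0.6 (mean multiplicity ~1.7 reads/site).
#'
#' @param genome_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param lambda_sites Background intensity of read-bearing sites per bp.
#' @param p_geom Geometric success probability of per-site multiplicities.
#' @param n_origins,origin_width,origin_fold Number, width (bp) and
#'   fold-enrichment of planted origins (`origin_fold` may be a vector,
#'   recycled).  Ignored when `origins` is given.
#' @param origins Optional tibble `start`, `width`, `fold` of planted origins.
#' @param gaps Optional tibble `start`, `end` of unmappable gaps.
#' @param timing_domain_size Size of constant-timing domains in bp.
#' @param timing_categories Timing category (1-6) per domain; default cycles
#'   1..6 across domains.
#' @param fraction_bin Bin size of the six simulated Repli-Seq fraction
#'   tracks.
#' @param marks Mark names to simulate.
#' @param mark_probs Matrix (marks x early/mid/late) of per-origin overlap
#'   probabilities; default mirrors open marks on early origins,
#'   H4K20me1/H3K27me3 on mid, H3K9me3 on late.
#' @param mark_width,n_background_marks Width of mark intervals and number of
#'   origin-independent background intervals per mark.
#' @param cgi_probs Per-group probability that an origin overlaps a CpG
#'   island.
#' @param seq_length Length of the generated sequence (bp).
#' @param n_g4,g4_loop_max Number and loop-size cap of planted G4 motifs.
#' @param seed Mandatory integer seed; every artifact is derivable from the
#'   config alone.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(genome_length = 1e7, chrom = "chr1",
                              lambda_sites = 0.01, p_geom = 0.6,
                              n_origins = 200, origin_width = 2000,
                              origin_fold = 8, origins = NULL, gaps = NULL,
                              timing_domain_size = 1e6,
                              timing_categories = NULL,
                              fraction_bin = 10000,
                              marks = c("H2AZ", "H3K9ac", "H3K4me3",
                                        "H4K20me1", "H3K27me3", "H3K9me3"),
                              mark_probs = NULL, mark_width = 1500,
                              n_background_marks = 50,
                              cgi_probs = c(early = 0.7, mid = 0.4,
                                            late = 0.15),
                              seq_length = 2e5, n_g4 = 50, g4_loop_max = 7,
                              seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  if (p_geom <= 0 || p_geom > 1) abort("`p_geom` must be in (0, 1].")
  if (lambda_sites < 0) abort("`lambda_sites` must be >= 0.")
  if (!is.null(origins)) {
    stopifnot(all(c("start", "width", "fold") %in% names(origins)))
    if (any(origins$fold < 1) || any(origins$width < 1)) {
      abort("origin folds must be >= 1 and widths >= 1.")
    }
  } else if (n_origins > 0 && (any(origin_fold < 1) || origin_width < 1)) {
    abort("origin folds must be >= 1 and widths >= 1.")
  }
  n_domains <- max(1, ceiling(genome_length / timing_domain_size))
  timing_categories <- timing_categories %||% rep_len(1:6, n_domains)
  if (length(timing_categories) != n_domains ||
      !all(timing_categories %in% 1:6)) {
    abort("`timing_categories` must give one category in 1..6 per domain.")
  }
  if (is.null(mark_probs)) {
    mark_probs <- rbind(
      H2AZ     = c(0.90, 0.50, 0.20),
      H3K9ac   = c(0.85, 0.45, 0.15),
      H3K4me3  = c(0.85, 0.40, 0.10),
      H4K20me1 = c(0.60, 0.85, 0.30),
      H3K27me3 = c(0.30, 0.85, 0.40),
      H3K9me3  = c(0.05, 0.30, 0.90))[marks, , drop = FALSE]
    colnames(mark_probs) <- c("early", "mid", "late")
  }
  if (!identical(colnames(mark_probs), c("early", "mid", "late")) ||
      !identical(rownames(mark_probs), marks)) {
    abort("`mark_probs` needs rownames = marks, colnames = early/mid/late.")
  }
  structure(list(genome_length = genome_length, chrom = chrom,
                 lambda_sites = lambda_sites, p_geom = p_geom,
                 n_origins = n_origins, origin_width = origin_width,
                 origin_fold = origin_fold, origins = origins, gaps = gaps,
                 timing_domain_size = timing_domain_size,
                 timing_categories = timing_categories,
                 fraction_bin = fraction_bin, marks = marks,
                 mark_probs = mark_probs, mark_width = mark_width,
                 n_background_marks = n_background_marks,
                 cgi_probs = cgi_probs, seq_length = seq_length,
                 n_g4 = n_g4, g4_loop_max = g4_loop_max,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_layout <- function(config) genome_layout(config$chrom,
                                             config$genome_length)

sim_gaps <- function(config) {
  if (is.null(config$gaps)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble(chrom = config$chrom, start = config$gaps$start,
         end = config$gaps$end)
}

#' @rdname simulation_config
#' @param config A `sim_config`.
#' @return `sim_mask()`: the mappable mask (genome minus gaps) as an interval
#'   tibble.
#' @export
sim_mask <- function(config) {
  complement_intervals(sim_gaps(config), sim_layout(config))
}

# Deterministic origin placement: one origin per equal-width slot, uniform
# within the slot, redrawn away from gaps.  Consumes a fixed number of RNG
# draws per origin so reads and tracks stay in sync.
place_origins <- function(config) {
  if (!is.null(config$origins)) {
    o <- config$origins
    return(tibble(chrom = config$chrom, start = o$start,
                  end = o$start + o$width, fold = o$fold,
                  name = sprintf("truth_%05d", seq_len(nrow(o)))))
  }
  n <- config$n_origins
  if (n == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  fold = numeric(), name = character()))
  }
  w <- config$origin_width
  slot <- config$genome_length / n
  if (slot < w * 1.5) abort("too many origins for the genome length.")
  gaps <- sim_gaps(config)
  starts <- vapply(seq_len(n), function(i) {
    lo <- (i - 1) * slot
    hi <- i * slot - w
    s <- lo + floor(runif(5) * (hi - lo))  # fixed draw count per origin
    cand <- tibble(chrom = config$chrom, start = s, end = s + w)
    ok <- !overlaps_any(cand, gaps)
    if (any(ok)) s[which(ok)[1]] else NA_real_
  }, numeric(1))
  keep <- !is.na(starts)
  tibble(chrom = config$chrom, start = starts[keep],
         end = starts[keep] + w,
         fold = rep_len(config$origin_fold, n)[keep],
         name = sprintf("truth_%05d", seq_len(sum(keep))))
}

#' Simulate an SNS-seq read-start profile with planted origins
#'
#' Read-bearing sites are placed by a Poisson process with intensity
#' `lambda_sites` times the local fold-enrichment; each site receives a
#' `Geometric(p_geom)` number of reads; reads inside mappability gaps are
#' discarded.  Fixed seed gives bitwise-identical output.
#'
#' @param config A [simulation_config()].
#' @return List: `profile` (read-start tibble), `truth` (planted origins with
#'   fold), `layout`, `mask`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- place_origins(config)
  G <- config$genome_length
  n_bg <- rpois(1, config$lambda_sites * G)
  pos <- floor(runif(n_bg, 0, G))
  if (nrow(truth) > 0) {
    extra_mu <- config$lambda_sites * (truth$fold - 1) *
      (truth$end - truth$start)
    n_extra <- rpois(nrow(truth), extra_mu)
    pos_extra <- unlist(purrr::map(seq_len(nrow(truth)), function(i) {
      floor(runif(n_extra[i], truth$start[i], truth$end[i]))
    }))
    pos <- c(pos, pos_extra)
  }
  gaps <- sim_gaps(config)
  if (nrow(gaps) > 0 && length(pos) > 0) {
    drop <- overlaps_any(tibble(chrom = config$chrom, start = pos,
                                end = pos + 1), gaps)
    pos <- pos[!drop]
  }
  mult <- rgeom(length(pos), config$p_geom) + 1
  profile <- read_start_profile(config$chrom, pos, mult)
  list(profile = profile, truth = truth, layout = sim_layout(config),
       mask = sim_mask(config))
}

# Timing category of each domain, and category at arbitrary positions.
sim_domain_table <- function(config) {
  n_dom <- length(config$timing_categories)
  tibble(chrom = config$chrom,
         start = (seq_len(n_dom) - 1) * config$timing_domain_size,
         end = pmin(seq_len(n_dom) * config$timing_domain_size,
                    config$genome_length),
         category = config$timing_categories)
}

sim_category_at <- function(config, pos) {
  dom <- pmin(floor(pos / config$timing_domain_size) + 1,
              length(config$timing_categories))
  config$timing_categories[dom]
}

category_group <- function(category) {
  dplyr::case_when(category %in% 1:2 ~ "early",
                   category %in% 3:4 ~ "mid",
                   category %in% 5:6 ~ "late",
                   TRUE ~ NA_character_)
}

# Exact MRT construction: mix two adjacent fraction midpoints so the bin's
# MRT equals the target exactly, guaranteeing exact category round trips.
fraction_weights_for_mrt <- function(m) {
  mid <- (seq_len(6) - 0.5) / 6
  i <- findInterval(m, mid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), 5)
  w <- matrix(0, length(m), 6)
  a <- (mid[i + 1] - m) / (mid[i + 1] - mid[i])
  w[cbind(seq_along(m), i)] <- a
  w[cbind(seq_along(m), i + 1)] <- 1 - a
  w
}

#' Simulate feature tracks, Repli-Seq fractions and a G4-seeded sequence
#'
#' Generates, from the same config (and the same planted origins as
#' [simulate_reads()]): chromatin-mark interval tracks whose per-origin
#' overlap probability depends on the origin's timing group; a CpG-island
#' track; six Repli-Seq fraction tracks whose per-bin mean replication timing
#' falls exactly in the domain's assigned category; and a random sequence
#' with planted G4 motifs and G4-free flanks.
#'
#' @param config A [simulation_config()].
#' @return List: `truth` (origins with `timing_category`, `timing_group`, and
#'   per-mark/CGI association flags), `marks` (named list of interval
#'   tibbles), `cgi`, `fractions` (long tibble `chrom,start,end,fraction,
#'   signal`), `timing_truth` (per fraction bin), `sequence` (named character
#'   vector), `g4_truth`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- place_origins(config)        # same RNG prefix as simulate_reads
  set.seed(config$seed + 1L)
  mid <- floor((truth$start + truth$end) / 2)
  truth$timing_category <- if (nrow(truth)) sim_category_at(config, mid)
                           else integer(0)
  truth$timing_group <- category_group(truth$timing_category)

  grp_idx <- match(truth$timing_group, colnames(config$mark_probs))
  marks <- setNames(vector("list", length(config$marks)), config$marks)
  for (m in config$marks) {
    pm <- config$mark_probs[m, ]
    hit <- runif(nrow(truth)) < pm[grp_idx]
    offs <- floor(runif(sum(hit), -config$mark_width / 2,
                        config$origin_width - config$mark_width / 2))
    st <- pmax(0, truth$start[hit] + offs)
    bg_st <- floor(runif(config$n_background_marks,
                         0, config$genome_length - config$mark_width))
    x <- tibble(chrom = config$chrom, start = c(st, bg_st),
                end = c(st, bg_st) + config$mark_width) |>
      arrange(.data$start)
    marks[[m]] <- x
    truth[[paste0("has_", m)]] <- overlaps_any(truth, x)
  }
  cgi_hit <- runif(nrow(truth)) < config$cgi_probs[truth$timing_group]
  cgi_st <- pmax(0, floor((truth$start + truth$end) / 2)[cgi_hit] - 500)
  cgi_bg <- floor(runif(config$n_background_marks,
                        0, config$genome_length - 1000))
  cgi <- tibble(chrom = config$chrom, start = c(cgi_st, cgi_bg),
                end = c(cgi_st, cgi_bg) + 1000) |> arrange(.data$start)
  truth$has_CGI <- overlaps_any(truth, cgi)

  fr <- sim_fractions(config)
  seqs <- sim_sequence(config)
  list(truth = truth, marks = marks, cgi = cgi, fractions = fr$fractions,
       timing_truth = fr$timing_truth, sequence = seqs$sequence,
       g4_truth = seqs$g4_truth)
}

sim_fractions <- function(config) {
  doms <- sim_domain_table(config)
  lo <- pmax((doms$category - 1) / 6, 1 / 12) + 1e-6
  hi <- pmin(doms$category / 6, 11 / 12) - 1e-6
  target <- lo + runif(nrow(doms)) * (hi - lo)
  bin <- config$fraction_bin
  nb <- ceiling(config$genome_length / bin)
  bin_start <- (seq_len(nb) - 1) * bin
  dom_idx <- pmin(floor(bin_start / config$timing_domain_size) + 1,
                  nrow(doms))
  w <- fraction_weights_for_mrt(target)[dom_idx, , drop = FALSE]
  amp <- stats::rgamma(nb, shape = 5, rate = 1 / 20)
  gaps <- sim_gaps(config)
  bins <- tibble(chrom = config$chrom, start = bin_start,
                 end = pmin(bin_start + bin, config$genome_length))
  if (nrow(gaps) > 0) amp[overlaps_any(bins, gaps)] <- 0
  fractions <- purrr::map_dfr(1:6, function(i) {
    mutate(bins, fraction = i, signal = amp * w[, i])
  })
  timing_truth <- mutate(bins,
                         category = ifelse(amp > 0, doms$category[dom_idx],
                                           NA_integer_),
                         mrt = ifelse(amp > 0, target[dom_idx], NA_real_))
  list(fractions = fractions, timing_truth = timing_truth)
}

# Random sequence whose background is free of G/C triples, with planted G4
# motifs (and their truth coordinates) inserted with T padding.
sim_sequence <- function(config) {
  L <- config$seq_length
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  r <- rle(base)
  ends <- cumsum(r$lengths)
  for (k in which(r$lengths >= 3 & r$values %in% c("G", "C"))) {
    idx <- seq(ends[k] - r$lengths[k] + 3, ends[k], by = 3)
    base[idx] <- ifelse(r$values[k] == "G", "A", "T")
  }
  n <- config$n_g4
  g4_truth <- tibble(chrom = character(), start = numeric(),
                     end = numeric(), strand = character())
  if (n > 0) {
    slot <- L / n
    if (slot < 120) abort("`seq_length` too small for `n_g4` motifs.")
    motifs <- vapply(seq_len(n), function(i) {
      minus <- i %% 2 == 0
      runs <- vapply(1:4, function(j)
        strrep(if (minus) "C" else "G", sample(3:4, 1)), character(1))
      # loops must not contain the run letter, or runs would merge
      loop_alpha <- if (minus) c("A", "G", "T") else c("A", "C", "T")
      loops <- vapply(1:3, function(j) {
        paste(sample(loop_alpha, sample.int(config$g4_loop_max, 1),
                     replace = TRUE), collapse = "")
      }, character(1))
      paste0(runs[1], loops[1], runs[2], loops[2], runs[3], loops[3], runs[4])
    }, character(1))
    at <- floor((seq_len(n) - 1) * slot +
                  runif(n) * (slot - nchar(motifs) - 2))
    for (i in seq_len(n)) {
      ins <- c("T", strsplit(motifs[i], "")[[1]], "T")
      base[(at[i] + 1):(at[i] + length(ins))] <- ins
    }
    g4_truth <- tibble(chrom = config$chrom, start = at + 1,
                       end = at + 1 + nchar(motifs),
                       strand = ifelse(seq_len(n) %% 2 == 0, "-", "+"))
  }
  seqs <- setNames(paste(base, collapse = ""), config$chrom)
  list(sequence = seqs, g4_truth = g4_truth)
}

#' Read a flat key=value simulation config file
#'
#' Numeric values are parsed as numbers; `origin_fold` and
#' `timing_categories` may be comma-separated lists; `gaps` is a
#' semicolon-separated list of `start-end` pairs.
#'
#' @param path Path to the text file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  args <- setNames(as.list(vals), keys)
  parse_num_vec <- function(v) as.numeric(strsplit(v, ",")[[1]])
  for (k in names(args)) {
    if (k %in% c("chrom", "marks")) {
      if (k == "marks") args[[k]] <- strsplit(args[[k]], ",")[[1]]
    } else if (k == "gaps") {
      pairs <- strsplit(strsplit(args[[k]], ";")[[1]], "-")
      args[[k]] <- tibble(start = as.numeric(vapply(pairs, `[`, "", 1)),
                          end = as.numeric(vapply(pairs, `[`, "", 2)))
    } else if (k %in% c("origin_fold", "timing_categories", "cgi_probs")) {
      args[[k]] <- parse_num_vec(args[[k]])
    } else {
      args[[k]] <- as.numeric(args[[k]])
    }
  }
  do.call(simulation_config, args)
}
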