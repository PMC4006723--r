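#' Compound Poisson-geometric (Polya-Aeppli) distribution
#'
#' Under the detection null, the read count of a genomic window is a compound
#' Poisson sum: the number of read-bearing sites in the window is
#' `Poisson(mu)` and each site carries a `Geometric(p)` number of reads on
#' \{1, 2, ...\} (mean `1/p`).  `dcpgeom()` returns the probability mass
#' `P(W = x)` computed by the Panjer recursion; `pcpgeom()` the upper tail
#' `P(W >= x)`.
#'
#' @param x Non-negative integer quantiles.
#' @param mu Poisson mean of the number of sites (>= 0).
#' @param p Geometric success probability in (0, 1].
#' @return Numeric vector of probabilities.
#' @examples
#' dcpgeom(0:5, mu = 2, p = 1)  # p = 1 is the plain Poisson limit
#' @export
dcpgeom <- function(x, mu, p) {
  pmf <- cpgeom_pmf(max(x), mu, p)
  out <- rep(0, length(x))
  ok <- x >= 0 & x == floor(x)
  out[ok] <- pmf[x[ok] + 1]
  out
}

#' @rdname dcpgeom
#' @export
pcpgeom <- function(x, mu, p) {
  out <- rep(1, length(x))
  idx <- which(x >= 1)
  if (length(idx)) {
    pmf <- cpgeom_pmf(max(x[idx]) - 1, mu, p)
    cdf <- cumsum(pmf)                  # cdf[k+1] = P(W <= k)
    out[idx] <- pmax(0, 1 - cdf[x[idx]])  # P(W >= x) = 1 - P(W <= x-1)
  }
  out
}

# pmf vector P(W = 0..nmax) via Panjer recursion; f_j = p q^(j-1).
cpgeom_pmf <- function(nmax, mu, p) {
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].")
  if (mu < 0) abort("`mu` must be >= 0.")
  nmax <- max(0, as.integer(nmax))
  g <- numeric(nmax + 1)
  g[1] <- exp(-mu)
  if (g[1] == 0) {
    abort("window site mean too large for the Panjer recursion (mu > ~700).")
  }
  if (nmax == 0 || mu == 0) {
    if (mu == 0) g[1] <- 1
    return(g)
  }
  q <- 1 - p
  jf <- seq_len(nmax) * p * q^(seq_len(nmax) - 1)  # j * f_j
  for (n in seq_len(nmax)) {
    g[n + 1] <- (mu / n) * sum(jf[seq_len(n)] * g[n:1])
  }
  g
}

# Smallest n with P(W > n) < eps: used to size pmf supports.
cpgeom_support <- function(mu, p, eps = 1e-12) {
  m <- mu / p
  v <- mu * (2 - p) / p^2
  max(20, ceiling(m + 12 * sqrt(v) + 10))
}

#' Estimate the compound-Poisson noise model from background coverage
#'
#' The geometric success probability is estimated by the method of moments
#' from the multiplicity distribution of read starts per occupied site
#' (`p = 1 / mean multiplicity`), and the site intensity as occupied sites
#' per bp, both restricted to background (non-low-coverage) segments.
#'
#' @param profile Read-start profile.
#' @param segments Coverage segments from [segment_coverage()]; only
#'   segments with `low_coverage == FALSE` contribute.  May be omitted to use
#'   the whole profile.
#' @return A `noise_model` object: list with `p_geom`, `lambda_sites`
#'   (sites per bp), `n_sites`, `mean_multiplicity`, `background_bp`.
#' @export
estimate_noise <- function(profile, segments = NULL) {
  if (is.null(segments)) {
    keep <- rep(TRUE, nrow(profile))
    bg_bp <- if (nrow(profile)) sum(tapply(profile$pos, profile$chrom, max)) + 1
             else 0
  } else {
    bg <- dplyr::filter(segments, !.data$low_coverage)
    if (nrow(bg) == 0) abort("no non-low-coverage segment available.")
    keep <- logical(nrow(profile))
    for (chr in unique(profile$chrom)) {
      sel <- profile$chrom == chr
      b <- dplyr::filter(bg, .data$chrom == chr) |> arrange(.data$start)
      if (nrow(b) == 0) next
      idx <- findInterval(profile$pos[sel], b$start)
      ok <- idx >= 1
      ok[ok] <- profile$pos[sel][ok] < b$end[idx[ok]]
      keep[sel] <- ok
    }
    bg_bp <- sum(bg$end - bg$start)
  }
  mult <- profile$count[keep]
  if (length(mult) == 0) abort("no occupied site in background segments.")
  mbar <- mean(mult)
  structure(list(p_geom = 1 / mbar,
                 lambda_sites = length(mult) / bg_bp,
                 n_sites = length(mult),
                 mean_multiplicity = mbar,
                 background_bp = bg_bp),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Compound-Poisson noise model\n")
  cat(sprintf("  p_geom (geometric success): %.4f (mean multiplicity %.3f)\n",
              x$p_geom, x$mean_multiplicity))
  cat(sprintf("  lambda_sites: %.5g sites/bp over %.3g background bp (%d sites)\n",
              x$lambda_sites, x$background_bp, x$n_sites))
  invisible(x)
}

#' Construct a noise model directly from parameters
#'
#' @param lambda_sites Intensity of read-bearing sites per bp (>= 0).
#' @param p_geom Geometric success probability in (0, 1].
#' @return A `noise_model` object.
#' @export
noise_model <- function(lambda_sites, p_geom) {
  if (p_geom <= 0 || p_geom > 1) abort("`p_geom` must be in (0, 1].")
  if (lambda_sites < 0) abort("`lambda_sites` must be >= 0.")
  structure(list(p_geom = p_geom, lambda_sites = lambda_sites,
                 n_sites = NA_integer_, mean_multiplicity = 1 / p_geom,
                 background_bp = NA_real_),
            class = "noise_model")
}
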