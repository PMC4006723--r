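---
title: "Detecting replication origins with a compound-Poisson scan statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting replication origins with a compound-Poisson scan statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscan)
```

## The detection model

SNS-seq purifies λ-exonuclease-resistant nascent strands of ~1.5–2 kb, so a
read pileup marks an origin with a physical resolution of about 2 kb:
calling narrower peaks claims resolution the assay does not have.  oriscan
therefore scans with fixed windows of width $u$ (default 2000 bp, exposed in
`scan_config()`), and the statistical question becomes: *how many reads must
a 2 kb window hold before it is surprising under noise?*

The noise model is compound Poisson.  Read-bearing sites arrive along the
genome as a Poisson process with intensity $\lambda_{\text{sites}}$ per bp,
and each site carries a Geometric($p$) number of reads on $\{1, 2, \dots\}$
— SNS material is locally amplified, so duplicate read starts are part of
the signal and are never deduplicated.  A window of width $u$ then has a
Pólya–Aeppli count $W$ with site mean $\mu = \lambda_{\text{sites}} u$; its
pmf is computed exactly by the Panjer recursion (`dcpgeom()`,
`pcpgeom()`).  With $p = 1$ the model collapses to plain Poisson counts.

Both parameters are estimated from the data by `estimate_noise()`: $p$ by
the method of moments on the per-site multiplicity distribution
($\hat p = 1/\overline{\text{multiplicity}}$) and
$\lambda_{\text{sites}}$ as the occupied-site density, both restricted to
background (non-excluded) segments.

## The scan threshold

Significance is genome-wise: the threshold $\tau$ is the smallest integer
such that $P(\max_t W_t \ge \tau) \le \alpha$ under the null, i.e. the
probability that the *richest* window in the scanned genome is a false
positive is at most $\alpha$ (default 0.05).  Two threshold modes share this
contract:

* **monte_carlo** — the reference mode: simulate the null genome many times
  and take the empirical tail of the maximum window count;
* **analytic** (default) — a discrete-scan upcrossing approximation: the
  maximum reaches $\tau$ iff the first window does or some later window
  crosses from below, and for windows overlapping by $u - s$ bp (step $s$)
  the crossing probability conditions on the count of the shared stretch.
  All terms are Pólya–Aeppli tails, computed once per segment as a whole
  curve in $\tau$.

The two modes are required by the test suite to agree within ±1 read; the
verifiable contract is the null exceedance probability, not any particular
closed form.  Because $\tau$ is an integer, the achieved genome-wise level
is typically below $\alpha$ (we measure ~0.03 at $\alpha = 0.05$ on 1 Mb
backgrounds); this conservatism is inherent to discrete counts.

Windows are slid at a default step of 200 bp (10× overlap).  The step only
affects boundary resolution; `step = window` gives disjoint tiles, and both
regimes are handled by the threshold calculation.  Ties are inclusive:
`count >= tau` is significant, consistent with "smallest $\tau$ with tail
$\le \alpha$".

## Coverage segmentation

Real SNS coverage is heterogeneous at large scales.  Binned counts (1 kb
default) are segmented per chromosome under a piecewise-constant Poisson
model: segment cost is twice the negative maximised log-likelihood, the
number of segments is chosen by a BIC-style penalty ($2\log n$ per extra
segment), and two solvers of the same objective are provided — an exact
fixed-$K$ dynamic program (verified against exhaustive enumeration) and a
PELT-pruned solver used by default.  Each segment contributes its own
$\lambda$, gets its own $\tau$ at level
$\alpha_i = \alpha \cdot L_i / \sum_j L_j$, and windows never straddle
segment boundaries.  Segments with intensity below 10% of the genome-wide
mean are flagged `low_coverage` and excluded from scanning — the model has
no power there and unmappable regions would otherwise generate spurious
boundary windows.

Two segmentation parameters are genuinely free and deserve comment:

* **Minimum segment length** (default 20 bins = 20 kb).  Segmentation is
  meant to capture *regional* coverage, not individual ~2 kb peaks.  An
  unconstrained optimum happily brackets every strong origin into its own
  2-bin segment, which inflates the local rate estimate and defeats the
  detection that segment was supposed to serve.  Setting the minimum
  segment length well above the origin scale (20 kb ≈ 10 windows) keeps
  peaks inside their regional background.  The residual effect — a segment
  containing an origin has a modestly inflated $\lambda$ — costs a few
  reads of threshold and is absorbed by the 8× signal strength the assay
  produces.
* **Bin size** (default 1 kb) and the **penalty constant**: neither is
  dictated by the method; both are exposed in `segment_coverage()`.

## Randomization nulls

Two randomization procedures are implemented, matching the two uses they
serve:

* `expected_overlap()` (origin-map comparison) samples sets carrying the
  *exact length multiset* of the mimicked set, placed uniformly on the
  mappable mask excluding that set's own footprint, 50 sets by default.
* `enrichment_test()` (feature association) samples intervals of the
  origins' *average* length, `n_reps` replicates of `n_intervals` each; the
  genome-scale choice of 100,000 intervals is scaled down proportionally to
  the mask so desk-scale genomes are not oversampled.

Placement is rejection-free and uniform over allowed start positions (mask
segments weighted by the number of valid starts).  The empirical p-value is
the add-one permutation form $(1 + \#\{\text{as or more extreme}\}) /
(n_{\text{reps}} + 1)$, computed one-sidedly in both directions; each side
is tested at half the nominal level so that the overall false-call rate of
the enriched/depleted labels is the nominal 0.05.  No multiple-testing
correction is applied across strata; stars are per-stratum, and this is
deliberate and documented.

One calibration caveat: the permutation p-value treats the observed
percentage as exchangeable with the null replicates, which holds when each
replicate samples about as many intervals as there are origins.  With far
larger replicates (the genome-scale 100,000) the expected percentage is a
high-precision chance estimate, but the p-value becomes anti-conservative
for small origin sets because the observed statistic is noisier than the
null ones.  Dense origin sets also bias the origin-excluding null slightly
low.  The calibration tests therefore use matched replicate sizes and an
origin footprint density in the realistic few-percent range.

## Replication timing

Six-fraction Repli-Seq signal is summarised per bin as the mean replication
timing $\text{MRT} = \sum_i w_i s_i / \sum_i s_i$ with midpoint weights
$w_i = (i - 0.5)/6$ on a unit S phase, so MRT lives in $[1/12, 11/12]$.
Zero-signal bins are undefined and stay unlabeled downstream.  Categories
are the six left-closed sixths of $[0,1]$ (the last one closed), 1–2 early,
3–4 mid, 5–6 late.  An origin takes the MRT of the bin containing its
midpoint — origins (~2–4 kb) are far smaller than timing bins, so averaging
over the span would only blur domain boundaries.

## G-quadruplex scanning

A motif is four runs of ≥3 G (or C, on the minus strand) separated by loops
of 1 to `loop_max` arbitrary bases.  The matching dialect is pinned by
tests: runs are *maximal*, scanning is greedy and leftmost, a motif spans
its four runs, and scanning resumes after the motif, so same-strand motifs
never overlap (opposite strands may).  Because gaps between runs only grow
when runs are skipped, chaining four *consecutive* runs is provably
complete, and the implementation is verified against an exhaustive
enumerator of all run/loop decompositions under the same selection rule.

## Discriminant analysis

The origins × marks matrix holds the linear distance (bp, 0 = overlap) from
each timing-labeled origin to the nearest peak of each mark; the six timing
categories collapse to early/mid/late.  LDA is computed from the
eigendecomposition of the within-whitened between-group covariance; axes
have unit pooled within-group variance and at most
$\min(g - 1, p)$ informative axes exist — for three groups that is two,
and although the source analyses display three axes for three groups, a
third classical axis carries no between-group variance, so `n_axes` is
capped and the discrepancy documented here rather than imitated.  Axis
signs are fixed so each axis's largest-magnitude variable correlation is
negative (distances decrease along every axis), making outputs reproducible
run to run.  Distances are used raw by default for fidelity; they are
heavy-tailed, and `log1p = TRUE` is provided and recommended when the
analysis is used for classification — the synthetic recovery tests use it.

## The synthetic world

`simulate_reads()` / `simulate_tracks()` generate, from one seeded config,
everything the toolkit consumes: a Poisson site process with geometric
multiplicities and planted 2 kb origin enrichments; mappability gaps that
swallow reads; six fraction tracks built by mixing two adjacent fraction
midpoints so each bin's MRT is *exactly* its target (timing round trips are
exact by construction); mark tracks placed around origins with
timing-group-dependent overlap probabilities (open marks on early origins,
H4K20me1/H3K27me3 on mid, H3K9me3 on late — the qualitative structure the
real analyses report); and a random sequence whose background is free of
G/C triples with G4 motifs planted at recorded positions.

Defaults are the desk-scale world: one 10 Mb chromosome,
$\lambda_{\text{sites}} = 0.01$/bp, $p = 0.6$, 200 origins of 2 kb at 8×
enrichment.  What a green test establishes is that the *statistical
machinery* behaves as specified on data satisfying the model's assumptions;
the generator deliberately omits GC/mappability biases, fragment-length
structure and sequencing error, so it says nothing about robustness to
those.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; overlap means ≥1 shared bp;
  strand is ignored for all origin/feature association.
* "Closer than g" clustering (`merge_within`) is a strict inequality on the
  edge-to-edge gap; `gap = 0` merges only strict overlaps and is idempotent.
* An empty background ($\lambda_{\text{sites}} = 0$) makes any window with
  ≥1 read significant — and an empty profile yields no detections.
* Segments shorter than the window produce one clipped, flagged window.
* The Panjer recursion underflows for window site means above ~700; the
  threshold search errors rather than silently losing precision (desk-scale
  and genome-scale configurations sit far below this).
* Manifests contain no wall-clock field, so identical runs are
  byte-identical end to end.

## Known limitations

* No GC-content or mappability correction of λ beyond segment-level
  adaptation and the mask.
* The input-DNA FDR calibration (`estimate_fdr_vs_input()`) is an upper
  bound: input peaks need not be false positives.
* Enrichment p-values are uncorrected across strata.
* The LDA offers no sparse/regularized variants beyond a ridge fallback for
  singular within-group covariance.
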