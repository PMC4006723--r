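# oriscan

Resolution-controlled detection of DNA replication origins from
short-nascent-strand (SNS) sequencing, with the downstream comparative
toolkit used to characterise origin maps: clustering and overlap with
randomization nulls, replication-timing assignment, G-quadruplex scanning,
chromatin-feature enrichment, and discriminant analysis of origin-to-mark
distances.

## The problem and the model

SNS-seq enriches ~1.5–2 kb nascent strands around replication initiation
sites, so origins cannot be resolved below ~2 kb; peak callers tuned for
ChIP-seq return much narrower peaks and an uncontrolled resolution.  oriscan
instead scans the genome with fixed windows of width *u* = 2 kb and calls a
window significant when its read count exceeds a threshold derived from a
compound-Poisson null:

* read-bearing **sites** occur along the genome as a Poisson process with
  local intensity λ(t);
* each site carries a **Geometric(p)** number of reads on {1, 2, …}
  (duplicate read starts are signal, not PCR artefacts to deduplicate);
* a window of width *u* therefore has a Pólya–Aeppli (compound
  Poisson-geometric) count, and the detection threshold τ is the smallest
  integer such that the probability that the *maximum* window count over the
  scanned genome reaches τ — the scan statistic's null tail — is at most a
  genome-wise level α (default 0.05).

Coverage heterogeneity is handled by first segmenting binned coverage into
constant-intensity regions with a penalized Poisson changepoint model
(dynamic programming / PELT, in C++): each segment gets its own λ and its
own τ, extremely low-coverage segments are excluded, and windows never
straddle segment boundaries.  Significant windows are merged into origins;
an origin's **efficiency** is its read count divided by its length (reads
per bp).

Everything downstream is tabular and pipe-friendly: interval sets are
tibbles (`chrom`, `start`, `end`, …; 0-based half-open, BED-native),
detection returns an `origin_scan` object with `tidy()`/`glance()` methods,
and the discriminant analysis returns an `origin_lda` with
`tidy()`/`glance()`/`augment()`/`autoplot()`.

## Worked example

```r
library(oriscan)

config <- simulation_config(seed = 1)   # 10 Mb, 200 planted 2 kb origins, 8x
sim    <- simulate_reads(config)
fit    <- detect_origins(sim$profile, sim$layout)
fit
#> origin_scan: 199 origins from 213,152 reads
#>   window 2000 bp, step 200 bp, alpha 0.05 (analytic threshold)
#>   326 segments (0 low-coverage, excluded); p_geom 0.593

tracks  <- simulate_tracks(config)
timing  <- compute_mrt(tracks$fractions)
origins <- assign_timing(tidy(fit), timing)

enrichment_test(origins, tracks$cgi, sim$mask,
                strata = origins$timing_group, n_reps = 200, seed = 2,
                feature_label = "CGI")
#> # A tibble: 3 x 7
#>   feature stratum     n observed_pct expected_pct empirical_p direction
#>   <chr>   <chr>   <int>        <dbl>        <dbl>       <dbl> <chr>
#> 1 CGI     early      79         70.9         2.33     0.00498 enriched
#> 2 CGI     late       40         20           2.33     0.00498 enriched
#> 3 CGI     mid        80         43.8         2.33     0.00498 enriched
```

The printed detection summary says 199 origins were called from ~213k reads
after the coverage was segmented into 326 constant-rate pieces, with the
per-site multiplicity parameter estimated at p ≈ 0.6 (mean ~1.7 reads per
site).  The enrichment table compares the percentage of origins overlapping
a CpG-island track per timing group against randomly placed intervals of the
same average length on the mappable genome: the synthetic world plants CGIs
preferentially at early origins, and the test recovers the gradient
(71% → 44% → 20%, all far above the ~2.3% chance level).

A shell interface mirrors the workflow
(`simulate | detect | cluster | compare | sharing | timing | g4scan |
enrich | summarize | lda`):

```sh
Rscript inst/cli/oriscan simulate --seed 1 --out-dir sim/
Rscript inst/cli/oriscan detect --reads sim/reads.bed --genome sim/genome.sizes --out origins
```

Every run writes a deterministic JSON manifest (parameters, seed, input
checksums, versions), so identical inputs and seed give byte-identical
outputs.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the
default synthetic world — simulate reads and tracks, detect origins, assign
timing, test CGI enrichment, fit the LDA — logging a short summary to
stderr:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| where | what |
|---|---|
| `R/layout.R`, `R/bed.R`, `R/intervals.R` | coordinate frame, BED/bedGraph IO, interval algebra |
| `R/profile.R`, `R/noise.R`, `R/segment.R`, `src/segment.cpp` | read-start profiles, compound-Poisson noise model, Poisson changepoint segmentation |
| `R/scan.R` | scan thresholds (analytic + Monte-Carlo), window scan, origin calling, input-DNA FDR |
| `R/compare.R`, `R/timing.R`, `R/g4.R`, `R/enrich.R`, `R/lda.R` | overlap/randomization, MRT and timing categories, G4 scanner, enrichment and stratified summaries, discriminant analysis |
| `R/simulate.R` | seeded synthetic-data generator |
| `R/cli.R`, `inst/cli/oriscan` | shell entry point |
| `vignettes/origin-detection.Rmd` | the methods vignette |
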