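# periscan

Genes regulated by the same transcription factor are not scattered at
random along a bacterial chromosome: in several species they recur at
roughly regular spacings of tens to hundreds of kilobases, an arrangement
thought to favour their spatial co-localisation in the folded nucleoid.
`periscan` gives microbial genomicists the tools to detect, localise and
exploit such periodic layout:

* **Period scanning.** Every candidate period P of a set of gene start
  coordinates is scored with the circular concentration statistic
  S = N·R², where R is the mean resultant length of the phase angles
  θ_j = 2π·(x_j mod P)/P.  Raw p-values come from the uniform null
  (Monte Carlo, or the Rayleigh large-N approximation); scan-level
  significance is calibrated exactly against Monte-Carlo null scans of the
  same size and grid (a max-statistic correction), with a per-period
  Šidák correction m(P) = max(1, ⌊G/P⌋) available for isolated tests.
  Harmonically related periods (2x–4x) are grouped into families, and
  periods shared between regulons (within 5 %) are reported.
* **Phase clustering.** For each significant period, features are placed
  on the phase circle and clustered with a deterministic DBSCAN under the
  circular distance, with neighbourhood radius ε = P^(1−e)·d^e
  interpolating between the period and the proximity threshold d via the
  clustering exponent e.  Each feature also receives a positional score —
  its leave-one-out contribution to S, min–max normalised to [0, 1]
  (the "clustergram" view).
* **Region mapping.** A variable-size sliding window (starting at 10 kbp,
  growing geometrically to 95 % of the genome) localises chromosome
  sub-regions that carry their own periodic pattern (the "chromogram"
  view), with per-window max-statistic calibration and merging of
  overlapping same-period windows.
* **Multi-view target prediction.** A modified AdaBoost combines two
  views of each candidate gene — binding-site strength (best PWM log-odds
  hit on either strand) and positional score — choosing at each iteration
  the view whose decision stump has the lower weighted error
  (α = ½·ln((1−ε)/ε)).  Regularised canonical correlation analysis of the
  per-iteration classifier scores quantifies the interplay between
  sequence and position information (the "correlation circle" view).
* **Synthetic benchmarks.** Generators plant periodic lattices, labelled
  regulons with implanted motifs, and anti-correlated sequence/position
  regimes, so every claim above is testable without downloads.

## Worked example

```r
library(periscan)

# a 4.64-Mb circular chromosome with 40 sites on a 93-kb lattice
# (2-kb jitter) plus 30 uniform background sites
sim <- generate_periodic_positions(seed = 7)
scan <- scan_periods(sim$fs, p_min = 50000, p_max = 500000, step = 30,
                     seed = 11)
scan
#> <period_scan> DOM mode, 15001 candidate periods in [50,000, 5e+05] bp, N = 70
#>   top period 92,960 bp (S = 30.98, corrected p = 0.00498)

top <- top_period(scan)
```

The top period, 92,960 bp, is within 0.05 % of the planted 93,000 bp; its
corrected p-value 0.005 is the Monte-Carlo floor of the 200-null-scan
calibration, i.e. no uniform genome of the same size produced a score
this high anywhere in the scan.  Downstream:

```r
params <- cluster_params(top$period, proximity = 1000,
                         clustering_exponent = 0.5)
head(clustergram_table(sim$fs, params), 3)
#>   name position phase cluster positional_score
#> 1 L039  3625657   217       1        0.9975657
#> 2 L031  2881991   231       1        0.9976121
#> 3 L034  3160878   238       1        0.9976352

regions <- map_periodic_regions(sim$fs, seed = 1)   # chromogram rows
```

The full three-step pipeline, with TSV outputs and a JSON run manifest,
is `run_patterns()`; the prediction half (train / predict / interplay)
is `run_precision()`.  A thin command-line wrapper over these functions
is installed at `inst/cli/periscan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/periscan.R", package="periscan"))')" \
  patterns --input genes.tsv --genome-length 4641652 --out results/
```

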