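---
title: "Detecting periodic genome layout and its interplay with binding-site sequence"
author: "periscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodic genome layout and its interplay with binding-site sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In compact microbial genomes, genes regulated by the same transcription
factor often recur at roughly regular spacings along the chromosome —
periods of tens to hundreds of kilobases.  Under thermodynamic models of
chromosome folding, genes "in phase" on such a lattice can co-localise in
three-dimensional space, which makes periodic layout a candidate organising
principle for transcription.  `periscan` detects these periods, clusters
the in-phase genes, maps the chromosomal regions that carry a local
pattern, and uses the positional signal — together with binding-site
sequence — to predict transcription-factor targets.

This vignette records the package's statistical model, the choices made
where the design was genuinely open, and what the synthetic benchmarks do
and do not demonstrate.

## The periodicity score and its null

For a candidate period $P$, each feature coordinate $x_j$ becomes a phase
$\phi_j = x_j \bmod P$ and an angle $\theta_j = 2\pi\phi_j/P$.  With the
mean resultant length $R = \lvert\sum_j e^{i\theta_j}\rvert / N$, the score
is the Rayleigh concentration statistic

$$S = N R^2, \qquad 0 \le S \le N,$$

maximal when all features share one phase and invariant under adding a
constant to all coordinates.  This score has the three properties the
analysis relies on: it is calibrated under a uniform null
($S \sim$ approximately Exp(1) for large $N$), it decomposes into
per-feature contributions (the positional score below), and an exact
lattice of period $T$ also scores $S = N$ at every divisor $T/m$, which
is what makes harmonic families visible.

Raw p-values for one period come either from Monte Carlo — positions
drawn uniformly on $[1, G]$, scored at the same $P$, with the add-one
estimator $(1 + \#\{S^* \ge S\})/(n_{mc} + 1)$ — or from the standard
large-$N$ tail approximation of the Rayleigh test (with the second-order
correction terms in $1/N$ and $1/N^2$).  The two agree to well under 0.01
for $N \gtrsim 30$; Monte Carlo is the reference, the approximation the
default inside large scans for speed.

## Multiple testing across a period scan

Two corrections are implemented, and the distinction matters.

`correct_pvalue()` applies the per-period Šidák form
$p_c = 1 - (1-p)^{m(P)}$ with $m(P) = \max(1, \lfloor G/P \rfloor)$:
shorter periods admit more full repetitions along the chromosome, hence
more chances of spurious alignment.  This is the appropriate correction
when a *single* period is tested in isolation.

A DOM scan, however, combs hundreds of thousands of periods, of which
roughly $G/P_{\min} - G/P_{\max}$ are statistically distinguishable
(adjacent periods decorrelate once the accumulated phase across the
chromosome shifts by a full cycle).  A per-period divisor correction does
not control the probability that a fully random genome shows *some*
"significant" period in such a comb.  `scan_periods()` therefore defaults
to an exact max-statistic calibration: `n_null` (default 200) uniform
feature sets of the same size are scanned on the same grid, the maximum
score of each is recorded, and a candidate's corrected p-value is the
add-one tail probability of the null maxima at its score.  The scan-wise
false-positive rate is then controlled at the nominal level by
construction, at the cost of a resolution floor of $1/(n_{null}+1)$ on
corrected p-values — which is why the top candidate of a strong scan is
ranked by score (`top_period()`), not by the saturated p-value.  The
calibration depends only on $(N, G, \text{grid})$ and can be computed once
and reused across scans (`calibrate_scan()`).

## Phase clustering and the positional score

Features in phase for a significant period are grouped by DBSCAN on the
phase circle, with the circular metric
$d(\phi_1,\phi_2) = \min(|\phi_1-\phi_2|,\, P - |\phi_1-\phi_2|)$ so that
clusters straddling phase 0 are never split.  The neighbourhood radius
interpolates geometrically between the period and the user's proximity
threshold $d$,

$$\varepsilon = P^{1-e}\, d^{\,e}, \qquad e \in (0, 1],$$

so $e = 1$ gives the plain proximity threshold and $e \to 0$ degenerates
towards a single cluster; the exponent is the sensitivity dial.  The
geometric form was chosen because it is the unique interpolation that is
scale-free in both $P$ and $d$ (a change of units moves both endpoints
consistently).  DBSCAN is implemented in the package (no suitable
implementation among the declared dependencies) and is deterministic:
points are visited in sorted phase order and border points keep the label
of the first core cluster that reaches them.

The positional score of feature $i$ is its leave-one-out contribution to
the score, $c_i = S(\text{all}) - S(\text{all} \setminus i)$, min–max
normalised to $[0, 1]$ per period (features aligned with the dominant
phase raise $S$; opposed features lower it).  Normalisation is per period
rather than global so the clustergram axis is always $[0, 1]$.  Note the
intrinsic limit visible in the benchmarks: a background gene that lands
in phase *by chance* is positionally indistinguishable from a lattice
member, so positional scores of uniform background genes are spread over
$[0, 1]$ rather than pinned at 0.

## Region mapping

Windows start at $w_0 = 10$ kbp and grow by a factor 1.5 until they cover
95 % of the genome, sliding by half their size (the growth factor and
step are unstated in the original description; both are exposed as
parameters).  Within a window holding at least 8 features, periods from
$w/20$ to $w/4$ are tested on a frequency-uniform grid (4 points per
natural frequency).  Both bounds are deliberate:

* periods longer than $w/4$ do not repeat often enough inside the window
  to be distinguishable from a single cluster of sites — a localised
  clump of features *is* phase concentration at long periods, and testing
  them produces genome-sized artifact regions;
* periods shorter than $w/20$ belong to smaller windows (or the global
  scan), and excluding them keeps the per-window multiple-testing burden
  low.

Window significance uses the same max-statistic calibration (uniform
positions inside the window; the null maximum's distribution is invariant
to rescaling the window, so calibrations are cached per feature count).
`n_null` defaults to 4000 so corrected p-values resolve below the mapping
cutoff of $5 \times 10^{-4}$.

Because an exact lattice scores equally at its divisors, a window's best
period may be a harmonic ($P_0/2$, $P_0/3$) of the true spacing by
sampling noise.  When an integer multiple (2–4x) of the best period is
itself significant at the cutoff, the largest such multiple — the
fundamental spacing — is reported instead; a genuine fine-period pattern
is unaffected because it is antipodal, hence insignificant, at its
multiples.

Overlapping significant windows whose periods agree within the 5 %
"common period" tolerance are merged.  The merged interval is the union
of the *smallest* significant window size in the component (large windows
detect the same lattice but smear its boundaries far beyond the periodic
stretch), while the best p-value of the whole component is kept.  Merging
iterates to a fixed point, so it is idempotent and order-independent.  On
circular chromosomes windows wrap; merged regions crossing the origin are
split into two reported rows, and a split half holding fewer than two
features is dropped.

## Multi-view boosting and the interplay analysis

Target prediction combines two views of each candidate gene: the
sequence view (best log-odds hit of each motif variant on either strand,
$-\infty$ for windows containing N) and the position view (positional
scores at each significant period, computed over all genes jointly —
an unsupervised, label-free transform).  Motif variants are the full
matrix plus versions trimmed of their least-informative flank columns.

The learner is AdaBoost with one modification: at each iteration every
view proposes its best decision stump (column, threshold at midpoints of
sorted distinct values, polarity), and the stump of the lower-error view
is appended with weight $\alpha = \frac{1}{2}\ln((1-\varepsilon)/\varepsilon)$.
Thresholds that fail to strictly separate their neighbouring values
(possible when two feature values differ by an ulp) are discarded, so the
recorded training error always matches the deployed stump.  Class
imbalance is handled by initial weights $1/2N^+$ and $1/2N^-$ per class.
With that initialisation, the quantity AdaBoost provably decreases at
every iteration is the *initial-weight-weighted* exponential loss
$\sum_i w^0_i e^{-y_i F(x_i)}$ (the product-of-$Z$ argument); the
unweighted loss can transiently rise on imbalanced data, and the tests
assert the weighted form.

For the interplay analysis, the per-iteration outputs
$\alpha_t h_t(x_i)$ are collected into one gene-by-iteration matrix per
view.  A decision stump has a sign indeterminacy ($h$ and $-h$ with
flipped polarity describe the same boundary), so each column is oriented
to correlate positively with its view's aggregate score before display —
a presentation convention, not a change to the model.  Regularised CCA
(columns standardised; ridge $\lambda$ on the correlation diagonals,
default 0.1 when either block has at least rows/2 columns, else 0;
whitening + SVD) returns the canonical correlations and, for the
correlation circle, the loadings of every variable on the bisector of the
first two paired variates.  Opposite-sign loadings of the two blocks on
the first variate indicate that sequence strength and positional
regularity trade off across the regulon.

## The synthetic benchmarks

The generators define the conditions under which every statistical claim
is tested:

* **Genome-wide scan benchmark** — a 4,641,652-bp circular chromosome
  (the *E. coli* K-12 length), a 93-kbp planted period (the spacing
  reported for several major *E. coli* regulons), 40 lattice sites with
  2-kbp Gaussian jitter, 30 uniform background sites; lattice offset
  uniform per seed so no test can overfit phase 0.  Scans comb
  [50, 500] kbp at 3 bp.
* **Null calibration** — 50-feature uniform genomes; raw p-values at a
  fixed 100-kbp period must pass a Kolmogorov–Smirnov test against
  Uniform(0,1), and full scans must report any significant period in at
  most a few percent of draws.
* **Phase clustering** — two Gaussian phase clusters (sd 1.5 kbp) at
  phases $0.2P$ and $0.7P$, ten members each, plus five uniform noise
  phases; clustered with exponent 0.75 and minimum cluster size 3 (with
  only five noise points, a minimum of 2 lets chance noise pairs form
  spurious clusters).
* **Region mapping** — a 20-kbp lattice of 12 sites confined to
  [1.0, 1.3] Mb with 200-bp jitter over 20 background sites: a clean
  local pattern whose detection is nonetheless near the resolution limit
  of 12 sites against a $5\times10^{-4}$ cutoff.
* **Regulon benchmark** — 40 targets / 80 non-targets, 200-bp promoter
  sequences with a 16-bp palindromic consensus implanted at probability
  0.9, targets on the 93-kbp lattice.  One-view regimes use no implant
  (position only) or near-uniform positions with certain implantation
  (sequence only).  The anti-correlated regime is balanced (60/60,
  because the traded-off signal lives only in targets) and binary: half
  the targets sit tightly on the lattice with no binding site, half carry
  a verbatim site at uniform positions — the limiting case of implant
  probability decreasing with lattice fidelity.

What passing these benchmarks shows: correct null calibration of the
scan statistics, power to recover planted structure at realistic sizes,
and internal consistency of every pipeline stage.  What it does not
show: robustness to the pathologies of real annotation data — operon
structure (partially addressed by the proximity filter), missing and
false regulatory interactions, non-uniform gene density around the
origin/terminus axis, or sequence background more structured than
i.i.d. nucleotides.  Conclusions about any real regulon still require
the usual orthogonal evidence.

## Numerical choices and limitations

* The scan kernel is C++ (Rcpp); scores match the R reference
  implementation to $10^{-9}$ and a brute-force complex sum to
  $10^{-12}$ in tests.
* Corrected p-values are floored at $1/(n_{null}+1)$; raise `n_null` if
  p-values below the floor are needed.
* Scores are translation invariant at every period for plain shifts;
  under shifts modulo $G$ invariance holds exactly on the CIRC grid
  ($P = G/k$) only, since wrapping changes a phase by $-G \bmod P$.
* Proximity filtering is greedy keep-first in coordinate order (with a
  wrap check on circular chromosomes dropping the later coordinate):
  deterministic and idempotent; the filtered set is what all downstream
  stages see.
* Degenerate inputs are errors, not guesses: fewer than 2 features after
  filtering, single-class labels, constant CCA columns, thresholds that
  separate nothing.
* Benchmark sizes in the test suite (200 null scans, 100 recovery seeds,
  50 clustering/mapping seeds, 20 boosting seeds) balance statistical
  resolution against a test suite that completes in a few minutes.
* The boosting weak learner is a decision stump per view; richer base
  classifiers (and more than two views) fit the same interface but are
  not provided.
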