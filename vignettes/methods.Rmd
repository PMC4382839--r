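---
title: "Methods: resampling-based sweep scans with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling-based sweep scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The statistics

`sweepscan` consumes per-locus summaries of two or more diploid
populations: the expected heterozygosity of each population and a single
multi-population F_ST per SNP. Three multi-locus statistics are computed
in every sliding window of n consecutive loci centred on a SNP:

* **mean heterozygosity**, one track per population — depressed inside a
  selective sweep affecting that population;
* **mean F_ST** — elevated when frequencies have diverged locally;
* **S²F_ST**, the variance of the per-locus F_ST values in the window —
  elevated when swept haplotypes differ between populations, producing an
  alternation of near-fixed high and near-zero low F_ST at consecutive
  loci. Mean F_ST averages this alternation away; its variance does not.

Windows are defined in locus-index space (a fixed count of SNPs), not in
base pairs, so marker density does not change the sampling properties of
the window statistic. Windows never span chromosome boundaries.

## The resampled baseline

Significance is judged against an empirical neutral expectation rather
than a parametric model. For each window size, `r` random sets of the
same number of loci are drawn from the pool by *unrestricted random
sampling* — loci drawn independently and uniformly **with replacement**,
ignoring chromosomal adjacency — and each statistic is computed on every
set with the same code path as the observed windows. The underlying
assumption is that historic selection is localized, so the genome-wide
(or chromosome-wide) frequency pool is dominated by neutral and
demographic forces; demography affects all loci and is therefore absorbed
into the baseline.

One set of draws per (pool, window size) serves all statistics, since a
resampled locus set determines all of them simultaneously; the baseline
is built once per size, not per window. The observed window statistic is
assigned the *inclusive-rank* tail percentile

    p_lower = #(baseline <= observed) / r
    p_upper = #(baseline >= observed) / r

(lower tail for heterozygosity, upper for mean F_ST and S²F_ST). An
observed value more extreme than every baseline value gets p = 1/(r+1),
not 0, so the −log10(p) display transform is finite; this floor is the
resolution limit of `r` resamples (−log10 ≈ 4.000043 at r = 10⁴). A
normal-approximation mode (`method = "zscore"`) standardises the observed
value against the baseline's mean and standard deviation instead; a
zero-variance baseline is flagged degenerate and returns p = 1, since a
constant statistic carries no signal.

## Aggregation across window sizes and interpretation

Every locus is evaluated at each window size that fits (default grid
`default_window_sizes()`: 5 to 65 by 2, 31 sizes), and per statistic the
*smallest* percentile across sizes is kept together with the achieving
size. Ties across sizes are resolved toward the smaller window, which
localizes signals more sharply. Loci near chromosome ends are evaluated
only at the sizes that fit — never padded or wrapped — and `n_sizes`
records how many sizes contributed so scores can be stratified by it;
loci with no fitting window at all are marked `unevaluated` rather than
zero-filled.

Outcomes at significance level `alpha` (default 0.01, a user parameter —
the method is for candidate discovery, and no threshold turns it into a
proof of selection):

| pattern | heterozygosity | S²F_ST | reading |
|---|---|---|---|
| `none` | not extreme | not extreme | no signal; does not exclude selection |
| `old_selection` | low in **all** populations | quiet (and mean F_ST quiet) | sweep in the ancestral population, before the split |
| `new_selection_one_pop` | low in **one** population | high | post-split sweep in one derived population |
| `new_selection_both` | low in **all** populations | high | post-split sweeps in both derived populations |

Classification uses heterozygosity and S²F_ST only; mean F_ST percentiles
are reported as a track but F_ST alone is a poor selection statistic.

### Maximum over sizes inflates extremes

Taking the minimum percentile over 31 correlated window sizes means that
under pure neutrality more than 1% of loci show a best percentile below
0.01 — the per-locus best score is not itself a p-value. This is by
design (the track is exploratory); no multiple-testing correction is
applied. Quantify the inflation for a given configuration by scanning
re-simulated neutral panels with `simulate_neutral()`.

### Peak ties

Inside a strong sweep many loci hit the percentile floor 1/(r+1)
simultaneously. `peak_locus()` therefore breaks −log10 ties by the most
extreme *observed* statistic value at the best window (lowest mean
heterozygosity; highest F_ST mean or variance), which restores a unique,
scientifically motivated peak.

## Design choices where the design was open

* **F_ST estimator.** The input format carries frequencies only, so the
  converter uses the frequency-based Wright/Nei form
  F_ST = (H_T − H_S)/H_T with H_S the unweighted mean of per-population
  2p(1−p) and H_T = 2p̄(1−p̄) at the mean frequency; sample-size
  weighting is available (`weighted = TRUE`). Values are clamped to
  [0, 1] and defined as 0 when H_T = 0. Any monotone-equivalent estimator
  would yield the same rank-based percentiles as long as observed and
  resampled statistics share it — which they do by construction (one code
  path).
* **Heterozygosity.** Expected, 2p(1−p), since the panel stores one value
  per population; observed heterozygote fraction is available as a
  converter flag (`observed = TRUE`).
* **Variance denominator.** S²F_ST uses the sample variance (n−1) by
  default; the population variance (n) is selectable
  (`var_type = "population"`). Percentiles are invariant to this choice
  because both sides of the comparison share it.
* **Pool scope.** Baselines are drawn from the same chromosome by
  default; `pool_scope = "genome"` pools all loci, useful for sparse
  chromosomes at the cost of mixing chromosome-specific backgrounds.
* **Per-population heterozygosity tracks.** Each population's mean
  heterozygosity gets its own percentile track (needed to separate the
  one-population from the both-populations outcome); mean F_ST gets a
  reported track of its own even though classification ignores it.
* **RNG discipline.** A single seeded generator streams all draws in a
  documented order — chromosomes in table order, window sizes ascending,
  one block of `size × r` indices per baseline — so a scan is
  reproducible bit-for-bit from `(input, config, seed)`.

## The simulator: what it emulates and what it does not

`simulate_neutral()` generates frequency-level neutral panels under the
Balding–Nichols model: per locus an ancestral frequency p is drawn
uniformly on [0.05, 0.95], and each population's frequency from a Beta
distribution with mean p and variance F·p·(1−p). The differentiation
parameter `F` (default 0.1, a typical between-continent human value)
controls the expected F_ST of the panel; with the two-population Wright
estimator used here the realised mean F_ST is ≈ F/(2−F) (≈ 0.05 at
F = 0.1), which the tests pin against an independent Monte-Carlo oracle.
Default panels use 10⁴ loci spaced 1 kb apart — large enough for stable
baselines, small enough that a full 31-size scan with r = 10⁴ runs in a
couple of seconds.

`inject_sweep()` plants the interpretable patterns directly in summary
space: heterozygosity of the targeted population(s) is multiplied by a
factor ramping linearly from `het_reduction` at the centre to 1 at the
sweep edges (triangular profile), and for post-split modes the F_ST
values inside the sweep are blended toward an alternation of near-fixed
high (0.95) and near-zero low (0.02) values — the alternative-fixation
haplotype mosaic — with the blend weight following the same ramp.

Deliberate simplifications: loci are exchangeable and unlinked (no
linkage disequilibrium, no recombination map, no allele-frequency
spectrum from a demographic history), sweeps have a stylised triangular
profile, and sampling noise of finite genotype counts enters only through
`sample_genotype_counts()`. Passing tests on these panels demonstrates
the *statistical machinery* — calibration of percentiles under
exchangeability, power to localize a strong planted signal, determinism —
not performance on real genomes, where background LD and demography
widen the null. Coalescent simulators are the higher-fidelity alternative
when that fidelity is needed.

## Numerical and degenerate-input behaviour

Rolling means and variances use cumulative sums (inputs are bounded in
[0, 1], so catastrophic cancellation is not a concern at window sizes
≤ 65); negative rolling variances from rounding are clamped to 0.
Constant pools give degenerate baselines (all values equal) and are legal;
chromosomes shorter than the smallest window contribute nothing and warn
when no chromosome is long enough. Duplicate positions are kept with a
warning — windows operate on record order. BED gene intervals are 0-based
half-open on disk and converted to 1-based inclusive internally.

## Gene-set enrichment

`score_genes()` summarises the −log10 track over the loci inside each
(optionally flanked) gene interval; the default summary is the maximum,
which captures single-peak sweeps (mean is available). `gene_set_test()`
compares the mean candidate-gene score with `n_random` random same-size
gene sets drawn without replacement from the scored universe; the
empirical p is the inclusive fraction of random sets scoring at least as
high, floored at 1/(n_random+1). Random sets are matched on set size
only; long genes collect more loci and hence higher maxima, so candidate
lists biased toward long genes inherit that bias — match on length or
SNP count externally when that matters.

## Known limitations

* A swept haplotype fully fixed for alternative alleles has F_ST = 1 at
  *every* locus inside it: windows within it see zero F_ST variance, so
  the S²F_ST signal comes only from the sweep's edges. Haplotypes shorter
  than the smallest window are easily overlooked; drop the smallest sizes
  if average haplotype length is suspected to be below them.
* Physical positions are used as-is; converting to genetic distances to
  absorb recombination-rate variation is recommended for real scans but
  out of scope here.
* Percentile resolution is bounded by r (floor 1/(r+1)); raise r for
  deeper tails. Baselines hold r values per (statistic, size) in memory —
  r = 10⁶ with 31 sizes is a few hundred MB; the r = 10⁸ regime would
  need a gridded counting approximation that is not implemented.

## Problem sizes used by the test suite

The suite simulates at desk scale, chosen to keep the full run near one
minute while leaving the statistical checks well-powered: calibration and
localization panels of 10⁴ loci with r = 10⁴ resamples, 50 seeded
replicates for the localization rate, 200 trials for permutation-test
calibration, and r ≤ 1000 baselines for the exact brute-force percentile
oracle.
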