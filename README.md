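# sweepscan

Resampling-based genome scans for signatures of positive selection from
matched allele-frequency data in two or more diploid populations.

## The problem

When an adaptive allele rises in frequency it drags linked neutral
variants with it, depressing heterozygosity in the surrounding region — a
selective sweep. Compared against a related population with no history of
selection at that locus, the swept region also shows elevated
allele-frequency differentiation. Because the swept haplotypes differ
between populations, per-locus F\_ST values *alternate* between high and
low along the region; this oscillation is captured by the multi-locus
F\_ST variance

    S²F_ST = Var( F_ST(locus i), i in window )

computed over the n = 5, 7, 9, …, k consecutive loci of a sliding window,
and is often more informative than mean F\_ST, which averages the high
and low values away.

`sweepscan` scores every SNP as follows:

1. Sliding windows of each size (default 5 to 65 by 2, i.e. 31 sizes) are
   centred on every SNP, never spanning chromosome boundaries.
2. For each window: per-population mean expected heterozygosity, mean
   F\_ST, and S²F\_ST.
3. For each (pool, window size), a baseline distribution is built by
   *unrestricted random sampling*: r random sets of the same number of
   loci drawn uniformly with replacement from the chromosome (or genome),
   with the identical statistic formulas.
4. Each observed window statistic gets a tail percentile — the inclusive
   rank in the sorted baseline divided by r (lower tail for
   heterozygosity, upper tail for the F\_ST statistics), floored at
   1/(r+1) so the −log10 transform stays finite.
5. Per locus and statistic the most extreme percentile across window
   sizes is kept with the window size achieving it, reported as
   −log10(percentile), and the locus is classified as `none`,
   `old_selection` (sweep before the population split: all populations
   low in heterozygosity, F\_ST quiet), `new_selection_one_pop`, or
   `new_selection_both` (sweeps after the split: elevated S²F\_ST).

The scan is a hypothesis-generating tool: it flags candidate regions for
downstream validation, it does not prove selection.

## Worked example

```r
library(sweepscan)

# neutral two-population background (Balding-Nichols, F = 0.1) with a
# strong post-split sweep in population 1 planted at locus 2500
tab <- simulate_neutral(n_loci = 5000, F = 0.1, seed = 42)
tab <- inject_sweep(tab, "chr1", 2500, 40, mode = "new_one_pop",
                    het_reduction = 0.1)

sc <- sweep_scan(tab, r = 10000, seed = 42)
summary(sc)
```

```
Selective-sweep genome scan
  loci: 5000  populations: 2  chromosomes: 1
  window sizes: 31 ( 5 to 65 ), r = 10,000 (chromosome pool, percentile)
  evaluated loci: 4996  alpha = 0.01
  outcomes: none=4853, old_selection=64, new_selection_one_pop=68, new_selection_both=11, unevaluated=4

Top loci by -log10 F_ST-variance percentile:
     name chrom     pos p_fst_var size_fst_var nlp_fst_var               outcome
 rs002459  chr1 2459000 9.999e-05           63    4.000043                  none
 rs002460  chr1 2460000 9.999e-05           57    4.000043 new_selection_one_pop
 rs002461  chr1 2461000 9.999e-05           57    4.000043 new_selection_one_pop
 rs002462  chr1 2462000 9.999e-05           57    4.000043 new_selection_one_pop
 rs002463  chr1 2463000 9.999e-05           55    4.000043 new_selection_one_pop
```

The sweep region floods the top of the S²F\_ST track: its percentiles hit
the resolution floor 1/(r+1) (−log10 ≈ 4.000043 at r = 10⁴), and the loci
are classified `new_selection_one_pop`. `peak_locus(sc, "het1")` returns
2503 — three loci from the planted centre (ties at the floor are broken
by the lowest observed mean heterozygosity). `plot(sc, "chr1")` draws the
−log10 tracks along the chromosome; `write_scan_table(sc, "results.tsv")`
writes the per-locus table.

Real data enter either as the six-column text panel
(`read_freq_table()`: name, chromosome, position, heterozygosity per
population, F\_ST) or as genotype counts (`read_genotype_counts()` +
`convert_genotypes()`, which drops loci with fewer than 10 genotypes in
any population and computes 2p(1−p) heterozygosity and Wright F\_ST).
`score_genes()` and `gene_set_test()` compare a candidate gene list
against random gene sets for enrichment of selection signals. A shell
front end lives at `exec/sweepscan` (subcommands `scan`, `plot`,
`enrich`).

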