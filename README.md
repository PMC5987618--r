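# utr3evo

Comparative analysis of 3' UTR evolution across teleost genomes.

3' untranslated regions carry the binding sites — miRNA targets above
all — that govern mRNA stability, localization and translation, and
their length and rate of change may matter for rapidly diversifying
clades such as cichlid fishes. `utr3evo` implements, as a tested and
reusable R package, the full comparative workflow for asking whether a
focal clade's 3' UTRs are longer, faster-evolving, repeat-depleted, or
richer in miRNA targets than those of background species:

1. **Feature extraction** — parse genome FASTA + GFF3, keep the
   canonical transcript of each gene (the stop-codon-bearing isoform
   with the longest CDS), extract spliced 5' UTR / CDS / 3' UTR
   sequences, and summarize length distributions in 50-nt windows.
2. **Orthology** — conjoin BLASTP HSPs per gene pair by colinear
   chaining, cluster genes into families by average-linkage
   agglomeration (weight floor 5 bits, ratio 0.33, size cap 100000),
   and extract 1:1 ortholog sets present in every species.
3. **Repeat content** — fraction of repeat-masked bases in 3' UTRs,
   5' UTRs, CDS and the whole genome per species, compared with an
   exact paired Wilcoxon signed-rank test.
4. **miRNA targets** — strict-seed scanning (perfect Watson-Crick
   complementarity to miRNA positions 2-8) with a nearest-neighbor
   stacking free-energy cutoff of -20 kcal/mol.
5. **Rate divergence** — per-gene two-regime Brownian-motion maximum
   likelihood on a painted time-calibrated tree. With tip covariance
   `V = σ²_f T_f + σ²_b T_b` (shared root-to-MRCA path lengths per
   regime) and the root profiled by GLS, each gene yields rates
   `σ̂²_focal`, `σ̂²_background` and the statistic
   `log10(σ̂²_f / σ̂²_b)`, t-tested against 0 genome-wide. The clade
   ratio of mean 3' UTR lengths is tested the same way.
6. **Enrichment** — top-5% outlier gene sets tested per term with the
   one-sided Fisher exact (hypergeometric upper-tail) test and
   Benjamini-Hochberg adjustment.

A fully seeded synthetic-data module generates genomes, annotations,
repeat tracks, miRNAs, similarity tables and term maps with known
planted truth, so the whole pipeline is testable end to end without
any downloads. `run_pipeline()` orchestrates all stages from one
configuration and writes TSV tables, a plain-text report and a
checksummed JSON manifest.

## Worked example

Simulate 200 genes on the default 9-taxon tree with the focal-clade
rate doubled, fit per-gene two-regime BM rates, and test the log10
rate ratios:

```r
library(utr3evo)

tp <- make_default_tree()
traits <- simulate_traits(tp$tree, tp$painting,
                          sig2_focal = 2, sig2_background = 1,
                          root_value = 1000, n_genes = 200, seed = 42)
fits <- fit_bm_rates(traits, tp$tree, tp$painting)
tidy(fits)
#> # A tibble: 200 × 8
#>   gene_id sig2_focal sig2_background root_state loglik rate_ratio log10_ratio
#>   <chr>        <dbl>           <dbl>      <dbl>  <dbl>      <dbl>       <dbl>
#> 1 g00001       0.789           0.419       996.  -28.7       1.88       0.275
#> 2 g00002       1.90            0.333       996.  -30.4       5.72       0.758
#> 3 g00003       2.09            0.591      1005.  -31.8       3.54       0.549
#> # ℹ 197 more rows

glance(fits)
#> # A tibble: 1 × 10
#>   n_genes  n_ok n_boundary n_degenerate mean_log10_ratio     t    df  p_value
#>     <int> <int>      <int>        <int>            <dbl> <dbl> <dbl>    <dbl>
#> 1     200   200          0            0            0.445  10.7   199 1.65e-21
```

The planted 2× rate difference is detected decisively (mean log10
ratio 0.445, t = 10.7, p ≈ 2e-21; note that with nine tips the
estimator itself contributes a positive offset to the mean — see the
methods vignette's calibration analysis before reading such a mean as
an unbiased effect size). `autoplot(fits)` draws the log10-ratio
histogram.

With nine species whose 3' UTR repeat fraction is below the
genome-wide fraction in every species, the exact signed-rank p is
2/2⁹:

```r
genome_frac <- c(0.29, 0.27, 0.26, 0.25, 0.37, 0.25, 0.30, 0.18, 0.52)
utr3_frac   <- c(0.15, 0.12, 0.13, 0.11, 0.20, 0.10, 0.14, 0.09, 0.34)
paired_signed_rank(utr3_frac, genome_frac)
#> # A tibble: 1 × 4
#>   n_pairs statistic p_value method
#>     <int>     <dbl>   <dbl> <chr>
#> 1       9         0 0.00391 exact
```

The full synthetic pipeline is one call:

```r
cfg <- simulation_config(seed = 7, n_genes = 60,
                         sig2_focal = 2, sig2_background = 1)
res <- run_pipeline(cfg, "out/")
```

A thin command-line wrapper with `simulate` and `all` subcommands is
installed at `inst/scripts/utr3evo.R`.

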