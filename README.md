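# goftscan

Window-based association testing of **sets of common and rare genetic
variants** against quantitative or binary traits, using the Berk–Jones
goodness-of-fit statistic on per-variant p-values.

The package is for statistical geneticists analysing sequencing (or
imputed dosage) data who want a set test tuned to *weak, sparse* signal —
the regime of common variants with small effects and rare variants that
are weakly associated at the population level — and who may want to fold
a second source of per-variant p-values (e.g. array-based results) into
the same windows as a p-value-level meta-analysis.

## The statistic

Under no association, the p-values of the variants in a genomic window
are Uniform(0, 1). For the sorted p-values `p₁ ≤ … ≤ p_L` of a window,
the scan computes

    G = L · max_{1≤j≤L} 2·K(j/L, p_j)

where `K(t, x) = t·log(t/x) + (1−t)·log((1−t)/(1−x))` for `0 < x < t < 1`,
`K = 0` for `t ≤ x`, and `K(1, x) = −log x` at the top order statistic
(the analytic limit). `K` is the Bernoulli Kullback–Leibler divergence:
large `G` means some fraction `j/L` of the window's p-values is
implausibly small under uniformity. Unlike sum-based set tests, the
maximisation adapts to where in the order statistics the signal sits;
unlike the minimum p-value, it is not tied to a single marker.

The pipeline around the statistic:

1. **Segmentation** — fixed-width windows (default 10 kbp), 0-based
   half-open, anchored at coordinate 0.
2. **Rare-variant collapsing** — within each window, maximal runs of
   rare variants (MAF < 5%) between adjacent common variants are summed
   into burden pseudo-variants.
3. **Per-variant tests** — OLS slope t-test (quantitative) or logistic
   score test (binary) per common variant and burden column, covariates
   supported.
4. **Permutation null** — the phenotype assignment is permuted `M` times
   (default 1000); the empirical p-value of a window is
   `#{G_perm ≥ G_obs}/M`. Genotype rows are permuted jointly, so LD is
   preserved.
5. **Meta-analysis (optional)** — an external table of per-variant
   p-values is merged into the windows (position-matched, duplicate
   sites dropped) before the statistic.

## Worked example

Simulate a small cohort — 142 individuals, 20 windows of 25 variants
with local LD, four windows carrying a block of 8 same-direction rare
causal variants — and scan it:

```r
library(goftscan)

sc  <- sim_scenario(n_samples = 142, n_windows = 20, variants_per_window = 25,
                    true_window_fraction = 0.2, causal_per_true_window = 8,
                    effect_size = 0.45, seed = 42)
sim <- simulate_genotypes(sc)
sim$genotypes
#> genotype_matrix: 142 samples x 500 variants (314 rare at MAF < 0.05, 17 monomorphic)

ph  <- simulate_phenotype(sim$genotypes, sim$causal, sc)
res <- goft_scan(sim$genotypes, ph, window_width = 10000,
                 n_permutations = 1000, seed = 7)
head(as.data.frame(res)[order(res$p_empirical),
                        c("window_id", "L", "n_burden", "G", "p_empirical")], 5)
#>        window_id  L n_burden         G p_empirical
#>  3:170000-180000 14        6 10.327962       0.015
#>    3:50000-60000 14        6  9.294278       0.034
#>  3:120000-130000 19        8  8.465730       0.062
#>  3:100000-110000 17        7  7.184432       0.092
#>        3:0-10000 14        6  4.047806       0.299

subset(sim$truth, is_true)$window_id
#> [1] "3:50000-60000"   "3:80000-90000"   "3:100000-110000" "3:180000-190000"
```

Each row is one 10-kbp window: `L` is the number of p-values entering
the statistic (common variants plus rare-run burden columns,
`n_burden` of them), `G` the Berk–Jones statistic, and `p_empirical`
the fraction of 1000 phenotype permutations whose statistic reached the
observed one. Two of the four causal windows head the ranking at this
small sample size; with `n = 142` and per-window heritability of a few
percent, partial power is the expected behaviour, not a defect.

Real data enter through `read_vcf()` (GT or DS fields),
`read_dose_tsv()` and `read_phenotype_tsv()`; results leave through
`write_results_tsv()` / `write_windows_bed()`. An external p-value
table (`read_external_tsv()`) passed as `external =` to `goft_scan()`
performs the meta-analysis merge. The same pipeline is scriptable via
`inst/cli/goftscan.R` (`run`, `meta`, `simulate` subcommands).

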