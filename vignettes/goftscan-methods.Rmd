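---
title: "Window-based goodness-of-fit association scans: methods and design"
author: "goftscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based goodness-of-fit association scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goftscan)
```

## The problem

Much of the heritability of complex traits is carried by variants that
single-marker association tests miss: common variants with small allelic
effects, and rare variants whose effects may be strong per allele but are
weak at the population level. Both regimes produce *weak, sparse* signal —
a handful of modestly small p-values scattered among many null ones. Set
tests that sum evidence over a region dilute such signal; the minimum
p-value fixates on a single marker.

`goftscan` takes the goodness-of-fit route. Under the null hypothesis of
no association, the per-variant p-values in a genomic window are a sample
from Uniform(0, 1). Association anywhere in the window shows up as a
departure of the empirical distribution of those p-values from
uniformity, and the Berk–Jones statistic is an optimality-backed way to
measure that departure in the weak/sparse regime. Because the statistic
consumes only p-values, windows can also be *enlarged* with p-values
computed from a second data source — array-based results merged into
sequencing windows — giving a p-value-level meta-analysis for free.

## The statistic

Let $p_1 \le \dots \le p_L$ be the sorted p-values of the $L$ testable
quantities in a window. The window statistic is

$$G = L \cdot \max_{1 \le j \le L} 2\,K\!\left(\tfrac{j}{L},\, p_j\right),
\qquad
K(t, x) = t \log\frac{t}{x} + (1 - t)\log\frac{1 - t}{1 - x}
\ \text{ for } 0 < x < t < 1,$$

with $K = 0$ whenever $t \le x$ and $K = +\infty$ when $x = 0 < t$.
$K$ is the Kullback–Leibler divergence between Bernoulli($t$) and
Bernoulli($x$): it asks how surprising it is that a fraction $j/L$ of the
p-values sits at or below $p_j$. The maximisation adapts to the signal
pattern — it is not tied to the single smallest p-value, which matters
because under sparse weak effects the most informative order statistic is
often not the first.

Two boundary conventions are ours to fix, because the piecewise
definition above is silent or degenerate there:

* **$t = 1$.** The top order statistic always has $t = j/L = 1$, which the
  literal "otherwise" branch would send to $+\infty$ for every window. We
  use the analytic limit $K(1, x) = -\log x$ (the $0\log 0 = 0$
  convention), which is the standard Berk–Jones form.
* **$p = 0$.** Permutation-derived input p-values can be exactly zero.
  They are clamped to a floor (default `1e-15`, configurable) before the
  divergence, and the clamping is reported. The $+\infty$ sentinel
  therefore never propagates into downstream arithmetic.

Ties among sorted p-values need no special handling; the formula is
well defined under ties. `log(t/x)` is evaluated as `log(t) - log(x)` and
the $1-t$ factors via `log1p`, so extreme ratios do not overflow.

## Per-variant tests

The scan needs one association p-value per testable column. For a
quantitative trait this is the two-sided t-test on the slope of an
additive least-squares regression of trait on dosage; for a binary trait,
the logistic score test under the null model. Both accept covariates.
These are the field-standard defaults for dosage data; fractional
(imputed) dosages enter the regression as-is. Zero-variance columns are
flagged untestable and excluded from the window's p-value set (they are
*not* assigned p = 1), and a window in which nothing is testable is
reported as untested.

Internally the tests are evaluated as a matrix engine: the design columns
are centred (and residualised against covariates, once) ahead of time, so
each phenotype evaluation — observed or permuted — is a single
cross-product. For the quantitative case this reproduces `lm()`
coefficients exactly (the tests assert equality at `1e-10`); for the
binary case without covariates it is the textbook intercept-only score
test, and with covariates the efficient score with the information
correction for the fitted nuisance model.

## Segmentation and rare-variant collapsing

Windows are fixed-width, half-open, 0-based intervals anchored at
coordinate 0 — *not* at the first observed variant — so window boundaries
are reproducible across datasets and runs; a variant at 1-based position
$pos$ belongs to the window containing $pos - 1$. The last window of a
chromosome is simply the last tile that contains a variant. Window width
defaults to 10 kbp and is a free parameter; widths of 10/100/500 kbp are
the usual operating points, with the trade-off that wide windows carry
more noise variants and therefore struggle to reach very small p-values
even when they contain signal (the tests demonstrate this dilution).

A variant is **rare** when its MAF is *strictly* below the threshold
(default 5%; MAF exactly 0.05 is common). MAF is always computed from the
analysed samples, not from external reference frequencies, and
monomorphic variants are dropped before classification. Within each
window, maximal runs of rare variants delimited by common variants are
collapsed by per-sample genotype summation into one burden pseudo-variant
per run; runs before the first and after the last common variant are
collapsed as their own groups rather than discarded (discarding them
would throw away signal for no reason). Collapsing never crosses a window
boundary — the window is the analysis unit. Setting the threshold to 0
disables collapsing exactly. The summation coding targets the regime
where rare causal alleles push the trait in a shared direction; when
effects are antagonistic within a run, the burden column loses power by
construction, which is a known property of burden coding rather than an
implementation choice.

## Permutation null and empirical p-values

Window sizes vary and variants within a window are in linkage
disequilibrium, so no single asymptotic null fits all windows. The scan
instead permutes the sample-to-phenotype assignment $M$ times (default
1000) and recomputes every per-variant p-value and every window's $G$
under each permutation. Permuting the assignment is equivalent to jointly
permuting whole genotype *rows*; genotype columns are never shuffled, so
within-window LD is preserved under the null. The empirical p-value of
window $s$ is
$p_s = \#\{G_s^{(m)} \ge G_s\} / M$ — the weak inequality means ties
count as exceedances, so a window whose observed configuration recurs
among the permutations cannot receive p = 0 by accident. The plain ratio
can still return 0 when the observed statistic exceeds every permuted
one; the $(\#+1)/(M+1)$ estimator is available behind `add_one = TRUE`
for consumers that need strictly positive values, but the default
preserves the plain formula.

Design choices worth stating:

* **One shared permutation per index $m$ across all windows**, generated
  reproducibly from `(seed, m)`. Exchangeability of samples is a
  genome-wide property, so sharing is valid, much cheaper than per-window
  draws, and makes results independent of scheduling; any parallel
  execution over windows inherits determinism from the per-$(seed, m)$
  streams.
* **Collapsing structure is frozen from the observed data.** MAF is
  invariant under phenotype permutation, so which variants form which
  runs never changes; only the regression p-values are recomputed.
* **Covariates under permutation.** The permuted phenotype is
  re-residualised against the covariates each time (for the quantitative
  engine this is one small projection per permutation). This is the
  standard raw-permutation approximation; it is exact when covariates and
  genotypes are independent.

Empirical p-values take values on the grid $\{0, 1/M, \dots, 1\}$, so a
granularity of $1/M$ bounds the smallest resolvable p-value; $M$ should
be chosen with the intended significance threshold in mind.

## Meta-analysis by p-value merging

An external table of per-variant p-values (chrom, pos, id, p) is merged
into the windows before the statistic: each record joins its window by
position, records duplicating an internally tested site on
(chrom, pos) are dropped — the internal, sequencing-derived p-value wins,
so a site is never counted twice — and the remaining records extend the
window's sorted set. Merging is idempotent, and records outside every
window are counted and reported, not fatal.

The permutation null for merged windows needs the external p-values'
behaviour under the null, but the external genotypes are not available to
permute. We re-draw the external p-values from Uniform(0, 1) under each
permutation — their exact null distribution when the external study has
no signal — and flag this approximation in the scan metadata
(`external_null = "uniform_resampling"`). When the external study *does*
carry signal at a site, the approximation is conservative for the null
windows and leaves the observed merged $G$ untouched. The tests confirm
that merging a null-uniform external source does not inflate the
false-positive rate, and that merging an informative source raises power.

## The synthetic-data generator

Real sequencing cohorts with simulated trait architectures (the usual
evaluation substrate for this kind of method) are not redistributable, so
the package carries a generator that targets the *statistical regime*
such data occupy rather than any particular cohort:

* a mixed MAF spectrum — a fraction of variants (default 70%) drawn
  uniformly from [0.001, 0.05), the rest from [0.05, 0.5];
* local LD from a latent Gaussian AR(1) process per haplotype
  (`ld_rho`, default 0.5): allele $=\,1\{Z < \Phi^{-1}(\mathrm{MAF})\}$,
  dosage = sum of two independent haplotypes, so realised frequencies are
  binomial around their targets and adjacent variants correlate
  positively;
* sparse causal structure: a subset of windows is "true", each carrying a
  *contiguous block* of rare causal variants (default 8) with one shared
  effect sign, emulating a compact functional element — the structure
  both the same-direction assumption and run-based collapsing are
  designed for — plus optionally causal common variants;
* a Gaussian trait $y = \sum_k \beta_k g_k + \varepsilon$ with
  configurable noise SD and independent noise per replicate (replicates
  share the genetic component, as in replicate-based power estimation).

The default cohort size is 142, a deliberately small sequencing-study
scale. The generator does **not** emulate pedigree structure or
relatedness (the scan assumes exchangeable, unrelated samples),
population stratification, realistic recombination-driven LD decay,
genotyping error, or missingness patterns. Passing tests on this
generator therefore demonstrate correctness of the statistical machinery
and the qualitative orderings (collapsing gain, meta gain, window-size
dilution, calibration) — not performance on any particular real cohort.

## Verification problem sizes and tolerances

The statistical checks are sized to be decisive without being wasteful:

* **Branch/oracle checks.** The divergence is verified on a 100-point
  grid of the $t \le x$ half-plane (exactly zero) and against direct
  arithmetic at interior points; the window statistic is compared with a
  naive term-by-term evaluation on 1,000 random p-vectors ($L \le 50$) at
  relative error $10^{-12}$.
* **Null calibration.** A null scenario with $n = 200$ samples, 200
  windows of 30 variants and $M = 200$ permutations; the false-positive
  rate at $\alpha \in \{0.01, 0.05, 0.10\}$ must fall in the exact
  binomial 95% acceptance region. Note the plain $\#/M$ estimator is
  slightly anti-conservative on its discrete grid
  ($P(p \le \alpha) = (\lfloor \alpha M \rfloor + 1)/(M+1)$ under the
  null), which the binomial region comfortably absorbs at these sizes.
* **Power orderings.** Collapsing gain: 100 true windows, $n = 400$,
  8 same-direction rare causal variants per window ($\beta = 0.25$,
  noise SD 1 — per-window heritability ≈ 2.5%, chosen so power sits in
  the informative mid-range); power at $\alpha = 0.05$ with collapsing
  must not fall below power without. Meta gain: one 1,100-sample cohort
  split 300 (sequencing) / 800 (array); four common sites per window,
  including a causal one ($\beta = 0.25$), reach the analysis only as
  external p-values computed in the array cohort; merged power must
  strictly exceed sequencing-only power at $\alpha \in \{0.01, 0.05\}$.
* **Empirical p-value law.** 500 null windows: p-values live exactly on
  the $1/M$ grid and their mean is within $0.5 \pm 0.03$ (Monte-Carlo
  standard error ≈ 0.013, plus a small upward tie bias from the atom of
  $G$ at 0, where $P(G = 0) \approx 1/(L+1)$ under the null).
* **Conservation.** Collapsed burden columns must reproduce per-sample
  rare dosage sums exactly (integer dosages sum without rounding) on 100
  random windows.

`scripts/acceptance.R` re-runs the calibration and both power
comparisons from scratch at these same sizes from a caller-supplied seed
and writes the resulting rates as JSON.

## Known limitations

* Association tests are marginal regressions; kinship/mixed-model
  adjustment is out of scope, so related samples violate the permutation
  exchangeability assumption.
* No analytic p-value for the Berk–Jones statistic is provided; all
  inference is permutation-based, and the $1/M$ granularity limits how
  small a reported p-value can be.
* Burden collapsing is unweighted summation; MAF- or
  annotation-weighted schemes are deliberately not implemented.
* The meta-analysis merge assumes the external study's samples do not
  overlap the sequencing cohort; overlap would correlate the merged
  p-values and is not corrected for.
* The `meta` command-line subcommand re-runs the scan from genotypes,
  phenotype and the external table; it cannot graft external p-values
  onto a finished results table, because the permutation null of the
  merged statistic is not recoverable from the table alone.
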