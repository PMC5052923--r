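# motifnull

Exact null models for DNA sequence motifs matched on information content.

A transcription-factor binding motif — a gapless alignment of N binding
sites of width L — often looks "unusual" in some respect: its conservation
is concentrated in a few positions, its per-column information content (IC)
follows a striking pattern, and so on. Deciding whether such a feature is
statistically remarkable requires a null ensemble of motifs that are
*comparable*, and the natural notion of comparability is equal information
content. motifnull provides exact samplers for two such null distributions
over the space of all 4^(N·L) motifs:

- the **maximum-entropy (MaxEnt) distribution** with a constraint on the
  expected motif IC: `P(M) ∝ exp(−λ H(M))`, a Boltzmann distribution with
  the motif's positional Shannon entropy `H(M)` in place of energy. The
  conjugate parameter λ is tuned so the mean IC hits a target;
- the **truncated-uniform (TU) distribution**: uniform over all motifs with
  IC in an interval `I ± ε`, sampled by rejection with the MaxEnt
  distribution as proposal.

Both samplers are exact (no MCMC): they exploit the fact that a column's
entropy depends only on its base-count vector, so the 4^N columns collapse
into the integer partitions of N into at most 4 parts — fewer than 6×10⁴
classes even at N = 200 — over which partition functions, tilted moments
and inverse-CDF sampling are computed exactly.

On top of the samplers the package provides:

- motif statistics: total and per-column IC, the **informational Gini
  coefficient** (IGC) `G(M) = 2 Σ_j j·c_(j) / (L Σ_j c_j) − (L+1)/L`
  measuring how unevenly information is spread across columns, and GC
  fraction;
- **parametric bootstrap percentiles** of any motif statistic against an
  IC-matched null ensemble;
- **GC-content-controlled sampling**: a second conjugate parameter μ tilts
  the assignment of counts to bases so the ensemble matches a target mean
  G+C fraction without disturbing the IC constraint;
- **motif IC p-values** `P(IC(M) > I)` under the uniform null, via an
  analytic bound `(Z_Q/Z_P)·½e^{−λI}`, a Gaussian moment-matching estimate
  (the bound times `erfcx(λσ/√2)`), and an importance-sampling estimate
  with a delta-method standard error — all on the log10 scale, stable past
  p = 10⁻¹⁰⁰ — plus E-value conversion under the one-occurrence-per-sequence
  (OOPS) model.

## Worked example

```r
library(motifnull)

# a motif: 6 sites of 10 bp
m <- motif(c("TTGACAGCTA", "TTGACAGCTT", "TTGACTGCTA",
             "TTCACAGATA", "TTGACAACTA", "ATGACAGCTG"))
motif_stats(m)
#> # A tibble: 1 × 6
#>   n_sites width entropy    ic   igc    gc
#>     <int> <int>   <dbl> <dbl> <dbl> <dbl>
#> 1       6    10    4.50  15.5 0.136 0.383

# is its IGC unusual among motifs of the same dimensions and IC?
bs <- bootstrap_percentile(m, "igc", n = 100, seed = 1)
bs$percentile
#> [1] 0.3

# sample 100 motifs with a 10-bit mean IC at N = 50, L = 10
model <- fit_maxent(N = 50, L = 10, target_ic = 10)
draws <- sample_maxent(model, 100, seed = 1)
mean(draws$ic)
#> [1] 9.915223

# uniform over the IC band 10 +/- 0.1 bits instead
tu <- fit_tu(50, 10, center_ic = 10, epsilon = 0.1)
range(sample_tu(tu, 100, seed = 1)$ic)
#> [1]  9.90049 10.04570

# how many 20 x 10 motifs have 10 +/- 0.1 bits of IC?
count_motifs_in_ic_band(20, 10, 10, 0.1, n_is = 10000, seed = 4)$log10_count
#> [1] 78.56548

# tail probability that a uniformly random 50 x 10 motif has IC > 12 bits
tidy(ic_pvalue(50, 10, ic = 12, n_is = 2000, seed = 1))[
  , c("log10_bound", "log10_moment", "log10_is", "is_se_log10")]
#> # A tibble: 1 × 4
#>   log10_bound log10_moment log10_is is_se_log10
#>         <dbl>        <dbl>    <dbl>       <dbl>
#> 1       -158.        -159.    -159.      0.0776
```

The first block says the example motif carries 15.5 of its maximal 20 bits
and spreads that information fairly evenly (IGC 0.14, an unremarkable 30th
percentile among IC-matched MaxEnt replicates). The band count reproduces the
order-of-magnitude calculation that ~10^78.6 of the ~10^120 motifs of
dimension 20×10 lie within 0.1 bits of 10 bits IC. In the p-value block the
moment-matching and importance-sampling estimates agree closely, with the
analytic bound above both, as it must be.

A thin command-line front end over the same functions is installed with the
package at `inst/cli/motifnull.R` (subcommands `stats`, `sample-maxent`,
`sample-tu`, `pvalue`, `bootstrap`; every run prints a JSON report carrying
its parameters, seed and fitted tilts).

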