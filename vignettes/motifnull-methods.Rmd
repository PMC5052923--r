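---
title: "Information-content-matched null models for sequence motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-content-matched null models for sequence motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifnull)
```

## The motif sampling problem

A motif here is a gapless alignment of $N$ DNA sites of common width $L$,
treated extensionally — the object is the set of sequences, not a
probability matrix summarizing them. Its total positional entropy is the
plug-in estimate
$$H(M) = -\sum_{c=1}^{L}\sum_{b\in\{A,C,G,T\}} p_c(b)\,\log_2 p_c(b),$$
with $p_c(b)$ the sample frequency of base $b$ in column $c$ and
$0\log 0 \equiv 0$. Under a uniform mononucleotide background the prior
uncertainty is 2 bits per position, so the information content is
$IC(M) = 2L - H(M) \in [0, 2L]$. All entropies in this package are in bits
(base-2 logarithms); no pseudocounts are added, because the null models
below are defined over exact count configurations, not smoothed estimates.

Given an observed motif with some statistic of interest — here chiefly the
*informational Gini coefficient*
$$G(M) = \frac{2\sum_{j} j\,c_{(j)}}{L\sum_j c_j} - \frac{L+1}{L},$$
with $c_{(1)} \le \dots \le c_{(L)}$ the sorted per-column ICs — the
question "is this value remarkable?" requires sampling motifs *of
comparable IC*. Naive approaches fail: of the $4^{200} \approx 2\times
10^{120}$ motifs with $N = 20$, $L = 10$, only about $10^{78.6}$ lie within
0.1 bits of 10 bits IC (`count_motifs_in_ic_band()` reproduces this
number), so uniform sampling essentially never lands there, while ad hoc
constructions do not control what else they condition on.

Two null distributions solve this cleanly:

* **Maximum entropy (MaxEnt).** The least-assuming distribution over all
  $4^{NL}$ motifs with a constrained mean entropy is the Boltzmann form
  $P(M) = Z^{-1} e^{-\lambda H(M)}$. The sampling probability of a motif
  depends only on its entropy — the sufficiency requirement that rules out
  trivial "return the input" samplers. Constraining mean IC is the same
  constraint restated, since $IC = 2L - H$.
* **Truncated uniform (TU).** The uniform distribution over
  $\{M : |IC(M) - I| \le \varepsilon\}$, for users who want a hard interval
  rather than a mean.

## Exact computation via count-vector classes

Entropy of a column depends only on its count vector
$(n_A, n_C, n_G, n_T)$, and only through the multiset of counts. The
$4^N$ columns therefore partition into equivalence classes indexed by the
integer partitions of $N$ into at most 4 parts. The class of a
representative $\bar n$ (stored sorted non-increasing) contains
$$w(\bar n) = \frac{4!}{\prod_v m(\bar n)_v!}\cdot\frac{N!}{\prod_b n_b!}$$
columns — base assignments times row arrangements, with $m$ the
multiplicities of values inside the tuple. The number of classes has the
closed form implemented in `class_count_closed_form()` and grows as
$O(N^3)$: 59,823 at $N = 200$, against $2.6\times10^{120}$ raw columns.

Everything reduces to sums over this table: the single-column partition
function $Z_c(\lambda) = \sum_{\bar n} w(\bar n) e^{-\lambda H(\bar n)}$
(computed by log-sum-exp; `log_partition_column()`), the tilted mean and
variance of column entropy (`tilted_moments()`), and — because entropy is
additive over columns — the motif-level distribution factors as
$Z = Z_c^L$, so a motif is sampled as $L$ independent columns.

Column sampling is a three-stage exact draw (`sample_column()`): (1) a
class with probability $\propto w e^{-\lambda H}$; (2) one of the $\le 4! $
distinct assignments of the count multiset to the bases, uniformly; (3) a
uniform arrangement of the resulting letters over the $N$ rows. Every
column inside a class is equiprobable by construction. A consequence used
heavily in the implementation: a motif's IC is fully determined at stage
(1), so the rejection sampler below decides acceptance from class indices
alone and only materializes letters for accepted motifs.

Correctness of this machinery is established two independent ways in the
test suite: exact big-integer verification that class weights sum to $4^N$
(an internal exact-arithmetic helper built from prime factorizations is
used, since weights exceed the exact range of doubles past $N \approx 25$),
and agreement to $10^{-9}$ with direct summation over all $4^N$ columns and
$4^{NL}$ motifs at small dimensions, for tilts $\lambda \in \{-2, 0, 1,
5\}$ and for a two-letter alphabet as well. The class table generalizes to
other alphabet sizes (partition counts grow as $O(N^{A-1})$; a warning is
issued above $A = 6$).

## Tuning, and the achievable range

`fit_maxent()` solves $\langle IC \rangle_\lambda = I^*$ by bracketed
Brent root-finding (initial bracket $[-1,1]$, doubled until it straddles;
the mean is strictly increasing in $\lambda$, so bracketing always
succeeds) followed by a Newton polish using the exact tilted variance. The
tolerance, $10^{-10}$ bits on the achieved mean, is set on the scientific
scale rather than on $\lambda$. Feasible targets lie strictly inside
$(L(2 - H_{\max}(N)),\, 2L)$, where $H_{\max}(N)$ is the entropy of the
most balanced partition; the endpoints are only reached in the
infinite-tilt limits, and infeasible requests produce an error naming the
interval. Note that $\lambda \approx N\ln 2$ at mid-range targets, a
consequence of the class density growing as $\sim 2^{NH}$ in entropy.

## The rejection sampler and its acceptance accounting

The TU sampler proposes from the MaxEnt model whose *mean* IC equals the
band center $I$ and accepts an in-band proposal with probability
$e^{\lambda(I_{\min} - IC)}$ for $\lambda > 0$, anchored so the ratio is 1
at the band endpoint where the proposal density is largest. For targets
below the untilted mean the tilt is negative and the anchor flips to
$I_{\max}$ — a symmetric extension the positive-tilt derivation leaves
implicit. The ratio is bounded below by $e^{-2|\lambda|\varepsilon}$, which
motivates the runtime-optimal default half-width $\varepsilon =
1/(2|\lambda|)$ (`default_epsilon()`), capped at 0.5 bits when $|\lambda| <
1$ where the cost argument degenerates. Proposals falling outside the band
have target density zero and are rejected before the ratio test.

Two acceptance summaries are reported, because they answer different
questions. `acceptance_rate` counts accepted motifs over *all* proposals
(both rejection kinds); it is the quantity that determines runtime, and it
decays with $N$ at fixed $\varepsilon$ because the proposal's IC standard
deviation shrinks while the band does not widen. `in_band_acceptance`
counts accepted motifs over proposals that reached the ratio test; it is
the empirical acceptance probability of the rejection step itself and
stays above $10^{-2}$ across the full validation grid ($L = 10$, $N$ up to
200, $\varepsilon = 0.1$). A per-motif proposal budget (default $10^6$)
turns pathological parameter combinations into a diagnostic error instead
of an unbounded loop.

Within the band the accepted sample is exactly uniform (verified against
exhaustive enumeration at $N = L = 2$). Its mean IC nevertheless sits
below the band center for large $N$: the underlying density of motifs is
roughly inverse-exponential in IC, so a uniform-on-the-set distribution
weights the lower end, an effect the validation grid reproduces.

## GC control

A second conjugate parameter $\mu$ reweights stage (2) of the column
sampler: assignments of the count multiset to bases are drawn with
probability $\propto e^{-\mu g}$, $g$ being the column GC fraction
realized by the assignment (negative $\mu$ raises GC; the user-facing API
takes a target GC fraction, so the sign convention is internal). Because
stage (1) is untouched, the entropy-class marginal — hence the fitted IC
constraint — is preserved exactly; `fit_gc()` only solves the
one-dimensional problem of matching
$\langle \%GC\rangle = \sum_{\bar n} P(\bar n) \sum_g g\,
u(g|\bar n)e^{-\mu g}/Z(\bar n, \mu)$ to the target. IC and GC are not
independent: a fully conserved column realizes only $g \in \{0, 1\}$ and a
balanced one only $g = 1/2$, so the feasible mean-GC interval
(`feasible_gc_range()`, endpoints $\sum_{\bar n} P(\bar n)\min\{g\}$ and
the corresponding max, with $P$ the $\lambda$-tilted class distribution)
narrows as the IC constraint tightens, and out-of-range targets error with
the interval in the message.

## Bootstrap percentiles

`bootstrap_percentile()` draws $n$ replicates (default 100) from the
IC-matched null of choice — MaxEnt, or TU with the runtime-optimal
$\varepsilon$ logged in the result — and reports the fraction of
replicates whose statistic falls *strictly below* the observed value. Ties
therefore lower the percentile; a midrank option (ties counted half) is
available but off by default, so the default matches the strict counting
definition. For motifs drawn from the null itself the percentile of a
continuous statistic is uniform on $[0,1]$, a property the suite checks by
Kolmogorov–Smirnov over repeated trials; for inputs whose IC sits at the
boundary of the achievable interval no IC-matched MaxEnt model exists and
the function errors with a suggestion to use the TU null with an explicit
band.

## IC p-values

The tail probability $p = P(IC(M) > I)$ under the uniform null is recast
with the tilted family $Q(M) = Z_Q^{-1} e^{\lambda\,IC(M)}$, with $\lambda$
tuned so $\langle IC\rangle_Q = I$:
$$p = \frac{Z_Q}{Z_P}\,\big\langle [IC(M) > I]\, e^{-\lambda IC(M)}
\big\rangle_Q, \qquad Z_P = 4^{NL}.$$
Three estimates are computed (`ic_pvalue()`), all in log space so the deep
tail ($p \ll 10^{-100}$) stays representable: the analytic bound
$(Z_Q/Z_P)\tfrac12 e^{-\lambda I}$, whose factor $\tfrac12$ assumes the
tilted IC distribution is symmetric about $I$ (results are flagged when
the exactly-computed skewness exceeds 1 in magnitude, where that halving
is heuristic); the Gaussian moment-matching estimate, the bound times
$\mathrm{erfcx}(\lambda\sigma/\sqrt2)$ with $\sigma^2$ the exact tilted
variance of IC; and a plain importance-sampling average over draws from
$Q$, with a delta-method standard error on the log scale. Strict
inequality is used in the indicator, as ties occur only on class
boundaries. The `erfcx` evaluation switches from direct computation to the
asymptotic series beyond $x = 15$, where the direct form overflows.

Validation at tiny dimensions checks all three against exhaustive
enumeration. At the study dimensions ($L = 10$, $N \in \{20, 50, 100\}$)
the moment and importance-sampling estimates agree within 0.1 decades from
the bulk down past $p = 10^{-100}$, and both match the empirical
complementary CDF of $10^3$ uniform draws down to its $p \approx 10^{-3}$
detection limit. A known limitation: the analytic bound exceeds the true
tail by the factor $1/\mathrm{erfcx}(\lambda\sigma/\sqrt2)$, which is
$\sim$17–40$\times$ at these dimensions (not within a single order of
magnitude, although it is at smaller $N \times L$); the bound is a
guarantee, the moment estimate is the accurate analytic approximation.
E-values under the OOPS alignment model multiply $p$ by $\prod_i (m_i - L
+ 1)$ (`evalue_oops()`).

## Validation harness and problem sizes

The synthetic studies are packaged as seeded, reproducible functions:

* `ic_recovery_grid()` — $L = 10$, $N \in \{20, 40, \dots, 200\}$ (steps
  of 20; the step size is this package's choice), targets $\{5, 10, 15\}$
  bits, 100 motifs per sampler per cell, TU at $\varepsilon = 0.1$. MaxEnt
  cell means sit within Monte-Carlo error of their targets; TU draws are
  all in-band.
* `igc_ic_comparison()` — $L = 10$, $N = 50$, 100 target-IC steps spanning
  0.1–19 bits of total IC, 100 motifs per sampler per step, TU at the
  runtime-optimal $\varepsilon$ per step. Per-step Kruskal–Wallis tests on
  IGC with Benjamini–Hochberg control at 5% FDR flag no systematic
  difference between the samplers; mean IGC rises as IC falls (more ways
  to spread little information unevenly) and IGC $\to 0$ as IC approaches
  2 bits per column, with variance shrinking likewise.
* `ic_pvalue_curve()` and `sample_uniform()` — the tail studies above.
* `build_oracle()` — exhaustive enumeration (guarded at $4^{NL} \le
  10^6$) backing every exactness claim.

These sizes run the whole suite in a couple of minutes on one core while
keeping every Monte-Carlo comparison at $\ge 10^4$ effective draws where a
distributional test is made. Grid cells derive per-cell seeds from the
master seed, so reports are bit-reproducible.

What the synthetic studies do *not* show: anything about biological
motifs. The generators emulate the null hypotheses themselves — motifs
exchangeable given IC (and optionally GC) — not curated motif collections,
alignment error, phylogenetic correlation between sites, or dinucleotide
background structure. Passing tests demonstrate that the samplers realize
their stated distributions exactly and that the estimators agree with
enumeration and with each other, not that real binding sites follow these
nulls; on real data the nulls are the *reference* against which excess
structure (e.g. high IGC) is measured.

## Design notes and degenerate inputs

* Sequences are stored in input order, but every statistic is invariant
  under row permutation; output FASTA headers encode motif and site
  indices for traceability.
* Ambiguity codes and gaps are rejected outright — the count-vector
  algebra has no principled treatment for them, and silent imputation
  would change IC.
* A motif with zero total IC makes the IGC formula 0/0; it is reported as
  0 with a warning, zero IC being the maximally even configuration.
* Canonical class representatives are sorted non-increasing; any fixed
  total order works, and this one makes the multiplicity factors
  computable from run lengths.
* Exact factorial arithmetic switches to log-gamma beyond the exact-double
  range; the two paths are cross-tested.
* Band-edge membership in the TU sampler uses an absolute $10^{-9}$-bit
  fuzz so ICs computed by different floating-point routes agree about the
  endpoints.
* A single `seed` argument per sampling call drives all randomness in that
  call (class draws, assignments, arrangements, rejection variates), which
  makes whole-call output byte-reproducible; per-motif substreams were
  considered and rejected as complexity without a testable benefit.
* `count_motifs_in_ic_band()` tunes its proposal to the band center when
  feasible and to the nearest interior mean otherwise (the
  importance-sampling identity holds at any tilt; centering is only
  variance-optimal).
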