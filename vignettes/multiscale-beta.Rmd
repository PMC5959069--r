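---
title: "Multi-scale partitioning of beta diversity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale partitioning of beta diversity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betascale)
```

## The problem

Montane grassland communities — and the galling insects that track their
host plants — are typically sampled under a nested design: plots within
mountains within mountain ranges. Two questions recur. First, how much of
the regional species richness is held locally versus contributed by
compositional differences among sampling units, and at which spatial scale?
Second, when sites do differ, is it because species are *replaced* along
gradients (turnover) or because poorer sites hold *subsets* of richer ones
(nestedness)? The two mechanisms have opposite conservation implications:
under turnover every site adds species and reserves must be spread out;
under nestedness protecting the richest sites captures most of the pool.

`betascale` implements the full analysis chain for presence/absence data
under such a design, plus a seeded metacommunity simulator so that every
statistic can be validated against structures whose generating mechanism is
known.

## Measures

### Pairwise and multiple-site dissimilarity

For two sites with `a` shared species and `b`, `c` exclusive ones, total
dissimilarity and its components are

- Sørensen: $\beta_{sor} = (b+c)/(2a+b+c)$
- Simpson (turnover): $\beta_{sim} = \min(b,c)/(a+\min(b,c))$
- nestedness-resultant: $\beta_{sne} = \beta_{sor}-\beta_{sim}$.

The Simpson component is blind to richness differences: it is 0 exactly
when one site's species are a subset of the other's, and equals the
Sørensen value when both sites are equally rich. For a whole set of sites
the multiple-site analogues use $\Sigma_{min}=\sum_{i<j}\min(b_{ij},b_{ji})$,
$\Sigma_{max}=\sum_{i<j}\max(b_{ij},b_{ji})$ and
$K=\sum_i S_i - S_T$:

$$\beta_{SIM}=\frac{\Sigma_{min}}{\Sigma_{min}+K},\qquad
\beta_{SOR}=\frac{\Sigma_{min}+\Sigma_{max}}{2K+\Sigma_{min}+\Sigma_{max}},\qquad
\beta_{SNE}=\beta_{SOR}-\beta_{SIM}.$$

These are single numbers for the whole set, not averages of pairwise
values. Because they grow with the number of sites, sets of different sizes
are compared through `beta_sample()`: the decomposition recomputed over
many random subsets of fixed size (default 10 sites, 1000 draws). Both the
full-matrix value and the resample mean are legitimate single-number
summaries and the package always reports both; they answer slightly
different questions (the value of *this* site set versus the expected value
of a standardized-size subset) and neither is treated as canonical.

`distribution_difference()` deliberately returns several summaries — the
cross-pair exceedance probability $P(X>Y)$ with ties counted one half, the
2.5%/97.5% quantiles of each distribution, and a 95%-interval overlap flag —
rather than a single verdict, because no unique test is standard for
comparing two resampling distributions.

### Additive partition

With levels ordered plot < mountain < range, $\alpha_l$ is the mean
richness of the (aggregated) units at level $l$, $\beta_l =
\alpha_{l+1}-\alpha_l$, and the top beta is $\gamma-\alpha_{top}$, so
$\alpha_1+\sum_l\beta_l=\gamma$ holds in species units and every component
can be read as a percentage of $\gamma$. Significance uses a sample-based
null: at each level, member units are shuffled among parent units keeping
the number of children per parent fixed. Each plot keeps its own species
list, so the plot-level alpha is invariant under the null (its null
variance is exactly 0 — asserted in the tests) and only the spatial
arrangement is randomized. An individual-based null (reallocating
individual occurrences) would need abundance data that presence/absence
plot records do not carry, and is out of scope. Defaults are 999
randomizations plus the observed arrangement; p-values are two-tailed
Monte-Carlo with the add-one correction $p = \min(1,\,2(k+1)/(n_{null}+1))$,
which cannot return 0.

### Local-regional regression

`local_regional_regression()` regresses the mean plot richness of each
regional unit on the unit's pooled richness, one point per unit — never one
point per plot, which would pseudoreplicate. The fit is ordinary least
squares with the standard F test on $1$ and $n_{units}-2$ degrees of
freedom. (Field studies sometimes quote $n_{units}-1$ denominator degrees
of freedom for this design; the package keeps the OLS convention.) The
diagonal `local = regional` is drawn in plots as the theoretical boundary
but is never fitted. All regional richnesses equal is reported as a
degenerate fit rather than a zero slope.

### Clustering

`upgma()` is unweighted average linkage: cluster-to-cluster distance is the
arithmetic mean of all cross-pair dissimilarities and node height is half
the merge distance, giving an ultrametric tree. Ties in the minimum
distance are broken by the lexicographic order of the pair's smallest
member labels so trees are identical across runs and platforms; the
unweighted (UPGMA) rather than weighted (WPGMA) form is used, matching what
"average linkage" normally denotes. Trees export to Newick with branch
lengths; labels containing spaces or metacharacters are single-quoted.

## The synthetic metacommunity generator

`simulate_metacommunity()` emulates the nested montane design: by default 2
ranges holding 7 and 4 mountains, 10 plots per mountain (110 plots) and 100
plant individuals recorded per plot, with a regional pool of 550 plant
species. 550 was chosen as a round figure near the plant richness such
surveys report, and divisible by 110 so that the gradient tiling can cover
every plot equally. Two assembly mechanisms are mixed by the single
parameter `turnover_weight` $w$:

- **Gradient turnover** (fraction $w$ of the pool): plots are ordered along
  one cyclic gradient (range by range, mountain by mountain) and each
  species occupies a window of `turnover_span` consecutive plots (default
  15, i.e. about a mountain and a half, so that neighbouring plots share
  most species, mountains share some, and ranges little). Window starts are
  assigned round-robin, so plot coverage is even — exactly even when the
  number of turnover species is divisible by the number of plots, which
  forces equal plot richness and hence $\beta_{SNE}=0$ in exhaustive mode.
  A single global gradient was preferred over independent per-mountain
  gradients with a separate pool-sharing rule: one mechanism yields the
  within-mountain, between-mountain and between-range structure at once,
  and makes the pure-turnover limiting case exact rather than approximate.
- **Nested loss** (fraction $1-w$): species are ranked once and every plot
  holds a prefix of the ranking, with capacity declining both along each
  mountain's gradient and with a mountain quality factor (evenly spaced
  from 1 to 0.5). All plots therefore form subset chains and
  $\beta_{SIM}=0$ in the pure-nested exhaustive limit.

Realized incidence then passes through sampling: each plot records
`individuals_per_plot` individuals drawn from a geometric-series abundance
distribution (shape 0.1) over the locally available species. The geometric
series was chosen over a log-series because a single closed-form parameter
suffices to create realistic rarity and sampling-induced absences. The
abundance ranking of nested species follows their loss ranking — rare
species drop out first, the usual empirical pattern — while turnover
species get random abundance ranks. Every plant species carries a Poisson
(`gall_rate`, default 0.7) number of strictly monophagous gall species,
each recorded where its host was recorded with probability `gall_detection`
(default 0.9); 0.7 galls per host reflects gall-to-plant richness ratios
around 0.7 reported for these grasslands, and one-host-per-gall mirrors the
morphotype-on-host operational species concept. `detection = "exhaustive"`
bypasses both the individual sampling and the gall detection filter; this
strict mode is what makes the limiting cases above exact and is used for
the forced-case tests.

### What passing tests do and do not show

The generator produces the *structures* the statistics are designed to
detect, with known truth, and the tests show the pipeline ranks turnover
against nestedness consistently with the generating weight $w$ (the
turnover share $\beta_{SIM}/\beta_{SOR}$ is monotone in $w$ and hits the
exact limits in strict mode). Two caveats. First, individual-based sampling
converts some true nestedness into apparent turnover — stochastic absences
among rare species differ between plots even when availability is perfectly
nested — so under sampling the turnover share stays high even at $w=0$;
this is a property of finite sampling that real surveys share, not an
implementation artifact. Second, the generator holds sampling effort and
gradient coverage even across mountains, so regional richness varies little
between mountains and the local-regional regression on default synthetic
data has almost no predictor variance; real montane data have richness
gradients (latitude, area, altitude span) that this generator does not
model, and the regression module is instead validated on engineered
fixtures with known closed-form fits.

## Numerical conventions

- Incidence matrices are dense integer 0/1 with first-appearance ordering
  of sites and species everywhere, so identical inputs give identical
  outputs; at the study's scale (about 110 sites) sparse storage would buy
  nothing.
- Species labels are trimmed of surrounding whitespace and otherwise
  matched exactly and case-sensitively; fuzzy taxon matching silently
  merges names and corrupts richness counts.
- Sites with no recorded species are accepted and flagged at read time but
  rejected by dissimilarity functions unless `drop_empty = TRUE`, because
  0/0 dissimilarities are undefined. A pair with $b=c=0$ and $a>0$ is
  defined as 0 for all three measures.
- The identity $\beta_{sne} = \beta_{sor}-\beta_{sim}$ is enforced to
  within $10^{-12}$ in validation; components are computed from exact
  integer counts so the identity is exact up to floating-point rounding.
- All stochastic stages (`beta_sample()`, `partition_significance()`,
  `simulate_metacommunity()`, `run_full_analysis()`) take explicit integer
  seeds, record them in their outputs, and are bitwise reproducible;
  `run_full_analysis()` derives per-stage seeds deterministically from one
  master seed and logs input checksums.

## Problem sizes used in validation

Unit tests run on small random matrices (4-12 sites) against brute-force
set-based oracles (500 random draws for the dissimilarity measures, 50 for
the clustering), plus `vegan`'s independent implementations as
cross-checks. The end-to-end validation simulates the full study design —
110 plots, 550-species pool, 100 individuals per plot — across a grid of
five turnover weights with ten seeds each, and runs the complete pipeline
(1000 resampling draws, 999 partition randomizations, per-range reruns) at
that scale; the whole suite completes in well under a minute per stage.

## Known limitations

- Presence/absence only: no abundance-weighted (Shannon/Simpson-number or
  Bray-Curtis) partitions, and no Jaccard-family decomposition.
- The additive-partition null is sample-based only; observed/expected
  directions under an individual-based null can differ.
- UPGMA only; no bootstrap support values or alternative linkages.
- The generator's mountains are exchangeable in expectation; it does not
  model environmental covariates, fire regimes, or geographic coordinates.
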