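# ordqual

Statistical-preference comparison of healthcare provider quality from
ordinal or cardinal data.

## The problem

Patient-experience surveys report each provider's *quality profile*: the
proportions of its patients choosing each of several ordered response
categories (e.g. very poor < fairly poor < neither < fairly good < very
good). Ordinal data of this kind have no well-defined mean, so the usual
toolkit — mean scores, coefficients of variation, "% good" after
dichotomizing — either depends on an arbitrary numerical scoring of the
categories or throws information away. `ordqual` implements a framework
that ranks and compares whole profiles directly, on a basis that applies
identically to ordinal and cardinal quality indicators, for analysts of
provider-level quality data (practice surveys, inspection ratings,
achievement scores) and health-services researchers studying geographic
variation in care quality.

## The measures

For providers *k* and *k′* with independent patient lists, draw one
patient at random from each. The **pairwise quality difference**

&nbsp;&nbsp;Δ<sub>kk′</sub> = P(Q<sub>k′</sub> > Q<sub>k</sub>) − P(Q<sub>k</sub> > Q<sub>k′</sub>) ∈ [−1, 1]

is the difference in chances that the *k′* patient fares strictly better
rather than strictly worse. It uses only the ordering of categories, so it
is invariant to any monotone relabeling of the scale.

The **comparative quality index** of provider *k* averages these contrasts
against the whole population with registration weights
p<sub>k′</sub>: Δ<sub>k</sub> = Σ<sub>k′</sub> p<sub>k′</sub> Δ<sub>k′k</sub>.
It has weighted mean zero and |Δ<sub>k</sub>| ≤ 1 − p<sub>k</sub>.

The **lottery index**

&nbsp;&nbsp;L = Σ<sub>k</sub>Σ<sub>k′</sub> p<sub>k</sub>p<sub>k′</sub>|Δ<sub>kk′</sub>| / (1 − Σ<sub>k</sub>p<sub>k</sub>²) ∈ [0, 1]

summarizes variation between providers: 0 when all profiles are
statistically equivalent, 1 when every pair is completely separated. L/2
is the average gain in the chance of a better outcome from choosing the
better of a random pair of providers rather than being assigned one.

Around this core the package provides group-level aggregation
(practices → commissioning groups), within- and between-group lottery
indices, a between-group Gini identity for cardinal scores (with
discretization as the default route), indirect standardization of
profiles for socio-demographic composition via per-cutoff distribution
regression (linear-probability or probit-binomial), clustered bootstrap
standard errors, Kendall τ<sub>a</sub> rank agreement, and a
synthetic-data generator with known ground truth.

## Worked example

Two practices on a poor < OK < good scale: A reports 40/10/50 and
B reports 30/30/40.

```r
library(ordqual)

A <- c(0.40, 0.10, 0.50)
B <- c(0.30, 0.30, 0.40)
pairwise_comparison(B, A)
#> <pairwise comparison> P(second better) = 0.3300, P(first better) = 0.3200,
#>   P(tie) = 0.3500, delta = +0.0100

ps <- provider_set(rbind(A = A, B = B), weight = c(0.5, 0.5),
                   scale = quality_scale(c("poor", "OK", "good")))
lottery_index(ps)
#> <lottery index> L = 0.0100 (numerator 0.005000 / normalizer 0.500000, K = 2)
```

A random patient of A has a 33% chance of reporting strictly better care
than a random patient of B, a 32% chance of strictly worse, and a 35%
chance of a tie — so A's profile is preferred by a 1 percentage-point
margin, and the two-practice lottery index is 0.01. Note both profiles
have mean 2.1 under scores 1/2/3: the mean cannot see this difference.

The same pair is bundled as a CSV fixture and drives the command line:

```sh
Rscript exec/ordqual.R lottery \
  --profiles inst/extdata/two_practice_example.csv \
  --scale inst/extdata/three_level_scale.yaml --within
#> average within-group L = 0.0100
```

Subcommands `indices`, `lottery`, `standardize`, `discretize`,
`simulate` and `report` cover the full pipeline; see
`vignettes/ordinal-quality-variation.Rmd` for the methods.

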