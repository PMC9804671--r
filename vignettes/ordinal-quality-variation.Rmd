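---
title: "Measuring provider quality variation from ordinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring provider quality variation from ordinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordqual)
```

## The measurement problem

Multicategory survey responses ("very poor" … "very good") carry no
cardinal scale. A mean score depends entirely on the numbers assigned to
the categories, and two providers can swap ranks under a different but
equally defensible scoring; dichotomizing at a "good care" threshold
discards the distinctions among the categories it merges. `ordqual`
instead compares whole quality profiles by the *statistical preference*
criterion: profile B beats profile A if a randomly drawn patient of B
reports strictly better care than a randomly drawn patient of A more
often than the reverse. Unlike first-order stochastic dominance, this
always delivers a verdict, and a graded one.

## Model and assumptions

Each patient belongs to exactly one of $K \ge 2$ providers; provider $k$
serves a share $p_k$ of registrations and has profile
$a_k(q)$, $q = 1,\dots,Q$ over the ordered categories. Draws from two
providers are independent (patient lists do not overlap). Writing
$F_k$ for the cumulative profile, the pairwise difference is

$$\Delta_{kk'} = \sum_q a_{k'}(q)\,F_k(q-1) \;-\; \sum_q a_k(q)\,F_{k'}(q-1) \in [-1,1],$$

computed from exact cumulative sums (profiles are finite discrete
distributions; nothing is simulated). The comparative quality index
$\Delta_k = \sum_{k'} p_{k'} \Delta_{k'k}$ compares provider $k$ with the
population; it is evaluated in $O(KQ)$ against the population mixture
profile rather than over all pairs. The lottery index

$$L = \frac{\sum_k \sum_{k'} p_k p_{k'} |\Delta_{kk'}|}{1 - \sum_k p_k^2} \in [0,1]$$

is the normalized patient-weighted mean absolute pairwise difference.
Two identities guard the implementation at run time: the shortcut
$\Delta = 1 - 2[P(\text{worse}) + \tfrac12 P(\text{tie})]$, and the
choice-value form $|\Delta| = 2\max(P_{>}, P_{<}) - (P_{>} + P_{<})$;
both are asserted to $10^{-12}$ inside every call.

Cardinal scores enter by rounding to a stated number of decimals
(half-away-from-zero, the convention of published statistics tables) and
treating the distinct rounded values as an ordinal scale. The pairwise
difference of two weighted cardinal samples also equals the ratio of the
Yitzhaki–Lerman between-group Gini (built from group mean ranks under
the pooled mid-rank CDF) to the conventional Pyatt between-group Gini
(built from group means), both signed; the pooled-mean factor cancels,
so the ratio is location- and scale-invariant. This identity requires
the group means to differ — with equal means the Pyatt term vanishes
while the true difference need not — so `pairwise_delta_gini()` returns
0 in that degenerate case and the discretization route remains the
default path; the identity serves as an exact cross-check in the test
suite.

## Indirect standardization

Quality differences partly reflect who the patients are. The package
standardizes indirectly through a *distribution regression*: for each
cumulative cutoff $q = 1,\dots,Q-1$, the observed cumulative proportion
$F_k(q)$ is regressed on the provider's socio-demographic composition
(main effects only: sex, eight age bands including 55–64, five ethnicity
groups, long-term-condition share, deprivation score) plus group
intercept dummies, with one reference category dropped per share block
and per group. Two links are available:

* **LPDRM** — linear probability, weighted least squares with
  registration weights (the framework weights patients everywhere else,
  so estimation does too);
* **GLDRM** — probit link with binomial quasi-likelihood, denominator
  $n$ = the provider's number of survey responses ($n = 1$, with a
  warning, where no response count exists).

Counterfactual profiles use each provider's own composition but replace
its group dummy with the population-share-weighted average of the
estimated group effects, applied on the link scale. Predictions are then
(i) censored to $[0,1]$, (ii) made non-decreasing across cutoffs by a
cumulative maximum — censoring alone cannot guarantee non-negative
category masses — (iii) rescaled per cutoff so the weighted mean of
$\hat F(q)$ matches the sample weighted mean of $F(q)$, and (iv) passed
through a second cumulative maximum with a logged count if the rescale
reintroduced a violation. The default rescale is multiplicative on the
cumulative proportions; additive rescaling and matching category-mass
means instead are available as options (`rescale`, `rescale_on`) since
either reading of "scaled to match the sample mean" is defensible.
*Residual* indices are defined as raw minus standardized, an exact
bookkeeping identity.

Zero-variance covariate columns (e.g. a composition constant across
providers) are absorbed by the intercept and dropped from estimation;
rank deficiency among varying columns is an error naming the columns.

## Inference

Standard errors come from a clustered bootstrap that resamples providers
with replacement *within their group*, preserving each group's provider
count, renormalizing weights each replicate, carrying composition rows
along, and refitting any model inside each replicate (full-pipeline
bootstrap; a statistic that does not refit can simply ignore the
composition argument). Replicates where a statistic is undefined — for
instance a resampled group collapsing onto one provider — are dropped
with a recorded count, and more than 20% drops is an error. The default
is 200 replications; 50 mirrors common published practice but is
noticeably noisy.

Rank agreement between two index vectors uses Kendall's $\tau_a$ with
the all-pairs denominator $n(n-1)/2$ (tied pairs count toward neither
concordance nor discordance but stay in the denominator), with a
leave-one-out jackknife SE and normal-quantile confidence interval.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| proportion-sum warning threshold | `provider_set()` | $10^{-6}$ | published tables are rounded; worse deviations deserve a warning before renormalization |
| `decimals` | `discretize()` | 1 | the resolution at which percentage-achievement scores are published |
| `link` | standardization | `lpdrm` | linear base case; probit `gldrm` as the well-specified robustness check |
| `rescale`, `rescale_on` | `predict_standardized()` | multiplicative, cumulative | simplest reading of mean-matching; alternatives exposed |
| `replications` | `bootstrap_se()` | 200 | 50-replicate SEs have ~10% Monte-Carlo noise themselves |
| averaging weights for within-group $L$ | `within_group_lottery()` | group registration shares | matches the patient-weighted construction of $L$; equal weighting is a trivial post-hoc reweighting of the returned per-group table |

## The synthetic generator

`generate_provider_data()` emulates the structure of national
practice-survey data: providers nested in groups; compositions drawn
from Dirichlet blocks (concentration 50 around realistic national
shares), a Beta(15,15) long-term-condition share and a Gamma-distributed
deprivation score (mean ≈ 21, SD ≈ 14, the shape of an area deprivation
index); log-normal registration counts (median 7000); a latent quality
location = compositional main effects + group effect + provider noise;
ordered-probit category probabilities with thresholds placed so the
baseline national profile is 2.1/4.4/10.6/37.8/45.1 percent; and
multinomial sampling noise at the configured number of survey responses.
Defaults are 5 groups × 40 providers, $Q = 5$, 200 responses, group-effect
SD 0.08 and provider-noise SD 0.20 on the latent scale — a compact
population whose index magnitudes are of the same order as national
practice data. The standard-normal latent with probit thresholds makes
the GLDRM exactly specified and the LPDRM a working approximation; a
`latent = "linear"` mode generates cumulative proportions directly
linear in the covariates, the regime in which the LPDRM is exact (used
for coefficient-recovery tests). `true_indices()` returns oracle raw,
standardized and residual indices from the true category probabilities,
with the standardized truth defined by the same group-effect
neutralization the estimator applies.

What the generator does *not* emulate: correlation between deprivation
and ethnic composition, survey non-response bias, suppression of small
cells, group sizes as unequal as real commissioning groups, or
inspection-rating dynamics. Passing recovery tests therefore shows the
estimator recovers *this* data-generating process, not that real survey
data satisfy its assumptions (practice-level regressions in particular
cannot rule out ecological bias).

## Numerical choices and degenerate inputs

* Weights always renormalize to sum 1; zero-weight providers are kept
  and contribute nothing.
* A lottery index is undefined when one provider holds all weight
  (normalizer ≤ $10^{-12}$): error.
* Singleton groups have no within-group variation; they are reported as
  `NA`, excluded from the within-group average with a warning, and the
  averaging weights renormalize over the remaining groups.
* Zero total variance makes variance-decomposition shares undefined;
  they return `NA` with a `defined = FALSE` flag rather than 0/0.
* Category collapse requires contiguous ordered blocks and at least two
  resulting categories.
* All-equal rounded scores would give a one-level scale; the scale is
  widened by one adjacent level so the (zero) indices remain defined.

## Problem sizes used in the tests

The test suite works at deliberately compact sizes chosen to exercise
every code path with tight oracles: brute-force double-sum checks on
1,000 random profile pairs ($Q \le 10$), the Gini identity on 200 random
two-group instances, coefficient recovery at 500 providers, and the
compositional-recovery experiment at the generator's default 5 × 40
population with a 100-replicate clustered bootstrap. The recovery
criterion — residual between-group variation within two bootstrap SEs
of zero when all variation is compositional — was verified at that size.

## Known limitations

* The standardization model is estimated on provider-level aggregates;
  interaction effects are not identifiable and ecological bias is
  possible by construction.
* The Gini identity route is silent (returns 0) when group means are
  exactly equal; use the discretization route, which is always exact.
* With many providers the pairwise stage of `lottery_index()` builds a
  $K \times K$ matrix; this is intended for within-group and group-level
  computations (hundreds of units), not for a single lottery index over
  many thousands of providers.
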