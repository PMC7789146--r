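---
title: "Scoring families for longevity: empirical and model-based approaches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring families for longevity: empirical and model-based approaches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(famscore)
library(dplyr)
```

## Why family scores

Human longevity clusters in families, but studies that recruit long-lived
participants by individual age alone pick up many *sporadically* long-lived
people — individuals who reached a high age without any familial
predisposition. A family history score summarizes how long-lived a whole
sibship is, so that study candidates can be chosen from families in which
exceptional survival is likely to be heritable rather than incidental. The
practical obstacle is family size: sibships in historical registers range
from two to well over a dozen members, and a useful score must not confuse
*family size* with *familial longevity*.

## The three scores

All scores start from the sex- and birth-cohort-specific **survival
percentile** of each member,
$$P_{ij} = 1 - S(t_{ij} \mid bc_{ij}, sex_{ij}),$$
where $t_{ij}$ is the age at death of member $j$ of family $i$ and $S$ is
taken from a reference lifetable (`lifetable()`, `lt_percentile()`).
A member is *long-lived* when $P_{ij} \ge c$; the default threshold
$c = 0.9$ marks the top decile of survivors of the member's own sex and
cohort.

**SE~f~** sums the per-member survival exceptionality
$SE_{ij} = -\log S(t_{ij}) - 1 = \Lambda(t_{ij}) - 1$ over the family
(`score_sef()`). Each member with survival above $e^{-1} \approx 0.37$
contributes positively, so the score grows without bound as members are
added: large families with *no* long-lived members can outscore small
families of extremely long-lived ones. The package implements it for
comparison and for its closed-form anchors; it is not a recommended
selection tool, and the living-member bonus that some of its descendants
add is deliberately out of scope (no published closed form).

**LRC** is the proportion of long-lived members,
$$LRC_i = \frac{1}{N_i} \sum_{j=1}^{N_i} I(P_{ij} \ge c),$$
(`score_lrc()`). It is bounded and comparable across populations, but as an
empirical proportion it is noisiest exactly where it looks most impressive:
a size-2 family reaches $LRC = 1$ with two lucky deaths, while a size-14
family almost never does.

**mLRC** replaces the empirical proportion with the posterior mean of the
family's longevity probability under a random-intercept logistic model
(`fit_mlrc()`, `score_mlrc()`):
$$Y_{ij} \mid u_i \sim \mathrm{Bernoulli}\!\left(\frac{e^{\beta_0+u_i}}{1+e^{\beta_0+u_i}}\right),
\qquad u_i \sim N(0, \sigma^2),$$
with $(\beta_0, \sigma)$ estimated by marginal maximum likelihood and
$$mLRC_i = E\!\left[\frac{e^{\beta_0+u}}{1+e^{\beta_0+u}} \,\middle|\,
y_{i1},\dots,y_{iN_i}\right].$$
Because the per-family likelihood depends on the data only through
$(k_i, N_i)$ — the number of long-lived members and the family size — the
score is an empirical-Bayes shrinkage of $k_i/N_i$ toward the population
level, with shrinkage strength decreasing in $N_i$. A size-2 family with
$k = 2$ is pulled well below 1; a size-14 family with $k = 0$ is pulled
less far up than a size-2 family with $k = 0$. These are the directional
properties the test suite asserts on every fitted model.

## Numerical choices

*Integration.* Marginal likelihoods and posterior means are integrals of a
log-concave integrand (Bernoulli kernel × normal density). They are
evaluated by **adaptive Gauss–Hermite quadrature**: a damped Newton search
finds each family's posterior mode (unique, by log-concavity), the nodes
are centred there and scaled by the local curvature, and the integral is
accumulated in log space. The default order of 60 keeps both the
log-likelihood and every posterior mean within $10^{-6}$ of dense-grid
trapezoid integration across $k \le n \le 14$, $\beta_0 \in [-4, 2]$,
$\sigma \in [0.1, 3]$ (the test suite checks this against an independent
oracle). Inside the replicated simulation study the fits use order 30:
the resulting $\sim 10^{-5}$ integration error is orders of magnitude
below replicate noise, at half the cost.

*Optimization.* The likelihood is maximized over $(\beta_0, \log\sigma)$ —
the log transform keeps the $\sigma \to 0$ boundary interior — with BFGS
from three starts ($\sigma \in \{0.5, 1, 2\}$, intercept at the pooled
prevalence logit), followed by Nelder–Mead polishing until a refit no
longer improves the log-likelihood. When the data carry no clustering the
likelihood is nearly flat in $\log\sigma$; the fit then reports a
near-zero $\sigma$ and, if the polish cannot settle, `converged = FALSE`
with a warning rather than an error.

*Degenerate data.* If every indicator is 0 (or every one is 1) the
intercept diverges and every family would receive the same score; the fit
refuses such data with an explicit error. At $\sigma = 0$ all integrals
reduce to closed logistic forms, which are used exactly rather than
through quadrature.

*Sufficiency caching.* `score_mlrc()` evaluates one posterior integral per
distinct $(k, n)$ pair and joins the results back — the replicated
simulation study would be infeasible without this.

## The benchmark simulation design

`generate_population()` draws, per replicate, 200 families each of sizes
2, 3, 8, 10 and 14. Family $i$ receives a latent effect
$u_i \sim N(0, 2^2)$; given $u_i$, each member's survival probability is
an independent draw from $\mathrm{Beta}(a,\, a e^{-(1+u_i)})$ with
$a = e^{0.1}$, and the member is long-lived when that draw is $\le 0.1$
(percentile $\ge 0.9$). Low $u_i$ therefore makes whole families
long-lived, and the ground truth for selection accuracy is the 10% (or
5%) of families with the lowest $u_i$ (`truly_long_lived()`).

Two conventions circulate for the direction of the family effect in this
kind of beta-percentile generator; they are easy to confuse and give
different marginal indicator rates (about 12% for the default, about 43%
for the alternative). The package's default treats the Beta draw as the
survival probability with low draws exceptional, which keeps the
lowest-$u$ families the most enriched and reproduces the qualitative
structure of the published family-size-by-score tables; the alternative
is available as `sim_config(u_direction = "flipped")`.

`run_simulation_study()` repeats generation, scoring, selection
(`select_top()`, seeded random tie-break) and PPV computation, and also
records the median family size within score bins
(cut-offs 0.1–0.5, `score_size_bins()`). Zero-valued scores are excluded
from the binning by default: the zero bin is dominated by small families
with no long-lived members and would mask the size pattern among positive
scores; this convention is also the only one under which the published
bin medians for the first LRC bin (median 10, range 10–14) are
reproducible. `include_zero = TRUE` restores a closed first bin.

Ties deserve a note: on the LRC grid, hundreds of families can share a
boundary value, so the selected set depends on the tie rule.
`select_top()` defaults to a seeded uniform tie-break — the neutral choice
when measuring selection accuracy — and offers a deterministic rule
(size-descending, then id) for exactly reproducible pipelines.

### What these simulations do and do not show

Replicated runs of this design give PPVs for LRC around 0.75 at top-10%
selection and around 0.77 for mLRC, with the mLRC advantage concentrated
in replicates where family-size confounding misleads the LRC (the numbers
your installation produces are computed by `scripts/acceptance.R` and by
the acceptance tests, not quoted here). The generator draws percentiles
directly; it does not model ages at death, censoring, secular mortality
trends or sibling competition, so a good PPV here demonstrates correct
shrinkage arithmetic, not performance on any particular register.

## The synthetic historical register and holdout validation

Because real historical sibship registers are not redistributable, the
package ships a synthetic stand-in, `generate_hsn_like()` (the "H" files
it writes are labelled synthetic throughout). It draws ~1105 sibships with
a mean of ~4.85 members (shifted, zero-truncated Poisson sizes), sexes,
birth years 1860–1905 and complete lifespans from a Gompertz
proportional-hazards model that also defines the reference lifetable
(`synthetic_lifetable()`), so annotation and generation are coherent. Two
family-level components drive familial longevity: a binary "long-lived
family" flag carrying a configurable log hazard ratio (default −0.3,
the scale reported for historical sibship validations), and a continuous
log-frailty (sd 0.5) that supplies the realistic continuous clustering
without which score-based selections would carry almost no survival
signal.

`run_hsn_pipeline()` reproduces the validation workflow: hold out one
random member per sibship, score the remaining siblings, select families
by threshold or top fraction, and fit a Cox model (sex- and
birth-cohort-adjusted; linear year by default, decade factors as an
option, both offered because published analyses rarely state which was
used) to the holdout members with the selection indicator as the
explanatory variable. The holdout set never touches the scores — the
pipeline asserts the disjointness.

Under this generator, the truth-based selection recovers the injected
log hazard ratio within its confidence interval and the null design is
well calibrated (both tested). The *comparative* claim — that the mLRC
selection predicts holdout survival more strongly than the LRC selection
— is at the edge of detectability at this scale: the paired difference
between the two Cox coefficients is an order of magnitude smaller than
its replicate noise, so individual replicates split roughly evenly. The
package reports both coefficients and leaves the comparison to the
analyst rather than overstating a separation the data cannot support.

## Problem sizes used by the shipped checks

The acceptance script runs the LRC-only study at 1000 replicates and the
mLRC study at 200 replicates (Monte-Carlo standard error of each reported
mean below half a percentage point); the test suite uses 1000 and 120
replicates respectively, 5 seeds of 2000 families for parameter recovery,
a 20-replicate null-calibration run and an 11-seed directional
comparison. These sizes were chosen so the full suite is a coffee-break
run on one core while keeping every Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* Censored lifespans are out of scope: every scored member needs an
  observed age at death, and the filters (`apply_filters()`) remove
  non-extinct cohorts rather than imputing.
* Only sibships are modelled; mixed degrees of relatedness would need a
  relatedness-weighted random effect.
* The logistic-normal model has no per-member covariates; sex and cohort
  enter only through the percentile computation.
* The binary indicator discards longevity information beyond the
  threshold; a continuous model-based score is a natural extension.
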