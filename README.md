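# famscore

Family-based longevity scores with random-effect shrinkage.

Human longevity clusters in families, and genetic studies of longevity
recruit participants more efficiently when candidates come from families
with a demonstrable history of exceptional survival. `famscore` computes
family history scores from sibship lifespan records and sex- and
birth-cohort-specific reference lifetables, for researchers designing
longevity case–control or GWA studies from historical register or pedigree
data.

## The scores

Each member's age at death is converted to a survival percentile
*P<sub>ij</sub>* = 1 − *S*(*t<sub>ij</sub>* | cohort, sex) against the
reference lifetable; a member is *long-lived* when *P<sub>ij</sub>* ≥ *c*
(default *c* = 0.9, the top decile of survivors). Three family scores are
provided:

* **SE<sub>f</sub>** = Σ<sub>j</sub> (Λ(*t<sub>ij</sub>*) − 1), the summed
  survival exceptionality (cumulative hazard minus one). Additive in
  members, hence systematically inflated for large families — implemented
  for comparison.
* **LRC** = Σ<sub>j</sub> I(*P<sub>ij</sub>* ≥ *c*) / *N<sub>i</sub>*, the
  proportion of long-lived siblings. Bounded, but noisy for small families.
* **mLRC**: a random-intercept logistic model
  P(*Y<sub>ij</sub>* = 1 | *u<sub>i</sub>*) = logit<sup>−1</sup>(β₀ +
  *u<sub>i</sub>*), *u<sub>i</sub>* ~ N(0, σ²), is fitted to the longevity
  indicators by marginal maximum likelihood (adaptive Gauss–Hermite
  quadrature), and each family is scored by the posterior mean of its
  longevity probability given (*k<sub>i</sub>*, *N<sub>i</sub>*). This
  shrinks small-family proportions toward the population level in
  proportion to their uncertainty, making rankings robust to family size.

The package also ships the supporting machinery: lifetable readers and
lookups, sibship filters (missing lifespans, non-extinct cohorts,
singletons), a one-member-per-family holdout split, selection rules with
explicit tie handling, a replicated PPV simulation benchmark, synthetic
sibship-register generators, and a Cox-regression holdout validation
pipeline.

## Worked example

```r
library(famscore)
library(dplyr)

pop  <- generate_population(sim_config(), seed = 2024)  # benchmark design
mlrc <- score_mlrc(pop$individuals)
glance(attr(mlrc, "fit"))
#> # A tibble: 1 × 7
#>   beta0 sigma logLik converged n_families n_individuals quadrature_order
#>   <dbl> <dbl>  <dbl> <lgl>          <int>         <int>            <dbl>
#> 1 -3.34  2.26 -2198. TRUE            1000          7400               60

head(arrange(mlrc, desc(value)), 4)
#> # A tibble: 4 × 5
#>   family_id  size score value threshold
#>   <chr>     <int> <chr> <dbl>     <dbl>
#> 1 F0601        10 mLRC  0.888       0.9
#> 2 F0608        10 mLRC  0.888       0.9
#> 3 F0769        10 mLRC  0.888       0.9
#> 4 F0454         8 mLRC  0.865       0.9

sel <- select_top(mlrc, fraction = 0.10, seed = 1)
ppv(sel, truly_long_lived(pop, 0.10))
#> [1] 0.72
```

The fitted intercept β₀ = −3.34 says a family at the population level has
about a 3.4% chance per member of reaching the top survival decile; the
large random-effect SD (σ = 2.26) reflects strong familial clustering. The
top-ranked families are size-8–10 families with many long-lived members —
under the empirical LRC, size-2 families with two lucky deaths would
crowd them out. Of the 100 families selected by mLRC, 72% belong to the
true lowest-decile latent-effect group.

For real data, start instead from CSV files:

```r
fam <- read_families("sibships.csv") |> apply_filters(reference_year = 2017)
lt  <- read_lifetable("lifetable.csv")
ann <- annotate_longevity(fam, lt, threshold = 0.9)
score_mlrc(ann)
```

A command-line wrapper (`inst/scripts/famscore`) exposes `score`,
`simulate`, `study` and `validate` subcommands over the same functions.

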