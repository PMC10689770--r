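# colpress

Colonization pressure and establishment richness from the global live
vertebrate trade.

## What problem this package addresses

The international trade in live terrestrial vertebrates moves thousands of
mammal, bird, reptile and amphibian species into countries where they do
not naturally occur. Every such *alien* species offered in a country adds
to that country's **colonization pressure** — the number of alien species
introduced to an area — which, together with insularity and socio-economic
conditions, shapes how many of those aliens go on to found self-sustaining
populations (**establishment richness**).

`colpress` is a research compendium for this analysis chain, aimed at
invasion ecologists and biodiversity-informatics practitioners. It
provides:

1. **Harmonization** of trade records from four heterogeneous source
   dialects — regulatory trade reports (CITES-like), enforcement records
   (LEMIS-like), zoo inventories (ISIS-like) and free-text online listings
   (OTAPS-like) — including quality control (duplicate lines, identical
   importer/exporter, missing or hybrid names, non-live terms), and
   taxonomic name resolution through a length-sorted key index
   (`build_key_index()`, `extract_name()`, `resolve_accepted()`).
2. **Classification** of every traded species × country combination as
   alien or native against country-level native-range sets, with
   per-country colonization pressure, native richness and establishment
   richness, source-overlap (Venn) accounting and headline share metrics.
3. **Establishment analysis**: matching established-species lists to
   traded aliens and comparing trade breadth (countries, summed area)
   between established and unestablished species.
4. **Statistical inference**: a maximum-likelihood linear mixed model with
   a biogeographic-realm random intercept (profiled over the variance
   ratio), all-subsets enumeration of the nine country-level predictors
   (2⁹ = 512 models), AICc ranking, Akaike weights, conditional model
   averaging, a logistic mixed model (adaptive Gauss–Hermite quadrature)
   for establishment versus trade breadth, univariate socio-economic
   models, paired t comparisons and cross-taxa correlations.
5. **Flow networks**: donor-region → recipient-region species-flow
   matrices among the 8 world economic regions, for all traded aliens and
   for established aliens.
6. A seeded **synthetic-data generator** that emulates the study
   conditions (7,780 species, four overlapping sources with the published
   per-source totals, 193 countries across 7 realms and 8 regions) and
   writes a truth ledger so every estimator can be checked by parameter
   recovery.

## The statistical core

For each vertebrate class, establishment richness `E_c` in country `c` is
modelled on the log scale,

    log(1 + E_c) = β₀ + Σ_j β_j x_cj + u_realm(c) + ε_c,
    u ~ N(0, τ²),  ε ~ N(0, σ²),

with nine standardized predictors: log area, log population density, log
GDP per capita, log(1 + colonization pressure), insularity (0/1), mean
temperature, log mean precipitation, log(1 + congeneric richness) and
sampling effort. All 2⁹ predictor subsets are fitted by maximum
likelihood, ranked by

    AICc = −2 logL + 2k + 2k(k+1)/(n−k−1),

and combined by **conditional averaging**: for each predictor, estimates
are averaged over the models containing it with renormalized Akaike
weights `w_i ∝ exp(−Δᵢ/2)`, and the unconditional standard error
`SE = Σ wᵢ √(varᵢ + (βᵢ − β̄)²)` feeds a |z| ≥ 1.96 significance rule.
Species-level establishment is modelled as
`logit P(established) = a + b · (number of trading countries)` with a
family random intercept.

## Worked example

```r
library(colpress)
library(dplyr)

cfg <- sim_config(scale = 0.05, n_countries = 60, seed = 11)
run <- run_pipeline(cfg)

run$shares %>% select(metric, numerator, denominator, value)
#> # A tibble: 6 × 4
#>   metric                numerator denominator value
#> 1 traded_of_extant            389       34285   1.1
#> 2 alien_of_traded             328         389  84.3
#> 3 established_of_alien         33         328  10.1
#> 4 traded_of_established        33          45  73.3
#> 5 native_only_of_traded        61         389  15.7
#> 6 both_of_alien               220         328  67.1

tidy(run$glmm)
#> # A tibble: 2 × 5
#>   term      estimate std.error statistic  p.value
#> 1 intercept  -3.31      0.316     -10.5  1.17e-25
#> 2 slope       0.0766    0.0129      5.93 2.98e- 9

run$inference$reptile$averaged %>%
  as_tibble() %>%
  select(predictor, estimate, se, z, significant) %>%
  arrange(desc(abs(z))) %>% head(4)
#> 1 colonization_pressure    0.273 0.0857  3.18  TRUE
#> 2 mean_temperature         0.177 0.0788  2.24  TRUE
#> 3 gdp_pc                  -0.126 0.0894 -1.41  FALSE
#> 4 insularity               0.148 0.197   0.753 FALSE
```

Reading the output: in this 60-country synthetic world, 84.3% of the 389
traded species are traded as aliens somewhere and 10.1% of those aliens
establish; the logistic mixed model recovers the generating establishment
slope (true value 0.08) as 0.077 ± 0.013; and conditional averaging flags
colonization pressure as the dominant establishment predictor, mirroring
the generative model. `autoplot(run$flow_all)` draws the 8×8 interregional
flow matrix and `autoplot(run$inference$reptile$averaged)` the coefficient
plot.

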