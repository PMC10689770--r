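---
title: "Methods: trade harmonization, alien classification and multimodel inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trade harmonization, alien classification and multimodel inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colpress)
```

## The analysis in one paragraph

`colpress` quantifies alien species in the live terrestrial vertebrate
trade and the drivers of their establishment. Trade records from four
source dialects are cleaned and name-resolved, every traded species ×
country combination is labelled alien or native against country-level
native-range sets, per-country colonization pressure (distinct alien
species traded) and establishment richness are aggregated, and
establishment richness is analysed with all-subsets AICc multimodel
inference over nine country-level predictors in a linear mixed model with
a biogeographic-realm random intercept. Donor→recipient species flows are
summarized among eight world economic regions. A seeded synthetic world
with a truth ledger provides the test bed.

## Name harmonization

Keys (scientific names, synonyms, vernacular and trade names) are
lowercased and ordered ascending by character length, ties broken
lexicographically (`build_key_index()`). Free-text listings are searched
for every key as a raw substring; among the keys present, the one ordered
*last* — i.e. the longest — wins (`extract_name()`). This reproduces
lookup-over-a-sorted-array semantics: scanning the sorted key column and
keeping the final hit. Two consequences are worth knowing:

* Substring matching has no word-boundary requirement, so a key can match
  inside a longer word ("anole" in "anoles"). That is faithful to the
  spreadsheet FIND mechanism the procedure mirrors; a `word_boundary`
  flag enables stricter matching when false positives matter.
* Equal-length ties return the lexicographically last key. Any
  deterministic rule would do; this one matches the sorted-array
  mechanism exactly.

Internally, candidate (text, key) pairs come from an inverted index on the
first three characters of each key — a key cannot occur in a text unless
its first trigram does — which keeps extraction exact while avoiding the
full keys × texts scan. Resolution to accepted names is an exact
lowercased lookup; unresolved strings are excluded and counted.

Quality control removes, in a fixed order: non-live terms (structured
dialects only), rows with no scientific name, genus-only (`sp.`, `spp.`)
and hybrid (`×`, "hybrid") names, rows whose importer equals their
exporter, and exactly duplicated lines. The removal report reconciles to
rows-in minus rows-out, and cleaning is idempotent. Raw duplicate lines
are removed *before* name resolution and duplicate (species, country,
source) observations are collapsed *after* it; zoo-inventory rows for
threatened species (IUCN VU/EN/CR) are dropped last, on the assumption
that zoo holdings of threatened species serve conservation rather than
commerce.

## Classification and aggregation

The native range of a species is the union of its native-extant,
native-possibly-extant, extinct and possibly-extinct country sets;
introduced-presence countries are excluded. A record is *alien* when its
country lies outside this set, *native* inside, and *unknown-range* when
the set is empty — unknown-range species are kept in trade totals but
excluded from richness numerators and denominators. Colonization pressure
per country is the count of distinct alien-labelled species, invariant to
how many sources duplicate a record. Percentages are reported rounded
half-up to one decimal, ratios to two, matching the reporting style of
the field.

## The mixed-model machinery

`fit_lmm_ml()` fits `y = Xβ + u_g + ε` by maximum likelihood, profiling
over the variance ratio λ = τ²/σ²: for fixed λ the GLS coefficients and
the ML residual variance are closed-form thanks to the block structure of
`(I + λZZᵀ)⁻¹`, leaving a one-dimensional optimization in log λ (interval
[e⁻²⁰, e¹²], plus an explicit λ = 0 boundary evaluation). ML rather than
REML is used because REML likelihoods are not comparable across fixed
effect structures, which multimodel AICc ranking requires; a REML refit
of a chosen model is a one-line extension. The parameter count is
k = (fixed effects incl. intercept) + 2 variance components — the
standard AICc bookkeeping for this family.

All 2⁹ predictor subsets (including the intercept-only model) are fitted;
AICc, Δ, Akaike weights `w ∝ exp(−Δ/2)`, the inclusive ΔAICc ≤ 2 top-model
set, and marginal R² = var(Xβ̂)/(var(Xβ̂)+τ̂²+σ̂²) (the fixed-effects
variance fraction) are reported per model. Conditional averaging averages
each coefficient over only the models containing it, with weights
renormalized within that subset; the unconditional standard error
`Σ wᵢ √(varᵢ + (βᵢ − β̄)²)` folds between-model spread into the interval,
and significance uses the two-sided normal rule |z| ≥ 1.96.

Transforms before fitting: natural log for area, population density, GDP
per capita and mean precipitation; log(1+x) for colonization pressure,
congeneric richness and the establishment-richness response; z-score
standardization of all continuous predictors (binary insularity stays
0/1). The standardization scheme is a genuine free choice — a two-SD
variant exists in the literature — so it is exposed as the `standardize`
argument; z-scoring is the default because the averaged coefficients are
then directly comparable per 1-SD change. Analysis rows are restricted to
upper-middle- and high-income countries by default, mirroring the
analysis population of the underlying study design.

`fit_logistic_mixed()` maximizes the marginal likelihood of
`logit P(est) = a + b·breadth + u_family` by adaptive Gauss–Hermite
quadrature: each family's integrand is recentred at its conditional mode
(Newton steps on the joint log-density) and scaled by its curvature, then
integrated on 15 nodes (configurable); nodes/weights come from the
Golub–Welsch eigendecomposition. τ can be fixed (τ = 0 reduces exactly to
plain logistic regression, which is how the implementation is
cross-checked against IRLS). A nested order/family/genus intercept
structure was simplified to the single family level — the dominant
taxonomic scale of establishment correlation — and is the natural
extension point. Complete separation along the predictor and single-class
outcomes are rejected up front.

Numerical details: likelihood evaluations use the stable `log(1+e^x)`
branch; the GLMM information matrix is a finite-difference Hessian at the
optimum; the LMM boundary fit λ = 0 is always compared against the
interior optimum so τ̂² = 0 is attainable exactly.

## Flow networks

One flow is counted per distinct (species, donor region, recipient
region) triple where the species is native in ≥ 1 country of the donor
region and alien-traded in ≥ 1 country of the recipient region — a
species native in two regions and alien-traded in three contributes six
triples. Native-country trade never generates a flow; a species alien-
traded in a different country of its own native region lands on the
diagonal (intraregional exchange). The region-pair (not country-pair)
counting rule follows the "species may be counted multiple times due to
multiple origins or destinations" convention of chord-diagram figures in
this literature. The country→region map is data, not code, since no
canonical table is published; the default synthetic world carries its
own.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions, fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| species per class | 1247 / 3451 / 2278 / 804 | published class totals (sum 7,780) |
| countries, realms, regions | 193, 7, 8 | published study frame |
| source totals | CITES 2371, LEMIS 3908, ISIS 3116, OTAPS 5053 | published per-source species counts; realized exactly after harmonization |
| single-source share | 0.451 | published overlap structure |
| breadth | 1 + NB(size 0.31, µ 9.6) | heavy-tailed; design simulation matches the published species-level shares (≈85.7% alien, ≈14.3% native-only, ≈65.9% of aliens also traded natively) and a mean breadth near 10.6 countries |
| per-draw alien probability | 0.63 | same design simulation |
| establishment logit | a = −3.21, b = 0.08 / country | prevalence ≈ 0.122 among traded aliens at the realized breadth distribution |
| establishment among never-alien species | 0.2 | pads the established pool so traded aliens are ≈78% of it |
| country model | β = (0.10, 0.10, 0.20, 0.35, 0.25, 0, 0.05, 0.05, 0.15), τ = 0.25, σ = 0.40, intercept 2.5 | colonization pressure and insularity dominant, one exact null (temperature); realistic per-country establishment counts |
| import attraction | 0.5·z(log pop) + 0.5·z(log trade) + 0.3·z(log GDPpc) | the shared "importing power" factor behind strong cross-taxa richness correlations and socio-economic gradients |
| noise | synonyms 0.30, typos 0.05, junk listings 0.20 | free-text listing noise is a stand-in: no generative description of real listing text exists, so these rates are plausible, not calibrated to any corpus |

Every planted artefact — QC violations by rule, typos, junk listings,
threatened zoo rows, the alien/native label of every (species, country)
pair, the establishment parameters and realized realm intercepts — is
booked in ledgers, so the tests can demand *exact* reconciliation:
cleaning removes precisely the planted violations, classification agrees
with the planted labels with zero errors, and per-source distinct-species
counts equal the configured marginals exactly.

Features of real data the generator does not emulate: trade volumes,
prices and temporal dynamics; subnational ranges (everything is
country-level); taxonomic revisions beyond simple synonymy;
spatially-autocorrelated covariates beyond the realm blocks; and real
listing language. Passing tests therefore demonstrate correctness of the
pipeline's logic and estimators under a controlled world — they do not
validate ecological conclusions about real trade data.

Establishment is generated twice, deliberately. The species-level
logistic layer drives the realistic end-to-end artifact (establishment
records placed in a subset of each species' alien-trade countries). A
separate country-level layer draws per-country, per-class establishment
richness directly from the log-linear model with realm intercepts on the
`log1p` scale; this is the layer used for coefficient-recovery studies,
because it makes the generating β well-defined on the scale the
inference fits. Richness is rounded to integers and floored at zero, a
mild attenuation accepted for realism.

## Seeds and determinism

One integer seed enters the configuration; each generator draws from an
independent named substream derived from it, so adding draws to one
generator never perturbs another. Identical configurations produce
byte-identical tables.

## Problem sizes used by the test suite

The shared unit-test world runs at 2% scale (≈156 species, 30 countries).
The acceptance suite runs the full default world once (7,780 species, 193
countries, 512-model averaging for each of the four classes, ≈1 minute),
a 50-replicate slope-recovery harness at n = 4,000 species, and a
25-replicate coefficient-recovery study at 150 countries (checking that
the averaged estimates' 95% intervals cover the generating β for ≥ 8 of 9
predictors in ≥ 80% of replicates — conditional averaging is mildly
biased away from zero for null predictors, which the unconditional SE
absorbs at these sample sizes). These sizes were chosen to keep the whole
suite in the minutes range while leaving the stochastic checks
well-powered.

## Known limitations

* Class-specific establishment contrasts (e.g. different
  established/unestablished breadth ratios per class) require
  class-specific establishment parameters; the default generator uses one
  global logistic model, so its realized ratios are homogeneous across
  classes.
* The LMM supports exactly one random-intercept grouping; crossed or
  nested structures need an external fitter.
* `extract_name()` returns at most one key per text (the longest);
  listings advertising several species yield their longest key only.
* Country-level resolution throughout: dependent territories, subnational
  units and marine ranges are out of scope.
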