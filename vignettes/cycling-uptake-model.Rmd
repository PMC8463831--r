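---
title: "Modelling commuter cycling uptake and its health and carbon impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling commuter cycling uptake and its health and carbon impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclehia)
```

cyclehia is an individual-level model of commuter cycling uptake and its
consequences. It answers questions of the form: *if cycling to work grew
under a given scenario, who would take it up, how much extra physical
activity would they get, how many premature deaths and sickness-absence
hours would that avert, what would that be worth, and how much car CO2
would be avoided?* — disaggregated by sex, age, ethnicity, car ownership,
income deprivation, urban/rural status, region and route hilliness.

The pipeline has five stages: a synthetic commuter population on
origin–destination (OD) pairs; logistic models of baseline cycling
propensity; five uptake scenarios; a physical-activity model converting
switched trips into weekly marginal-MET hours (mMETh); and comparative risk
assessment plus carbon accounting. This vignette explains each stage's
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data can and cannot demonstrate.

## The synthetic population

Real commuting microdata of this kind (census OD tables with per-individual
age, sex and mode, enriched with imputed car ownership and ethnicity and
routed distances and gradients) are safeguarded and cannot ship with a
package. `generate_population()` emulates their structure:

* **Zones** carry region (11 regions: the 10 standard regions of England
  and Wales with London split into Inner and Outer), an income-deprivation
  quintile, one of five urban/rural classes, and a sparsity flag.
* **OD pairs** carry a fastest-route distance and a mean uphill gradient.
  Distances are log-normal with class-specific parameters chosen so mean
  sub-30 km commutes are about 8.3 km from urban zones and 11.6 km from
  rural ones — log-normal being the standard commute-length shape when only
  means are published. Gradients are truncated normal on [0, 5]% with means
  1.8% (urban) and 2.1% (rural), about 1.9% overall. Routes of 30 km or
  more, and an explicit overseas category, are flagged `far`; they exist in
  the population (about 12% of commuters) but are excluded from all
  scenario uptake. Commuters with no fixed workplace (8.75%) keep a home
  zone and carry its mean sub-30 km route attributes.
* **Commuters** get sex, age band and main mode from configurable
  marginals; cycling itself comes from a logistic model in distance,
  hilliness and demographics (`default_cycle_coef()`), so that the fitting
  stage has a well-specified truth to recover.

Car ownership and ethnicity are then **imputed sequentially** within each
OD-pair-by-mode cell: the cell's true count of car owners is known (here,
drawn from mode-conditional marginals — drivers almost always own cars,
cyclists and bus users less often), and exactly that many individuals are
flagged, selected by weighted sampling without replacement with weights
increasing in age and male sex. Ethnicity is imputed second, so its weights
can condition on the just-imputed car ownership. Two properties matter and
are tested: per-cell marginals are *exact*, not merely expected; and the
sequential-renormalisation sampling scheme is exactly base R's
`sample()`, so inclusion probabilities can be enumerated independently.
Note this means car ownership is associated with cycling through the cell
marginals rather than causally in the generating logit — which mirrors how
the association arises in census-style data.

The generator consumes one RNG stream in a documented order (zones, OD
pairs, individuals, car, ethnicity) from a single seed, and is
bit-reproducible.

## Baseline propensity models

`fit_baseline()` fits cycling (yes/no) on fixed-workplace sub-30 km
commuters with the basis {d, √d, d², g, d·g, √d·g}: the non-linear distance
terms capture the rise-then-decay of cycling with distance, and the
interactions let hilliness steepen the distance deterrent. This exact basis
matches the published national commuter-cycling model family and keeps the
design matrix small.

`fit_near_market()` stratifies by region × sex × broad age band (16–49,
50+), giving 44 models, and adds age category, ethnicity, household car,
income-deprivation quintile (entered as a centred numeric score),
urban/rural class and sparsity as main effects. Stratification is what
allows, say, the distance deterrent to be stronger for women and older
commuters, or the car-ownership effect to be weaker in London — both
checked on synthetic data constructed with those features. Within-stratum
interactions are deliberately excluded: stratification already provides the
effect modification that matters.

Numerical choices: fits use `stats::glm.fit` (binomial ML) on an explicit
dummy design, so levels absent from a stratum simply drop (coefficient zero
at prediction); single-class outcomes raise a separation error rather than
returning a degenerate fit; strata with fewer than 30 cyclists fall back to
the pooled baseline model with a warning — small enough to matter only
where a stable stratum fit is impossible anyway. Predictions are defined
only on (0, 30) km; callers must exclude far commuters. No-fixed-workplace
commuters receive their home zone's commuter-weighted mean predicted
propensity (the natural reading of averaging "over their OD pair" for
people who have no destination; zones without fixed-workplace commuters
fall back to the regional mean, with a message).

## The five scenarios

All scenarios return a per-commuter switch probability; uptake is computed
in expectation (fractional cyclists), with `realise_switches()` available
for seeded 0/1 draws. Existing cyclists always keep cycling; far commuters
never switch in.

* **Government Target (Equality)** doubles cycling nationally. Switch
  probabilities are proportional to the baseline (route-only) propensity —
  identical for everyone on the same route, hence "equality" — with one
  national scale factor λ solved so expected new cyclists equal existing
  ones. If scaling would push any probability past 1 it is capped and λ
  re-solved on the uncapped remainder (water-filling); an unattainable
  target errors rather than silently undershooting. Doubling is interpreted
  as doubling *commuters* who cycle.
* **Government Target (Near Market)** reuses the Equality scenario's
  regional totals but distributes them within each region proportionally to
  the 44-model demographic propensities, so uptake mirrors current
  demographic skews.
* **Gender Equality** raises each OD pair's female cycling share to the
  male share (no change where women already cycle more), spreading the
  required uptake equally over the pair's female non-cyclists. All new
  cyclists are women.
* **Go Dutch** shifts each pair's baseline propensity on the logit scale by
  `intercept + per_km × distance` (defaults 2.499 and −0.07384, the
  published Netherlands-equivalence uplift family) and raises the pair to
  the resulting target share, spread equally over its non-cyclists. The
  "current share" subtracted from the target is the model's baseline
  propensity, not the pair's noisy empirical share: this makes a zero
  uplift exactly the identity and stops tiny pairs from "topping up"
  sampling noise. Uptake is floored at zero — the scenario never removes
  cyclists.
* **E-bikes** recomputes the baseline propensity with the gradient
  coefficients attenuated by 50% and the linear distance penalty by 10%
  (electric assistance makes hills and distance less of a barrier), applies
  the same Dutch uplift, and takes the larger of the e-bike and Go Dutch
  targets per pair, so e-bike uptake is never below Go Dutch. With zero
  relief it reduces exactly to Go Dutch.

On any common synthetic population the national shares order as baseline <
Gender Equality ≤ Government Target < Go Dutch < E-bikes.

## Mode shift

New cyclists' former modes follow the current mode split of each pair's
non-cyclists (`allocate_proportional()`); at the individual level each
switcher's former mode is simply their own baseline mode, and the two views
agree whenever switch probabilities are constant within a pair. Fractional
allocations are canonical; largest-remainder integerisation is provided for
display only. Former mode gates everything downstream: ex-walkers trigger a
physical-activity debit, and only ex-car-drivers generate carbon savings
(car passengers get health but no carbon benefit).

## The activity model

A route with mean uphill gradient g% is one leg climbing at g and one leg
descending, with descending speed and energy expenditure set equal to the
flat. Uphill speed is `v_flat − k·√g`; route speed is the time-weighted
(harmonic) combination of the legs. Intensity uses a cycling power equation
`P(v, g) = (a + b·v²)·v + m·g₀·v·(g/100)` (rolling resistance, air
resistance, gravity), converted to mMET via gross efficiency and a resting
metabolic rate, minus one MET.

One structural choice deserves emphasis. Evaluating the whole power
equation at the reduced climbing speed makes route intensity *non-monotone*
near zero gradient: √g has infinite slope at 0, so the speed-dependent
resistance power initially falls faster than the gravity term rises. We
instead model the climbing leg as *flat-ground propulsive effort sustained,
plus the gravity climbing work at the reduced climbing speed*. That is
physically reasonable (riders hold their effort and lose speed to gravity),
keeps the di Prampero structure, and makes route intensity strictly
increasing in gradient, as a hill model should be.

The constants are *effective calibrated values*, not physical measurements:
`v_flat` = 15 km/h and `b` = 0.3125 are fixed; `k` is solved so route speed
at a 1.5% gradient is exactly 13.9 km/h; and (`a`, `m`) solve a 2×2 linear
system so that route intensity at 1.5% is exactly 5.39 mMET *and* the
population-mean e-bike intensity over the default gradient distribution is
exactly 3.5 mMET. Because intensity is linear in `a` and `m`, this
calibration is exact, not fitted. Walking assumes the relative uphill
effort and speed penalties are proportional to cycling's, with the flat
base solved in closed form so the population-mean walking intensity is 3.6
mMET. E-bikes are 1.8 mMET below conventional cycling on the flat, incur
half the extra uphill effort, and half the uphill speed penalty.
Population means use a deterministic 2001-point quadrature over the default
truncated-normal gradient distribution (mean 1.9, sd 1.0 on [0, 5]%), not
Monte Carlo. Degenerate parameters (uphill speed below 4 km/h, negative
e-bike intensity) are floored with a warning.

Weekly dose = trips/week × (distance ÷ route speed) × route intensity, with
trips/week from a sex × age table averaging about 5 one-way trips
(`default_trips_per_week()`; the survey-derived values are not published,
so the defaults encode the usual pattern of fewer trips for women and older
commuters). Ex-walkers are debited the displaced walking dose computed the
same way; because walking the same route takes much longer, short cycled
trips that displace walking can yield a *negative* net dose — a real
feature, not a bug, of mode-shift health accounting.

## Health and carbon impacts

The mortality dose-response is a relative risk of 0.9 per 8.75 mMETh/week
(≈150 min of moderate activity at 3.5 mMET), power-scaled:
`RR = max(cap, 0.9^(dose/8.75))`, capped at 0.55 for cycling and 0.70 for
walking. Net deaths averted per person-year are
`m·(1 − RR_cycle(gain)) − m·(1 − RR_walk(displaced))` with `m` the
age/sex/region background mortality rate. The walking debit uses the same
protective-side formula and cap (the harm equals the protection the
walking was providing); the alternative inverse-risk reading is a one-line
change isolated in `deaths_averted()`. Each death averted is worth the
individual's age/sex-specific years of life lost, discounted at 1.5%/year
as a closed-form annuity `(1 − (1+r)^−L)/r` (handling fractional L), and
monetised at £57,965 per YLL (2010 prices). Sickness absence uses the
identical machinery with base 0.75 and cap 0.50, applied to age/sex/region
annual sickness hours and valued at the regional hourly salary — exposed as
one scalar per region, sidestepping the mean-vs-median earnings ambiguity.
Results are single-year: no lags, no ageing of the cohort.

Because the dose-response is non-linear, expected impacts are computed as
`p_switch × impact(full-switch dose)`, never `impact(p_switch × dose)`.

Background rates ship as synthetic in-code tables
(`default_background_rates()`) spanning the published anchor ranges
(mortality 0.24–28 per 1000 across age bands, higher for men; YLL per death
declining with age; sickness hours 8.2–69.9; salary £17.16–£24.15). They
are placeholders with the right structure and magnitudes, not vital
statistics.

Carbon: only ex-car-drivers count, at
`n × distance × trips/week × 52.2 × 0.182 kg/km`, with former car distance
taken equal to the new cycling route distance. The carbon price is a
user-supplied appraisal scalar (default £70/tonne in examples), since no
canonical value is built in.

## Reporting

`mode_share_table()`, `impact_table()`, `per_million_table()` and
`hilliness_table()` aggregate by any of the eight grouping variables, always
with a whole-sample row that group rows sum to. The hilliness table
contrasts health benefits computed with each route's own gradient against a
re-run with all gradients forced to the population mean — quantifying how
much the gradient-aware health model narrows the apparent flat-vs-hilly
benefit gap (hilly areas see less uptake but more benefit per switched
trip).

## What the tests show, and problem sizes

The test suite checks arithmetic identities against hand-computed oracles,
enumeration oracles for the weighted sampling, parameter recovery against
known generating coefficients (baseline model at n = 50,000; the 44
stratified models at 5,000 commuters per stratum, judged family-wise at 3
standard errors), exact calibration of the scenario totals, and the
conservation properties (marginal exactness, ledger additivity, zero dose ⇒
zero impact). Statistical checks use populations of 6,000–50,000 commuters
over 60 zones — large enough for stable fits and small enough that the
whole suite runs in well under a minute.

Passing these tests shows the machinery is correct *given the generator's
assumptions*. The synthetic population does not reproduce spatial
autocorrelation, realistic OD network structure, distance-dependent mode
splits among non-cyclists, within-region heterogeneity of rates tables, or
the true joint distribution of demographics — so absolute impact magnitudes
on synthetic runs are illustrative, while the worked-example anchors
(0.986; 13.9 km/h; 5.39, 3.6 and 3.5 mMET) and all calibration and
conservation properties are exact.

## Known limitations

Travel distances are fixed (no induced demand or destination change); no
churn among existing cyclists; no injury, air-pollution or noise pathways;
no morbidity beyond sickness absence; single-main-mode commutes only; the
e-bike scenario assumes all new uptake under it uses e-bike intensities.
These mirror the standard scope of national active-travel appraisal tools.
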