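---
title: "Global biomass-movement accounting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global biomass-movement accounting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomovr)
```

## The metric

The package accounts for *biomass movement*: the total biomass of a group
of organisms multiplied by the average distance its individuals actively
travel per year,

$$ M = B \times d_{\mathrm{yr}} \qquad [\,\mathrm{t\,km\,yr^{-1}}\,], $$

displayed at headline scale in Gt km yr⁻¹. The metric has units of mass ×
speed (momentum-like) and puts a migrating tern flock, the global wolf
population, commuters in cars and mesopelagic fish on a single axis. A
group's movement is the sum over its member species or subgroups, so the
accounting is a tree: leaves are species records, internal nodes are sums.

The core assumptions inherited by everything downstream:

* **Additivity.** Group movement is exactly the sum of member movements;
  no interaction terms. `aggregate_movement()` is therefore permutation-
  invariant and equal to a flat sum over leaves (tested to 10⁻⁹ relative).
* **Annual averaging.** Distances are annual means per individual; daily
  distances convert at 365 d yr⁻¹. No seasonal reweighting is applied.
* **Active movement only.** Drifting, passive transport and (for humans)
  vehicle mass are excluded; vehicle *mass* movement is a separate fixture
  scenario, not part of the biomass tree.

## Uncertainty: deliberately conservative

Each quantity is carried as mean + range (`uncertain()`), tagged by
whether the range is a 95% CI, extrema, or a bound-only record. Two
choices are intentionally conservative rather than probabilistically
optimal:

* **Arithmetic-sum propagation.** A parent's lower/upper offsets are the
  sums of its children's offsets. Independent errors would justify
  root-sum-square (offered as `method = "quadrature"`, never the default),
  but the dominant errors here — biomass census bias, under-resolved
  tracking — are shared across subgroups, and quadrature would understate
  them. The arithmetic-sum interval provably contains the quadrature
  interval (property-tested).
* **Endpoint products.** For `B × d` the range is `[B_low × d_low,
  B_high × d_high]`, the exact worst-case interval under comonotone
  errors.

Groups with too little data for a central estimate carry an *upper bound*
instead: biomass × daily activity time × characteristic speed × 365. Such
bound-only leaves contribute to a node's upper bound but never to its
mean — absence of data is never converted into movement.

## Trajectory analysis

Annual distances for tracked species come from GPS fixes: consecutive
great-circle (haversine, sphere R = 6371 km) distances summed along each
track, annualized by covered time. Numerical and policy choices:

* **Gaps are never bridged.** Fix pairs more than `max_gap` apart
  (default 7 d, a typical avian GPS duty-cycle failure scale) contribute
  neither path nor covered time; tracks with coverage below 0.5 are
  flagged unusable. Interpolating across a data hole would fabricate
  movement with the bias direction *unknown*; dropping it biases distance
  low, consistently with the metric's other conservatisms.
* **Sampling always underestimates.** A sampled polyline can only cut
  corners of the true path, so path length is monotonically non-increasing
  under subsampling (property-tested, and visible in the generator: at
  1-day fixes foraging tortuosity is mostly lost, only migration
  displacement survives). Estimates are lower bounds in this sense.
* **Sphere, not ellipsoid.** The ≲0.5% geometric error is far below
  biological uncertainty.
* **Species-level estimate.** Mean of per-individual annualized distances
  with a nonparametric bootstrap over individuals (1,000 replicates,
  percentile 95% interval, fixed seed; bit-reproducible).

## Energetics

The cost of transport COT(m) = a·mᵇ (J kg⁻¹ m⁻¹, b ≤ 0) converts movement
to energy: since 1 Gt km = 10¹⁵ kg m and 1 TWh = 3.6 × 10¹⁵ J,

$$ E[\mathrm{TWh\,yr^{-1}}] = M[\mathrm{Gt\,km\,yr^{-1}}] \times
   \mathrm{COT} / 3.6, $$

and mean power spreads E over the 3.1536 × 10⁷-s year. The default
walk/run constants (a = 10.7, b = −0.316) put a 70-kg walker at
≈2.8 J kg⁻¹ m⁻¹ (≈0.7 kcal kg⁻¹ km⁻¹), the standard benchmark; published
group-average COTs enter as flat (b = 0) registry entries, since the
per-mode scaling constants behind them are not part of the bundled data.
The dietary calorie is 4184 J.

**Headline rounding.** Headline values round to one significant figure,
half away from zero (`round_sigfig()`); raw values are always kept
alongside. Two derivation orders for power are implemented: the default
derives power from unrounded energy and rounds once; a
`"round_then_derive"` mode derives power from the already-rounded energy.
At one significant figure the two disagree (e.g. 222 TWh yr⁻¹ → 25.4 →
30 GW direct, but 200 → 22.8 → 20 GW via the rounded energy). Published
tables of this kind are not always consistent with a single order; the
package keeps both paths explicit, and its tests assert printed cells only
where one of the two documented paths reaches them. Two cells of the
bundled energy table are reachable by neither (the wild-land-mammal row,
whose printed 20 TWh yr⁻¹ is below the half-away rounding of 25, and the
humans-walking power, printed 50 GW against a raw 57): for these the tests
pin the raw arithmetic and this vignette records the discrepancy.

## Human mobility: two-step estimation

Per-country per-mode travel demand (road, rail, air, walking+cycling, in
per-capita km yr⁻¹) is first harmonized from reported rows (total
passenger-km, per-capita-per-day, etc.), then gaps are filled by two
models and their average:

1. **Income-group mean** — the population-weighted mean per-capita demand
   of reported countries in the same World Bank income group.
2. **GDP regression** — per mode, OLS of log demand on log GDP per capita
   fitted to reported countries; predictions are exponentiated *with the
   log-normal retransformation factor* exp(σ̂²/2), because totals built
   from median (uncorrected) predictions are systematically low.

Reported entries pass through bit-identical; combined totals are therefore
never below the reported total. Conversion to biomass movement multiplies
person-km by body mass (default 54 kg, per-country override) — 1 Gt km =
10¹² kg km. Scenario variants scale entries by data-quality multipliers
(defaults: reported ×1, imputed ×0.5 / ×2), standing in for scenario rules
that are not part of the bundled data. Imputed walking/cycling demand has
a floor of 1 km d⁻¹ per person: walking data are globally sparse and a
lower imputed value is not credible for any population.

## What the generators emulate — and what they do not

All tests run on synthetic inputs with exact, brute-force-recomputable
ground truth (noise realizations are data, not truth):

* `gen_species_table()` — log-normal body masses per group, abundance
  ∝ m⁻⁰·⁷⁵, day range d = c·mᵉ with log-normal noise (c = 1 km d⁻¹ at
  1 kg, e = 0.25, σ = 0.4 — literature-style conventions, configurable).
  The positive mass–distance allometry reproduces the qualitative
  signature that large animals contribute more to movement than to
  biomass.
* `gen_tracks()` — migration legs between waypoints at cruise speed plus
  correlated-random-walk foraging bouts, built on an hourly path whose
  integrated length is the truth; fixes are subsampled with optional
  dropout.
* `gen_country_table()` — four income groups × 12 countries, GDP
  log-normals a decade apart, demand = α·GDPᵝ·noise (β = 0.8, σ = 0.3 for
  motorized modes), and missingness logistic in log GDP (50% at
  GDP/capita 2,000, ≈70% for low-income vs ≈2% for high-income
  countries), so gaps concentrate where they do in real mobility data
  while every income group retains some reported members.
* `gen_historical_series()` — exponential marine decline through the
  configured endpoints (80,000 → 30,000 Gt km yr⁻¹ over 1850–2020) and
  logistic human growth calibrated to 40-fold.

They do **not** emulate: real geography or coastlines, species lists,
behavioural segmentation, seasonal migration phenology, or the actual
national-statistics landscape. Passing tests therefore demonstrate that
the *estimators* are correct and well-calibrated under the stated
generative assumptions — not that the bundled headline values are right;
those enter as fixture inputs with provenance strings and are
re-derived only where desk arithmetic allows.

Determinism: every generator seeds R's Mersenne-Twister through a
per-component offset of the bundle seed, so identical (seed, config)
reproduce a bundle bit for bit and adding a generator never perturbs
another.

## Problem sizes

The bundled analysis and test runs use 100–300 synthetic species, 4–8
tracks of a few weeks at hourly fixes, 48 countries × 4 modes with 30%
masking, and 200 replicates (n = 100 countries, σ = 0.3) for the
elasticity-coverage study — sizes at which every check runs in seconds
while leaving the estimators nothing to hide behind: recovery tolerances
(1% dense-track recovery, 10% end-to-end mobility recovery, ≥90% CI
coverage) are set by the study design, not tuned to the draws.

## Known limitations

* Fine-scale tortuosity below the fix interval is invisible; all
  track-based distances are underestimates by construction.
* The fixture file carries headline printed values, not the underlying
  species-by-species synthesis; quantities that require that synthesis
  (e.g. single-species shares of a group total) are represented, not
  re-derived.
* Bound-only biomass is included in a node's biomass total but its
  movement only in the bound, so the node invariant
  `weighted_daily_km = movement / biomass / 365` reads as a
  *biomass-weighted* mean only when all leaves carry central estimates.
* The diel-vertical-migration arithmetic (participation fraction,
  up+down counting) is not closed by the bundled inputs; the fixture
  stores the printed totals, and the naive full-participation product
  (5 Gt × 1 km × 365 ≈ 1,800 Gt km yr⁻¹) brackets the printed ~1,000
  from above.
* The prokaryote motility bound computes to ≈63 Gt km yr⁻¹ at
  10 μm s⁻¹ and full-time motility against a printed order-of-magnitude
  "~50"; the fixture stores both.
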