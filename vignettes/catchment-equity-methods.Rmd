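---
title: "Catchment-area disaggregation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catchment-area disaggregation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchequity)
```

## The monitoring problem

Universal-coverage schemes are supposed to leave no one behind, but their
information systems typically report at the district level and no finer.
This package operationalises an equity monitor for exactly that situation:
the unit of analysis is the district, and the key derived variable is the
**catchment category** — the finest level of the administrative hierarchy
(state > district > subdistrict > neighbourhood) at which a district's
health-care centres (HCCs) provide coverage. Every indicator is then
disaggregated by that category, and by its binarisation into N
(neighbourhood-level access) versus MTN (anything coarser, including no
facility at all). The monitor answers four questions: who is being left
behind (income-stratified utilization), why (cost and density), where
(facility and district distribution), and how to respond (the tested
contrasts that justify reallocation).

## The classification rule

The category is decided purely from the per-subdistrict facility counts.
With counts `h_1..h_s` over `s` subdistricts: no facilities is `zero`; an
uncovered subdistrict alongside at least one facility is `district`; full
coverage with exactly `s` facilities is `subdistrict`; full coverage with
surplus is `neighborhood`. A verbal rule of the form "a centre per group of
neighbourhoods" is not directly decidable from tabular data, so the package
adopts this structural surrogate: surplus beyond one-per-subdistrict is what
distinguishes neighbourhood-level coverage. The classification is monotone —
adding a facility can only refine, never coarsen, the category — and the
test suite checks it exhaustively against an independently written
branch-predicate oracle on all small instances.

Health-map planning norms typically target a fixed insured population per
centre (default 10,000). The optional gate `require_target_ratio` makes the
`neighborhood` label conditional on meeting that target, degrading
overloaded districts to `subdistrict`. It is off by default because the
structural rule alone matches how the category definitions are stated; the
gate encodes the stricter planning norm when wanted.

`zero` is grouped with MTN in the binary contrast, and zero-category
districts are included in MTN utilization denominators by default
(`include_zero_in_mtn = TRUE`): having no facility is an accessibility state
of the underserved side, and excluding those insured would overstate MTN
utilization. The flag exposes the other reading for sensitivity analysis.

## The indicators

**Utilization rates** are pooled ratios, not averages of district ratios:
`Σ visits / Σ insured` over the districts in scope (state or national) and
group (N, MTN, or all — the *geographic* rate, which is therefore always an
insured-weighted mean of the two group rates). Visits count annual visits,
not distinct visitors; rates above 1 are expected. Income-stratified rates
divide poor (rich) visits by poor (rich) insured, pooling only districts
whose income-stratified visits are reported: a missing income split is
explicit missingness (`NA`), never zero, and such districts still contribute
to the all-insured rates. A group with no districts or an empty denominator
yields `NA` while the remaining rates are computed.

**Cost per capita** converts each category's pooled annual cost to USD at a
single flat buying rate (`fx_rate`, default 7 local units per USD; no
inflation or PPP adjustment) and divides by the category's accessible
insured. Zero insured makes the indicator undefined (`NA`); zero spending
with insured present is a true 0.

**The distribution table** reports counts and row-percentages of population,
insured, poor, rich, districts and HCCs by category. Percentages are rounded
half-up to two decimals — the convention of published administrative tables
(base R's `round()` is round-half-even and would print some boundary cells
differently). Published sources sometimes print a grand total that exceeds
the sum of the category cells (an uncategorised remainder); the `totals`
argument accepts such published denominators, in which case that row's
percentages sum to slightly under 100. Without it, denominators are the
category sums and each row sums to 100 within ±0.05. The packaged
`table1_districts()` fixture is exactly such a source: its published insured
total exceeds the category sum by 13,484, and the published percentages only
reproduce against the published total (`table1_totals()`).

**Density classes** bin each district's percentage share of its state's
insured population into five classes with closed lower bounds:
[0,20) very low, [20,40) low, [40,60) moderate, [60,80) high, [80,100]
very high.

## The rank tests

The headline comparisons are a Mann-Whitney test of district-level
utilization rates between N and MTN, and a Kruskal-Wallis test of
district-level per-capita cost across the four categories. Named tests leave
several conventions open; the package fixes them as follows and documents
the choice rather than hiding it:

* ties are handled by midranks throughout;
* Mann-Whitney p-values are two-sided; for pooled samples of at most 12 the
  p-value is computed by complete enumeration of the permutation
  distribution of U over the observed midranks (exact even under ties;
  the distribution is symmetric about `n_x n_y / 2`, so the two-sided tail
  is well defined), otherwise a normal approximation with tie-corrected
  variance and a continuity correction of 1/2 is used — the crossover
  `exact_limit = 12` keeps the enumeration below `choose(12, 6) = 924`
  subsets;
* Kruskal-Wallis uses the standard tie-corrected H against the chi-square
  law with `k − 1` degrees of freedom; if every pooled value is identical
  the correction degenerates and H is defined as 0 with p = 1;
* districts with undefined rates (no insured population) are excluded with
  a message; an undefined value has no rank;
* no multiplicity adjustment is applied: the pipeline reports two planned,
  separately interpreted tests.

Both tests carry per-group `n`, median and IQR. Quartiles use the
order-statistic interpolation placing quantile `q` at position
`1 + q(n − 1)` (`stats::quantile` type 7). The tests are checked against
three independent routes: a pair-counting permutation oracle (exact branch),
`stats::wilcox.test` / `stats::kruskal.test` on tie-free data (approximate
branch), and Monte-Carlo type-I error at `α = 0.05`.

## What the synthetic country emulates

`simulate_country()` generates district tables with the statistical
structure the analysis assumes, plus the latent truth needed to test
recovery:

* **hierarchy** — subdistricts per district and neighbourhoods per
  subdistrict drawn uniformly from configured ranges (defaults 3–8 and
  4–12);
* **population** — lognormal across districts (`meanlog = 11.2`,
  `sdlog = 1.4` by default, giving a national population near 38 M across
  198 districts with the heavy right skew of real settlement patterns: the
  densest fifth of districts holds about 70% of the insured);
* **insurance** — binomial at coverage 0.438, a realistic national-scheme
  level;
* **income gradient** — the poor share of the insured is
  `0.40 + 0.45 (1 − density percentile)`, clamped to [0.05, 0.95]; poor and
  rich partition the insured exactly, so conservation is testable to the
  person;
* **facility allocation** — a national budget (default one HCC per 10,000
  insured) distributed by one of three policies. `density_proportional`
  gives each district a continuous share proportional to
  `insured^allocation_exponent` and snaps it to the nearest feasible
  administrative pattern — nothing, one district-level facility, one per
  subdistrict, or the rounded share when it exceeds full subdistrict
  coverage. The snapping reflects how coverage is actually deployed (as
  patterns, not fractional facilities), makes the intended category well
  defined, and produces all four categories from density alone.
  `equitable` staffs every subdistrict before distributing any surplus
  (erroring if the budget cannot), and `per_capita_target` allocates
  `round(insured / target)` per district, subdistrict-first;
* **visits** — Poisson per district and income stratum with mean
  `insured × visit_prob(category) × income multiplier`; defaults 1.4, 0.6,
  0.25, 0 visits/insured/year from neighbourhood to zero, with poor
  multipliers 1.2 (N) and 0.6 (MTN) encoding protection where access is
  fine and exclusion where it is coarse. Poisson (not Bernoulli) because
  observed rates exceed one visit per person per year;
* **cost** — `n_hcc × cost_fixed + visits × cost_per_visit`, scaled by a
  remoteness/scale factor `(median insured / insured)^elasticity`: unit
  costs fall with scale in dense districts and rise in sparse ones, which is
  what drives per-capita cost upward as the catchment coarsens;
* **reporting gaps** — a configured number of states (5 of 18 in the
  reference preset) have their income-stratified visits masked as missing,
  exercising the explicit-missingness path of the indicators.

Randomness is organised as one substream per district (seeded from the
scenario seed, the district counter and the stage), so adding districts or
reordering stages never perturbs earlier draws, and a scenario's
`scenario_hash()` — which excludes the seed — identifies the experimental
condition across replicate seeds.

`paper_regime()` is the reference preset: `allocation_exponent = 1.3` and
`remoteness_cost_elasticity = 1.3` on top of the defaults. Those two values
were calibrated once so that the generated regime shows the intended
structure — roughly a fifth to a quarter of districts at neighbourhood
level holding 70–90% of facilities, and aggregate per-capita cost strictly
increasing from neighbourhood to district catchments — and are documented
free parameters, as are the income multipliers, for which no published
magnitudes exist.

## What the generator does not emulate

Passing the pipeline on synthetic countries demonstrates internal
correctness — classification, aggregation, test behaviour, determinism —
under known truth. It does not validate the framework against real data,
and several features of real systems are deliberately absent: no geography
(no coordinates, travel times or 5-km buffers; accessibility is purely
administrative), no within-district heterogeneity, no overdispersion of
visit counts beyond Poisson (real utilization is noisier; the very tight
within-group spread of simulated N-district rates is a signature of this),
no copayment or quality effects (which in real settings can suppress
utilization even where access is fine), and no facility-level records (the
unit of analysis is the district throughout).

## Numerical and interface conventions

Undefined indicators are `NA`, never 0. Validation rejects, with
field-level messages, any record violating the structural invariants
(negative counts, income strata exceeding totals, facility vectors of the
wrong length); it is idempotent, and the CSV interchange format round-trips
byte-identically. All pipeline outputs are deterministic functions of the
input table and flags; `tests.json` and the CSVs carry no timestamps, so
identical runs are byte-identical — which is asserted in the test suite.

Problem sizes in the shipped tests were chosen to give stable checks at
interactive runtimes: the reference scenario uses 18 states × 11 districts
(198 districts, comparable to a real national district grid), Monte-Carlo
calibration uses 500 null replicates per test, and the exhaustive classifier
grid covers all facility patterns with up to 4 subdistricts and 3 HCCs each.

## Known limitations

The classification is structural: a district with surplus facilities
crowded into one subdistrict still counts as covered at neighbourhood level
only if every subdistrict has one. State-level rates are pooled ratios and
can be dominated by a single large district. The cost indicator divides by
accessible insured rather than by users, so it mixes price and utilization
effects. And the published-totals mechanism reproduces a source's
percentages but cannot recover how the source's uncategorised remainder
should be classified.
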