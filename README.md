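# catchequity

Health-equity monitoring from district-level administrative data.

National insurance schemes often know, for every district, how many people
they insure, how many of those are poor, where their health-care centres
(HCCs) sit in the administrative hierarchy, how often the insured visit, and
what the services cost — and nothing finer. `catchequity` turns exactly that
table into disaggregated equity indicators: it classifies each district by
the *catchment level* of its facilities, splits every indicator by that
classification, and tests whether utilization and cost differ between the
well-served and the left-behind.

## The method

A district's **catchment category** is the finest administrative level at
which its HCCs provide coverage, decided from the per-subdistrict facility
counts `h_1, …, h_s`:

| rule | category |
|---|---|
| `sum(h) = 0` | `zero` — no facility at all |
| some `h_j = 0`, `sum(h) ≥ 1` | `district` — one facility serves the whole district |
| all `h_j ≥ 1`, `sum(h) = s` | `subdistrict` — exactly one per subdistrict |
| all `h_j ≥ 1`, `sum(h) > s` | `neighborhood` — surplus centres serve neighbourhood groups |

Categories collapse to the binary contrast **N** (neighborhood) vs **MTN**
(more than neighborhood: subdistrict, district or zero). On top of the
classification the package computes, for each state and nationally:

* the **utilization rate** `U_g = Σ visits_g / Σ insured_g` for
  `g ∈ {N, MTN, all}` (the all-districts version is the *geographic* rate),
  and its four income-stratified versions (poor/rich × N/MTN), pooling only
  districts that report income-stratified visits;
* the **cost indicator** `C_k = (Σ cost_k / fx) / Σ insured_k` per catchment
  category `k`, in USD per insured person at a flat buying rate `fx`
  (default 7);
* the **distribution table**: counts and percentages of population, insured,
  poor, rich, districts and HCCs across categories;
* **density classes**: each district's share of its state's insured
  population, binned at 20/40/60/80%.

Group differences are tested with a Mann-Whitney test (district utilization
rates, N vs MTN) and a Kruskal-Wallis test (district per-capita cost across
categories), both on midranks with tie corrections, exact permutation
p-values for small samples, and median/IQR summaries attached.

Because the administrative tables this method was designed for are not
publicly deposited, the package ships a synthetic-country generator
(`simulate_country()`, `paper_regime()`) with known ground truth, so every
stage of the pipeline is testable end to end.

## Worked example

The packaged national fixture carries published category totals for an
18-state country (37.4 M people, 43.8% insured, 1,313 HCCs in 189
districts):

```r
library(catchequity)
distribution_table(table1_districts(), weight = "n_districts",
                   totals = table1_totals())
#> # A tibble: 24 × 5
#>   measure          catchment_level    count percent    total
#>   <fct>            <ord>              <dbl>   <dbl>    <dbl>
#> 1 population_total neighborhood    19240308   51.4  37418999
#> 2 population_total subdistrict     10391005   27.8  37418999
#> 3 population_total district         6884931   18.4  37418999
#> 4 population_total zero              902755    2.41 37418999
#> 5 insured_total    neighborhood    11367127   69.3  16396484
#> 6 insured_total    subdistrict      3320733   20.2  16396484
#> ...
```

69.33% of the insured live in neighborhood-catchment districts, which hold
78.07% of all HCCs — facility placement has followed insured density.

On a synthetic country in the same regime, the full pipeline recovers the
equity pattern from known truth:

```r
sim <- simulate_country(paper_regime(seed = 1))
res <- run_pipeline(sim$districts, out_dir = "report")

res$rates[res$rates$scope == "national", ]
#>   scope    n_districts n_rate mtn_rate geographic_rate poor_n_rate poor_mtn_rate
#> 1 national         198   1.52    0.287            1.22        1.68         0.207
#>   rich_n_rate rich_mtn_rate
#> 1        1.40         0.398

res$tests$utilization_n_vs_mtn
#> Mann-Whitney test (normal-approximation)
#>   U = 7685, p = 2.354e-27
#>   N: n = 53, median = 1.529, IQR = 0.01573
#>   MTN: n = 145, median = 0.1823, IQR = 0.1906

res$cost
#>   catchment_level n_districts insured_total cost_local cost_usd_per_capita
#> 1 neighborhood             53      12201307 280874071.                3.29
#> 2 subdistrict              24       1575149  94815951.                8.60
#> 3 district                 74       2063062 187676607.               13.0
#> 4 zero                     47        280737         0                 0
```

Reading the numbers: insured people with neighbourhood-level access make
1.52 visits/person/year against 0.29 in MTN districts; the poor out-utilize
the rich where access is fine (1.68 vs 1.40) and under-utilize them where it
is coarse (0.21 vs 0.40); and per-capita cost climbs as the catchment
coarsens. `run_pipeline()` writes the classified table, all indicator CSVs,
`tests.json` and a `report.md` organised around the four monitoring
questions (who / why / where / how). `plot_distribution()`,
`plot_utilization()` and `plot_cost()` draw the corresponding figures;
`tidy()`/`glance()` tidy the test objects.

A thin command-line wrapper is installed at `inst/cli/catchequity`
(`simulate` and `run` subcommands).

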