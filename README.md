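# godwitwinter

Why do male and female bar-tailed godwits (*Limosa lapponica*) winter in
different places? The sexes are strongly dimorphic — females ~20% heavier
with ~25% longer bills — and two mechanisms could sort them along the
northwest-European coast:

* **Energetics (Bergmann's rule):** colder northern sites are closer to
  the Arctic breeding grounds, and the larger sex loses less heat per unit
  mass, so relative wintering costs could favour females in the north.
* **Resource partitioning:** benthic prey are stratified by depth.
  Short-billed males peck prey from the top ~4 cm of sediment; long-billed
  females probe to 30 cm. Each sex should winter where *its* food is.

`godwitwinter` implements the full analysis chain for ecologists weighing
these hypotheses: a sex-specific bioenergetic wintering-cost model,
two-layer benthic biomass processing, sex-ratio inference from flock
scans, the statistical battery that confronts the hypotheses, and a
seeded synthetic-study generator so every stage is testable without field
data.

## The model in brief

Per site and sex, maintenance power is

    M_maint = BMR + H_sm                                   (W)
    BMR     = 5.06 * BM^0.729                              (BM in kg)
    H_sm    = max(0, K_es (T_b - T_a)(1 + K_u u^exp) - K_r R_g)

with body temperature T_b = 41 °C, thermal conductance K_es (0.0914 W/°C
males, 0.1111 females), air temperature T_a, wind u and global radiation
R_g. Round-trip migration cost is `C_flight = (2D / S) * C_sex` with
S = 75 km/h and C_sex = 67 (female) / 55 (male) kJ/h; D is the great-circle
distance to the breeding grounds (70°16′ N, 24°05′ E), or a per-site
override. The seasonal total integrates maintenance over a 182-day winter:
`M_maint * 182 * 86.4 + C_flight` (kJ).

Sex ratios are analysed on the empirical-logit scale per scan session,
`logit((y + 0.5) / (n + 1))`; benthic cores are split into top (0–4 cm)
and bottom (5–30 cm) ash-free dry mass, with the site bottom-layer share
computed as a mean of per-core ratios. The head-to-head test is a
four-correlation panel: % female against cost, bottom-layer biomass,
top-layer biomass, and bottom-layer share.

## Worked example

Costs for the packaged six-site study table (the coldest, closest site
shown):

```r
library(godwitwinter)
sites <- read_sites(gw_example("study_sites.csv"))
costs <- wintering_cost(sites)
costs[costs$site == "Sylt-Romo Wadden Sea", ]
#>                   site    sex bmr_w heat_loss_w maintenance_w migration_kj seasonal_total_kj
#> 1 Sylt-Romo Wadden Sea female 2.220       8.081         10.30         3466            165441
#> 2 Sylt-Romo Wadden Sea   male 1.948       6.632          8.58         2845            137763
```

The female's larger mass and conductance make her winter ~28,000 kJ more
expensive than the male's at the same site; migration (3466 vs 2845 kJ)
is only ~3% of the budget. A full synthetic run under the
resource-partitioning hypothesis:

```r
res <- run_pipeline(run_config(scenario = synthetic_scenario("resource_partitioning", seed = 1)))
res
#> <gw_report>
#> Sites: 6
#>
#> Site effect on sex ratio:
#> <gw_test> Gaussian likelihood-ratio test for a site effect on session logits (exact-F p)
#>   statistic = 155.65, df = 5, p = < 1e-16
#>
#> Cost ~ distance: R-squared = 0.317
#>
#> Hypothesis panel:
#>   cost       r =  0.060  p = 0.909
#>   bottom     r =  0.441  p = 0.000416
#>   top        r = -0.486  p = 8.42e-05
#>   bottom_pct r =  0.996  p = 2.69e-05
```

The panel shows the resource-partitioning signature: percent female is
positively correlated with deep biomass and bottom share, negatively with
surface biomass, and uncorrelated with wintering cost.

A thin CLI over the same functions lives at `inst/scripts/pipeline.R`
(subcommands `simulate`, `energetics`, `summarize-benthos`, `sexratio`,
`analyze`, `report`).

## Package layout

* `R/energetics.R` — cost model (BMR allometry, heat loss, haversine, migration)
* `R/benthos.R` — AFDM, layer densities, site summaries
* `R/field_observations.R` — empirical logits, sex ratios, bias tests, profile scores
* `R/inference.R` — site-effect LRT, ANOVA/Tukey, Pearson panel, linear fits
* `R/synthetic_data.R` — scenario definition and the four generator stages
* `R/pipeline.R`, `R/io.R` — end-to-end orchestration, CSV/JSON round trips
* `vignettes/wintering-methods.Rmd` — full model description, assumptions,
  generator calibration and limitations
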