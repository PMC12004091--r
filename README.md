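# ppafire

Persistent positive anomalies (PPAs) in 500 hPa geopotential height are
large, long-lived ridges — the blocking-like circulation patterns behind
many European heatwaves and droughts. Because they suppress precipitation,
raise temperatures and pre-dry fuels over thousands of kilometres for a
week or more, they are strong synoptic-scale predictors of extreme fire
weather and burned area. `ppafire` implements, as a tested and reusable R
pipeline, the full analysis chain that links PPA events to surface fire
weather and wildfire activity:

* **Detection and tracking.** Daily Z500 anomalies against a per-calendar-day
  climatology; a 5-day moving mean; a `sin(45°)/sin(φ)` latitude correction
  for atmospheric energy dispersion; a seasonally varying magnitude
  threshold (the domain-mean standard deviation of the latitude-corrected
  anomaly in a 28-day moving calendar window); cells exceeding 1 s.d. for
  ≥ 5 consecutive days become PPA cells; spatially contiguous cells are
  clustered (8-connectivity), tracked by day-to-day overlap, and labelled
  as PPA events once they reach 40 000 km², with per-day strength
  Σ anomaly × area (gpm km²).
* **Fire weather.** The Canadian Fire Weather Index System (FFMC, DMC, DC,
  ISI, BUI, FWI) with daily moisture carry-over from noon weather, vapour
  pressure deficit from a Magnus-type saturation formula, the hot–dry–windy
  index, and extreme-fire-weather days (FWIx) above each cell-month's 95th
  FWI percentile.
* **Association.** Each cell-day is classified into a 2×2 exposure × outcome
  table — exposure means a PPA overlapped the cell that day or within the
  preceding 7 days (0 days for FWIx) — and the odds ratio

  `OR = (a + k)(d + k) / ((b + k)(c + k))`, `k = 2`

  (a partial Haldane correction applied to all four cells) is computed per
  cell and month, summarized by region, and complemented by the percentage
  of burned area falling on exposed cell-days.
* **Diagnostics.** Lead–lag composites of surface anomalies and burned area
  in a ±15-day window around each event's maximum strength, and per-cell
  regression t-statistics (algebraically the pooled two-sample t) contrasting
  PPA and non-PPA days.
* **Synthetic ground truth.** A fully seeded generator producing
  spatiotemporally correlated Z500 backgrounds with injected events of known
  amplitude, size and duration, surface weather coupled to those events, and
  fire occurrences with a configurable true exposure odds ratio — so every
  stage is testable against known answers without reanalysis downloads.

The package is aimed at fire-climate researchers who want either the full
pipeline (gridded reanalysis + burned-area records in, association tables
out) or its parts (`cfwis()`, `odds_ratio()`, `leadlag_composite()`, …) as
tidyverse-friendly building blocks: data frames in, tibbles out, with
`tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Simulate a default synthetic world (16×16 one-degree grid over 40–55°N,
three March–October seasons, AR(1) background with injected blocking-like
events, coupled surface weather, fires with true odds ratio 3) and run the
whole pipeline:

```r
library(ppafire)

cfg <- pipeline_config(sim = synth_config(seed = 1))
res <- run_pipeline(cfg, quiet = TRUE)

glance(res$events)
#> # A tibble: 1 × 5
#>   n_events events_per_season mean_duration_days mean_max_area_km2
#>      <int>             <dbl>              <dbl>             <dbl>
#> 1       74              24.7                 13           203615.
```

74 events are tracked across three seasons with a mean lifespan of 13 days:
under a strongly autocorrelated background, most detected events are
genuine persistent anomalies of the background circulation itself, on top
of the six injected ones. Regional odds ratios for extreme fire weather:

```r
res$summary_fwix$by_region
#> # A tibble: 4 × 7
#>   region   mean_or median_or   q25   q75 share_gt1 n_cells
#>   <chr>      <dbl>     <dbl> <dbl> <dbl>     <dbl>   <int>
#> 1 Eastern     4.15      2.94  1.90  5.16     0.953     512
#> 2 Northern    5.78      3.47  2.47 11.8      0.982     512
#> 3 Southern    5.53      3.47  2.34  8.19     0.973     512
#> 4 Western     5.65      3.35  2.10 12.4      0.977     512
```

Extreme fire weather is several times more likely under a PPA in every
quadrant of the synthetic domain (97% of cell-months have OR > 1), because
the generator couples warm, dry, calm weather to event days. Burned-area
attribution:

```r
res$attribution$attribution
#> # A tibble: 5 × 4
#>   region   ppa_burned_area_ha total_burned_area_ha percent
#>   <chr>                 <dbl>                <dbl>   <dbl>
#> 1 Eastern              21149.               84037.    25.2
#> 2 Northern             16516.               83681.    19.7
#> 3 Southern             19139.               94127.    20.3
#> 4 Western              12439.               81964.    15.2
#> 5 all                  69243.              343809.    20.1
```

About a fifth of the burned area falls on exposed cell-days here: fires were
generated from the six injected events only, while the exposure mask also
contains the background's own persistent anomalies.

`autoplot(res$composite)` draws the lead–lag composites,
`plot_or_map(res$or_fire, month = 7)` maps July cell-level odds ratios, and
`plot_ppa_days(res$pct_ppa_days)` maps the monthly percentage of PPA days.

Real data enter the same pipeline through `read_field_csv()` /
`read_field_nc()` (CF-style NetCDF) for gridded fields, a `date, lat, lon,
area_ha` table for fire records, and `region_map()` for user-defined
regional masks. A thin command-line wrapper lives at
`inst/cli/ppafire.R` (`simulate` and `run-all` subcommands over a YAML
config).

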