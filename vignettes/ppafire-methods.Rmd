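---
title: "Detecting persistent positive anomalies and quantifying their wildfire associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting persistent positive anomalies and quantifying their wildfire associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ppafire` turns gridded 500 hPa geopotential height (Z500) and tabular
burned-area records into an event-based analysis of how persistent positive
anomalies (PPAs) — blocking-like, quasi-stationary ridges — relate to
surface fire weather and wildfire activity. This vignette documents the
model and its assumptions, the parameters that matter, the synthetic-data
generator that provides ground truth, and the numerical and design choices
made where the method left room.

## The detection model

A PPA event is an excursion of the Z500 field that is simultaneously
*large* (positive anomaly above a seasonally varying magnitude threshold),
*persistent* (at least 5 consecutive days per cell), and *extensive*
(a contiguous cluster reaching 40 000 km²). The stages:

1. **Climatology and anomalies.** The climatology is the raw per-calendar-day
   cross-year mean for each cell, computed only from days inside the season
   window (March–October by default; calendar days are keyed by
   month–day, so leap days never arise). No additional smoothing is applied
   to the climatology: the 5-day moving mean applied to anomalies already
   suppresses day-level noise, and a configurable smoothing window would
   couple the two choices opaquely. Anomalies require at least two years —
   with one year they would be identically zero.
2. **Temporal smoothing.** A centred 5-day moving mean per cell
   (`smooth_time()`, window must be odd). At season edges the window
   shrinks to the available days and never crosses a season boundary;
   synoptic persistence should not be manufactured from a different year's
   weather.
3. **Latitude correction.** Each anomaly is scaled by
   `sin(45°)/sin(φ)` (`latitude_correction()`). Geopotential anomalies of
   equal circulation strength grow with the Coriolis parameter, so without
   this weighting high-latitude ridges would dominate detection. The
   formula and the 45°N reference follow the standard convention of the
   persistent-anomaly literature; both are arguments.
4. **Seasonal threshold.** For each calendar day, the per-cell standard
   deviation of anomalies pooled over a 28-day moving calendar window
   across all years is averaged over the domain, giving one scalar per
   calendar day (`seasonal_threshold()`; a per-cell variant sits behind
   `per_cell = TRUE`). Summer pressure gradients are weaker than spring
   ones, and a fixed threshold would flood the detector in March and
   starve it in July.

   The threshold is computed from the **unsmoothed** latitude-corrected
   anomaly, and the smoothed series is flagged against it. This is a
   deliberate resolution of an ambiguity: latitude correction is a
   per-cell constant, so it commutes with the moving mean, but smoothed
   vs. unsmoothed input to the s.d. changes the meaning of "1 s.d."
   materially. A 5-day mean of white noise retains only ~45% of the
   marginal s.d. while acquiring lag-1 autocorrelation ≈ 0.8; a threshold
   equal to the *smoothed* series' own s.d. is therefore exceeded in
   5-day runs so often that even temporally white noise yields hundreds
   of spurious events per few dozen seasons. Measured against the raw
   anomaly s.d., the smoothed series needs a ≈ 2.2 s.d. excursion of its
   own scale to flag, and white-noise seasons stay essentially empty —
   which is what a persistence detector should do on persistence-free
   input.
5. **Flagging, clustering, tracking, labelling.** Cells at or above
   `multiplier × threshold` for ≥ `min_duration = 5` consecutive days
   (runs confined to a season) are PPA cells. Per day, flagged cells are
   clustered by 8-connectivity (diagonal contiguity is standard for
   synoptic features; 4-connectivity is a switch). Clusters on consecutive
   days are linked when they share at least one cell. The linking rule is
   deterministic: each cluster's *main parent* is the overlapping track
   with the largest previous-day area (ties to the older track); a track
   continues into its largest main child; other main children start new
   tracks with a parent link; a parent whose children were all claimed by
   larger parents terminates with a merge link. One-day interruptions end
   a track — persistence is already enforced at cell level, so gap
   bridging would double-count it. A track becomes an event when its
   daily area (spherical cell areas on a 6371-km sphere) reaches
   `min_event_area = 40 000 km²` on at least one day.

   Event duration counts the **full track lifespan**, including days
   before the size criterion is first met: the size test designates the
   tracked object, it does not truncate it. The alternative (duration
   from the first qualifying day) is available via
   `duration_from_qualifying = TRUE`. Daily strength is
   Σ anomaly × cell area (gpm km²) over member cells, using the same
   latitude-corrected smoothed anomaly that drove detection; event
   identifiers order by start date, then west-to-east centroid.

## Fire weather

`cfwis_step()` implements the published Canadian Fire Weather Index System
equations (fine fuel moisture code with rain and drying/wetting phases;
duff moisture code and drought code with rain phases and monthly
day-length factors at the standard 46°N reference tables; ISI, BUI and FWI
from the standard closed forms). Start-up codes FFMC 85 / DMC 6 / DC 15
are applied at each season start with no overwintering of the drought
code. The system consumes noon weather with wind in km/h; the hot–dry–windy
index consumes m/s — converters are explicit, never implicit. Saturation
vapour pressure uses the Magnus-type formula
`e_s(T) = 6.112·exp(17.67·T/(T+243.5))` hPa. Extreme fire weather (FWIx)
marks days strictly above the cell-month's 95th percentile of FWI pooled
across years, with percentiles by linear interpolation between order
statistics (`type = 7`); by construction ~5% of a large pool is flagged.

## Association statistics

`classify_days()` classifies each cell-day exactly once: *exposed* if a PPA
overlapped the cell on that day or any of the preceding `lag_days` days
(7 for fires, reflecting fuel pre-drying; 0 for FWIx), crossed with the
outcome indicator, accumulated per cell and calendar month across years.
The day-anchored reading is chosen over an event-anchored one because it
partitions days — `a + b + c + d` equals the number of analysed days, which
the tests verify on randomized fixtures — and is symmetric with the
zero-lag FWIx construction. A classified day's month is its own calendar
month.

The odds ratio adds the correction `k = 2` to **all four** cells of every
table: it keeps zero-cell tables finite and reduces small-sample bias, at
the price of shrinking large ORs toward 1; `k` is an argument (0.5 gives
the classical Haldane–Anscombe correction, 0 the raw OR). Cell-months with
no outcome days at all (`a + c = 0`) are flagged `insufficient_data` and
excluded from summaries. Regional summaries are unweighted means (plus
median, quartiles, share of OR > 1) over valid cell-months within region ×
month; the pooled regional figure averages that region's cell-months, and
the overall figure averages the regional means. Burned-area attribution
sums hectares on exposed cell-days over total hectares, per region and
pooled, with a histogram of burned area by days since the most recent PPA
day.

## Diagnostics

For each event the footprint is frozen at the member cells on the
max-strength day (ties to the earliest day), and each anomaly variable is
averaged over that footprint at lags −15…+15; composites average across
events per lag, dropping out-of-season lags and reporting contributing-event
counts. Freezing the footprint keeps the composite a property of the mature
event rather than of the evolving membership.

The per-cell-month PPA effect is the OLS slope of the anomaly on the
PPA/non-PPA indicator divided by its standard error, computed through the
algebraically identical pooled two-sample t-statistic; the identity is
asserted against `lm()` to 10⁻¹⁰ relative error. Cell-months with fewer
than two days in either group or zero residual variance yield no t. A
Shapiro–Wilk screen of group-mean residuals on sampled cell-months replaces
a visual Q–Q assessment; results are logged, never enforced.

## The synthetic generator

The generator provides ground truth for every stage. Its defaults are the
desk-scale study conditions used throughout the tests: a 16×16 one-degree
grid at 40–55°N, three March–October seasons, AR(1) day-to-day coefficient
ρ = 0.8, marginal s.d. σ_z = 80 gpm, spatial Gaussian smoothing with a
2-cell length scale (`smooth_len = 0` gives fully independent noise), two
injected events per season with amplitude 1.5–3× the realized threshold,
radius 2.5–3.5 cells, duration 8–12 days and 0.25 cells/day drift; event
days carry +4 °C, −15% RH, wind × 0.7 and precipitation-occurrence
suppression 0.5; fires have baseline daily probability p₀ = 0.01 and true
exposure odds ratio 3 with a 7-day lag; burned areas are log-normal with
median 100 ha. Everything derives deterministically from one seed.

Design choices that needed care:

* **Latitude variance profile.** The background's raw s.d. scales as
  `sin(φ)/sin(45°)`, so the latitude correction *equalizes* variance
  across the domain — as it is designed to do for the real atmosphere.
  A latitude-uniform background would make the correction itself create
  inhomogeneity against the spatially uniform threshold, concentrating
  false alarms at the southern edge: an artifact of the toy world, not of
  the method.
* **Amplitude calibration.** Injected bumps are specified as a multiple of
  the *realized* threshold of the pure background (computed by running the
  anomaly pipeline on it), so detectability is controlled regardless of
  background parameters. The raw amplitude is divided by the
  latitude-correction factor at the bump centre and inflated by
  `n_years/(n_years − 1)` because the cross-year climatology absorbs
  `1/n_years` of any injected signal. For the same reason, events are
  rejection-placed in (day-of-season × cell) space across **all** years:
  two events colliding in calendar days and location would corrupt each
  other's anomalies through the shared climatology.
* **Truth footprints.** An event-day's footprint is the set of cells whose
  expected processed amplitude exceeds the threshold; the catalog also
  records the half-prominence *core* (expected amplitude at least midway
  between threshold and peak). Recovery matching (`detection_recovery()`)
  counts an injected event as found when a single detected event covers at
  least half its core cell-days: cells whose expected signal merely grazes
  the threshold are flagged only about half the time by symmetric noise,
  so including them in the denominator would measure noise, not detector
  skill.
* **Progressive drying.** Precipitation suppression ramps up over
  `drying_ramp_days = 10` days into an event rather than switching on at
  full strength. Drought builds gradually under a persistent ridge (the
  slow-moisture-code analogue), and this is what places the composite
  precipitation minimum at or after maximum strength; with uniform
  suppression the expected composite would be flat across event days and
  the trough position would be decided by noise. The ramp spans a typical
  event lifetime so the build-up remains monotone through the
  max-strength day.

What the generator does *not* emulate: real Z500 spectra, orography,
land–sea contrasts, the seasonal geography of European fire regimes, fire
spread and size–weather coupling (sizes are independent log-normals), and
reanalysis biases. Passing tests therefore demonstrate the correctness and
calibration of the *machinery* — detection, classification, estimation —
not that any particular real-world association will take a particular
value.

## Validation design and problem sizes

The test suite checks, among ~1 700 assertions: clustering against a
brute-force flood fill and tracking against an independent data-frame
implementation of the documented linking rule on randomized scenarios; the
CFWIS against an independently coded scalar transliteration of the
published equations (agreement well within 0.1 code units on a 1 000-point
randomized weather grid, plus exhaustive monotonicity lattices — rain wets,
drought dries, spread grows with wind and fine-fuel dryness); worked
odds-ratio tables exactly; the regression/two-sample identity to 10⁻¹⁰;
and end-to-end ground-truth recovery.

Recovery runs use ten two-season worlds (40 injected events) with
temporally white (ρ = 0) backgrounds and amplitudes ≥ 2× threshold:
recall must reach 0.95 and the mean duration error stay within ±2 days.
The false-alarm floor uses twenty seasons of fully independent noise
(`rho = 0, smooth_len = 0`) and tolerates at most one spurious event; with
spatial correlation retained, temporally white noise still produces on the
order of one event per season purely through the size criterion — a
sensitivity worth knowing when interpreting event counts on real data.
Under the default ρ = 0.8 background, injected events frequently merge
with the background's own genuine persistent anomalies, so duration
fidelity is only assessed on quiet backgrounds. Odds-ratio recovery uses
pooled 2×2 tables over ≥ 125 000 classified cell-days per world, twenty
seeds per true OR ∈ {1, 2, 3}, with the truth exposure mask (the exposure
fires were generated under), and must land within ±10%. Composite
structure pools ~60 detected events across twelve quiet-background worlds.
These sizes were chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error far from the tolerances.

## Limitations

* The tracking rule (overlap linking, largest-area continuation) is one
  deterministic choice among several defensible ones; event counts and
  durations can shift under alternatives, and the original method's
  linking micro-decisions are under-specified.
* The scalar threshold is spatially uniform by design; regions whose
  variance the latitude correction does not fully equalize will flag
  unevenly (the per-cell threshold switch trades this against
  comparability across space).
* No negative-anomaly (cut-off low) detection, no hemispheric wraparound,
  no confidence intervals on ORs beyond the optional Woolf-type extension
  point, and no spatial-autocorrelation adjustment: cell-level ORs are
  summarized regionally precisely because neighbouring cells are not
  independent.
* NetCDF I/O requires `ncdf4`; the delimited-text path is the portable
  fallback.
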