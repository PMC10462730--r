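# reefstorm

Quantifying how the tropical-cyclone disturbance regime shapes the
resistance and recovery of Caribbean coral communities.

Reef monitoring programs measure living coral cover; cyclone best-track
archives record where storms went and how strong they were. `reefstorm`
joins the two: it catalogs reef-by-storm crossings under tiered
distance/intensity retention rules, summarises each reef's disturbance
regime, measures per-event resistance and post-storm recovery (overall and
by coral life-history group), builds unimpacted control series, and runs
the associated inference. A seeded synthetic-data generator with known
ground truth exercises the whole pipeline, so every stage is testable
without licensed survey databases.

## The quantities at the core

For a reef surveyed one year before and one year after a storm with covers
`pre` and `post` (percent of the benthos):

- **absolute resistance** = `post − pre` (percentage points),
- **relative resistance** = `(post − pre) / pre × 100`,
- **annual recovery rate** `CR = (pca − pcb) / d`, where `pcb` is cover one
  year post-storm, `pca` cover at the end of the series, and `d` the years
  between them,
- **relative recovery** at any year = cover that year minus cover one year
  pre-storm.

A storm is attributed to a reef when its minimum track-vertex distance `d`
(haversine, R = 6371 km) satisfies the tiered rule: any tropical-storm
strength within 35 km, Saffir–Simpson 3–5 within 35–65 km, only 4–5 within
65–100 km. Per reef, the regime over 1851–2017 is summarised by storm
count, mean return interval, the temporal dispersion statistic
`ψ(Y) = var(Y)/mean(Y) − 1` of annual counts (0 ≈ Poisson-like, > 0
clustered, < 0 regular), and the inverse-distance-weighted mean of storm
peak winds.

## Worked example

```r
library(reefstorm)

world  <- synth_bundle(synth_params(seed = 1, n_sites = 40,
                                    initial_cover = c(50, 80)))
totals <- annual_series(world$surveys)
events <- totals |>
  match_pre_post(world$catalog) |>
  add_resistance()

median(events$resistance_abs)
paired_wilcoxon(events$pre_cover, events$post_cover)
```

prints (seed 1):

```
## storms: 294   intersections: 101   events: 98
## median abs resistance: -8.98
# A tibble: 1 x 4
  statistic  p_value n_used degenerate
      <dbl>    <dbl>  <int> <lgl>
1         2 9.00e-18     98 FALSE
```

The generator injected an immediate impact of −8.5 percentage points per
storm (−5.5 competitive, −3.0 stress-tolerant, 0 weedy) on top of a 0.25
%/yr background decline with 2-point observation noise; the matched events
recover that impact (−8.98 here at one seed, median over 98 events), and
the paired Wilcoxon rejects "no pre/post change" overwhelmingly. Per-reef
regime metrics come from the same catalog:

```r
disturbance_regime(world$catalog, storm_peak_wind(world$tracks),
                   sites = world$sites, window = c(1970, 2017))
#> # A tibble: 40 x 6
#>   site_id  n_storms return_time_yr     psi dispersion_class weighted_mean_intensity_kt
#> 1 site_001        1             NA  0      stochastic       ...
#> 2 site_002        2             15 -0.0213 regular          ...
```

`run_all(config)` chains every stage (ingest → intersect → cover →
resilience → inference), writes tidy CSVs plus a JSON manifest with input
checksums and record counts, and is byte-for-byte deterministic for a fixed
seed. Fitted objects (`piecewise_fit`, `fit_resilience_lmm`) follow broom
conventions (`tidy()`, `glance()`, `autoplot()`).

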