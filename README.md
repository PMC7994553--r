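# resilmob

Community resilience metrics from large-scale mobility data.

`resilmob` measures how urban neighborhoods respond to and recover from a
disaster using smartphone geolocation pings, following the
mobility-analytics playbook developed around Hurricane Harvey (Houston,
August-September 2017): infer where people sleep, watch how many of them
stay put when the storm hits, cluster the neighborhood response curves, and
summarize each neighborhood's resilience in a single signed
area-under-the-curve statistic. It is written for spatial-epidemiology and
disaster-analytics researchers who have a ping panel (device id, unix
timestamp, lat/lon, accuracy) and administrative polygons, and for anyone
who wants to study the method itself: a seeded synthetic-city generator
reproduces the statistical structure of a commercial ping panel, so the
entire pipeline can be exercised, tested, and benchmarked without any
proprietary data.

## The method

1. **Preprocessing** — device ids are standardized, the all-zero generic id
   dropped, coordinates averaged over 5-minute bins, timestamps localized
   to a fixed UTC-5 offset, pings near major roads masked, and every ping
   assigned to a ~1 km x 1 km grid cell ("neighborhood").
2. **Daily residence** (nighttime argmax) — a device's residence cell on
   day *d* is the cell with the most qualifying pings,
   `H_{u,d} = argmax_cell #pings`, where on weekdays only night-window
   pings (20:00-07:00) qualify.
3. **Activity deviation** — for each cell, the daily resident count
   `U_{N,d}` is compared with its pre-event baseline `U_NA` (mean count
   before August 16): `D_{N,d} = (U_{N,d} - U_NA) / U_NA`. A 3-day centered
   moving average extracts the trend (61 days of deviations give a 59-day
   trend).
4. **Response clustering** — neighborhoods are grouped by Ward
   agglomerative clustering of their trend curves (merge cost
   `SS(Ci u Cj) - SS(Ci) - SS(Cj)`); the four groups are named by curve
   shape: *shelter-in-place* (bell up), *stable* (flat), *distressed*
   (U, partial return), *abandoned* (deep U, persistent deficit).
5. **Resilience capacity** — per cell or group: impact magnitude
   (peak |trend| in the impact window), time-to-recovery (days from the
   peak to a sustained return to the post-event equilibrium level), and the
   unified capacity `RC_N = ∫_{t0}^{t2} A_N(t) dt` (trapezoidal, in
   day-fraction units; negative for activity loss, positive for
   shelter-in-place gains).
6. **Evacuation OD analysis** — for the most active, persistently observed
   devices, spatiotemporal DBSCAN (eps 0.25 in rescaled units = 250 m /
   6 h) finds per-device activity areas; k-means on their hourly profiles
   types them residential/work/other; the pre-event home is the busiest
   residential-or-work area, and daily locations during the evacuation
   window build origin-destination records with statuses
   stay / evacuate / inactive and destination tiers home / within-county /
   within-state / out-of-state.
7. **Damage validation** — zone-level damaged-property counts are
   apportioned to cells by household share and correlated with resilience
   capacity.

## Worked example

Simulate a small city (16 archetype neighborhoods, 100 devices each) and
run the full resilience pipeline:

```r
library(resilmob)

cfg <- synth_config(grid_rows = 4, grid_cols = 5,
                    cells_per_archetype = c(shelter_in_place = 4, stable = 4,
                                            distressed = 4, abandoned = 4),
                    devices_per_cell = 100, seed = 1)
city <- generate_city(cfg)

aa <- analyze_activity(city$pings, city$grid,
                       baseline_window = c(cfg$study_start, cfg$baseline_end),
                       study_window = c(cfg$study_start, cfg$study_end))
aa$series
#> <activity_series> 16 cells x 59 trend days (2017-08-02 .. 2017-09-29)

pipe <- run_resilience_pipeline(aa$series,
                                impact_window = as.Date(c("2017-08-25",
                                                          "2017-09-04")),
                                k = 4)
pipe$groups[, .(archetype, n_cells, impact = round(impact, 3),
                time_to_recovery, recovered, rc = round(rc, 2))]
#>           archetype n_cells impact time_to_recovery recovered    rc
#> 1: shelter_in_place       4  0.369               11      TRUE  2.20
#> 2:       distressed       4  0.325               11      TRUE -2.24
#> 3:        abandoned       4  0.459               16      TRUE -5.82
#> 4:           stable       4  0.106                3      TRUE -0.22
```

The four generated response archetypes are recovered from raw pings alone:
the shelter-in-place group shows a positive bell (impact 0.37 configured,
0.369 recovered) with positive capacity, the abandoned group the deepest
dip and the most negative capacity, the stable group stays near zero.
`evacuation_summary(...)` produces the Table-3-style crosstab of
stay/evacuate/inactive counts and destination tiers by origin group, and
`apportion_damage()` + `damage_capacity_association()` reproduce the
negative damage-capacity relationship.

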