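---
title: "Measuring community resilience from mobility pings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community resilience from mobility pings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `resilmob`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the method left room.

## 1. The measurement model

The pipeline treats a smartphone ping panel as a noisy census of where
people sleep. Its chain of inference is:

**Residence.** On each day, a device "resides" in the 1-km grid cell
holding the plurality of its night-window pings (20:00-07:00 local; on
weekends all hours count, since daytime presence at home is informative
there). This argmax rule assumes one residence per device per day and that
nighttime location is a reliable residence proxy; both fail for night-shift
workers and multi-home users, which is accepted as panel noise.

**Deviation.** Per cell, the daily resident count `U` is converted into a
dimensionless deviation from the cell's own pre-event baseline `U_NA`
(mean daily count over the pre-event equilibrium window, by default
2017-08-01 through 2017-08-16): `D = (U - U_NA) / U_NA`. `D` is bounded
below by -1 (the cell empties), equals 0 at normal activity, and is
scale-invariant: doubling panel coverage leaves it unchanged, which is what
makes cross-neighborhood comparison meaningful at ~35% device coverage.

**Trend.** A 3-day centered moving average suppresses day-of-week and
sampling noise. A centered (not trailing) window was chosen because the
trend is interpreted symmetrically around event dates; it costs one day at
each end of the series, so a 61-day study window yields a 59-day trend.

**Grouping.** Neighborhood trend curves are clustered bottom-up with the
Ward criterion. The merge cost implemented is the non-negative increase in
within-cluster sum of squares, `SS(Ci u Cj) - SS(Ci) - SS(Cj)`; the
agglomeration is deterministic, with ties broken on the smallest pair of
cluster indices. `k = 4` is the default (the empirically observed number of
response shapes); `k = "auto"` picks the largest relative gap between
successive merge heights, the numeric analogue of reading the dendrogram.
Groups are then *named* by the shape of their mean curve — magnitude first
(a peak |deviation| under 0.2 is "stable", because the sign of a flat
curve's peak is sampling noise), then sign (positive peak:
"shelter_in_place"), then terminal level (mean of the last 7 days at or
below -0.125: "abandoned", else "distressed").

**Resilience capacity.** Per curve: impact = max |trend| in the impact
window (default: event onset through onset + 10 days); `t0` = its date
(earliest on ties); the post-event equilibrium level = mean trend over the
final 14 days; `t2` = first date at or after `t0` where the trend stays
within `tol = 0.05` of that level for 3 consecutive days; and
`RC = ∫_{t0}^{t2} trend dt` by the trapezoid rule at daily steps, in
day-fraction units. The integrand is referenced to the *pre-event* baseline
(equilibrium level 0), not the post-event level: groups that plateau below
baseline must accumulate large negative capacity, and the bell-shaped group
positive capacity, for the statistic to rank groups the way the published
tabulations do. Curves that never sustain the band are censored
("not recovered within study"): the integral then runs to the series end
and is flagged. Group metrics are computed on the group's mean curve, and
the mean of per-cell metrics is reported alongside, since either reading of
"mean impact per cluster" is defensible.

**Evacuation.** The origin-destination analysis screens for devices
observed throughout the study (at least one ping every ISO week) and active
in the direct impact window, keeping the top quartile by ping volume.
Per device, DBSCAN in rescaled space-time (kilometres within the device's
own activity bounding box; time-of-day as 5-minute bins mapped to [0, 1];
`eps = 0.25`, making 250 m and 6 h equivalent radii) finds activity areas;
`min_pts = max(4, ceiling(0.3 x active_days))` scales the density threshold
with how long the device was observed while the floor of 4 prevents
trivial clusters. Hourly activity profiles, EWMA-smoothed over a 3-bin
span, are k-means clustered (k = 4, fixed seed, best of 20 restarts) and
typed by rule: at least half the mass in 20:00-07:00 is residential, at
least half in 09:00-18:00 is work, else other. The pre-event home is the
busiest pre-event cluster among residential/work types (residential
preferred on ties); daily locations prioritize residential clusters.
Over the evacuation window (Aug 23 - Sep 2) a device *stays* if every daily
location falls in its home cell, *evacuates* if any leaves it (destination
= modal non-home location by days present), and is *inactive* if it emits
nothing after event onset. Destinations are tiered by point-in-polygon
against the county, then the state; displacement distance is the haversine
home-destination distance in miles.

**Validation.** Damage tallies published per coarse zone are apportioned to
cells by household share (`est = zone_rate x cell_households`, conserving
zone totals) and correlated (Pearson, with an OLS fit) against per-cell
capacity.

## 2. Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| cell size | 1000 | m | neighborhood scale of the published method |
| night window | 20:00-07:00 | h | residence proxy hours |
| 5-min bin | 300 | s | reporting-frequency standardization |
| UTC offset | -5 | h | fixed local clock (no DST) for reproducibility |
| road buffer | 50 | m | width unstated in the source method; config knob |
| baseline window | Aug 1-16 | days | pre-event equilibrium |
| `min_devices` | 10 | devices | baseline floor guarding the deviation ratio |
| trend window | 3 | days | stated decomposition |
| impact window | onset + 10 | days | covers the disruption peak |
| `eq_window` | 14 | days | post-event equilibrium estimate |
| recovery `tol` | 0.05 | fraction | band half-width; unstated upstream |
| recovery `persist` | 3 | days | one-day touches are not recovery |
| DBSCAN `eps` | 0.25 | rescaled | = 250 m / 6 h |
| `min_pts` rule | max(4, 0.3 x days) | points | density threshold scaling |
| EWMA span | 3 | hourly bins | profile denoising; unstated upstream |
| k-means | k = 4, 20 restarts | — | four common profile types |

## 3. What the synthetic city emulates — and what it does not

`generate_city()` produces the statistical structure the analysis assumes:
per-device diurnal ping streams over the two-month window, four response
archetypes at their published parameter values (impact depths
0.37 / 0.10 / 0.34 / 0.48; the abandoned group plateaus 20% below
baseline; status shares and destination mixes at the published
tallies), a multi-day disruption, evacuation flows with three destination
tiers, and inactive devices that go silent at onset.

The central design decision is that **activity curves are realized through
night-window device presence**, because the deviation statistic counts
resident devices, not ping volume. Each cell-day has a target count
`T = q0 x n x (1 + curve)`, where `q0 = 0.8` is the baseline probability
that a device spends the night at home and emits at least one night ping —
a value chosen a priori as a realistic nightly at-home emission rate.
Available stayers are present independently with probability
`min(1, T / available)`; when a positive curve exceeds stayer capacity
(the shelter-in-place peak, with evacuees and inactive devices absent),
the deficit is filled by Poisson-distributed one-day "visitor" devices,
the synthetic analogue of shelter influx. Within-county evacuees are
routed to dedicated unpopulated "commons" cells (shelter districts), so
destination inflow cannot distort the archetype cells' curves; commons
cells have zero pre-event baseline and are dropped by the `min_devices`
guard, exactly as sparsely-resident cells are in real data.

Displacement windows follow the published behavior: abandoned-group
evacuees stay away through the study end (they "do not fully return");
all others return at `peak + recovery_days`.

Not emulated: road networks (the road mask is exercised on constructed
fixtures instead), device churn and ad-id resets, app multiplexing,
population non-response (the ~35% coverage of the real panel is a free
parameter with no modeled mechanism), multi-stop evacuation trips, and
spatially correlated noise. Passing round-trip tests therefore demonstrates
that the pipeline recovers the signal structure it assumes — not that those
assumptions hold in any particular commercial panel.

## 4. Numerical choices and degenerate inputs

* Grid cells are half-open (`[x0 + k s, x0 + (k+1) s)`); a point exactly on
  a shared edge belongs to the higher-index cell. Residence ties break to
  the lowest `(col, row)`; the argmax is otherwise silent on ties.
* Projection is a local equirectangular frame (metre-true to ~0.1% at city
  scale), used consistently by the generator and the grid.
* The all-zero advertisement id is dropped; standardization is idempotent,
  and 5-minute bins are anchored at the unix epoch so binning is
  deterministic.
* DBSCAN neighborhoods include the point itself; border points join the
  cluster of their *nearest* core neighbor, making labels independent of
  input order (classic DBSCAN's first-come border assignment is not).
  Clusters are numbered by smallest member index. All-noise output is
  valid.
* An empty ping stream, a silent device-day, or a device with no pre-event
  residential/work cluster are all valid outcomes (empty table, gap,
  unassigned — each counted, never errors); ill-posed configurations
  (peak before onset, recovery past the study end, k > n) are rejected
  with explicit messages.
* Recovery of a curve still drifting at the series end is censored rather
  than extrapolated; a device with in-window silence but later pings is
  "unclassified" and reported separately, conserving group counts.
* Trapezoidal capacity is exact for the piecewise-linear curves used
  throughout (verified against closed forms at 1e-9).

## 5. Problem sizes

The full synthetic round trip used by the acceptance checks runs the study
conditions: 4 archetypes x 30 cells x 200 devices = 24,000 devices over
61 days (~7 million pings). The per-device DBSCAN/OD chain runs on a
stratified subsample of 2,000 devices (500 per archetype); at that size
every recovery tolerance is expressed in binomial standard errors of the
subsample, and a larger panel adds cost but no statistical information.
Unit tests use miniature cities (tens of devices per cell) whose noise
bounds scale accordingly.

## 6. Known limitations

* A device is equated with a person, and one residence per day is assumed.
* The fixed UTC-5 clock ignores DST (the study window does not cross a
  transition).
* The damage association is correlational; application-based damage
  tallies carry self-selection bias, so the sign — not the magnitude — is
  the validated quantity.
* Group naming is a post-hoc rule on curve shape; with fewer than four
  distinct shapes in the data, two groups may legitimately share a name.
* The "percentile distance" deviation is a fraction, not a percentile; it
  is implemented as the printed formula.
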