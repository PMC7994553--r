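#' Standardize, grid-assign and summarize a raw ping stream
#'
#' Front half of the pipeline: [standardize_pings()], optional
#' [mask_roads()], [assign_grid()], [residence_table()] and
#' [build_activity_series()].
#'
#' @param pings raw ping data.table (`device_id`, `t`, `lat`, `lon`,
#'   `accuracy`).
#' @param grid a [grid_spec()].
#' @param baseline_window `c(start, end)` Date pair of the pre-event
#'   equilibrium.
#' @param study_window optional `c(start, end)` Date pair completing the
#'   activity series (defaults to the observed range).
#' @param tz_offset fixed UTC offset in hours (default -5).
#' @param roads optional road layer for [mask_roads()].
#' @param road_buffer_m road mask buffer (default 50).
#' @param min_devices baseline inclusion threshold (default 10).
#' @param window trend moving-average width (default 3).
#' @return list: `series` (an `activity_series`), `residences`,
#'   `standardized` (the grid-tagged standardized pings).
#' @export
analyze_activity <- function(pings, grid, baseline_window,
                             study_window = NULL, tz_offset = -5,
                             roads = NULL, road_buffer_m = 50,
                             min_devices = 10, window = 3) {
  bbox <- c(grid$lon_min, grid$lon_max, grid$lat_min, grid$lat_max)
  std <- standardize_pings(pings, bbox = bbox, tz_offset = tz_offset)
  if (!is.null(roads)) std <- mask_roads(std, roads, road_buffer_m)
  tagged <- assign_grid(std, grid)
  res <- residence_table(tagged)
  dates <- if (is.null(study_window)) NULL else
    seq(study_window[1], study_window[2], by = "day")
  series <- build_activity_series(res, baseline_window, dates = dates,
                                  min_devices = min_devices,
                                  window = window)
  list(series = series, residences = res, standardized = tagged)
}

#' Per-cell resilience profiles
#'
#' @param series an `activity_series` from [build_activity_series()].
#' @inheritParams resilience_profile
#' @return data.table `col`, `row`, `impact`, `t0`, `t2`,
#'   `time_to_recovery`, `recovered`, `rc`.
#' @export
cell_profiles <- function(series, impact_window, eq_window = 14, tol = 0.05,
                          persist = 3) {
  mat <- series$trend_matrix
  dates <- series$trend_dates
  out <- lapply(seq_len(nrow(mat)), function(i) {
    p <- resilience_profile(mat[i, ], dates, impact_window, eq_window, tol,
                            persist)
    data.table(col = series$cells$col[i], row = series$cells$row[i],
               impact = p$impact, t0 = p$t0, t2 = p$t2,
               time_to_recovery = p$time_to_recovery,
               recovered = p$recovered, rc = p$rc)
  })
  rbindlist(out)
}

#' Cluster neighborhoods and profile the groups
#'
#' Back half of the pipeline: Ward agglomeration of the trend curves,
#' post-hoc archetype naming of the groups by mean-curve shape, group and
#' per-cell resilience profiles.
#'
#' @inheritParams cell_profiles
#' @param k number of groups or `"auto"` (default 4).
#' @return list: `clustering` (a `ward_clustering`), `group_names`
#'   (archetype name per group label), `groups` ([group_profiles()] table
#'   with an `archetype` column), `cells` ([cell_profiles()] table with
#'   `label` and `archetype`).
#' @export
run_resilience_pipeline <- function(series, impact_window, k = 4,
                                    eq_window = 14, tol = 0.05,
                                    persist = 3) {
  mat <- series$trend_matrix
  dates <- series$trend_dates
  model <- ward_agglomerate(mat, k)
  impact_idx <- which(dates >= impact_window[1] & dates <= impact_window[2])
  group_names <- label_archetypes(mat, model$labels, impact_idx)
  groups <- group_profiles(mat, model$labels, dates, impact_window,
                           eq_window, tol, persist)
  groups[, archetype := group_names[group]]
  cells <- cell_profiles(series, impact_window, eq_window, tol, persist)
  cells[, label := model$labels]
  cells[, archetype := group_names[label]]
  list(clustering = model, group_names = group_names, groups = groups[],
       cells = cells[])
}
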