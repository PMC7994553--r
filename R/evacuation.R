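#' Select the most active, persistently observed devices
#'
#' Screens the panel for devices observed throughout the study period
#' (at least one ping in every ISO week it spans) and active during the
#' direct impact window, then keeps the top quartile by total ping count.
#' Ties at the cutoff are broken by device id order, so an all-tied panel
#' yields exactly `ceiling(n / 4)` devices.
#'
#' @param pings standardized pings.
#' @param impact_window `c(start, end)` Date pair of the direct impact
#'   period.
#' @param top_frac fraction of qualifying devices retained (default 0.25).
#' @param period optional `c(start, end)` study period (default: observed
#'   date range) defining the weekly-coverage screen.
#' @return character vector of selected device ids; attribute `"ranking"`
#'   holds the full qualifying table.
#' @export
select_active_users <- function(pings, impact_window, top_frac = 0.25,
                                period = NULL) {
  dt <- as.data.table(pings)
  if (is.null(period)) period <- range(dt$local_date)
  all_weeks <- unique(format(seq(period[1], period[2], by = "day"), "%G-%V"))
  cov <- dt[local_date >= period[1] & local_date <= period[2],
            .(n_weeks = uniqueN(format(local_date, "%G-%V"))),
            by = device_id]
  covered <- cov[n_weeks == length(all_weeks), device_id]
  active <- dt[local_date >= impact_window[1] &
                 local_date <= impact_window[2], unique(device_id)]
  totals <- dt[, .(n_total = .N), by = device_id]
  qual <- totals[device_id %in% covered & device_id %in% active]
  if (nrow(qual) < 4L) stop("fewer than 4 qualifying devices")
  setorder(qual, -n_total, device_id)
  k <- ceiling(nrow(qual) * top_frac)
  out <- qual$device_id[seq_len(k)]
  setattr(out, "ranking", qual)
  out
}

#' Rescale one device's pings into space-time features
#'
#' Coordinates become kilometres within the device's own activity bounding
#' box (equirectangular, longitude scaled at the box mid-latitude);
#' time-of-day is the 5-minute bin index mapped from 0-288 to 0-1. With
#' `eps = 0.25` this makes 250 m and 6 h equivalent radii. A degenerate
#' (single-point) box yields all-zero spatial features.
#'
#' @param pings standardized pings of a single device (`lon`, `lat`,
#'   `day_bin`).
#' @return numeric matrix with columns `x_km`, `y_km`, `t_norm`.
#' @export
rescale_features <- function(pings) {
  dt <- as.data.table(pings)
  if (nrow(dt) == 0L) stop("no pings for device")
  lat_mid <- (min(dt$lat) + max(dt$lat)) / 2
  cbind(x_km = (dt$lon - min(dt$lon)) * 111.320 * cos(lat_mid * pi / 180),
        y_km = (dt$lat - min(dt$lat)) * 110.540,
        t_norm = dt$day_bin / 288)
}

#' Density-based spatiotemporal clustering (DBSCAN)
#'
#' Standard DBSCAN on a feature matrix: a core point has at least `min_pts`
#' neighbors (itself included) within `eps`; clusters are the connected
#' components of the core-point adjacency graph; a non-core point joins the
#' cluster of its nearest core neighbor within `eps` (deterministic border
#' rule, invariant to input order), and everything else is noise (label 0).
#' Clusters are numbered by their smallest member index.
#'
#' @param x numeric feature matrix.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighborhood size for a core point.
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscan_st <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(if (min_pts <= 1L) 1L else 0L)
  dmat <- as.matrix(dist(x))
  nb <- dmat <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    ci <- which(core)
    adj <- nb[ci, ci, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[ci] <- comp
    ## border points: nearest core within eps
    for (i in which(!core)) {
      dcore <- dmat[i, ci]
      ok <- dcore <= eps
      if (any(ok)) {
        labels[i] <- comp[which(ok)[which.min(dcore[ok])]]
      }
    }
    ## renumber by smallest member index
    first <- tapply(seq_len(n)[labels > 0], labels[labels > 0], min)
    remap <- integer(max(labels))
    remap[as.integer(names(first))] <- rank(first)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  labels
}

#' Activity areas for one device
#'
#' Runs [dbscan_st()] on the device's rescaled pings with
#' `eps` in rescaled units and `min_pts = max(floor_pts,
#' ceiling(coef * active_days))`, where `active_days` is the number of
#' distinct days the device pinged. Each resulting activity cluster is
#' summarized by centroid, size, active dates and a normalized 24-bin
#' hourly profile.
#'
#' @param pings standardized pings of one device.
#' @param eps neighborhood radius in rescaled units (default 0.25,
#'   i.e. 250 m / 6 h).
#' @param min_pts override for the minimum cluster mass (default: the
#'   active-day rule).
#' @param floor_pts,coef parameters of the active-day rule.
#' @return list: `assign` (per-ping labels), `clusters` (data.table
#'   `cluster`, `size`, `lon`, `lat`, `n_dates`), `profiles` (clusters x 24
#'   matrix), `date_counts` (data.table `cluster`, `date`, `n`).
#' @export
cluster_activity <- function(pings, eps = 0.25, min_pts = NULL,
                             floor_pts = 4, coef = 0.3) {
  dt <- as.data.table(pings)
  active_days <- uniqueN(dt$local_date)
  if (is.null(min_pts)) min_pts <- max(floor_pts, ceiling(coef * active_days))
  labels <- dbscan_st(rescale_features(dt), eps, min_pts)
  dt <- copy(dt)[, cluster := labels]
  cl <- dt[cluster > 0,
           .(size = .N, lon = mean(lon), lat = mean(lat),
             n_dates = uniqueN(local_date)),
           by = cluster]
  setorder(cl, cluster)
  profiles <- NULL
  if (nrow(cl) > 0L) {
    hp <- dt[cluster > 0, .N, by = .(cluster, hour = floor(local_hour))]
    profiles <- matrix(0, nrow(cl), 24)
    profiles[cbind(match(hp$cluster, cl$cluster), hp$hour + 1L)] <- hp$N
    profiles <- profiles / rowSums(profiles)
  }
  date_counts <- dt[cluster > 0, .(n = .N), by = .(cluster, date = local_date)]
  list(assign = labels, clusters = cl, profiles = profiles,
       date_counts = date_counts)
}

#' Activity areas for a set of devices
#'
#' Applies [cluster_activity()] per device and stacks the results.
#'
#' @param pings standardized pings.
#' @param devices optional device-id subset.
#' @inheritParams cluster_activity
#' @return list: `clusters` (data.table with `device_id`, `cluster`,
#'   `size`, `lon`, `lat`, `n_dates`), `profiles` (matrix aligned with
#'   `clusters` rows), `date_counts` (`device_id`, `cluster`, `date`, `n`),
#'   `last_active` (`device_id`, `last_date`).
#' @export
device_activity_clusters <- function(pings, devices = NULL, eps = 0.25,
                                     min_pts = NULL, floor_pts = 4,
                                     coef = 0.3) {
  dt <- as.data.table(pings)
  if (!is.null(devices)) dt <- dt[device_id %in% devices]
  last_active <- dt[, .(last_date = max(local_date)), by = device_id]
  parts <- lapply(split(dt, by = "device_id", sorted = TRUE), function(d) {
    ca <- cluster_activity(d, eps, min_pts, floor_pts, coef)
    if (nrow(ca$clusters) == 0L) return(NULL)
    list(clusters = data.table(device_id = d$device_id[1], ca$clusters),
         profiles = ca$profiles,
         date_counts = data.table(device_id = d$device_id[1],
                                  ca$date_counts))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  list(clusters = rbindlist(lapply(parts, `[[`, "clusters")),
       profiles = do.call(rbind, lapply(parts, `[[`, "profiles")),
       date_counts = rbindlist(lapply(parts, `[[`, "date_counts")),
       last_active = last_active)
}

.NIGHT_HOURS <- c(20:23, 0:6)
.WORK_HOURS <- 9:17

#' Type activity areas by hourly profile
#'
#' Smooths each cluster's 24-bin hourly profile with an exponentially
#' weighted moving average, renormalizes, and k-means-clusters the profiles
#' (fixed seed, best of `nstart` restarts by within-cluster SS). Each
#' k-means centroid is labeled by rule: residential when at least half its
#' mass lies in the 20:00-07:00 night window, work when at least half lies
#' in 09:00-18:00, otherwise other; members inherit their centroid's label.
#'
#' @param profiles clusters x 24 matrix of normalized hourly profiles.
#' @param k number of profile archetypes (default 4).
#' @param span EWMA smoothing span in hourly bins (default 3).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 20).
#' @return list: `types` (character per profile row), `assignment` (k-means
#'   group per row), `centroids`, `centroid_types`, `model`.
#' @export
profile_and_type <- function(profiles, k = 4, span = 3, seed = 20170825,
                             nstart = 20) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of activity clusters")
  sm <- t(apply(profiles, 1, .ewma, span = span))
  sm <- sm / rowSums(sm)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  km <- kmeans(sm, centers = k, nstart = nstart, iter.max = 100)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ctypes <- apply(km$centers, 1, .profile_type)
  list(types = unname(ctypes[km$cluster]), assignment = km$cluster,
       centroids = km$centers, centroid_types = ctypes, model = km)
}

.ewma <- function(x, span) {
  alpha <- 2 / (span + 1)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in seq_along(x)[-1]) y[i] <- alpha * x[i] + (1 - alpha) * y[i - 1]
  y
}

.profile_type <- function(p) {
  p <- p / sum(p)
  if (sum(p[.NIGHT_HOURS + 1L]) >= 0.5) "residential"
  else if (sum(p[.WORK_HOURS + 1L]) >= 0.5) "work"
  else "other"
}

#' Pre-event home activity area per device
#'
#' Among a device's residential- or work-typed clusters, picks the one with
#' the most pings in the pre-event window, preferring residential on count
#' ties. Devices with no qualifying cluster are left unassigned (and are
#' excluded downstream, counted).
#'
#' @param ac output of [device_activity_clusters()].
#' @param types character vector aligned with `ac$clusters` rows (from
#'   [profile_and_type()]).
#' @param pre_event_window `c(start, end)` Date pair.
#' @return data.table `device_id`, `cluster`, `lon`, `lat`, `type`,
#'   `n_win`; attribute `"n_unassigned"` counts devices with clusters but
#'   no home.
#' @export
assign_home <- function(ac, types, pre_event_window) {
  cl <- copy(ac$clusters)[, type := types]
  win <- ac$date_counts[date >= pre_event_window[1] &
                          date <= pre_event_window[2],
                        .(n_win = sum(n)), by = .(device_id, cluster)]
  cand <- win[cl, on = c("device_id", "cluster"), nomatch = NULL]
  cand <- cand[!is.na(n_win) & n_win > 0 & type %in% c("residential", "work")]
  setorder(cand, device_id, -n_win, type, -size, cluster)  # residential < work
  homes <- unique(cand, by = "device_id")
  homes <- homes[, .(device_id, cluster, lon, lat, type, n_win)]
  setattr(homes, "n_unassigned",
          uniqueN(ac$clusters$device_id) - nrow(homes))
  homes
}

#' Daily activity location per device
#'
#' For each device and day, the location is the most active
#' residential-typed cluster activated that day if any, otherwise the most
#' active cluster of any type; days with no activity yield no record.
#'
#' @inheritParams assign_home
#' @param window optional `c(start, end)` Date pair restricting the days.
#' @return data.table `device_id`, `date`, `cluster`, `lon`, `lat`,
#'   `type`, `n`.
#' @export
daily_locations <- function(ac, types, window = NULL) {
  cl <- copy(ac$clusters)[, type := types]
  dc <- ac$date_counts
  if (!is.null(window)) dc <- dc[date >= window[1] & date <= window[2]]
  d <- cl[, .(device_id, cluster, lon, lat, type)][dc,
         on = c("device_id", "cluster")]
  d[, is_res := type == "residential"]
  setorder(d, device_id, date, -is_res, -n, cluster)
  out <- unique(d, by = c("device_id", "date"))
  out[, is_res := NULL]
  out[]
}

#' Origin-destination evacuation records
#'
#' Classifies each home-assigned device over the evacuation window:
#' `stay` when every in-window daily location falls in the home grid cell,
#' `evacuate` when some daily location leaves it (destination = the modal
#' non-home location, by days present), `inactive` when the device emits no
#' pings after event onset, and `unclassified` when it has no in-window
#' data but pings later. Destinations are tiered by point-in-polygon
#' against the county then the state; the displacement distance is the
#' haversine home-to-destination distance in miles.
#'
#' @param homes output of [assign_home()].
#' @param dailies output of [daily_locations()] (already restricted to the
#'   evacuation window, or restricted here via `od_window`).
#' @param last_active data.table `device_id`, `last_date` (from
#'   [device_activity_clusters()]).
#' @param od_window `c(start, end)` Date pair of the evacuation window.
#' @param event_onset Date; devices silent from this date on are inactive.
#' @param grid a [grid_spec()] for cell tagging.
#' @param county,state polygon feature lists from [read_geojson()] (`NULL`
#'   leaves tiers `NA`).
#' @return data.table, one row per home-assigned device: `device_id`,
#'   `status`, `home_col`, `home_row`, `home_lon`, `home_lat`, `dest_lon`,
#'   `dest_lat`, `dest_col`, `dest_row`, `tier`, `distance_miles`.
#' @export
build_od <- function(homes, dailies, last_active, od_window, event_onset,
                     grid, county = NULL, state = NULL) {
  h <- copy(as.data.table(homes))
  hxy <- grid_project(grid, h$lon, h$lat)
  h[, home_col := as.integer(floor(hxy$x / grid$cell_size))]
  h[, home_row := as.integer(floor(hxy$y / grid$cell_size))]
  setnames(h, c("lon", "lat"), c("home_lon", "home_lat"))

  d <- as.data.table(dailies)[date >= od_window[1] & date <= od_window[2]]
  dxy <- grid_project(grid, d$lon, d$lat)
  d[, col := as.integer(floor(dxy$x / grid$cell_size))]
  d[, row := as.integer(floor(dxy$y / grid$cell_size))]
  d[col < 0L | col >= grid$n_cols | row < 0L | row >= grid$n_rows,
    `:=`(col = NA_integer_, row = NA_integer_)]

  d <- d[h[, .(device_id, home_col, home_row)], on = "device_id",
         nomatch = NULL]
  d[, away := is.na(col) | is.na(row) | col != home_col | row != home_row]

  status_dt <- d[, .(n_days = .N, n_away = sum(away)), by = device_id]
  out <- h[, .(device_id, cluster, home_col, home_row, home_lon, home_lat)]
  out <- status_dt[out, on = "device_id"]
  out <- last_active[out, on = "device_id"]
  out[, status := fifelse(last_date < event_onset, "inactive",
                  fifelse(is.na(n_days), "unclassified",
                  fifelse(n_away > 0, "evacuate", "stay")))]
  out[is.na(status), status := "unclassified"]

  ## destination: modal non-home daily location of each evacuee
  away <- d[away == TRUE]
  dest <- away[, .(n_days = uniqueN(date), lon = lon[1], lat = lat[1],
                   dcol = col[1], drow = row[1]),
               by = .(device_id, cluster)]
  setorder(dest, device_id, -n_days, cluster)
  dest <- unique(dest, by = "device_id")
  setnames(dest, c("lon", "lat", "dcol", "drow"),
           c("dest_lon", "dest_lat", "dest_col", "dest_row"))
  out <- dest[, .(device_id, dest_lon, dest_lat, dest_col, dest_row)][
    out, on = "device_id"]
  out[status != "evacuate",
      `:=`(dest_lon = NA_real_, dest_lat = NA_real_,
           dest_col = NA_integer_, dest_row = NA_integer_)]

  out[, tier := NA_character_]
  ev <- which(out$status == "evacuate")
  if (length(ev) > 0L && !is.null(county) && !is.null(state)) {
    in_county <- points_in_polygon(out$dest_lon[ev], out$dest_lat[ev], county)
    in_state <- points_in_polygon(out$dest_lon[ev], out$dest_lat[ev], state)
    out$tier[ev] <- ifelse(in_county, "within_county",
                           ifelse(in_state, "within_state", "out_of_state"))
  }
  out[status == "stay", tier := "home"]
  out[, distance_miles := NA_real_]
  if (length(ev) > 0L) {
    out$distance_miles[ev] <- haversine_miles(out$home_lon[ev],
                                              out$home_lat[ev],
                                              out$dest_lon[ev],
                                              out$dest_lat[ev])
  }
  out[, c("n_days", "n_away", "last_date", "cluster") := NULL]
  setcolorder(out, c("device_id", "status", "home_col", "home_row",
                     "home_lon", "home_lat", "dest_lon", "dest_lat",
                     "dest_col", "dest_row", "tier", "distance_miles"))
  out[]
}

#' Evacuation crosstab with shares
#'
#' Tabulates disaster-response status (stay / evacuate / inactive) and
#' evacuee destination tiers by origin group, with percentages of the group
#' sample (tier percentages are of the group's evacuees) rounded to two
#' decimals, plus an overall row. Accepts either device-level records
#' (columns `group`, `status`, `tier`) or pre-aggregated counts (columns
#' `group`, `stay`, `evacuate`, `inactive`, and optionally `sample_n`,
#' `within_county`, `within_state`, `out_of_state`).
#'
#' @param x data.table in either form; a missing `group` column puts
#'   everything in one group.
#' @return data.table, one row per origin group plus `"all"`, with count
#'   (`*_n`) and percentage (`*_pct`) columns.
#' @export
evacuation_summary <- function(x) {
  dt <- as.data.table(x)
  if ("status" %in% names(dt)) {
    if (!"group" %in% names(dt)) dt[, group := "all"]
    counts <- dt[, .(
      stay = sum(status == "stay"),
      evacuate = sum(status == "evacuate"),
      inactive = sum(status == "inactive"),
      unclassified = sum(!status %in% c("stay", "evacuate", "inactive")),
      within_county = sum(status == "evacuate" &
                            tier %in% "within_county"),
      within_state = sum(status == "evacuate" & tier %in% "within_state"),
      out_of_state = sum(status == "evacuate" & tier %in% "out_of_state")
    ), by = group]
    counts[, sample_n := stay + evacuate + inactive + unclassified]
  } else {
    counts <- copy(dt)
    for (cc in c("within_county", "within_state", "out_of_state",
                 "unclassified")) {
      if (!cc %in% names(counts)) counts[, (cc) := 0L]
    }
    if (!"sample_n" %in% names(counts)) {
      counts[, sample_n := stay + evacuate + inactive + unclassified]
    }
  }
  if (nrow(counts) > 1L && !"all" %in% counts$group) {
    tot <- counts[, lapply(.SD, sum), .SDcols = !"group"]
    counts <- rbind(counts, data.table(group = "all", tot), fill = TRUE)
  }
  counts[, `:=`(
    stay_pct = round(100 * stay / sample_n, 2),
    evacuate_pct = round(100 * evacuate / sample_n, 2),
    inactive_pct = round(100 * inactive / sample_n, 2),
    within_county_pct = round(100 * within_county / pmax(evacuate, 1), 2),
    within_state_pct = round(100 * within_state / pmax(evacuate, 1), 2),
    out_of_state_pct = round(100 * out_of_state / pmax(evacuate, 1), 2)
  )]
  counts[evacuate == 0,
         c("within_county_pct", "within_state_pct",
           "out_of_state_pct") := NA_real_]
  setcolorder(counts, c("group", "sample_n", "stay", "stay_pct",
                        "evacuate", "evacuate_pct", "inactive",
                        "inactive_pct", "unclassified", "within_county",
                        "within_county_pct", "within_state",
                        "within_state_pct", "out_of_state",
                        "out_of_state_pct"))
  counts[]
}
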