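#' Disaster-response archetype specification
#'
#' Parameterizes one of the four empirical neighborhood response shapes:
#' shelter-in-place (bell up), stable (flat), distressed (U with partial
#' return), abandoned (deep U with a persistent deficit). The deviation
#' curve is piecewise linear: zero before `impact_start`, reaching
#' `-impact_depth` at `peak_date` (a negative depth encodes a rise), then
#' moving to `post_offset` over `recovery_days` and holding it.
#'
#' @param name one of `"shelter_in_place"`, `"stable"`, `"distressed"`,
#'   `"abandoned"`.
#' @param impact_depth peak fractional deviation; positive = drop,
#'   negative = rise.
#' @param impact_start,peak_date Dates bounding the onset ramp.
#' @param recovery_days days from peak to the post-event plateau.
#' @param post_offset persistent post-event deviation fraction.
#' @param evac_share fraction of the cell's devices that relocate.
#' @param dest_mix probabilities over `within_county`, `within_state`,
#'   `out_of_state` destinations (must sum to 1).
#' @param inactive_share fraction of devices emitting no pings after the
#'   event.
#' @return object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, impact_depth, impact_start, peak_date,
                           recovery_days, post_offset = 0, evac_share = 0,
                           dest_mix = c(within_county = 1, within_state = 0,
                                        out_of_state = 0),
                           inactive_share = 0) {
  name <- match.arg(name, c("shelter_in_place", "stable", "distressed",
                            "abandoned"))
  impact_start <- as.Date(impact_start)
  peak_date <- as.Date(peak_date)
  stopifnot(recovery_days >= 0,
            evac_share >= 0, inactive_share >= 0,
            evac_share + inactive_share <= 1)
  if (abs(sum(dest_mix) - 1) > 1e-9) stop("dest_mix must sum to 1")
  structure(list(name = name, impact_depth = impact_depth,
                 impact_start = impact_start, peak_date = peak_date,
                 recovery_days = as.integer(recovery_days),
                 post_offset = post_offset, evac_share = evac_share,
                 dest_mix = dest_mix, inactive_share = inactive_share),
            class = "archetype_spec")
}

#' Default archetype parameters
#'
#' Impact depths, recovery durations, post-event offsets, response-status
#' shares and destination mixes for the four groups, at their
#' published-tabulation values for the Hurricane Harvey case (Houston,
#' 2017): e.g. the abandoned group dips 48% and plateaus 20% below
#' baseline, with 22.35% of its devices evacuating and 78.31% of those
#' staying within the county.
#'
#' @param event_start impact onset (default 2017-08-25).
#' @param peak_date peak-impact date (default 2017-08-29).
#' @return named list of [archetype_spec()] objects.
#' @export
default_archetypes <- function(event_start = as.Date("2017-08-25"),
                               peak_date = as.Date("2017-08-29")) {
  list(
    shelter_in_place = archetype_spec(
      "shelter_in_place", impact_depth = -0.37,
      impact_start = event_start, peak_date = peak_date,
      recovery_days = 14, post_offset = 0,
      evac_share = 837 / 9953, inactive_share = 623 / 9953,
      dest_mix = c(within_county = 552, within_state = 133,
                   out_of_state = 152) / 837),
    stable = archetype_spec(
      "stable", impact_depth = 0.10,
      impact_start = event_start, peak_date = peak_date,
      recovery_days = 5, post_offset = 0,
      evac_share = 1506 / 16506, inactive_share = 1064 / 16506,
      dest_mix = c(within_county = 1008, within_state = 220,
                   out_of_state = 278) / 1506),
    distressed = archetype_spec(
      "distressed", impact_depth = 0.34,
      impact_start = event_start, peak_date = peak_date,
      recovery_days = 14, post_offset = -0.05,
      evac_share = 559 / 4187, inactive_share = 290 / 4187,
      dest_mix = c(within_county = 381, within_state = 57,
                   out_of_state = 121) / 559),
    abandoned = archetype_spec(
      "abandoned", impact_depth = 0.48,
      impact_start = event_start, peak_date = peak_date,
      recovery_days = 28, post_offset = -0.20,
      evac_share = 438 / 1960, inactive_share = 202 / 1960,
      dest_mix = c(within_county = 343, within_state = 49,
                   out_of_state = 46) / 438)
  )
}

#' Deviation curve implied by an archetype
#'
#' @param spec an [archetype_spec()].
#' @param dates Date vector covering the event window.
#' @return numeric deviation fraction per date.
#' @export
make_archetype_curve <- function(spec, dates) {
  dates <- as.Date(dates)
  if (spec$peak_date < spec$impact_start) {
    stop("peak_date precedes impact_start")
  }
  if (spec$impact_start < min(dates) || spec$impact_start > max(dates)) {
    stop("dates do not cover the event window")
  }
  rec_end <- spec$peak_date + spec$recovery_days
  if (rec_end > max(dates)) {
    stop("recovery extends past the end of the date range")
  }
  d <- as.numeric(dates)
  t_start <- as.numeric(spec$impact_start)
  t_peak <- as.numeric(spec$peak_date)
  t_rec <- as.numeric(rec_end)
  peak_val <- -spec$impact_depth
  v <- numeric(length(d))
  ramp <- d > t_start & d <= t_peak
  if (t_peak > t_start) {
    v[ramp] <- peak_val * (d[ramp] - t_start) / (t_peak - t_start)
  } else {
    v[d == t_peak] <- peak_val
  }
  fall <- d > t_peak & d <= t_rec
  if (t_rec > t_peak) {
    v[fall] <- peak_val +
      (spec$post_offset - peak_val) * (d[fall] - t_peak) / (t_rec - t_peak)
  }
  v[d == t_peak] <- peak_val
  v[d > t_rec] <- spec$post_offset
  v
}

#' Synthetic city configuration
#'
#' Study conditions for the ping generator: a 2-month window
#' (2017-08-01 to 2017-09-30) with the pre-event equilibrium ending
#' August 16, an 11 x 12 grid of 1-km cells holding 30 cells per archetype
#' (the remaining cells are unpopulated "commons" that receive
#' within-county evacuees, playing the role of downtown shelter areas),
#' and 200 devices per archetype cell.
#'
#' @param grid_rows,grid_cols grid dimensions in cells.
#' @param cells_per_archetype named integer vector, cells per archetype;
#'   the total must leave at least one commons cell free when any
#'   archetype sends within-county evacuees.
#' @param devices_per_cell devices homed in each archetype cell.
#' @param study_start,study_end,baseline_end study window Dates.
#' @param pings_per_device_day mean pings emitted by a device on a day it
#'   is present at home.
#' @param night_activity_fraction fraction of those pings falling in the
#'   20:00-07:00 night window.
#' @param night_presence baseline probability that a device is present
#'   (and so emits night pings) at its residence on a given day.
#' @param work_share fraction of devices with a weekday work location.
#' @param work_rate mean weekday pings at the work location.
#' @param origin_lon,origin_lat south-west corner of the grid.
#' @param cell_size cell edge in metres.
#' @param tz_offset fixed UTC offset (hours) of generated timestamps.
#' @param seed RNG seed; identical seeds give identical output.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(grid_rows = 11, grid_cols = 12,
                         cells_per_archetype = c(shelter_in_place = 30,
                                                 stable = 30,
                                                 distressed = 30,
                                                 abandoned = 30),
                         devices_per_cell = 200,
                         study_start = as.Date("2017-08-01"),
                         study_end = as.Date("2017-09-30"),
                         baseline_end = as.Date("2017-08-16"),
                         pings_per_device_day = 5,
                         night_activity_fraction = 0.65,
                         night_presence = 0.8,
                         work_share = 0.55, work_rate = 1.5,
                         origin_lon = -95.8, origin_lat = 29.55,
                         cell_size = 1000, tz_offset = -5, seed = 20170825) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  baseline_end <- as.Date(baseline_end)
  stopifnot(study_start < baseline_end, baseline_end < study_end,
            grid_rows > 0, grid_cols > 0, devices_per_cell > 0,
            all(cells_per_archetype > 0), pings_per_device_day > 0,
            night_activity_fraction > 0, night_activity_fraction < 1,
            night_presence > 0, night_presence <= 1)
  if (sum(cells_per_archetype) > grid_rows * grid_cols) {
    stop("more archetype cells requested than grid cells")
  }
  structure(as.list(environment()), class = "synth_config")
}

.city_grid <- function(cfg) {
  lat_max <- cfg$origin_lat + cfg$grid_rows * cfg$cell_size / 110540
  lat_mid <- (cfg$origin_lat + lat_max) / 2
  m_lon <- 111320 * cos(lat_mid * pi / 180)
  lon_max <- cfg$origin_lon + cfg$grid_cols * cfg$cell_size / m_lon
  grid_spec(cfg$origin_lon, lon_max, cfg$origin_lat, lat_max, cfg$cell_size)
}

## km offsets -> degrees around the grid centre (used for out-of-grid
## destinations and the administrative polygons)
.offset_deg <- function(grid, dx_km, dy_km) {
  lat_mid <- (grid$lat_min + grid$lat_max) / 2
  list(dlon = dx_km * 1000 / (111320 * cos(lat_mid * pi / 180)),
       dlat = dy_km * 1000 / 110540)
}

#' County and state polygons for a synthetic city
#'
#' The "county" is the grid extent with a 2-km margin; the "state" is a
#' 400-km half-width rectangle around the grid centre, so within-state
#' destinations (drawn at 100-300 km) fall inside it and out-of-state
#' destinations (500 km and beyond) fall outside.
#'
#' @param grid a [grid_spec()].
#' @return list of closed lon/lat ring matrices `county`, `state`.
#' @export
city_polygons <- function(grid) {
  m <- .offset_deg(grid, 2, 2)
  county <- cbind(
    lon = c(grid$lon_min - m$dlon, grid$lon_max + m$dlon,
            grid$lon_max + m$dlon, grid$lon_min - m$dlon,
            grid$lon_min - m$dlon),
    lat = c(grid$lat_min - m$dlat, grid$lat_min - m$dlat,
            grid$lat_max + m$dlat, grid$lat_max + m$dlat,
            grid$lat_min - m$dlat))
  ctr_lon <- (grid$lon_min + grid$lon_max) / 2
  ctr_lat <- (grid$lat_min + grid$lat_max) / 2
  s <- .offset_deg(grid, 400, 400)
  state <- cbind(
    lon = ctr_lon + c(-s$dlon, s$dlon, s$dlon, -s$dlon, -s$dlon),
    lat = ctr_lat + c(-s$dlat, -s$dlat, s$dlat, s$dlat, -s$dlat))
  list(county = county, state = state)
}

#' Generate a synthetic ping panel with known ground truth
#'
#' Simulates the device panel of a city hit by a multi-day disruption.
#' Each archetype cell's expected nighttime resident count tracks
#' `(1 + curve(t)) * baseline` exactly: available stayers are present with
#' probability `min(1, target / available)` and, when a positive curve
#' exceeds stayer capacity (the shelter-in-place peak), the deficit is
#' filled with Poisson "visitor" devices, mirroring shelter influx.
#' Devices are assigned a response status (stay / evacuate / inactive) at
#' the archetype's shares; evacuees relocate to a sampled destination tier
#' during their displacement window (through study end for the abandoned
#' group, through `peak + recovery_days` otherwise) and within-county
#' destinations land in commons cells; inactive devices stop pinging at
#' event onset. Present devices emit night pings (20:00-07:00, always at
#' least one) and daytime pings at home, plus weekday pings at a work cell
#' for a share of devices.
#'
#' @param cfg a [synth_config()].
#' @param archetypes named list of [archetype_spec()]s; names must match
#'   `cfg$cells_per_archetype`.
#' @return list: `pings` (data.table `device_id`, `t`, `lat`, `lon`,
#'   `accuracy`, unsorted raw stream), `truth` (list of `devices`, `cells`,
#'   `curves`, `baseline_target`), `grid`, `polygons`, `config`.
#' @export
generate_city <- function(cfg, archetypes = default_archetypes()) {
  stopifnot(inherits(cfg, "synth_config"))
  stopifnot(all(names(cfg$cells_per_archetype) %in% names(archetypes)))
  set.seed(cfg$seed)
  grid <- .city_grid(cfg)
  dates <- seq(cfg$study_start, cfg$study_end, by = "day")
  n_days <- length(dates)
  arch_names <- names(cfg$cells_per_archetype)

  ## --- cells ------------------------------------------------------------
  cells <- CJ(col = 0:(cfg$grid_cols - 1L), row = 0:(cfg$grid_rows - 1L))
  cells <- cells[sample(.N)]
  cells[, archetype := c(rep(arch_names, cfg$cells_per_archetype),
                         rep("commons", .N - sum(cfg$cells_per_archetype)))]
  commons <- cells[archetype == "commons"]
  need_commons <- any(vapply(arch_names, function(a) {
    archetypes[[a]]$evac_share * archetypes[[a]]$dest_mix[["within_county"]]
  }, numeric(1)) > 0)
  if (need_commons && nrow(commons) == 0L) {
    stop("within-county evacuees need at least one commons cell")
  }

  curves <- rbindlist(lapply(arch_names, function(a) {
    data.table(archetype = a, date = dates,
               value = make_archetype_curve(archetypes[[a]], dates))
  }))

  ## --- devices ----------------------------------------------------------
  acells <- cells[archetype != "commons"]
  dev <- acells[rep(seq_len(.N), each = cfg$devices_per_cell)]
  setnames(dev, c("col", "row"), c("home_col", "home_row"))
  n_dev <- nrow(dev)
  dev[, device_id := sprintf("D%07d", seq_len(n_dev))]
  ctr <- cell_center(grid, dev$home_col, dev$home_row)
  off <- .offset_deg(grid, 0.001, 0.001)   # degrees per metre
  dev[, `:=`(home_lon = ctr$lon + runif(n_dev, -300, 300) * off$dlon,
             home_lat = ctr$lat + runif(n_dev, -300, 300) * off$dlat)]

  evac_p <- vapply(dev$archetype, function(a) archetypes[[a]]$evac_share,
                   numeric(1))
  inact_p <- vapply(dev$archetype, function(a) archetypes[[a]]$inactive_share,
                    numeric(1))
  u <- runif(n_dev)
  dev[, status := fifelse(u < evac_p, "evacuate",
                  fifelse(u < evac_p + inact_p, "inactive", "stay"))]

  ## destinations for evacuees
  dev[, `:=`(tier = NA_character_, dest_lon = NA_real_, dest_lat = NA_real_)]
  ev <- which(dev$status == "evacuate")
  if (length(ev) > 0L) {
    tiers <- c("within_county", "within_state", "out_of_state")
    dev$tier[ev] <- vapply(dev$archetype[ev], function(a) {
      sample(tiers, 1L, prob = archetypes[[a]]$dest_mix)
    }, character(1))
    wc <- ev[dev$tier[ev] == "within_county"]
    if (length(wc) > 0L) {
      pick <- commons[sample(.N, length(wc), replace = TRUE)]
      pctr <- cell_center(grid, pick$col, pick$row)
      dev$dest_lon[wc] <- pctr$lon + runif(length(wc), -300, 300) * off$dlon
      dev$dest_lat[wc] <- pctr$lat + runif(length(wc), -300, 300) * off$dlat
    }
    far <- ev[dev$tier[ev] != "within_county"]
    if (length(far) > 0L) {
      dist_km <- fifelse(dev$tier[far] == "within_state",
                         runif(length(far), 100, 300),
                         runif(length(far), 500, 1500))
      theta <- runif(length(far), 0, 2 * pi)
      o <- .offset_deg(grid, dist_km * cos(theta), dist_km * sin(theta))
      dev$dest_lon[far] <- (grid$lon_min + grid$lon_max) / 2 + o$dlon
      dev$dest_lat[far] <- (grid$lat_min + grid$lat_max) / 2 + o$dlat
    }
  }

  ## displacement windows
  dev[, `:=`(disp_start = as.Date(NA), disp_end = as.Date(NA))]
  for (a in arch_names) {
    sp <- archetypes[[a]]
    idx <- which(dev$archetype == a & dev$status == "evacuate")
    if (length(idx) > 0L) {
      dev$disp_start[idx] <- sp$impact_start
      dev$disp_end[idx] <- if (a == "abandoned") cfg$study_end else
        min(cfg$study_end, sp$peak_date + sp$recovery_days)
    }
  }
  dev[, has_work := runif(n_dev) < cfg$work_share]
  wcell <- cells[sample(.N, n_dev, replace = TRUE)]
  wctr <- cell_center(grid, wcell$col, wcell$row)
  dev[, `:=`(work_lon = wctr$lon + runif(n_dev, -300, 300) * off$dlon,
             work_lat = wctr$lat + runif(n_dev, -300, 300) * off$dlat)]

  ## --- per-cell-day presence targets ------------------------------------
  onset <- min(vapply(arch_names,
                      function(a) as.numeric(archetypes[[a]]$impact_start),
                      numeric(1)))
  onset <- as.Date(onset, origin = "1970-01-01")
  q0 <- cfg$night_presence
  cellstat <- dev[, .(n_stay = sum(status == "stay"),
                      n_evac = sum(status == "evacuate"),
                      n_inact = sum(status == "inactive")),
                  by = .(home_col, home_row, archetype)]
  cd <- cellstat[, .(date = dates), by = .(home_col, home_row, archetype,
                                           n_stay, n_evac, n_inact)]
  cd <- curves[cd, on = c("archetype", "date")]
  ## evacuees of archetype a are displaced over one shared window
  for (a in arch_names) {
    sp <- archetypes[[a]]
    dend <- if (a == "abandoned") cfg$study_end else
      min(cfg$study_end, sp$peak_date + sp$recovery_days)
    cd[archetype == a,
       n_evac := n_evac * as.integer(!(date >= sp$impact_start &
                                         date <= dend))]
  }
  cd[, n_inact := n_inact * as.integer(date < onset)]
  n_cell <- cfg$devices_per_cell
  cd[, target := q0 * n_cell * (1 + value)]
  cd[, avail := n_stay + n_evac + n_inact]
  cd[, p_home := fifelse(avail > 0, pmin(1, target / avail), 0)]
  cd[, deficit := pmax(0, target - avail)]

  ## --- device-days -------------------------------------------------------
  keep <- dev[, .(device_id, home_col, home_row, home_lon, home_lat, status,
                  archetype, disp_start, disp_end, dest_lon, dest_lat,
                  has_work, work_lon, work_lat)]
  dd <- keep[rep(seq_len(.N), each = n_days)]
  dd[, date := rep(dates, times = nrow(keep))]
  dd[, displaced := status == "evacuate" & !is.na(disp_start) &
       date >= disp_start & date <= disp_end]
  dd[, gone := status == "inactive" & date >= onset]
  dd <- dd[gone == FALSE]
  dd[, at_home := !displaced]
  dd <- cd[, .(home_col, home_row, date, p_home)][
    dd, on = c("home_col", "home_row", "date")]
  dd[, present := fifelse(at_home, runif(.N) < p_home, runif(.N) < q0)]
  dd <- dd[present == TRUE]
  dd[, `:=`(loc_lon = fifelse(at_home, home_lon, dest_lon),
            loc_lat = fifelse(at_home, home_lat, dest_lat))]

  lam_night <- cfg$pings_per_device_day * cfg$night_activity_fraction
  lam_day <- cfg$pings_per_device_day - lam_night
  dd[, n_night := 1L + rpois(.N, max(lam_night - 1, 0))]
  dd[, n_day := rpois(.N, lam_day)]
  weekday <- !.is_weekend(dd$date)
  dd[, n_work := fifelse(at_home & has_work & weekday,
                         rpois(.N, cfg$work_rate), 0L)]

  ## --- visitors ----------------------------------------------------------
  vis <- cd[deficit > 0]
  vis[, n_vis := rpois(.N, deficit)]
  vis <- vis[n_vis > 0]
  visitors <- NULL
  if (nrow(vis) > 0L) {
    visitors <- vis[rep(seq_len(.N), n_vis),
                    .(home_col, home_row, date)]
    vctr <- cell_center(grid, visitors$home_col, visitors$home_row)
    visitors[, `:=`(device_id = sprintf("V%08d", seq_len(.N)),
                    loc_lon = vctr$lon + runif(.N, -300, 300) * off$dlon,
                    loc_lat = vctr$lat + runif(.N, -300, 300) * off$dlat,
                    n_night = 1L + rpois(.N, max(lam_night - 1, 0)))]
  }

  ## --- expand to pings ----------------------------------------------------
  night_src <- rbind(
    dd[n_night > 0, .(device_id, date, loc_lon, loc_lat, n = n_night)],
    if (!is.null(visitors)) visitors[, .(device_id, date, loc_lon, loc_lat,
                                         n = n_night)])
  night <- night_src[rep(seq_len(.N), n)]
  nn <- nrow(night)
  morning <- runif(nn) < 7 / 11
  hr <- numeric(nn)
  hr[morning] <- runif(sum(morning), 0, 7)
  hr[!morning] <- runif(sum(!morning), 20, 24)
  night[, sec := hr * 3600]

  day_src <- dd[n_day > 0, .(device_id, date, loc_lon, loc_lat, n = n_day)]
  day <- day_src[rep(seq_len(.N), n)]
  day[, sec := runif(.N, 9, 19) * 3600]

  work_src <- dd[n_work > 0, .(device_id, date, loc_lon = work_lon,
                               loc_lat = work_lat, n = n_work)]
  work <- work_src[rep(seq_len(.N), n)]
  work[, sec := runif(.N, 9, 18) * 3600]

  pings <- rbind(night[, -"n"], day[, -"n"], work[, -"n"])
  np <- nrow(pings)
  pings[, `:=`(
    lon = loc_lon + rnorm(np, 0, 45) * off$dlon,
    lat = loc_lat + rnorm(np, 0, 45) * off$dlat,
    t = as.numeric(date) * 86400 + sec - cfg$tz_offset * 3600,
    accuracy = runif(np, 5, 40))]
  pings <- pings[, .(device_id, t, lat, lon, accuracy)]
  setorder(pings, device_id, t)

  truth_curves <- curves[cells[archetype != "commons"], on = "archetype",
                         allow.cartesian = TRUE][
    , .(col, row, archetype, date, value)]
  setorder(truth_curves, col, row, date)

  list(pings = pings,
       truth = list(
         devices = dev[, .(device_id, home_col, home_row, archetype,
                           status, tier, disp_start, disp_end, has_work)],
         cells = cells[, .(col, row, archetype)],
         curves = truth_curves,
         baseline_target = q0 * n_cell),
       grid = grid,
       polygons = city_polygons(grid),
       config = cfg)
}

#' Synthetic zone-level damage counts
#'
#' Draws per-cell damaged-property counts as Binomial(households, rate)
#' with archetype-specific per-household rates (defaults: 151/1000 for
#' abandoned down to 105/1000 for shelter-in-place, so damage decreases
#' with resilience rank) and aggregates them to coarse zones, emulating
#' damage tallies published only at zipcode-like resolution.
#'
#' @param cells data.table `col`, `row`, `archetype` (e.g.
#'   `truth$cells` from [generate_city()]).
#' @param zones optional data.table `col`, `row`, `zone`; by default cells
#'   are tiled into `block` x `block` zones.
#' @param rates named per-household damage fractions by archetype.
#' @param households_per_cell mean households per cell (Poisson).
#' @param block zone tiling size in cells (default 2).
#' @return list: `zones` (data.table `zone`, `damaged`, `households`),
#'   `cells` (`col`, `row`, `zone`, `archetype`, `households`,
#'   `true_damaged`).
#' @export
generate_damage <- function(cells,
                            zones = NULL,
                            rates = c(shelter_in_place = 0.105,
                                      stable = 0.115,
                                      distressed = 0.135,
                                      abandoned = 0.151,
                                      commons = 0.115),
                            households_per_cell = 1200,
                            block = 2) {
  dt <- copy(as.data.table(cells))
  if (is.null(zones)) {
    dt[, zone := sprintf("Z%02d_%02d", col %/% block, row %/% block)]
  } else {
    dt <- as.data.table(zones)[dt, on = c("col", "row")]
    if (anyNA(dt$zone)) stop("every cell must be zoned")
  }
  if (!all(dt$archetype %in% names(rates))) {
    stop("missing damage rate for archetype: ",
         paste(setdiff(dt$archetype, names(rates)), collapse = ", "))
  }
  dt[, households := rpois(.N, households_per_cell)]
  if (any(dt$households <= 0)) dt[households <= 0, households := 1L]
  dt[, true_damaged := rbinom(.N, households, rates[archetype])]
  zone_tab <- dt[, .(damaged = sum(true_damaged),
                     households = sum(households)), by = zone]
  list(zones = zone_tab[],
       cells = dt[, .(col, row, zone, archetype, households, true_damaged)])
}

#' Write / read a synthetic-city configuration as plain text
#'
#' Key-value (`key = value`) serialization of a [synth_config()].
#'
#' @param cfg a [synth_config()].
#' @param path file path.
#' @export
write_synth_config <- function(cfg, path) {
  ser <- function(v) {
    if (inherits(v, "Date")) as.character(v)
    else if (length(v) > 1) paste(sprintf("%s:%s", names(v), v),
                                  collapse = ",")
    else as.character(v)
  }
  lines <- vapply(names(unclass(cfg)),
                  function(k) sprintf("%s = %s", k, ser(cfg[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, 1, FUN.VALUE = ""))
  parse_val <- function(k, v) {
    if (k %in% c("study_start", "study_end", "baseline_end")) return(as.Date(v))
    if (grepl(":", v, fixed = TRUE)) {
      parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
      return(setNames(as.numeric(vapply(parts, `[[`, 2, FUN.VALUE = "")),
                      vapply(parts, `[[`, 1, FUN.VALUE = "")))
    }
    suppressWarnings(num <- as.numeric(v))
    if (!is.na(num)) num else v
  }
  args <- Map(parse_val, names(vals), vals)
  do.call(synth_config, args)
}
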