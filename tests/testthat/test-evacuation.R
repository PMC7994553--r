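library(data.table)

std_ping <- function(id, date, hour, lon, lat) {
  date <- as.Date(date)
  data.table(device_id = id, local_date = date, local_hour = hour,
             day_bin = as.integer(hour * 12), lon = lon, lat = lat,
             t = as.numeric(date) * 86400 + hour * 3600, accuracy = 10)
}

test_that("active-user screen keeps the weekly-present top quartile", {
  dates <- seq(as.Date("2017-08-01"), as.Date("2017-08-28"), by = "day")
  mk_dev <- function(id, n_per_day) {
    rbindlist(lapply(dates, function(d) {
      std_ping(id, rep(d, n_per_day), seq(1, 23, length.out = n_per_day),
               -95, 29)
    }))
  }
  p <- rbindlist(lapply(1:8, function(i) mk_dev(sprintf("d%d", i), i)))
  sel <- select_active_users(p, impact_window = as.Date(c("2017-08-10",
                                                          "2017-08-15")))
  expect_setequal(sel, c("d8", "d7"))

  ## all-tied counts: exactly ceiling(n/4), by id order
  tied <- rbindlist(lapply(sprintf("t%02d", 1:10),
                           function(id) mk_dev(id, 3)))
  expect_equal(select_active_users(tied,
                                   as.Date(c("2017-08-10", "2017-08-15"))),
               c("t01", "t02", "t03"), ignore_attr = TRUE)

  ## a device missing one whole week is excluded regardless of volume
  gap <- mk_dev("big", 50)
  gap <- gap[!(local_date >= as.Date("2017-08-07") &
                 local_date <= as.Date("2017-08-13"))]
  p2 <- rbind(p, gap)
  expect_false("big" %in%
                 select_active_users(p2, as.Date(c("2017-08-10",
                                                   "2017-08-15"))))
})

test_that("rescaled feature distances anchor 250 m and 6 h at 0.25", {
  base <- std_ping("a", "2017-08-01", 12, -95, 29)
  north <- copy(base)[, lat := lat + 0.25 / 110.540]       # 250 m north
  later <- copy(base)[, day_bin := day_bin + 72L]          # 6 h later
  f_sp <- rescale_features(rbind(base, north))
  expect_equal(dist(f_sp)[1], 0.25, tolerance = 1e-6)
  f_t <- rescale_features(rbind(base, later))
  expect_equal(dist(f_t)[1], 0.25, tolerance = 1e-12)
  f_same <- rescale_features(rbind(base, base))
  expect_equal(dist(f_same)[1], 0)
})

test_that("DBSCAN handles textbook cases", {
  ## 20 coincident pings form one cluster, no noise
  x <- matrix(0, 20, 3)
  expect_equal(dbscan_st(x, 0.25, 4), rep(1L, 20))
  ## two blobs 1 km apart -> two clusters; a remote singleton is noise
  set.seed(51)
  blob <- function(cx) cbind(cx + rnorm(15, 0, 0.02), rnorm(15, 0, 0.02),
                             0.5)
  x2 <- rbind(blob(0), blob(1), c(5, 5, 0.5))
  lab <- dbscan_st(x2, 0.25, 4)
  expect_equal(lab[31], 0L)
  expect_equal(uniqueN(lab[1:15]), 1L)
  expect_equal(uniqueN(lab[16:30]), 1L)
  expect_true(lab[1] != lab[16])
})

test_that("DBSCAN equals the brute-force density-connectivity oracle", {
  set.seed(52)
  for (trial in 1:5) {
    n <- sample(50:200, 1)
    x <- cbind(runif(n, 0, 2), runif(n, 0, 2), runif(n))
    eps <- runif(1, 0.1, 0.4)
    min_pts <- sample(3:8, 1)
    expect_equal(dbscan_st(x, eps, min_pts), brute_dbscan(x, eps, min_pts))
  }
})

test_that("profile typing separates night and office-hour archetypes", {
  mk_prof <- function(hours, n) {
    t(replicate(n, {
      p <- rep(0.001, 24)
      p[hours + 1] <- p[hours + 1] + runif(length(hours), 0.5, 1)
      p / sum(p)
    }))
  }
  night <- mk_prof(c(21:23, 0:5), 12)
  office <- mk_prof(10:16, 12)
  pt <- profile_and_type(rbind(night, office), k = 2)
  expect_equal(unique(pt$types[1:12]), "residential")
  expect_equal(unique(pt$types[13:24]), "work")

  ## k = 1: centroid is the mean smoothed profile
  one <- profile_and_type(night, k = 1)
  expect_equal(uniqueN(one$assignment), 1L)
  expect_error(profile_and_type(night, k = 99), "exceeds")

  ## four constructed archetypes recovered by k-means
  set.seed(53)
  four <- rbind(night, office, mk_prof(6:8, 12), mk_prof(17:19, 12))
  truth <- rep(1:4, each = 12)
  pt4 <- profile_and_type(four, k = 4)
  expect_gte(ari(pt4$assignment, truth), 0.9)
})

test_that("home assignment prefers the busiest pre-event residential cluster", {
  ac <- list(
    clusters = data.table(
      device_id = c("d", "d", "d"), cluster = 1:3,
      size = c(50L, 80L, 400L), lon = c(0, 0.01, 0.02),
      lat = c(0, 0.01, 0.02), n_dates = c(10L, 10L, 10L)),
    date_counts = data.table(
      device_id = "d", cluster = c(1L, 2L, 3L),
      date = as.Date("2017-08-05"), n = c(30L, 20L, 900L)))
  ## "other"-typed cluster 3 is ineligible despite being busiest
  homes <- assign_home(ac, c("residential", "work", "other"),
                       as.Date(c("2017-08-01", "2017-08-24")))
  expect_equal(homes$cluster, 1L)
  ## work wins when it is the only eligible pre-event cluster
  ac2 <- list(clusters = ac$clusters[2],
              date_counts = ac$date_counts[2])
  expect_equal(assign_home(ac2, "work",
                           as.Date(c("2017-08-01", "2017-08-24")))$type,
               "work")
  ## no pre-event activity: unassigned
  ac3 <- list(clusters = ac$clusters[1],
              date_counts = data.table(device_id = "d", cluster = 1L,
                                       date = as.Date("2017-09-05"),
                                       n = 10L))
  h3 <- assign_home(ac3, "residential", as.Date(c("2017-08-01",
                                                  "2017-08-24")))
  expect_equal(nrow(h3), 0L)
  expect_equal(attr(h3, "n_unassigned"), 1L)
})

test_that("daily location prioritizes residential clusters", {
  ac <- list(
    clusters = data.table(device_id = "d", cluster = 1:2, size = c(10L, 99L),
                          lon = c(0, 1), lat = c(0, 1), n_dates = c(5L, 5L)),
    date_counts = data.table(device_id = "d", cluster = c(1L, 2L),
                             date = as.Date("2017-08-28"), n = c(2L, 50L)))
  dl <- daily_locations(ac, c("residential", "other"))
  expect_equal(dl$cluster, 1L)     # residential beats busier "other"
  dl2 <- daily_locations(list(clusters = ac$clusters[2],
                              date_counts = ac$date_counts[2]), "other")
  expect_equal(dl2$cluster, 2L)    # lone "other" cluster is used
})

test_that("OD classification separates stay, evacuate and inactive", {
  g <- grid_spec(0, 0.10, 0, 0.10, cell_size = 1000)
  ring <- function(lon0, lon1, lat0, lat1) {
    cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
          lat = c(lat0, lat0, lat1, lat1, lat0))
  }
  county <- poly_features(ring(-0.01, 0.11, -0.01, 0.11))
  state <- poly_features(ring(-1, 1, -1, 1))
  win <- as.Date(c("2017-08-23", "2017-09-02"))
  onset <- as.Date("2017-08-25")
  ctr <- cell_center(g, c(0L, 5L), c(0L, 5L))

  homes <- data.table(device_id = c("s", "e1", "e2", "i"), cluster = 1L,
                      lon = ctr$lon[1], lat = ctr$lat[1],
                      type = "residential", n_win = 10L)
  dailies <- rbind(
    data.table(device_id = "s", date = seq(win[1], win[2], by = "day"),
               cluster = 1L, lon = ctr$lon[1], lat = ctr$lat[1],
               type = "residential", n = 5L),
    ## e1 crosses to another cell inside the county polygon
    data.table(device_id = "e1", date = seq(onset, win[2], by = "day"),
               cluster = 2L, lon = ctr$lon[2], lat = ctr$lat[2],
               type = "residential", n = 5L),
    ## e2 leaves the county but stays in the state
    data.table(device_id = "e2", date = seq(onset, win[2], by = "day"),
               cluster = 2L, lon = 0.5, lat = 0.5,
               type = "residential", n = 5L))
  last_active <- data.table(device_id = c("s", "e1", "e2", "i"),
                            last_date = as.Date(c("2017-09-30", "2017-09-30",
                                                  "2017-09-30",
                                                  "2017-08-24")))
  od <- build_od(homes, dailies, last_active, win, onset, g, county, state)
  expect_equal(od[device_id == "s", status], "stay")
  expect_equal(od[device_id == "s", tier], "home")
  expect_equal(od[device_id == "e1", .(status, tier)],
               data.table(status = "evacuate", tier = "within_county"))
  expect_equal(od[device_id == "e2", tier], "within_state")
  expect_equal(od[device_id == "i", status], "inactive")
  expect_gt(od[device_id == "e2", distance_miles],
            od[device_id == "e1", distance_miles])
})

test_that("evacuation summary conserves counts and computes shares", {
  dev <- data.table(
    group = rep(c("g1", "g2"), c(10, 4)),
    status = c(rep("stay", 6), rep("evacuate", 3), "inactive",
               rep("stay", 4)),
    tier = c(rep("home", 6), "within_county", "within_county",
             "out_of_state", NA, rep("home", 4)))
  s <- evacuation_summary(dev)
  g1 <- s[group == "g1"]
  expect_equal(g1$sample_n, 10L)
  expect_equal(g1$stay + g1$evacuate + g1$inactive + g1$unclassified, 10L)
  expect_equal(g1$stay_pct, 60)
  expect_equal(g1$within_county_pct, round(200 / 3, 2))
  all_row <- s[group == "all"]
  expect_equal(all_row$sample_n, 14L)
  ## everyone-stays degenerate case
  stay_only <- evacuation_summary(data.table(group = "g",
                                             status = rep("stay", 5),
                                             tier = "home"))
  expect_equal(stay_only$stay_pct, 100)
  expect_equal(stay_only$evacuate_pct, 0)
  expect_true(is.na(stay_only$within_county_pct))
})
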