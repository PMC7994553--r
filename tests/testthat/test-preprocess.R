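library(data.table)

raw_ping <- function(id, t, lat, lon, acc = 10) {
  data.table(device_id = id, t = t, lat = lat, lon = lon, accuracy = acc)
}

test_that("5-minute averaging collapses a bin to its coordinate mean", {
  p <- raw_ping("abc", t = 900 + seq(0, 299, length.out = 10),
                lat = 29 + (1:10) / 1000, lon = -95 - (1:10) / 1000)
  out <- standardize_pings(p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$lat, mean(29 + (1:10) / 1000))
  expect_equal(out$lon, mean(-95 - (1:10) / 1000))
  expect_equal(out$t, 900)
  expect_equal(out$device_id, "ABC")
})

test_that("generic ids, out-of-box and malformed rows are dropped and counted", {
  p <- rbind(
    raw_ping("00000000-0000-0000-0000-000000000000", 0, 29, -95),
    raw_ping("dev1", 0, 29, -95),
    raw_ping("dev1", 1e6, 45, -95),        # outside bbox
    raw_ping("dev2", 2e6, NA_real_, -95))  # malformed
  out <- standardize_pings(p, bbox = c(-96, -94, 28, 30))
  log <- attr(out, "log")
  expect_equal(out$device_id, "DEV1")
  expect_equal(log$n_generic_id, 1L)
  expect_equal(log$n_outside_bbox, 1L)
  expect_equal(log$n_malformed, 1L)
  ## empty stream in, empty stream out
  empty <- standardize_pings(raw_ping(character(), numeric(), numeric(),
                                      numeric(), numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("standardize is idempotent on its own output", {
  set.seed(1)
  p <- raw_ping(sample(c("a", "b"), 200, TRUE),
                t = sort(runif(200, 0, 86400 * 3)),
                lat = 29 + runif(200) / 10, lon = -95 - runif(200) / 10)
  once <- standardize_pings(p)
  twice <- standardize_pings(once)
  expect_equal(as.data.frame(twice[order(device_id, t)]),
               as.data.frame(once[order(device_id, t)]),
               ignore_attr = TRUE)
})

test_that("local calendar fields honor the fixed UTC offset", {
  ## unix 18000 = 1970-01-01 05:00 UTC = midnight local at UTC-5
  out <- standardize_pings(raw_ping("a", 18000, 29, -95))
  expect_equal(out$local_hour, 0)
  expect_equal(out$local_date, as.Date("1970-01-01"))
  expect_equal(out$day_bin, 0L)
})

test_that("road masking removes buffered pings and counts them", {
  road <- list(list(rings = list(cbind(lon = c(-95.05, -94.95),
                                       lat = c(29, 29)))))
  on_road <- raw_ping("a", 0, 29, -95)
  far <- raw_ping("b", 0, 29 + 100 / 110540, -95)  # ~100 m north
  std <- standardize_pings(rbind(on_road, far))
  out <- mask_roads(std, road, buffer_m = 50)
  expect_equal(out$device_id, "B")
  expect_equal(attr(out, "n_road_masked"), 1L)
  expect_warning(pass <- mask_roads(std, NULL), "unfiltered")
  expect_equal(nrow(pass), 2L)
})

test_that("a constructed stream with 30% of pings on roads loses exactly those", {
  set.seed(7)
  n <- 200
  on_road <- seq_len(n) <= 60
  lat <- ifelse(on_road, 29, 29 + runif(n, 500, 2000) / 110540)
  p <- raw_ping(sprintf("d%03d", seq_len(n)), t = seq_len(n) * 400,
                lat = lat, lon = -95 + runif(n, -0.001, 0.001))
  road <- list(list(rings = list(cbind(lon = c(-95.1, -94.9),
                                       lat = c(29, 29)))))
  out <- mask_roads(standardize_pings(p), road, buffer_m = 50)
  expect_equal(nrow(out), 140L)
  expect_equal(attr(out, "n_road_masked"), 60L)
})

test_that("uniform points spread over grid cells uniformly", {
  g <- grid_spec(-95.8, -95.7, 29.5, 29.6, cell_size = 2000)
  set.seed(11)
  n <- 1000
  xy <- data.table(x = runif(n, 0, g$n_cols * 2000),
                   y = runif(n, 0, g$n_rows * 2000))
  ll <- grid_unproject(g, xy$x, xy$y)
  p <- raw_ping(sprintf("d%04d", 1:n), t = (1:n) * 301, lat = ll$lat,
                lon = ll$lon)
  tagged <- assign_grid(standardize_pings(p), g)
  counts <- tagged[, .N, by = .(col, row)]
  full <- CJ(col = 0:(g$n_cols - 1), row = 0:(g$n_rows - 1))
  counts <- counts[full, on = c("col", "row")][is.na(N), N := 0L]
  gof <- suppressWarnings(chisq.test(counts$N))
  expect_gt(gof$p.value, 0.001)
  expect_equal(sum(counts$N), n)
})
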