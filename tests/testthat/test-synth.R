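library(data.table)

dates61 <- seq(as.Date("2017-08-01"), as.Date("2017-09-30"), by = "day")

test_that("archetype curves hit their configured depth and plateau", {
  ab <- default_archetypes()$abandoned
  curve <- make_archetype_curve(ab, dates61)
  expect_equal(min(curve), -0.48)
  expect_equal(curve[length(curve)], -0.20)
  expect_equal(curve[dates61 <= ab$impact_start], rep(0, 25))

  st <- default_archetypes()$stable
  expect_equal(max(abs(make_archetype_curve(st, dates61))), 0.10)

  ## a rise is encoded as negative depth
  sh <- default_archetypes()$shelter_in_place
  expect_equal(max(make_archetype_curve(sh, dates61)), 0.37)

  ## no event, no curve
  none <- archetype_spec("stable", 0, "2017-08-25", "2017-08-29", 0)
  expect_equal(make_archetype_curve(none, dates61), rep(0, 61))
})

test_that("ill-posed curve specs are rejected", {
  expect_error(make_archetype_curve(
    archetype_spec("stable", 0.1, "2017-08-25", "2017-08-20", 5),
    dates61), "precedes")
  expect_error(make_archetype_curve(
    archetype_spec("stable", 0.1, "2017-08-25", "2017-08-29", 60),
    dates61), "past")
  expect_error(archetype_spec("stable", 0.1, "2017-08-25", "2017-08-29", 5,
                              dest_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(archetype_spec("stable", 0.1, "2017-08-25", "2017-08-29", 5,
                              evac_share = 0.7, inactive_share = 0.5))
  expect_error(synth_config(grid_rows = 2, grid_cols = 2,
                            cells_per_archetype = c(stable = 9)),
               "more archetype cells")
})

test_that("identical seeds give byte-identical ping panels", {
  cfg <- synth_config(grid_rows = 2, grid_cols = 3,
                      cells_per_archetype = c(stable = 2, abandoned = 2),
                      devices_per_cell = 15, seed = 77)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$pings, b$pings)
  expect_identical(a$truth$devices, b$truth$devices)
  c2 <- generate_city(synth_config(grid_rows = 2, grid_cols = 3,
                                   cells_per_archetype = c(stable = 2,
                                                           abandoned = 2),
                                   devices_per_cell = 15, seed = 78))
  expect_false(identical(a$pings, c2$pings))
})

test_that("a quiet stable-only city shows only sampling-level deviations", {
  quiet <- list(stable = archetype_spec("stable", 0, "2017-08-25",
                                        "2017-08-29", 0))
  cfg <- synth_config(grid_rows = 2, grid_cols = 4,
                      cells_per_archetype = c(stable = 6),
                      devices_per_cell = 60, work_share = 0.5, seed = 101)
  city <- generate_city(cfg, quiet)
  aa <- analyze_activity(city$pings, city$grid,
                         baseline_window = city_baseline_window(city),
                         study_window = c(cfg$study_start, cfg$study_end),
                         tz_offset = cfg$tz_offset)
  mean_dev <- aa$series$deviation[, .(m = mean(D)), by = .(col, row)]
  expect_equal(nrow(mean_dev), 6L)
  bound <- 3 / sqrt(cfg$devices_per_cell * 61)
  expect_true(all(abs(mean_dev$m) < bound))
})

test_that("an abandoned cell's curve is recovered at panel scale", {
  cfg <- synth_config(grid_rows = 2, grid_cols = 3,
                      cells_per_archetype = c(abandoned = 4),
                      devices_per_cell = 200, seed = 103)
  city <- generate_city(cfg)
  aa <- analyze_activity(city$pings, city$grid,
                         baseline_window = city_baseline_window(city),
                         study_window = c(cfg$study_start, cfg$study_end),
                         tz_offset = cfg$tz_offset)
  truth <- copy(city$truth$curves)
  truth[, sm := frollmean(value, 3, align = "center"), by = .(col, row)]
  cmp <- aa$series$trend[truth[!is.na(sm)], on = c("col", "row", "date"),
                         nomatch = NULL]
  rmse <- cmp[, .(rmse = sqrt(mean((trend - sm)^2))), by = .(col, row)]
  expect_equal(nrow(rmse), 4L)
  expect_true(all(rmse$rmse < 0.05))
})

test_that("synthetic damage reflects configured rates", {
  set.seed(55)
  ## two archetypes at rates 0.15 vs 0.05: recovered zone rates ratio ~ 3
  cells <- CJ(col = 0:3, row = 0:4)
  cells[, archetype := rep(c("abandoned", "stable"), each = 10)]
  zones <- copy(cells)[, zone := archetype]
  dmg <- generate_damage(cells, zones = zones[, .(col, row, zone)],
                         rates = c(abandoned = 0.15, stable = 0.05),
                         households_per_cell = 2000)
  zr <- dmg$zones[, .(zone, rate = damaged / households)]
  ratio <- zr[zone == "abandoned", rate] / zr[zone == "stable", rate]
  expect_equal(ratio, 3, tolerance = 0.15)

  ## the flagship abandoned rate 151/1000 is recovered within 10%
  ab <- data.table(CJ(col = 0:4, row = 0:1), archetype = "abandoned")
  d2 <- generate_damage(ab, households_per_cell = 1500)
  recovered <- sum(d2$zones$damaged) / sum(d2$zones$households) * 1000
  expect_equal(recovered, 151, tolerance = 0.1)

  ## all-stable city: zone rates uniform up to sampling noise
  st <- data.table(CJ(col = 0:5, row = 0:5), archetype = "stable")
  d3 <- generate_damage(st, households_per_cell = 1500)
  rates <- d3$zones[, damaged / households]
  se <- sqrt(0.115 * 0.885 / d3$zones$households)
  expect_true(all(abs(rates - 0.115) < 4 * se))
  expect_error(generate_damage(st, zones = data.table(col = 0L, row = 0L,
                                                      zone = "z")),
               "zoned")
})

test_that("synthetic config survives its plain-text round trip", {
  cfg <- synth_config(devices_per_cell = 123, seed = 9,
                      night_presence = 0.75)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$devices_per_cell, 123)
  expect_equal(back$seed, 9)
  expect_equal(back$night_presence, 0.75)
  expect_equal(back$study_start, cfg$study_start)
  expect_equal(back$cells_per_archetype, cfg$cells_per_archetype)
})
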