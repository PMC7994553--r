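## A small shared synthetic city, built once per test run.
.city_cache <- new.env(parent = emptyenv())

small_city <- function() {
  if (is.null(.city_cache$city)) {
    cfg <- synth_config(
      grid_rows = 4, grid_cols = 5,
      cells_per_archetype = c(shelter_in_place = 4, stable = 4,
                              distressed = 4, abandoned = 4),
      devices_per_cell = 40, seed = 4242)
    .city_cache$city <- generate_city(cfg)
  }
  .city_cache$city
}

city_dates <- function(city) {
  seq(city$config$study_start, city$config$study_end, by = "day")
}

city_baseline_window <- function(city) {
  c(city$config$study_start, city$config$baseline_end)
}

poly_features <- function(ring) list(list(rings = list(ring)))
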