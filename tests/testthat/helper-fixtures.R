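# Shared fixture builders; everything is generated in code.

make_measurements <- function(values, species = "Zn", zone = "North",
                              site_id = "ZN_01",
                              start = as.Date("2022-02-01"),
                              censored = rep(FALSE, length(values))) {
  tibble::tibble(
    site_id = site_id, zone = zone,
    date = start + seq_along(values) - 1,
    species = species,
    value_ng_m3 = values,
    censored = censored
  )
}

# Long table over several species sharing the same dates (one zone/site).
make_panel <- function(species_values, zone = "North", site_id = "ZN_01",
                       start = as.Date("2022-02-01")) {
  purrr::imap_dfr(species_values, function(v, sp) {
    make_measurements(v, species = sp, zone = zone, site_id = site_id,
                      start = start)
  })
}

# Straight-line trajectory tibble.
make_track <- function(id, lats, lons, direction = "backward",
                       start = as.POSIXct("2022-02-01 00:00:00", tz = "UTC"),
                       interval_h = 12) {
  tibble::tibble(
    trajectory_id = id, direction = direction,
    timestamp = start + (seq_along(lats) - 1) * interval_h * 3600,
    lat = lats, lon = lons
  )
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
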