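test_that("measurement CSV parsing handles values, BLD flags and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,zone,date,species,value_ng_m3,censored",
    "ZN_01,North,2022-02-01,Zn,57.9,0",
    "ZN_01,North,2022-02-02,Zn,BLD,0",
    "ZN_01,North,2022-02-03,Zn,61.2,0"
  ), path)
  m <- read_measurements(path)
  expect_equal(nrow(m), 3)
  expect_equal(sum(m$censored), 1)
  expect_equal(m$value_ng_m3[c(1, 3)], c(57.9, 61.2))
  expect_true(is.na(m$value_ng_m3[2]))

  writeLines("site_id,zone,date,species,value_ng_m3,censored", path)
  expect_equal(nrow(read_measurements(path)), 0)
})

test_that("schema errors name the missing column and bad rows are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,zone,date,species,censored",
               "ZN_01,North,2022-02-01,Zn,0"), path)
  expect_error(read_measurements(path), "value_ng_m3",
               class = "pm10risk_schema_error")

  writeLines(c("site_id,zone,date,species,value_ng_m3,censored",
               "ZN_01,North,2022-02-01,Zn,-4,0"), path)
  expect_error(read_measurements(path), "row", class = "pm10risk_validation_error")

  writeLines(c("site_id,zone,date,species,value_ng_m3,censored",
               "ZN_01,North,2022-02-01,Xx,4,0"), path)
  expect_error(read_measurements(path), "Unknown species",
               class = "pm10risk_species_error")
})

test_that("write/read round-trip is the identity on all fields", {
  m <- make_panel(list(Zn = c(1, 2, 3), As = c(0.5, 4, 2)))
  m$censored[2] <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back[order(back$species, back$date), ]),
               as.data.frame(m[order(m$species, m$date), ]),
               ignore_attr = TRUE)
})

test_that("schema remapping reads files with custom column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station,zone,date,species,conc,censored",
               "ZN_01,North,2022-02-01,Zn,5,0"), path)
  m <- read_measurements(path, schema = c(site_id = "station", value_ng_m3 = "conc"))
  expect_equal(m$site_id, "ZN_01")
  expect_equal(m$value_ng_m3, 5)
})

test_that("trajectory reader groups ids, infers interval, rejects disorder", {
  t1 <- make_track("A", lats = 11 + 0:4 / 100, lons = -72.7 + 0:4 / 100)
  t2 <- make_track("B", lats = 11.2 + 0:4 / 100, lons = -72.5 - 0:4 / 100,
                   direction = "forward")
  mixed <- dplyr::bind_rows(t1, t2)[order(rep(1:5, 2)), ]  # interleave ids
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(mixed, path)
  tr <- read_trajectories(path)
  expect_equal(sort(unique(tr$trajectory_id)), c("A", "B"))
  expect_equal(attr(tr, "interval_h"), 12)
  expect_equal(sum(tr$trajectory_id == "A"), 5)  # 5 points = 4 segments

  bad <- t1
  bad$timestamp[3] <- bad$timestamp[1]
  readr::write_csv(bad, path)
  expect_error(read_trajectories(path), class = "pm10risk_format_error")
})

test_that("tdump endpoint shim parses the fixed-column dialect", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "     1     1",
    "    GDAS    22     2     1     0",
    "     2 BACKWARD OMEGA",
    "    22     2     1     0   11.050  -72.670    500.0",
    "    22     2     1     0   11.100  -72.500    500.0",
    "     1 PRESSURE",
    "     1     1    22     2     1     0     0     0     0.0   11.050  -72.670    500.0  850.0",
    "     1     1    22     1    31    12     0     0   -12.0   11.060  -72.500    600.0  840.0",
    "     2     1    22     2     1     0     0     0     0.0   11.100  -72.500    500.0  850.0",
    "     2     1    22     1    31    12     0     0   -12.0   11.120  -72.300    600.0  840.0"
  ), path)
  tr <- read_tdump(path)
  expect_equal(length(unique(tr$trajectory_id)), 2)
  expect_true(all(tr$direction == "backward"))
  expect_equal(attr(tr, "interval_h"), 12)
  expect_equal(sort(unique(tr$lat)), c(11.05, 11.06, 11.10, 11.12))
})

test_that("config readers accept YAML and JSON with unit-bearing keys", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ET: 8", "EF: 250", "ED: 25"), yml)
  p <- read_exposure_params(yml)
  expect_equal(p$ET, 8)
  expect_equal(p$EF, 250)
  expect_equal(p$BW, 70)  # preset fallback

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"Cr(VI)": {"RfC_mg_m3": 2e-4}, "Tri": {"TEF": 0.02}}', js)
  tox <- read_toxicity_table(js)
  expect_equal(tox$RfC_mg_m3[tox$species == "Cr(VI)"], 2e-4)
  expect_equal(tox$TEF[tox$species == "Tri"], 0.02)
  expect_equal(tox$TEF[tox$species == "BaP"], 1)  # untouched
})
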