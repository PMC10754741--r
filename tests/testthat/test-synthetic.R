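test_that("degenerate targets give constant, censor-free series", {
  targ <- tibble::tibble(zone = "North", species = "Zn", mean = 50, sd = 0, lod = 10)
  m <- gen_concentrations(targ, n_days = 20, seed = 1)
  expect_true(all(m$value_ng_m3 == 50))
  expect_true(!any(m$censored))

  high_lod <- tibble::tibble(zone = "North", species = "Zn", mean = 5, sd = 1,
                             lod = 1e6)
  m2 <- gen_concentrations(high_lod, n_days = 20, seed = 1)
  expect_true(all(m2$censored))

  bad <- tibble::tibble(zone = "North", species = "Zn", mean = 0, sd = 2)
  expect_error(gen_concentrations(bad, n_days = 5), class = "pm10risk_params_error")
})

test_that("moment matching recovers target mean and sd within 3 SE at n = 1e4", {
  targ <- tibble::tibble(zone = "North", species = "Cr(VI)",
                         mean = 104.16, sd = 66.28)
  n <- 1e4
  m <- gen_concentrations(targ, n_days = n, seed = 101)
  se_mean <- 66.28 / sqrt(n)
  expect_lt(abs(mean(m$value_ng_m3) - 104.16), 3 * se_mean)
  # sd standard error for a lognormal is inflated by its kurtosis; bound loosely
  expect_lt(abs(stats::sd(m$value_ng_m3) - 66.28), 0.1 * 66.28)
})

test_that("generation is deterministic under a seed, including written CSVs", {
  targ <- tibble::tibble(zone = c("North", "South"), species = c("Zn", "Cu"),
                         mean = c(50, 30), sd = c(10, 8))
  m1 <- gen_concentrations(targ, n_days = 30, seed = 7)
  m2 <- gen_concentrations(targ, n_days = 30, seed = 7)
  expect_identical(m1, m2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m1, f1); write_measurements(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- gen_trajectories(5, seed = 9)
  t2 <- gen_trajectories(5, seed = 9)
  expect_identical(t1, t2)
})

test_that("the correlation knob induces within-zone correlation on the log scale", {
  targ <- tibble::tibble(zone = "North", species = c("Zn", "Cu"),
                         mean = c(50, 30), sd = c(20, 12))
  m <- gen_concentrations(targ, n_days = 500, seed = 3, correlation = 0.8)
  cm <- correlation_matrix(m)
  expect_gt(cm$r["Zn", "Cu"], 0.5)
  m0 <- gen_concentrations(targ, n_days = 500, seed = 3, correlation = 0)
  cm0 <- correlation_matrix(m0)
  expect_lt(abs(cm0$r["Zn", "Cu"]), 0.2)
})

test_that("zero spread gives straight lines; easterly regime points tracks east", {
  tr <- gen_trajectories(3, prevailing_deg = 90, spread_deg = 0, seed = 1,
                         directions = "backward")
  one <- tr[tr$trajectory_id == tr$trajectory_id[1], ]
  # eastward geodesic stepping drifts latitude by ~1 km over a 1000 km path
  expect_lt(stats::sd(one$lat), 0.02)
  expect_true(all(diff(one$lon) < 0))             # arrives westward at receptor

  # mean bearing from the receptor to backward endpoints is east +/- 15 deg
  trs <- gen_trajectories(500, prevailing_deg = 90, spread_deg = 20, seed = 6,
                          directions = "backward")
  far <- trs[!duplicated(trs$trajectory_id), ]    # chronological start = far end
  brg <- geosphere::bearing(cbind(-72.67, 11.05), cbind(far$lon, far$lat))
  mean_brg <- (atan2(mean(sin(brg * pi / 180)), mean(cos(brg * pi / 180))) *
                 180 / pi) %% 360
  expect_lt(abs(mean_brg - 90), 15)
})

test_that("daily risk series scale linearly and preserve ordering of planted episodes", {
  targ <- tibble::tibble(zone = "North",
                         species = c("Cr(VI)", "As", "BaP", "IDP"),
                         mean = c(104, 45, 0.5, 2), sd = c(30, 10, 0.2, 0.5))
  m <- gen_concentrations(targ, n_days = 12, seed = 21)
  rd <- gen_risk_days(m)
  m2 <- m
  m2$value_ng_m3 <- 2 * m2$value_ng_m3
  rd2 <- gen_risk_days(m2)
  expect_equal(rd2$CR, 2 * rd$CR)
  expect_equal(rd2$ILCR, 2 * rd$ILCR)
  expect_equal(rd2$HI, 2 * rd$HI)
})

test_that("planted 5x episode days are exactly the days above the 75th percentile", {
  targ <- tibble::tibble(zone = "North", species = c("Cr(VI)", "BaP"),
                         mean = c(104, 0.5), sd = c(20, 0.1))
  n_days <- 40
  m <- gen_concentrations(targ, n_days = n_days, seed = 33)
  episode_days <- sort(unique(m$date))[c(3, 7, 11, 15, 19, 23, 27, 31, 35, 39)]
  idx <- m$date %in% episode_days
  m$value_ng_m3[idx] <- 5 * m$value_ng_m3[idx]
  rd <- gen_risk_days(m)
  thr <- stats::quantile(rd$CR, 0.75, type = 7, names = FALSE)
  selected <- rd$date[rd$CR >= thr]
  # 10 planted episodes = exactly the top quartile of 40 days
  expect_setequal(as.character(selected), as.character(episode_days))
})
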