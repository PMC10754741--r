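test_that("Igeo boundaries, classes and unit discipline behave as specified", {
  b <- 20
  expect_equal(igeo(1.5 * b, b)$igeo, 0)
  expect_equal(as.character(igeo(1.5 * b, b)$pollution_class), "none")
  expect_equal(igeo(3 * b, b)$igeo, 1)
  expect_equal(as.character(igeo(3 * b, b)$pollution_class), "unpolluted_to_moderate")
  expect_equal(as.character(igeo_class(1.08)), "moderate")
  expect_equal(as.character(igeo_class(c(-2, 0.5, 2.5, 3.5, 4.5, 6))),
               c("none", "unpolluted_to_moderate", "moderate_to_heavy",
                 "heavy", "heavy_to_extreme", "extreme"))
  expect_warning(res <- igeo(10, NA_real_), "Background")
  expect_true(is.na(res$igeo))
  expect_error(igeo(10, 5, unit = "ng_m3", background_unit = "mg_kg"),
               class = "pm10risk_unit_error")
})

test_that("Igeo is increasing in concentration and invariant to joint rescaling", {
  cs <- sort(stats::runif(10, 1, 100))
  ig <- igeo(cs, 10)$igeo
  expect_true(all(diff(ig) > 0))
  for (k in c(0.1, 2, 7)) {
    expect_equal(igeo(k * 50, k * 10)$igeo, igeo(50, 10)$igeo)
  }
  # class assignment is a monotone step function of igeo
  xs <- sort(stats::runif(50, -3, 7))
  expect_true(!is.unsorted(as.integer(igeo_class(xs))))
})

test_that("diagnostic ratios average daily ratios and label sources", {
  m <- make_panel(list(Ant = c(2, 4, 6), Phe = c(2, 4, 6)))
  r <- diagnostic_ratios(m)
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, 0)
  expect_equal(r$source_label, "pyrogenic")

  m2 <- make_panel(list(FR = c(0, 0, 0), Pyr = c(1, 2, 3)))
  r2 <- diagnostic_ratios(m2)
  expect_equal(r2$mean, 0)
  expect_equal(r2$source_label, "petroleum/mixed")

  # a day with a zero denominator is omitted and counted
  m3 <- make_panel(list(BbF = c(1, 0, 3), BkF = c(1, 0, 1)))
  r3 <- diagnostic_ratios(m3)
  expect_equal(r3$n_days, 2)
  expect_equal(r3$n_omitted, 1)
  expect_equal(r3$mean, mean(c(0.5, 0.75)))
  expect_equal(r3$source_label, "diesel-influenced")
})

test_that("generator-drawn congener days recover a target ratio within 3 SE", {
  # Ant and Phe drawn so that the daily Ant/(Ant+Phe) ratio centres near 0.47
  n <- 400
  targ <- tibble::tibble(zone = "North", species = c("Ant", "Phe"),
                         mean = c(0.47, 0.52), sd = c(0.10, 0.12))
  m <- gen_concentrations(targ, n_days = n, seed = 5)
  r <- diagnostic_ratios(m)
  expect_lt(abs(r$mean - 0.47 / (0.47 + 0.52)), 3 * r$sd / sqrt(n) + 0.02)
  expect_true(all(r$mean >= 0 & r$mean <= 1))
})

test_that("composition fractions sum to 100 and reproduce hand-summed shares", {
  two <- tibble::tibble(zone = "North", species = c("Zn", "Cu"), mean = c(5, 5))
  f <- composition_fractions(two)
  expect_equal(f$fraction_pct, c(50, 50))

  met <- composition_fractions(campaign_zone_summary("metals"))
  for (z in unique(met$zone)) {
    expect_equal(sum(met$fraction_pct[met$zone == z]), 100)
  }
  al_n <- met$fraction_pct[met$zone == "North" & met$species == "Al"]
  expect_equal(al_n, 82.76833, tolerance = 1e-5)

  pah <- composition_fractions(campaign_zone_summary("pahs"))
  idp_s <- pah$fraction_pct[pah$zone == "South" & pah$species == "IDP"]
  expect_equal(idp_s, 27.21154, tolerance = 1e-5)

  expect_error(composition_fractions(two[1, ]), class = "pm10risk_validation_error")
  zero <- tibble::tibble(zone = "North", species = c("Zn", "Cu"), mean = c(0, 0))
  expect_error(composition_fractions(zero), class = "pm10risk_validation_error")
})

test_that("exceedance factors recover regulatory multiples", {
  expect_equal(exceedance_factor(12, 12), 1)
  expect_equal(round(exceedance_factor(104.16, 12), 1), 8.7)
  expect_equal(exceedance_factor(66.03, 12), 5.5025)
  expect_error(exceedance_factor(10, 0), class = "pm10risk_validation_error")
})

test_that("correlation matrices are symmetric with unit diagonal and exact poles", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- make_panel(list(Zn = x, Cu = x, Pb = max(x) + 1 - x))
  cm <- correlation_matrix(m)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["Zn", "Cu"], 1)
  expect_equal(cm$r["Zn", "Pb"], -1)
  # constant series gives an NA cell
  m2 <- make_panel(list(Zn = x, Cu = rep(2, length(x))))
  cm2 <- correlation_matrix(m2)
  expect_true(is.na(cm2$r["Zn", "Cu"]))
})

test_that("independent series rarely exceed |r| = 0.3 at n = 100", {
  set.seed(99)
  hits <- 0
  for (i in 1:40) {
    m <- make_panel(list(Zn = stats::rlnorm(100), Cu = stats::rlnorm(100)))
    cm <- correlation_matrix(m)
    if (abs(cm$r["Zn", "Cu"]) < 0.3) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})
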