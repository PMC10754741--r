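#' Generate synthetic daily speciated concentrations
#'
#' Draws daily species concentrations from lognormal distributions
#' moment-matched to per-(zone, species) target arithmetic means and
#' standard deviations - the right-skewed, non-negative shape typical of
#' daily speciated PM10 data. Draws below the species' limit of detection
#' are flagged censored (the drawn value is retained so round-trips are
#' exact; censoring policies are applied at summary time). With `sd = 0`
#' the series is constant at the mean. Optionally, a Gaussian copula on
#' the log scale induces a common correlation across species within a
#' zone-day, for exercising correlation analyses. Deterministic under
#' `seed`.
#'
#' @param targets Tibble with `zone`, `species`, `mean`, `sd` (ng/m3) and
#'   optionally `lod` (ng/m3, default 0 = nothing censored), e.g. from
#'   [campaign_zone_summary()].
#' @param n_days Number of consecutive sampling days.
#' @param start_date First sampling day.
#' @param seed Integer seed.
#' @param site_prefix Prefix for the generated one-site-per-zone ids.
#' @param correlation Optional common pairwise correlation (Gaussian, log
#'   scale) across species within a zone; 0 = independent.
#' @return A measurement tibble (see [read_measurements()]).
#' @export
#' @examples
#' targets <- tibble::tibble(zone = "North", species = "Cr(VI)",
#'                           mean = 104.16, sd = 66.28, lod = 10)
#' m <- gen_concentrations(targets, n_days = 50, seed = 1)
#' mean(m$value_ng_m3)
gen_concentrations <- function(targets, n_days,
                               start_date = as.Date("2022-02-01"),
                               seed = 1L, site_prefix = "SYN",
                               correlation = 0) {
  targets <- as_tibble(targets)
  assert_species(targets$species)
  assert_zone(targets$zone)
  if (!"lod" %in% names(targets)) targets$lod <- 0
  targets$lod[is.na(targets$lod)] <- 0
  if (n_days < 1) abort("n_days must be >= 1", class = "pm10risk_params_error")
  if (any(targets$mean < 0) || any(targets$sd < 0) || any(targets$lod < 0)) {
    abort("Targets (mean, sd, lod) must be >= 0", class = "pm10risk_params_error")
  }
  if (any(targets$mean == 0 & targets$sd > 0)) {
    abort("A zero-mean target cannot have sd > 0", class = "pm10risk_params_error")
  }
  if (abs(correlation) >= 1) {
    abort("correlation must be in (-1, 1)", class = "pm10risk_params_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  dates <- start_date + seq_len(n_days) - 1
  zones <- unique(targets$zone)
  out <- purrr::map_dfr(zones, function(z) {
    tz <- targets[targets$zone == z, ]
    k <- nrow(tz)
    # Common-factor Gaussian copula on the log scale (equicorrelation).
    zmat <- if (correlation > 0) {
      f <- rnorm(n_days)
      sqrt(correlation) * matrix(f, n_days, k) +
        sqrt(1 - correlation) * matrix(rnorm(n_days * k), n_days, k)
    } else {
      matrix(rnorm(n_days * k), n_days, k)
    }
    purrr::map_dfr(seq_len(k), function(s) {
      mu <- tz$mean[s]; sg <- tz$sd[s]
      vals <- if (mu == 0) rep(0, n_days)
              else if (sg == 0) rep(mu, n_days)
              else {
                lp <- lnorm_moments(mu, sg)
                exp(lp$meanlog + lp$sdlog * zmat[, s])
              }
      tibble(
        site_id = paste0(site_prefix, "_", z),
        zone = z,
        date = dates,
        species = tz$species[s],
        value_ng_m3 = vals,
        censored = vals < tz$lod[s]
      )
    })
  })
  validate_measurements(out)
}

#' Generate synthetic forward/backward trajectory bundles
#'
#' Correlated random walks emulating air-mass trajectories around a
#' receptor under a prevailing wind. `prevailing_deg` is the meteorological
#' wind direction (degrees the wind blows FROM; 90 = easterly). Backward
#' trajectories extend upwind from the receptor (towards where the air came
#' from), forward trajectories downwind; each step heading is the
#' appropriate bearing plus Gaussian jitter of `spread_deg`, at fixed
#' `speed_kmh` over `interval_h` hours per step, one track per day and
#' direction. Deterministic under `seed`.
#'
#' @param n_days Number of consecutive days (one arrival/departure per day).
#' @param receptor_lat,receptor_lon Receptor position, decimal degrees.
#' @param prevailing_deg Prevailing wind direction (degrees FROM, default
#'   90: easterly, the prevailing regime at the mine).
#' @param spread_deg Angular jitter sd per step, degrees.
#' @param speed_kmh Transport speed, km/h.
#' @param n_points Endpoints per trajectory (including the receptor).
#' @param interval_h Hours between endpoints (default 12).
#' @param start_date Date of the first track.
#' @param directions Which of `"backward"`, `"forward"` to generate.
#' @param seed Integer seed.
#' @return A trajectory tibble (see [read_trajectories()]); backward
#'   trajectories are stored in chronological order, arriving at the
#'   receptor at their final point.
#' @export
gen_trajectories <- function(n_days, receptor_lat = 11.05, receptor_lon = -72.67,
                             prevailing_deg = 90, spread_deg = 20,
                             speed_kmh = 15, n_points = 7, interval_h = 12,
                             start_date = as.Date("2022-02-01"),
                             directions = c("backward", "forward"),
                             seed = 1L) {
  directions <- match.arg(directions, several.ok = TRUE)
  if (spread_deg < 0) abort("spread_deg must be >= 0", class = "pm10risk_params_error")
  if (speed_kmh <= 0 || interval_h <= 0 || n_points < 2 || n_days < 1) {
    abort("Need speed_kmh > 0, interval_h > 0, n_points >= 2, n_days >= 1",
          class = "pm10risk_params_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  step_m <- speed_kmh * interval_h * 1000
  out <- purrr::map_dfr(seq_len(n_days), function(d) {
    day0 <- as.POSIXct(paste(start_date + d - 1, "00:00:00"), tz = "UTC")
    purrr::map_dfr(directions, function(dir) {
      base_bearing <- if (dir == "backward") prevailing_deg
                      else (prevailing_deg + 180) %% 360
      pos <- matrix(c(receptor_lon, receptor_lat), nrow = 1)
      for (s in seq_len(n_points - 1)) {
        brg <- base_bearing + rnorm(1, 0, spread_deg)
        pos <- rbind(pos, geosphere::destPoint(pos[nrow(pos), ], brg, step_m))
      }
      # Backward: walked upwind from the receptor; chronologically the air
      # travels from the far point to the receptor.
      if (dir == "backward") pos <- pos[rev(seq_len(n_points)), , drop = FALSE]
      tibble(
        trajectory_id = sprintf("T%03d_%s", d, substr(dir, 1, 1)),
        direction = dir,
        timestamp = day0 + (seq_len(n_points) - 1) * interval_h * 3600,
        lat = pos[, 2],
        lon = pos[, 1]
      )
    })
  })
  validate_trajectories(out)
}

#' Daily risk series from synthetic (or measured) daily concentrations
#'
#' Computes, per zone and day, the deterministic risk metrics that drive
#' CPF mapping: the metals hazard index HI (summed HQ over species with an
#' RfC), the summed metals cancer risk CR (over species with an IUR), and
#' the PAH ILCR from the day's TEQ. Exposure parameters are held at the
#' deterministic preset; censored records are substituted per `policy`.
#'
#' @param measurements Daily measurement tibble.
#' @param params An [exposure_params()] object.
#' @param toxicity A [toxicity_table()].
#' @param policy A [censor_policy()].
#' @return Tibble `zone, date, HI, CR, ILCR` (metrics `NA` where the day
#'   has no species with the needed toxicity field).
#' @export
gen_risk_days <- function(measurements, params = exposure_params(),
                          toxicity = toxicity_table(),
                          policy = censor_policy("zero")) {
  m <- validate_measurements(measurements)
  m <- apply_censor_policy(m, policy)
  tox <- toxicity
  m <- m %>%
    left_join(tox[, c("species", "RfC_mg_m3", "IUR_per_ug_m3", "TEF")],
              by = "species") %>%
    mutate(
      EC = exposure_concentration(.data$value_ng_m3 / 1000, params),
      hq = ifelse(is.na(.data$RfC_mg_m3), NA_real_,
                  .data$EC / (.data$RfC_mg_m3 * params$CF)),
      cr = ifelse(is.na(.data$IUR_per_ug_m3), NA_real_,
                  .data$EC * .data$IUR_per_ug_m3),
      teq_i = .data$value_ng_m3 * .data$TEF
    )
  sf <- tox$SF_per_mg_kg_day[tox$species == "BaP"]
  daily <- m %>%
    group_by(.data$zone, .data$date) %>%
    summarise(
      HI = if (all(is.na(.data$hq))) NA_real_ else sum(.data$hq, na.rm = TRUE),
      CR = if (all(is.na(.data$cr))) NA_real_ else sum(.data$cr, na.rm = TRUE),
      TEQ = if (all(is.na(.data$teq_i))) NA_real_ else sum(.data$teq_i, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(ILCR = .data$TEQ * sf * params$IR * params$EF * params$ED * 1e-6 /
             (params$BW * params$AT)) %>%
    select("zone", "date", "HI", "CR", "ILCR")
  daily
}
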