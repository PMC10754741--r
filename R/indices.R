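#' Geo-accumulation index
#'
#' Muller's pollution index, `Igeo = log2(C / (1.5 * B))`, comparing a
#' measured concentration against 1.5 times the geochemical background `B`.
#' Both sides must be supplied in the same declared unit: the operation
#' refuses mixed units rather than guessing a conversion. The seven ordered
#' pollution classes are: none (Igeo <= 0), unpolluted-to-moderate (0, 1],
#' moderate (1, 2], moderate-to-heavy (2, 3], heavy (3, 4],
#' heavy-to-extreme (4, 5], extreme (> 5).
#'
#' @param c Concentration (vectorised); must be > 0.
#' @param background Background value in the same unit as `c`; `NA` yields
#'   an `NA` index with a warning (e.g. no regional background for Al).
#' @param unit Declared unit string, recorded on the output; both inputs
#'   are asserted to share it.
#' @param background_unit Unit of `background` (defaults to `unit`).
#' @return A tibble `igeo, pollution_class` with attribute `unit` and
#'   `background` echoing the inputs used.
#' @export
#' @examples
#' igeo(104.16, 33)  # moderate pollution
igeo <- function(c, background, unit = "ng_m3", background_unit = unit) {
  if (!identical(unit, background_unit)) {
    abort(paste0("Igeo refuses mixed units: concentration in ", unit,
                 " vs background in ", background_unit,
                 "; harmonize them explicitly"),
          class = "pm10risk_unit_error")
  }
  if (any(c <= 0, na.rm = TRUE)) {
    abort("Igeo needs strictly positive concentrations",
          class = "pm10risk_validation_error")
  }
  if (any(background <= 0, na.rm = TRUE)) {
    abort("Igeo needs strictly positive backgrounds where present",
          class = "pm10risk_validation_error")
  }
  if (anyNA(background)) {
    warn("Background missing for some entries: Igeo reported as NA")
  }
  ig <- log2(c / (1.5 * background))
  out <- tibble(igeo = ig, pollution_class = igeo_class(ig))
  attr(out, "unit") <- unit
  attr(out, "background") <- background
  out
}

#' Pollution class from an Igeo value
#'
#' @param ig Numeric Igeo values.
#' @return Ordered factor over the seven Muller classes.
#' @export
igeo_class <- function(ig) {
  labels <- c("none", "unpolluted_to_moderate", "moderate",
              "moderate_to_heavy", "heavy", "heavy_to_extreme", "extreme")
  cut(ig, breaks = c(-Inf, 0, 1, 2, 3, 4, 5, Inf), labels = labels,
      right = TRUE, ordered_result = TRUE)
}

#' PAH diagnostic source ratios
#'
#' Computes the three congener-pair diagnostic ratios per day -
#' Ant/(Ant+Phe), FR/(FR+Pyr), BbF/(BbF+BkF) - then averages the daily
#' ratios per zone (mean of daily ratios, not ratio of means) and labels
#' the likely emission-source type from the zone mean: Ant/(Ant+Phe) > 0.10
#' pyrogenic (else petrogenic); FR/(FR+Pyr) > 0.60 biomass/coal combustion
#' (else petroleum/mixed); BbF/(BbF+BkF) > 0.50 diesel-influenced (else
#' gasoline/mixed). Days where a denominator is zero or a congener is
#' absent are omitted, with the omission count reported.
#'
#' @param measurements Daily measurement tibble (see [read_measurements()]);
#'   censored records are excluded.
#' @return A tibble `zone, ratio_name, mean, sd, n_days, n_omitted,
#'   source_label`.
#' @export
diagnostic_ratios <- function(measurements) {
  m <- validate_measurements(measurements)
  m <- m[!m$censored & m$species %in% c("Ant", "Phe", "FR", "Pyr", "BbF", "BkF"), ]
  wide <- m %>%
    tidyr::pivot_wider(id_cols = c("zone", "site_id", "date"),
                       names_from = "species", values_from = "value_ng_m3")
  for (sp in c("Ant", "Phe", "FR", "Pyr", "BbF", "BkF")) {
    if (!sp %in% names(wide)) wide[[sp]] <- NA_real_
  }
  defs <- list(
    list(name = "Ant/(Ant+Phe)", num = "Ant", other = "Phe",
         cut = 0.10, above = "pyrogenic", below = "petrogenic"),
    list(name = "FR/(FR+Pyr)", num = "FR", other = "Pyr",
         cut = 0.60, above = "biomass/coal combustion", below = "petroleum/mixed"),
    list(name = "BbF/(BbF+BkF)", num = "BbF", other = "BkF",
         cut = 0.50, above = "diesel-influenced", below = "gasoline/mixed")
  )
  purrr::map_dfr(defs, function(d) {
    num <- wide[[d$num]]
    den <- wide[[d$num]] + wide[[d$other]]
    ok <- !is.na(den) & den > 0
    per_day <- tibble(zone = wide$zone, ok = ok,
                      ratio = ifelse(ok, num / den, NA_real_))
    per_day %>%
      group_by(.data$zone) %>%
      summarise(mean = mean(.data$ratio[.data$ok]),
                sd = stats::sd(.data$ratio[.data$ok]),
                n_days = sum(.data$ok),
                n_omitted = sum(!.data$ok),
                .groups = "drop") %>%
      filter(.data$n_days > 0) %>%
      mutate(
        ratio_name = d$name,
        sd = ifelse(is.na(.data$sd), 0, .data$sd),
        source_label = as.character(ifelse(.data$mean > d$cut, d$above, d$below))
      ) %>%
      select("zone", "ratio_name", "mean", "sd", "n_days", "n_omitted",
             "source_label")
  })
}

#' Compositional mass fractions of zone means
#'
#' Each species' percentage of the summed zone means,
#' `fraction_i = 100 * mean_i / sum(means)`, computed per zone over the
#' requested species set.
#'
#' @param zone_summaries Tibble with `zone`, `species`, `mean`.
#' @param species_set Species to include (default: all present).
#' @return A tibble `zone, species, mean, fraction_pct`; fractions sum to
#'   100 within each zone.
#' @export
#' @examples
#' f <- composition_fractions(campaign_zone_summary("metals"))
#' f[f$species == "Al", ]
composition_fractions <- function(zone_summaries, species_set = NULL) {
  zs <- as_tibble(zone_summaries)
  assert_species(zs$species)
  if (!is.null(species_set)) zs <- zs[zs$species %in% species_set, ]
  if (length(unique(zs$species)) < 2) {
    abort("composition_fractions needs at least 2 species",
          class = "pm10risk_validation_error")
  }
  out <- zs %>%
    group_by(.data$zone) %>%
    mutate(total = sum(.data$mean)) %>%
    ungroup()
  if (any(out$total <= 0)) {
    abort("Zone totals must be positive to form fractions",
          class = "pm10risk_validation_error")
  }
  out %>%
    mutate(fraction_pct = 100 * .data$mean / .data$total) %>%
    select("zone", "species", "mean", "fraction_pct")
}

#' Exceedance factor against a regulatory limit
#'
#' @param mean Zone mean concentration (vectorised), same unit as `limit`.
#' @param limit Regulatory limit (> 0), e.g. the 12 ng/m3 US-EPA limit for
#'   airborne Cr(VI).
#' @return `mean / limit`.
#' @export
#' @examples
#' exceedance_factor(104.16, 12)
exceedance_factor <- function(mean, limit) {
  if (any(limit <= 0)) abort("limit must be > 0", class = "pm10risk_validation_error")
  if (any(mean < 0, na.rm = TRUE)) {
    abort("mean must be >= 0", class = "pm10risk_validation_error")
  }
  mean / limit
}

#' Pearson correlation matrix across species
#'
#' Pairs daily values per (site, date) across a species set and computes
#' the Pearson correlation matrix with two-sided p-values. Pairs with
#' fewer than `min_pairs` complete days, or with a constant series, give
#' `NA` cells.
#'
#' @param measurements Daily measurement tibble; censored records excluded.
#' @param species_set Species to correlate (default: all present).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return A list with matrices `r` (unit diagonal) and `p`, plus `n`
#'   (pair counts).
#' @export
correlation_matrix <- function(measurements, species_set = NULL, min_pairs = 3) {
  m <- validate_measurements(measurements)
  m <- m[!m$censored, ]
  if (!is.null(species_set)) {
    assert_species(species_set)
    m <- m[m$species %in% species_set, ]
  }
  wide <- m %>%
    tidyr::pivot_wider(id_cols = c("site_id", "date"),
                       names_from = "species", values_from = "value_ng_m3")
  sp <- setdiff(names(wide), c("site_id", "date"))
  k <- length(sp)
  r <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
  p <- r
  n <- matrix(0L, k, k, dimnames = list(sp, sp))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      x <- wide[[sp[i]]]; y <- wide[[sp[j]]]
      ok <- complete.cases(x, y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) { r[i, i] <- 1; p[i, i] <- 0; next }
      if (sum(ok) < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}
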