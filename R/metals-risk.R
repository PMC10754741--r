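#' Hexavalent chromium from total chromium
#'
#' In coal-mining atmospheres the hexavalent fraction of particulate
#' chromium is conventionally estimated as one-seventh of total Cr.
#'
#' @param c_total_cr Total chromium concentration, ng/m3 (vectorised).
#' @return Cr(VI) concentration, ng/m3.
#' @export
#' @examples
#' chromium_vi(729.12)
chromium_vi <- function(c_total_cr) {
  if (!is.numeric(c_total_cr) || any(is.na(c_total_cr)) || any(c_total_cr < 0)) {
    abort("Total Cr concentration must be numeric and >= 0",
          class = "pm10risk_validation_error")
  }
  c_total_cr / 7
}

#' Exposure concentration (inhalation)
#'
#' Time-weighted exposure concentration
#' `EC = C * ET * EF * ED / AT_n`, the airborne concentration averaged over
#' the exposure scenario. With continuous exposure (`ET*EF*ED = AT_n`)
#' EC equals the ambient concentration; otherwise EC < C.
#'
#' @param c Ambient concentration, ug/m3 (vectorised).
#' @param params An [exposure_params()] object.
#' @return EC in ug/m3.
#' @export
exposure_concentration <- function(c, params = exposure_params()) {
  validate_exposure_params(params)
  if (any(c < 0, na.rm = TRUE)) {
    abort("Concentration must be >= 0", class = "pm10risk_validation_error")
  }
  c * params$ET * params$EF * params$ED / params$AT_n
}

#' Hazard quotient
#'
#' `HQ = EC / (RfC * CF)` with RfC in mg/m3 and CF converting ug to mg
#' (default 1000 ug/mg). HQ > 1 flags potential non-cancer exposure risk.
#'
#' @param ec Exposure concentration, ug/m3 (vectorised).
#' @param rfc Chronic inhalation reference concentration, mg/m3. `NA`
#'   propagates to an `NA` HQ with a warning (never a silent zero).
#' @param cf Conversion factor, ug/mg.
#' @return HQ (dimensionless).
#' @export
hazard_quotient <- function(ec, rfc, cf = 1000) {
  if (any(cf <= 0)) abort("CF must be > 0", class = "pm10risk_validation_error")
  if (any(ec < 0, na.rm = TRUE)) {
    abort("EC must be >= 0", class = "pm10risk_validation_error")
  }
  if (any(rfc <= 0, na.rm = TRUE)) {
    abort("RfC must be > 0 where present", class = "pm10risk_validation_error")
  }
  if (anyNA(rfc)) {
    warn("RfC missing for some species: HQ reported as NA")
  }
  ec / (rfc * cf)
}

#' Hazard index
#'
#' Sums per-species hazard quotients into the mixture hazard index
#' `HI = sum(HQ_i)` and reports each species' share of HI. HI > 1 signals
#' possible non-carcinogenic risk from the metal mixture.
#'
#' @param hqs Named numeric vector of per-species HQs; `NA` entries
#'   (species without an RfC) are excluded from the sum.
#' @return A list with `HI`, `contributions` (shares summing to 1 when
#'   HI > 0), `n_species`, and `flag` (`TRUE` when HI > 1).
#' @export
#' @examples
#' hazard_index(c(Cu = 0.5, As = 0.5, `Cr(VI)` = 1.0))
hazard_index <- function(hqs) {
  keep <- !is.na(hqs)
  if (!any(keep)) {
    abort("All HQ values are NA: nothing to sum", class = "pm10risk_validation_error")
  }
  hqs <- hqs[keep]
  hi <- sum(hqs)
  shares <- if (hi > 0) hqs / hi else rep(NA_real_, length(hqs))
  list(HI = hi, contributions = shares, n_species = length(hqs), flag = hi > 1)
}

#' Lifetime excess cancer risk for a metal
#'
#' `CR = EC * IUR`. Risk classes follow the conventional screening
#' thresholds: below 1e-6 negligible, within [1e-6, 1e-4] acceptable,
#' above 1e-4 likely harmful (boundaries assigned to the closed middle
#' interval).
#'
#' @param ec Exposure concentration, ug/m3 (vectorised).
#' @param iur Inhalation unit risk, per ug/m3; `NA` yields `NA` risk
#'   (species without an IUR are excluded from totals).
#' @return Numeric CR vector.
#' @export
cancer_risk <- function(ec, iur) {
  if (any(ec < 0, na.rm = TRUE) || any(iur < 0, na.rm = TRUE)) {
    abort("EC and IUR must be >= 0", class = "pm10risk_validation_error")
  }
  ec * iur
}

#' Classify a lifetime cancer risk value
#'
#' @param cr Numeric CR/ILCR values.
#' @param labels Length-3 character vector for the below/within/above
#'   classes.
#' @return Ordered factor of risk classes (`NA` in, `NA` out).
#' @export
#' @examples
#' classify_cancer_risk(c(1e-7, 1e-5, 2e-4))
classify_cancer_risk <- function(cr, labels = c("negligible", "acceptable", "likely_harmful")) {
  stopifnot(length(labels) == 3)
  out <- ifelse(is.na(cr), NA_character_,
         ifelse(cr < 1e-6, labels[1],
         ifelse(cr <= 1e-4, labels[2], labels[3])))
  factor(out, levels = labels, ordered = TRUE)
}

#' Deterministic metals risk table
#'
#' Runs the full deterministic inhalation risk chain for PM10-bound heavy
#' metals on zone summary statistics: ng/m3 means are converted to ug/m3,
#' propagated through [exposure_concentration()], [hazard_quotient()] and
#' [cancer_risk()], and classified. Species lacking an RfC get an `NA` HQ;
#' species lacking an IUR (Al, Zn, Cu, Mn) get an `NA` CR and are excluded
#' from zone totals.
#'
#' @param zone_summaries Tibble with `zone`, `species`, `mean` (ng/m3),
#'   e.g. from [summarize_zone()] or [campaign_zone_summary()].
#' @param params An [exposure_params()] object.
#' @param toxicity A [toxicity_table()].
#' @return A tibble `zone, species, c_ng_m3, EC_ug_m3, HQ, CR, cr_class`
#'   with the exposure parameters attached as attribute `params`.
#' @export
#' @examples
#' risk <- metals_risk(campaign_zone_summary("metals"))
#' zone_hazard_index(risk)
metals_risk <- function(zone_summaries, params = exposure_params(),
                        toxicity = toxicity_table()) {
  zs <- as_tibble(zone_summaries)
  assert_species(zs$species, "metals")
  assert_zone(zs$zone)
  validate_exposure_params(params)
  tox <- tibble(species = toxicity$species,
                RfC_mg_m3 = toxicity$RfC_mg_m3,
                IUR_per_ug_m3 = toxicity$IUR_per_ug_m3)
  out <- zs %>%
    select("zone", "species", c_ng_m3 = "mean") %>%
    left_join(tox, by = "species") %>%
    mutate(
      EC_ug_m3 = exposure_concentration(.data$c_ng_m3 / 1000, params),
      HQ = suppressWarnings(hazard_quotient(.data$EC_ug_m3, .data$RfC_mg_m3, params$CF)),
      CR = cancer_risk(.data$EC_ug_m3, .data$IUR_per_ug_m3),
      cr_class = classify_cancer_risk(.data$CR)
    ) %>%
    select("zone", "species", "c_ng_m3", "EC_ug_m3", "HQ", "CR", "cr_class")
  if (anyNA(out$HQ)) {
    warn(paste0("No RfC for: ",
                paste(unique(out$species[is.na(out$HQ)]), collapse = ", "),
                " - HQ reported as NA"))
  }
  attr(out, "params") <- unclass(params)
  out
}

#' Zone hazard index table
#'
#' Aggregates a [metals_risk()] table into one hazard index per zone with
#' per-species HQ shares.
#'
#' @param metal_risk Output of [metals_risk()].
#' @return A tibble `zone, HI, flag` with a `contributions` list-column of
#'   named share vectors.
#' @export
zone_hazard_index <- function(metal_risk) {
  metal_risk %>%
    group_by(.data$zone) %>%
    summarise(res = list(hazard_index(setNames(.data$HQ, .data$species))),
              .groups = "drop") %>%
    mutate(
      HI = vapply(.data$res, `[[`, numeric(1), "HI"),
      flag = vapply(.data$res, `[[`, logical(1), "flag"),
      contributions = lapply(.data$res, `[[`, "contributions")
    ) %>%
    select("zone", "HI", "flag", "contributions")
}
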