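#' BaP toxic-equivalent concentration (TEQ)
#'
#' Scales each PAH congener concentration to benzo[a]pyrene potency,
#' `TEQ_i = C_i * TEF_i`, and sums to `TEQ_total = sum(TEQ_i)`. Per-congener
#' percentage contributions to the total are reported alongside. A congener
#' without a TEF in the toxicity table is an explicit error: congeners are
#' never silently dropped from the mixture.
#'
#' @param concentrations Named numeric vector of PAH concentrations in
#'   ng/m3 (names are species codes), or a tibble with `species` and `mean`
#'   columns.
#' @param toxicity A [toxicity_table()] supplying the `TEF` column.
#' @return A tibble `species, c_ng_m3, TEF, TEQ_ng_m3, contribution_pct`
#'   with `TEQ_total` (ng/m3) attached as an attribute. When all
#'   concentrations are zero the contributions are undefined and reported
#'   as `NA`.
#' @export
#' @examples
#' pah <- campaign_zone_summary("pahs")
#' north <- pah[pah$zone == "North", ]
#' t <- teq(setNames(north$mean, north$species))
#' attr(t, "TEQ_total")
teq <- function(concentrations, toxicity = toxicity_table()) {
  if (is.data.frame(concentrations)) {
    concentrations <- setNames(concentrations$mean, concentrations$species)
  }
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    abort("Concentrations must be named by species", class = "pm10risk_validation_error")
  }
  assert_species(names(concentrations), "pahs")
  if (any(concentrations < 0)) {
    abort("Concentrations must be >= 0", class = "pm10risk_validation_error")
  }
  tef <- require_toxicity_field(toxicity, names(concentrations), "TEF", "teq")
  teq_i <- unname(concentrations) * tef
  total <- sum(teq_i)
  out <- tibble(
    species = names(concentrations),
    c_ng_m3 = unname(concentrations),
    TEF = tef,
    TEQ_ng_m3 = teq_i,
    contribution_pct = if (total > 0) 100 * teq_i / total else NA_real_
  )
  attr(out, "TEQ_total") <- total
  out
}

#' Incremental lifetime cancer risk from PAH exposure
#'
#' `ILCR = TEQ_total * SF * IR * EF * ED * 1e-6 / (BW * AT)` where the
#' 1e-6 factor converts the ng/m3 TEQ into the mg-based dose the slope
#' factor expects. Classes: acceptable below 1e-6, elevated within
#' [1e-6, 1e-4], high above 1e-4.
#'
#' @param teq_total BaP-equivalent concentration, ng/m3 (vectorised).
#' @param params An [exposure_params()] object (uses IR, EF, ED, BW, AT).
#' @param sf Cancer slope factor, per mg/kg/day (default: BaP inhalation
#'   slope factor from the shipped toxicity preset).
#' @return A tibble `ILCR, risk_class`.
#' @export
#' @examples
#' ilcr(0.909)
ilcr <- function(teq_total, params = exposure_params(),
                 sf = toxicity_table()$SF_per_mg_kg_day[
                   toxicity_table()$species == "BaP"]) {
  validate_exposure_params(params)
  if (any(teq_total < 0, na.rm = TRUE)) {
    abort("TEQ must be >= 0", class = "pm10risk_validation_error")
  }
  if (length(sf) != 1 || is.na(sf) || sf < 0) {
    abort("Slope factor must be a single non-negative number",
          class = "pm10risk_validation_error")
  }
  risk <- teq_total * sf * params$IR * params$EF * params$ED * 1e-6 /
    (params$BW * params$AT)
  tibble(
    ILCR = risk,
    risk_class = classify_cancer_risk(risk, c("acceptable", "elevated", "high"))
  )
}

#' Deterministic PAH risk tables per zone
#'
#' Computes the TEQ decomposition and the ILCR for every zone of a PAH
#' zone-summary table.
#'
#' @param zone_summaries Tibble with `zone`, `species`, `mean` (ng/m3).
#' @param params An [exposure_params()] object.
#' @param toxicity A [toxicity_table()] (TEF and BaP slope factor).
#' @return A list with `teq` (long tibble of per-zone congener TEQ and
#'   contribution) and `ilcr` (tibble `zone, TEQ_total, ILCR, risk_class`).
#' @export
#' @examples
#' res <- pah_risk(campaign_zone_summary("pahs"))
#' res$ilcr
pah_risk <- function(zone_summaries, params = exposure_params(),
                     toxicity = toxicity_table()) {
  zs <- as_tibble(zone_summaries)
  assert_species(zs$species, "pahs")
  assert_zone(zs$zone)
  sf <- toxicity$SF_per_mg_kg_day[toxicity$species == "BaP"]
  zones <- unique(zs$zone)
  teq_tbls <- lapply(zones, function(z) {
    sub <- zs[zs$zone == z, ]
    t <- teq(setNames(sub$mean, sub$species), toxicity)
    t$zone <- z
    t
  })
  ilcr_tbl <- purrr::map2_dfr(teq_tbls, zones, function(t, z) {
    total <- attr(t, "TEQ_total")
    res <- ilcr(total, params, sf)
    tibble(zone = z, TEQ_total = total, ILCR = res$ILCR, risk_class = res$risk_class)
  })
  out <- list(
    teq = bind_rows(teq_tbls) %>% select("zone", dplyr::everything()),
    ilcr = ilcr_tbl
  )
  attr(out, "params") <- unclass(params)
  out
}
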