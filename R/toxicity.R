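#' Toxicity and background reference table
#'
#' Per-species toxicity reference values used by the risk equations:
#' chronic inhalation reference concentration (RfC, mg/m3), inhalation unit
#' risk (IUR, per ug/m3), cancer slope factor (SF, per mg/kg/day),
#' benzo[a]pyrene toxic equivalency factor (TEF, dimensionless), and soil
#' background concentration (mg/kg) for the geo-accumulation index.
#'
#' The shipped preset combines EPA IRIS and California OEHHA inhalation
#' values for the metals, the Nisbet & LaGoy TEF scale for the PAH congeners
#' (triphenylene, a non-priority congener without a canonical TEF, defaults
#' to the chrysene-class value 0.01), and soil backgrounds representative of
#' Colombian surface soils. All values are overridable: pass a data frame of
#' replacements or read a config with [read_toxicity_table()]. A species
#' without a value for a field is `NA`; operations that require that field
#' either error or return `NA` with a warning, never a silent zero.
#'
#' @param overrides Optional data frame with a `species` column and any of
#'   `RfC_mg_m3`, `IUR_per_ug_m3`, `SF_per_mg_kg_day`, `TEF`,
#'   `background_mg_kg`; matching cells replace the preset.
#' @return A tibble with one row per registered species.
#' @export
#' @examples
#' tox <- toxicity_table()
#' tox[tox$species == "Cr(VI)", ]
toxicity_table <- function(overrides = NULL) {
  tox <- tibble(
    species = species_registry("all"),
    RfC_mg_m3 = NA_real_,
    IUR_per_ug_m3 = NA_real_,
    SF_per_mg_kg_day = NA_real_,
    TEF = NA_real_,
    background_mg_kg = NA_real_
  )
  set <- function(tbl, sp, field, value) {
    tbl[[field]][match(sp, tbl$species)] <- value
    tbl
  }
  # Inhalation RfC (mg/m3): IRIS / OEHHA chronic values; Al provisional.
  tox <- set(tox, c("Al", "Cr", "Cr(VI)", "Mn", "Cu", "As"),
             "RfC_mg_m3", c(5e-3, 1e-4, 1e-4, 5e-5, 1e-3, 1.5e-5))
  # Inhalation unit risk (per ug/m3); Al, Zn, Cu, Mn have none.
  tox <- set(tox, c("Cr", "Cr(VI)", "As", "Pb"),
             "IUR_per_ug_m3", c(1.2e-2, 1.2e-2, 4.3e-3, 1.2e-5))
  # BaP inhalation cancer slope factor (OEHHA), applied to the TEQ.
  tox <- set(tox, "BaP", "SF_per_mg_kg_day", 3.14)
  # Nisbet & LaGoy TEFs; Tri assigned the chrysene-class 0.01.
  pah <- species_registry("pahs")
  tef <- c(Nap = 0.001, Acy = 0.001, Ace = 0.001, Flu = 0.001, Phe = 0.001,
           Ant = 0.01, FR = 0.001, Pyr = 0.001, BaA = 0.1, Tri = 0.01,
           IDP = 0.1, BbF = 0.1, BaP = 1, BkF = 0.1)
  tox <- set(tox, pah, "TEF", unname(tef[pah]))
  # Soil backgrounds (mg/kg) representative of Colombian surface soils;
  # none available for Al in the study region.
  tox <- set(tox, c("Cr", "Cr(VI)", "Mn", "Cu", "Zn", "As", "Pb"),
             "background_mg_kg", c(33, 33, 500, 35, 65, 15, 10))
  if (!is.null(overrides)) {
    tox <- apply_toxicity_overrides(tox, overrides)
  }
  tox
}

apply_toxicity_overrides <- function(tox, overrides) {
  overrides <- as_tibble(overrides)
  if (!"species" %in% names(overrides)) {
    abort("Toxicity overrides need a 'species' column", class = "pm10risk_params_error")
  }
  assert_species(overrides$species)
  fields <- intersect(names(overrides), setdiff(names(tox), "species"))
  for (f in fields) {
    idx <- match(overrides$species, tox$species)
    keep <- !is.na(overrides[[f]])
    tox[[f]][idx[keep]] <- overrides[[f]][keep]
  }
  bad <- vapply(fields, function(f) any(tox[[f]] < 0, na.rm = TRUE), logical(1))
  if (any(bad)) {
    abort(paste0("Negative toxicity values in: ", paste(fields[bad], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  tox
}

#' Read a toxicity table from a YAML or JSON config
#'
#' The config maps species codes to unit-bearing keys (`RfC_mg_m3`,
#' `IUR_per_ug_m3`, `SF_per_mg_kg_day`, `TEF`, `background_mg_kg`), e.g.
#' `Cr(VI): {RfC_mg_m3: 1.0e-4, IUR_per_ug_m3: 1.2e-2}`. Values present in
#' the file override the shipped preset; everything else is retained.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A tibble as from [toxicity_table()].
#' @export
read_toxicity_table <- function(path) {
  cfg <- read_config_file(path)
  if (length(cfg) == 0) return(toxicity_table())
  rows <- purrr::imap(cfg, function(vals, sp) {
    tibble(species = sp, !!!vals)
  })
  toxicity_table(overrides = bind_rows(rows))
}

require_toxicity_field <- function(tox, species, field, op) {
  idx <- match(species, tox$species)
  if (anyNA(idx)) {
    abort(paste0(op, ": species missing from toxicity table: ",
                 paste(species[is.na(idx)], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  vals <- tox[[field]][idx]
  if (anyNA(vals)) {
    abort(paste0(op, ": no ", field, " available for: ",
                 paste(species[is.na(vals)], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  vals
}
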