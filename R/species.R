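#' Registered chemical species
#'
#' The package tracks seven PM10-bound heavy metals (with hexavalent chromium
#' derived from total chromium) and fourteen PAH congeners routinely
#' quantified by XRF and GC-MS speciation of high-volume filter samples.
#' All concentration tables are validated against this registry so that a
#' typo in a species code fails loudly instead of silently dropping rows.
#'
#' @param group One of `"all"`, `"metals"`, `"pahs"`.
#' @return Character vector of species codes.
#' @export
#' @examples
#' species_registry("metals")
species_registry <- function(group = c("all", "metals", "pahs")) {
  group <- match.arg(group)
  metals <- c("Al", "Cr", "Cr(VI)", "Mn", "Cu", "Zn", "As", "Pb")
  pahs <- c("Nap", "Acy", "Ace", "Flu", "Phe", "Ant", "FR", "Pyr",
            "BaA", "Tri", "IDP", "BbF", "BaP", "BkF")
  switch(group, all = c(metals, pahs), metals = metals, pahs = pahs)
}

#' Monitoring zones
#'
#' @return Character vector of the three monitoring zones around the mine.
#' @export
zone_levels <- function() c("North", "South", "Populated")

assert_species <- function(species, group = "all") {
  known <- species_registry(group)
  bad <- setdiff(unique(species), known)
  if (length(bad) > 0) {
    abort(paste0("Unknown species: ", paste(bad, collapse = ", "),
                 ". Registered species: ", paste(known, collapse = ", ")),
          class = "pm10risk_species_error")
  }
  invisible(species)
}

assert_zone <- function(zone) {
  bad <- setdiff(unique(as.character(zone)), zone_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown zone(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ", paste(zone_levels(), collapse = ", ")),
          class = "pm10risk_zone_error")
  }
  invisible(zone)
}
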