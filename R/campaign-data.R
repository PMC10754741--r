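#' Bundled zone summary statistics from an opencast coal-mine campaign
#'
#' Per-zone summary statistics (mean, standard deviation, maximum, minimum,
#' in ng/m3) of daily PM10-bound heavy metal and PAH concentrations measured
#' at eight high-volume sampling sites around Latin America's largest
#' opencast coal mine (La Guajira, Colombia; February-May 2022), grouped
#' into North, South and Populated zones. Below-detection minima (As and Pb)
#' are recorded as `NA`. Cr(VI) is the one-seventh-of-total-chromium
#' estimate (see [chromium_vi()]). These tables drive the worked examples
#' and supply realistic targets for the synthetic generator.
#'
#' @param group `"metals"` or `"pahs"`.
#' @return A tibble with columns `zone`, `species`, `mean`, `sd`, `max`,
#'   `min`, `n_days`.
#' @export
#' @examples
#' campaign_zone_summary("pahs")
campaign_zone_summary <- function(group = c("metals", "pahs")) {
  group <- match.arg(group)
  path <- system.file("extdata", paste0(group, "_zone_summary.csv"),
                      package = "pm10risk", mustWork = TRUE)
  out <- readr::read_csv(path, col_types = readr::cols(
    zone = readr::col_character(),
    species = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  assert_species(out$species, group)
  assert_zone(out$zone)
  out
}
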