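#' Read a speciated concentration table
#'
#' Reads daily speciated PM10 concentrations from a delimited text file with
#' columns `site_id, zone, date, species, value_ng_m3, censored` (ISO dates;
#' `censored` in {0, 1}, or the literal value `"BLD"` in `value_ng_m3` for a
#' below-detection record). Column names can be remapped through `schema`.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(value_ng_m3 = "conc")`.
#' @return A tibble of measurements with columns `site_id`, `zone`, `date`,
#'   `species`, `value_ng_m3`, `censored`.
#' @export
read_measurements <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Measurement file not found: ", path), class = "pm10risk_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  canonical <- c("site_id", "zone", "date", "species", "value_ng_m3", "censored")
  colmap <- setNames(canonical, canonical)
  if (!is.null(schema)) colmap[names(schema)] <- unname(schema)
  missing <- colmap[!colmap %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "pm10risk_schema_error")
  }
  out <- tibble(
    site_id = raw[[colmap["site_id"]]],
    zone = raw[[colmap["zone"]]],
    date = as.Date(raw[[colmap["date"]]]),
    species = raw[[colmap["species"]]],
    value_raw = raw[[colmap["value_ng_m3"]]],
    censored_raw = raw[[colmap["censored"]]]
  )
  bld <- toupper(trimws(out$value_raw)) %in% c("BLD", "ND", "<LOD")
  out$value_ng_m3 <- suppressWarnings(as.numeric(out$value_raw))
  out$value_ng_m3[bld] <- NA_real_
  out$censored <- bld | out$censored_raw %in% c("1", "TRUE", "true")
  validate_measurements(
    out[, c("site_id", "zone", "date", "species", "value_ng_m3", "censored")]
  )
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: round-tripping preserves site, zone,
#' date, species, value and censoring flag.
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  measurements <- validate_measurements(measurements)
  out <- measurements
  out$censored <- as.integer(out$censored)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_measurements <- function(m) {
  m <- as_tibble(m)
  needed <- c("site_id", "zone", "date", "species", "value_ng_m3", "censored")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "pm10risk_schema_error")
  }
  assert_species(m$species)
  assert_zone(m$zone)
  if (anyNA(m$date)) {
    abort("Unparseable dates in measurement table (expect ISO yyyy-mm-dd)",
          class = "pm10risk_schema_error")
  }
  bad <- which(!m$censored & (is.na(m$value_ng_m3) | m$value_ng_m3 < 0))
  if (length(bad) > 0) {
    abort(paste0("Non-censored rows must have a value >= 0; offending row(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  dup <- duplicated(m[, c("site_id", "date", "species")])
  if (any(dup)) {
    abort(paste0("Duplicate (site_id, date, species) record(s) at row(s): ",
                 paste(head(which(dup), 10), collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  m[, needed]
}

#' Censoring policy for below-detection values
#'
#' Below-detection (BLD) records carry no usable value; before computing
#' zone statistics they are substituted according to a policy. The default
#' substitutes LOD/2, the most common convention for left-censored
#' environmental data; alternatives substitute zero or omit the record.
#'
#' @param method One of `"half_lod"`, `"zero"`, `"omit"`.
#' @param lod Named numeric vector of per-species limits of detection in
#'   ng/m3 (required for `"half_lod"` whenever a censored record of that
#'   species is seen; LODs are instrument-specific and must be supplied by
#'   the user).
#' @return A `censor_policy` object.
#' @export
censor_policy <- function(method = c("half_lod", "zero", "omit"), lod = NULL) {
  method <- match.arg(method)
  if (!is.null(lod)) {
    if (is.null(names(lod)) || any(names(lod) == "")) {
      abort("lod must be a named numeric vector (names are species codes)",
            class = "pm10risk_params_error")
    }
    assert_species(names(lod))
    if (any(lod < 0)) abort("LODs must be >= 0", class = "pm10risk_params_error")
  }
  structure(list(method = method, lod = lod), class = "censor_policy")
}

apply_censor_policy <- function(m, policy) {
  cen <- m$censored
  if (!any(cen)) return(m)
  if (policy$method == "omit") {
    return(m[!cen, , drop = FALSE])
  }
  if (policy$method == "zero") {
    m$value_ng_m3[cen] <- 0
    return(m)
  }
  sp <- unique(m$species[cen])
  have <- sp %in% names(policy$lod)
  if (!all(have)) {
    abort(paste0("half_lod policy needs an LOD for censored species: ",
                 paste(sp[!have], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  m$value_ng_m3[cen] <- policy$lod[m$species[cen]] / 2
  m
}

#' Summarise daily measurements per zone and species
#'
#' Computes the per-zone, per-species mean, sample standard deviation
#' (n - 1 denominator), maximum, minimum and day count after substituting
#' censored values per `policy`. The policy used is recorded in the
#' `censor_policy` attribute of the result so downstream tables are
#' self-describing.
#'
#' @param measurements Measurement tibble (see [read_measurements()]).
#' @param policy A [censor_policy()]; default substitutes LOD/2 and
#'   therefore requires LODs whenever censored records are present.
#' @return A tibble with columns `zone`, `species`, `mean`, `sd`, `max`,
#'   `min`, `n_days` (all concentrations in ng/m3).
#' @export
#' @examples
#' m <- tibble::tibble(site_id = "ZN_01", zone = "North",
#'                     date = as.Date("2022-02-01") + 0:2,
#'                     species = "Zn", value_ng_m3 = c(1, 2, 3),
#'                     censored = FALSE)
#' summarize_zone(m)
summarize_zone <- function(measurements, policy = censor_policy()) {
  m <- validate_measurements(measurements)
  m <- apply_censor_policy(m, policy)
  if (nrow(m) == 0) {
    abort("No records remain after applying the censoring policy",
          class = "pm10risk_validation_error")
  }
  dropped <- dplyr::anti_join(
    distinct(validate_measurements(measurements), .data$zone, .data$species),
    distinct(m, .data$zone, .data$species),
    by = c("zone", "species")
  )
  if (nrow(dropped) > 0) {
    abort(paste0("All values censored under policy 'omit' for: ",
                 paste(paste(dropped$zone, dropped$species, sep = "/"), collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  out <- m %>%
    group_by(.data$zone, .data$species) %>%
    summarise(
      mean = mean(.data$value_ng_m3),
      sd = stats::sd(.data$value_ng_m3),
      max = max(.data$value_ng_m3),
      min = min(.data$value_ng_m3),
      n_days = dplyr::n_distinct(.data$date),
      .groups = "drop"
    ) %>%
    mutate(sd = ifelse(is.na(.data$sd), 0, .data$sd)) %>%
    arrange(factor(.data$zone, levels = zone_levels()), .data$species)
  attr(out, "censor_policy") <- policy$method
  out
}
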