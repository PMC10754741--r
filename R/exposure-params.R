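#' Exposure scenario parameters
#'
#' Builds the exposure-parameter set used by every risk equation. The default
#' preset is the EPA residential adult scenario: continuous exposure
#' (ET = 24 h/day, EF = 350 days/year) over ED = 30 years, averaged over a
#' 70-year lifetime, with an adult inhalation rate of 20 m3/day and body
#' weight 70 kg. Every risk output records the parameter set used so tables
#' are self-describing.
#'
#' @param ET Exposure time, hours per day.
#' @param EF Exposure frequency, days per year.
#' @param ED Exposure duration, years.
#' @param AT_n Averaging time for non-/cancer inhalation equations, hours
#'   (default 70 years expressed in hours).
#' @param AT Average lifespan, days (default 70 years expressed in days).
#' @param IR Inhalation rate, m3 per day.
#' @param BW Body weight, kg.
#' @param CF Conversion factor, ug per mg (used in the hazard quotient).
#' @return An object of class `exposure_params` (a validated named list).
#' @export
#' @examples
#' p <- exposure_params()
#' p$AT_n / (24 * 365) # averaging lifetime in years
exposure_params <- function(ET = 24, EF = 350, ED = 30,
                            AT_n = 70 * 365 * 24, AT = 70 * 365,
                            IR = 20, BW = 70, CF = 1000) {
  p <- list(ET = ET, EF = EF, ED = ED, AT_n = AT_n, AT = AT,
            IR = IR, BW = BW, CF = CF)
  validate_exposure_params(p)
  structure(p, class = "exposure_params")
}

validate_exposure_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("Exposure parameters must be finite numeric scalars; bad: ",
                 paste(names(p)[!num], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  pos <- vapply(p, function(x) x > 0, logical(1))
  if (!all(pos)) {
    abort(paste0("Exposure parameters must be strictly positive; bad: ",
                 paste(names(p)[!pos], collapse = ", ")),
          class = "pm10risk_params_error")
  }
  if (p$ET > 24) abort("ET cannot exceed 24 h/day", class = "pm10risk_params_error")
  if (p$EF > 366) abort("EF cannot exceed 366 days/year", class = "pm10risk_params_error")
  if (p$ET * p$EF * p$ED > p$AT_n) {
    abort("ET * EF * ED must not exceed AT_n (exposure cannot exceed the averaging time)",
          class = "pm10risk_params_error")
  }
  invisible(p)
}

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure parameters (inhalation scenario)\n")
  cat(sprintf("  ET  %6g h/day    EF %6g days/yr   ED %6g yr\n", x$ET, x$EF, x$ED))
  cat(sprintf("  AT_n %.0f h   AT %.0f days\n", x$AT_n, x$AT))
  cat(sprintf("  IR  %6g m3/day   BW %6g kg        CF %6g ug/mg\n", x$IR, x$BW, x$CF))
  invisible(x)
}

#' Read exposure parameters from a YAML or JSON config file
#'
#' Recognised keys are `ET`, `EF`, `ED`, `AT_n`, `AT`, `IR`, `BW`, `CF`;
#' missing keys fall back to the residential-adult preset of
#' [exposure_params()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `exposure_params` object.
#' @export
read_exposure_params <- function(path) {
  cfg <- read_config_file(path)
  keys <- intersect(names(cfg), names(formals(exposure_params)))
  do.call(exposure_params, cfg[keys])
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "pm10risk_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort(paste0("Unsupported config format '.", ext, "' (expected YAML or JSON)"),
          class = "pm10risk_io_error")
  }
}
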