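#' Run the end-to-end risk analysis pipeline
#'
#' Orchestrates the full analysis on a config: zone summaries from daily
#' measurements (or pre-summarised tables), compositional fractions and
#' geo-accumulation indices, deterministic metals and PAH risk, Monte
#' Carlo uncertainty, and - when trajectories and a receptor grid are
#' configured - CPF risk mapping. Optional stages missing their inputs are
#' skipped with a logged warning, never silently. All stage outputs are
#' written as CSV under `out_dir` together with a JSON run manifest
#' (config hash, seed, input digests, package version, timestamp), so a
#' run is a pure function of (inputs, config, seed).
#'
#' @param config A named list (or path to a YAML/JSON file) with elements:
#'   `measurements` (path to a daily concentration CSV) or `metal_summary`
#'   / `pah_summary` (paths to summary CSVs; default: the bundled campaign
#'   tables); optional `params` (list of exposure-parameter overrides),
#'   `toxicity` (path to a toxicity config), `lod` (named list of
#'   per-species LODs, ng/m3), `censor_method`, `mc` (list with
#'   `n_iterations`), `cpf` (list with `trajectories` path, `grid` =
#'   list(origin_lat, origin_lon, cell_km, n_rows, n_cols), `metric` in
#'   HI/CR/ILCR, `threshold_pct`), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the stage outputs plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config_file(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  params <- do.call(exposure_params, config$params %||% list())
  toxicity <- if (!is.null(config$toxicity)) read_toxicity_table(config$toxicity)
              else toxicity_table()
  log_stage <- function(stage, msg) {
    message(sprintf("[pm10risk] %-12s %s", stage, msg))
  }
  inputs <- character()
  outputs <- list()

  # --- zone summaries ---------------------------------------------------
  if (!is.null(config$measurements)) {
    meas <- read_measurements(config$measurements)
    inputs <- c(inputs, measurements = config$measurements)
    lod <- unlist(config$lod %||% list())
    pol <- censor_policy(config$censor_method %||% "half_lod",
                         lod = if (length(lod)) lod else NULL)
    zs <- summarize_zone(meas, pol)
    metal_summary <- zs[zs$species %in% species_registry("metals"), ]
    pah_summary <- zs[zs$species %in% species_registry("pahs"), ]
    log_stage("summarize", sprintf("%d records -> %d zone-species summaries",
                                   nrow(meas), nrow(zs)))
  } else {
    meas <- NULL
    metal_summary <- if (!is.null(config$metal_summary)) {
      inputs <- c(inputs, metal_summary = config$metal_summary)
      readr::read_csv(config$metal_summary, show_col_types = FALSE)
    } else campaign_zone_summary("metals")
    pah_summary <- if (!is.null(config$pah_summary)) {
      inputs <- c(inputs, pah_summary = config$pah_summary)
      readr::read_csv(config$pah_summary, show_col_types = FALSE)
    } else campaign_zone_summary("pahs")
    log_stage("summarize", "using pre-summarised zone tables")
  }
  outputs$metal_summary <- metal_summary
  outputs$pah_summary <- pah_summary

  # --- indices ----------------------------------------------------------
  outputs$metal_fractions <- composition_fractions(metal_summary)
  outputs$pah_fractions <- composition_fractions(pah_summary)
  bg <- toxicity$background_mg_kg[match(metal_summary$species, toxicity$species)]
  ig <- suppressWarnings(igeo(metal_summary$mean, bg))
  outputs$igeo <- tibble(zone = metal_summary$zone,
                         species = metal_summary$species,
                         background = bg,
                         igeo = ig$igeo, pollution_class = ig$pollution_class)
  if (!is.null(meas)) {
    outputs$diagnostic_ratios <- tryCatch(diagnostic_ratios(meas),
                                          error = function(e) NULL)
  }
  log_stage("indices", sprintf("%d fraction rows, %d igeo rows",
                               nrow(outputs$metal_fractions) + nrow(outputs$pah_fractions),
                               nrow(outputs$igeo)))

  # --- deterministic risk ----------------------------------------------
  mr <- suppressWarnings(metals_risk(metal_summary, params, toxicity))
  outputs$metals_risk <- mr
  hi <- zone_hazard_index(mr)
  outputs$hazard_index <- tibble(zone = hi$zone, HI = hi$HI, flag = hi$flag)
  pr <- pah_risk(pah_summary, params, toxicity)
  outputs$pah_teq <- pr$teq
  outputs$pah_ilcr <- pr$ilcr
  log_stage("risk", sprintf("%d metal rows, %d zones HI, %d zones ILCR",
                            nrow(mr), nrow(hi), nrow(pr$ilcr)))

  # --- Monte Carlo ------------------------------------------------------
  if (!is.null(config$mc)) {
    n_it <- as.integer(config$mc$n_iterations %||% 10000)
    mc_tbl <- purrr::map_dfr(unique(metal_summary$zone), function(z) {
      res <- mc_zone_risk(metal_summary[metal_summary$zone == z, ],
                          pah_summary[pah_summary$zone == z, ],
                          params, toxicity, n_iterations = n_it, seed = seed)
      mutate(res, zone = z)
    })
    outputs$mc <- select(mc_tbl, "zone", dplyr::everything())
    log_stage("monte-carlo", sprintf("%d outputs x %d iterations", nrow(mc_tbl), n_it))
  } else {
    log_stage("monte-carlo", "skipped (no mc config)")
  }

  # --- CPF --------------------------------------------------------------
  if (!is.null(config$cpf) && !is.null(config$cpf$trajectories) && !is.null(meas)) {
    tr <- read_trajectories(config$cpf$trajectories)
    inputs <- c(inputs, trajectories = config$cpf$trajectories)
    g <- do.call(grid_spec, config$cpf$grid)
    metric <- config$cpf$metric %||% "HI"
    risk_days <- gen_risk_days(meas, params, toxicity,
                               censor_policy(config$censor_method %||% "zero"))
    zone_pick <- config$cpf$zone %||% risk_days$zone[1]
    series <- risk_days[risk_days$zone == zone_pick, c("date", metric)]
    names(series) <- c("date", "value")
    asg <- assign_endpoints(tr, g)
    outputs$cpf <- cpf(asg, series,
                       percentile_threshold = config$cpf$threshold_pct %||% 75)
    log_stage("cpf", sprintf("metric %s, zone %s: %d non-empty cells",
                             metric, zone_pick, nrow(outputs$cpf)))
  } else if (!is.null(config$cpf)) {
    warn("CPF stage skipped: needs both daily measurements and a trajectories file")
    log_stage("cpf", "skipped (missing inputs)")
  } else {
    log_stage("cpf", "skipped (no cpf config)")
  }

  # --- write outputs + manifest ----------------------------------------
  for (nm in names(outputs)) {
    tbl <- outputs[[nm]]
    if (is.data.frame(tbl)) {
      tbl <- tbl[, !vapply(tbl, is.list, logical(1)), drop = FALSE]
      readr::write_csv(as.data.frame(tbl), file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
    }
  }
  manifest <- list(
    package = "pm10risk",
    version = as.character(utils::packageVersion("pm10risk")),
    seed = seed,
    config_hash = rlang::hash(config),
    input_digests = lapply(as.list(inputs), function(p) rlang::hash(readLines(p))),
    params = unclass(params),
    censor_method = config$censor_method %||% "half_lod",
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- manifest
  invisible(outputs)
}
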