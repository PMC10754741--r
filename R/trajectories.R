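#' Read air-mass trajectories from CSV
#'
#' Expects columns `trajectory_id, direction, timestamp, lat, lon`
#' (decimal degrees, WGS84; `direction` in {forward, backward}). Points are
#' grouped by trajectory id, ordered in time, and the endpoint interval is
#' inferred from the timestamps and validated to be constant within each
#' trajectory.
#'
#' @param path Path to a CSV file.
#' @return A tibble of trajectory points with columns `trajectory_id`,
#'   `direction`, `timestamp` (POSIXct, UTC), `lat`, `lon`; the inferred
#'   interval in hours is attached as attribute `interval_h`.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Trajectory file not found: ", path), class = "pm10risk_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    trajectory_id = readr::col_character(),
    direction = readr::col_character(),
    timestamp = readr::col_datetime(),
    lat = readr::col_double(),
    lon = readr::col_double()
  ), progress = FALSE)
  validate_trajectories(raw)
}

validate_trajectories <- function(tr) {
  tr <- as_tibble(tr)
  needed <- c("trajectory_id", "direction", "timestamp", "lat", "lon")
  missing <- setdiff(needed, names(tr))
  if (length(missing) > 0) {
    abort(paste0("Missing trajectory column(s): ", paste(missing, collapse = ", ")),
          class = "pm10risk_schema_error")
  }
  bad_dir <- setdiff(unique(tr$direction), c("forward", "backward"))
  if (length(bad_dir) > 0) {
    abort(paste0("direction must be 'forward' or 'backward'; found: ",
                 paste(bad_dir, collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  tr <- arrange(tr, .data$trajectory_id, .data$timestamp)
  intervals <- tr %>%
    group_by(.data$trajectory_id) %>%
    summarise(
      n_pts = dplyr::n(),
      dt = list(as.numeric(diff(.data$timestamp), units = "hours")),
      .groups = "drop"
    )
  if (any(intervals$n_pts < 2)) {
    abort(paste0("Trajectories need at least 2 points: ",
                 paste(intervals$trajectory_id[intervals$n_pts < 2], collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  for (i in seq_len(nrow(intervals))) {
    dt <- intervals$dt[[i]]
    if (any(dt <= 0)) {
      abort(paste0("Non-monotone timestamps in trajectory ",
                   intervals$trajectory_id[i]),
            class = "pm10risk_format_error")
    }
    if (diff(range(dt)) > 1e-6) {
      abort(paste0("Irregular endpoint interval in trajectory ",
                   intervals$trajectory_id[i]),
            class = "pm10risk_format_error")
    }
  }
  iv <- unique(round(vapply(intervals$dt, function(d) d[1], numeric(1)), 6))
  attr(tr, "interval_h") <- if (length(iv) == 1) iv else iv
  tr
}

#' Read HYSPLIT-style tdump endpoint files
#'
#' Thin shim for the fixed-column HYSPLIT trajectory endpoint ("tdump")
#' dialect: a header block (number-of-grids line, grid lines, a
#' trajectory-count line, one starting-point line per trajectory, a
#' variable-count line) followed by endpoint records whose columns are
#' trajectory number, grid number, year, month, day, hour, minute,
#' forecast hour, age (h), latitude, longitude, height, and diagnostic
#' variables. Trajectory ages < 0 mark backward runs.
#'
#' @param path Path to a tdump endpoint file.
#' @param id_prefix Prefix for generated trajectory ids.
#' @return A trajectory tibble as from [read_trajectories()].
#' @export
read_tdump <- function(path, id_prefix = "tdump") {
  if (!file.exists(path)) {
    abort(paste0("tdump file not found: ", path), class = "pm10risk_io_error")
  }
  lines <- readLines(path)
  toks <- lapply(trimws(lines), function(l) strsplit(l, "\\s+")[[1]])
  n_grids <- suppressWarnings(as.integer(toks[[1]][1]))
  if (is.na(n_grids)) {
    abort("Malformed tdump header (first token must be the grid count)",
          class = "pm10risk_format_error")
  }
  i <- 1 + n_grids + 1                       # line holding the trajectory count
  n_traj <- as.integer(toks[[i]][1])
  first_data <- i + n_traj + 2               # skip start lines + variable line
  rec <- toks[seq(first_data, length(toks))]
  rec <- rec[vapply(rec, length, integer(1)) >= 11]
  to_num <- function(k) vapply(rec, function(r) as.numeric(r[k]), numeric(1))
  yr <- to_num(3); yr <- ifelse(yr < 100, 2000 + yr, yr)
  ts <- ISOdatetime(yr, to_num(4), to_num(5), to_num(6), to_num(7), 0, tz = "UTC")
  age <- to_num(9)
  out <- tibble(
    trajectory_id = paste0(id_prefix, "_", formatC(to_num(1), width = 2, flag = "0")),
    timestamp = ts,
    lat = to_num(10),
    lon = to_num(11),
    age_h = age
  )
  dir_by_id <- out %>%
    group_by(.data$trajectory_id) %>%
    summarise(direction = if (any(.data$age_h < 0)) "backward" else "forward",
              .groups = "drop")
  out <- out %>%
    select(-"age_h") %>%
    left_join(dir_by_id, by = "trajectory_id") %>%
    select("trajectory_id", "direction", "timestamp", "lat", "lon")
  validate_trajectories(out)
}

#' Write trajectories to CSV
#'
#' @param trajectories Trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  tr <- validate_trajectories(trajectories)
  readr::write_csv(tr, path, progress = FALSE)
  invisible(path)
}
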