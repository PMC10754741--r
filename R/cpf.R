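#' Geographic grid specification for CPF mapping
#'
#' An axis-aligned grid of square cells anchored at a south-west origin.
#' Cells are half-open on their east and north edges, so a point on a
#' shared edge belongs to the cell for which that edge is the closed
#' (west/south) side. Positions are converted to kilometres on a local
#' tangent plane at the origin (adequate below ~100 km domain scale).
#'
#' @param origin_lat,origin_lon South-west corner, decimal degrees (WGS84).
#' @param cell_km Cell size in km (default 1).
#' @param n_rows,n_cols Grid dimensions (default 32 x 32).
#' @return A `grid_spec` object.
#' @export
#' @examples
#' grid_spec(10.9, -72.9)
grid_spec <- function(origin_lat, origin_lon, cell_km = 1,
                      n_rows = 32, n_cols = 32) {
  if (cell_km <= 0 || n_rows < 1 || n_cols < 1) {
    abort("Grid needs positive cell size and dimensions",
          class = "pm10risk_validation_error")
  }
  structure(list(origin_lat = origin_lat, origin_lon = origin_lon,
                 cell_km = cell_km, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

# Local tangent-plane km east/north of the grid origin.
grid_xy <- function(grid, lat, lon) {
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(grid$origin_lat * pi / 180)
  list(x = (lon - grid$origin_lon) * km_per_deg_lon,
       y = (lat - grid$origin_lat) * km_per_deg_lat)
}

# Centre of cell (i = row from south, j = col from west) in lat/lon.
grid_cell_center <- function(grid, i, j) {
  km_per_deg_lat <- 110.574
  km_per_deg_lon <- 111.320 * cos(grid$origin_lat * pi / 180)
  list(lat = grid$origin_lat + ((i - 0.5) * grid$cell_km) / km_per_deg_lat,
       lon = grid$origin_lon + ((j - 0.5) * grid$cell_km) / km_per_deg_lon)
}

#' Assign trajectory endpoints to grid cells
#'
#' Every endpoint inside the grid is assigned to exactly one cell under the
#' half-open convention; out-of-bounds endpoints are kept with
#' `in_bounds = FALSE` and counted separately.
#'
#' @param trajectories Trajectory tibble (see [read_trajectories()]).
#' @param grid A [grid_spec()].
#' @return The endpoint tibble with added `i` (row, from south), `j`
#'   (column, from west), `in_bounds`, and `date` (the trajectory day:
#'   calendar date of its first timestamp).
#' @export
assign_endpoints <- function(trajectories, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  tr <- validate_trajectories(trajectories)
  xy <- grid_xy(grid, tr$lat, tr$lon)
  j <- floor(xy$x / grid$cell_km) + 1
  i <- floor(xy$y / grid$cell_km) + 1
  inb <- xy$x >= 0 & xy$y >= 0 & j <= grid$n_cols & i <= grid$n_rows
  tr$i <- ifelse(inb, as.integer(i), NA_integer_)
  tr$j <- ifelse(inb, as.integer(j), NA_integer_)
  tr$in_bounds <- inb
  day <- tr %>%
    group_by(.data$trajectory_id) %>%
    summarise(date = as.Date(min(.data$timestamp)), .groups = "drop")
  out <- left_join(tr, day, by = "trajectory_id")
  attr(out, "grid") <- grid
  attr(out, "n_out_of_bounds") <- sum(!inb)
  out
}

#' Step weighting for sparsely visited grid cells
#'
#' CPF values in cells crossed by very few trajectories are statistically
#' unstable; the standard remedy is a step-function down-weighting by the
#' cell's endpoint count relative to the mean count over non-empty cells.
#' Default scheme: weight 1 when `n_ij > 2 * n_mean`, 0.7 when
#' `n_mean < n_ij <= 2 * n_mean`, 0.42 when `0.5 * n_mean < n_ij <= n_mean`,
#' 0.05 otherwise. Breakpoints and weights are configurable.
#'
#' @param n_ij Endpoint count(s) per cell (vectorised).
#' @param n_mean Mean endpoint count over non-empty cells (> 0).
#' @param breaks Multiples of `n_mean` delimiting the steps, descending.
#' @param weights Weights for counts above each break, plus a final weight
#'   below the last break; `length(weights) == length(breaks) + 1`.
#' @return Numeric weights in [0, 1], non-decreasing in `n_ij`.
#' @export
#' @examples
#' weight_function(c(1, 5, 12, 30), n_mean = 10)
weight_function <- function(n_ij, n_mean, breaks = c(2, 1, 0.5),
                            weights = c(1, 0.7, 0.42, 0.05)) {
  if (n_mean <= 0) abort("n_mean must be > 0", class = "pm10risk_validation_error")
  if (any(n_ij < 0)) abort("Counts must be >= 0", class = "pm10risk_validation_error")
  if (length(weights) != length(breaks) + 1 || is.unsorted(rev(breaks)) ||
      is.unsorted(rev(weights))) {
    abort("Need descending breaks and matching descending weights (one more weight than breaks)",
          class = "pm10risk_params_error")
  }
  w <- rep(weights[length(weights)], length(n_ij))
  for (k in rev(seq_along(breaks))) {
    w[n_ij > breaks[k] * n_mean] <- weights[k]
  }
  w
}

#' Conditional probability function over the grid
#'
#' For each grid cell, the CPF is the fraction of its trajectory endpoints
#' that belong to high-risk days, where a day is high-risk when the daily
#' receptor risk metric is at or above the `percentile_threshold` of the
#' series (or an absolute `threshold` if given). Sparse cells are
#' down-weighted via [weight_function()].
#'
#' @param assignment Endpoint assignment from [assign_endpoints()].
#' @param risk Tibble `date, value`: the daily receptor risk series (HI,
#'   CR or ILCR). Every trajectory day must have a risk value.
#' @param percentile_threshold Percentile (0-100) defining high-risk days
#'   (default 75, the CPF convention).
#' @param threshold Optional absolute cutoff overriding the percentile.
#' @param breaks,weights Passed to [weight_function()].
#' @return Tibble `i, j, lat, lon, n, m, cpf_raw, weight, cpf_weighted`
#'   over non-empty cells, with attributes `threshold`, `n_high_days`,
#'   `grid`.
#' @export
cpf <- function(assignment, risk, percentile_threshold = 75, threshold = NULL,
                breaks = c(2, 1, 0.5), weights = c(1, 0.7, 0.42, 0.05)) {
  grid <- attr(assignment, "grid")
  if (is.null(grid)) {
    abort("assignment must come from assign_endpoints()", class = "pm10risk_validation_error")
  }
  risk <- as_tibble(risk)
  if (!all(c("date", "value") %in% names(risk))) {
    abort("risk needs 'date' and 'value' columns", class = "pm10risk_schema_error")
  }
  pts <- assignment[assignment$in_bounds, ]
  missing_days <- setdiff(as.character(unique(pts$date)), as.character(risk$date))
  if (length(missing_days) > 0) {
    abort(paste0("No risk value for trajectory day(s): ",
                 paste(head(missing_days, 5), collapse = ", ")),
          class = "pm10risk_validation_error")
  }
  thr <- threshold %||%
    quantile(risk$value, percentile_threshold / 100, type = 7, names = FALSE)
  high_days <- risk$date[risk$value >= thr]
  if (length(high_days) == 0) {
    warn("No day reaches the high-risk threshold: CPF map is all zero")
  }
  if (length(high_days) == nrow(risk)) {
    warn("Every day reaches the high-risk threshold (degenerate risk series)")
  }
  cells <- pts %>%
    group_by(.data$i, .data$j) %>%
    summarise(n = dplyr::n(),
              m = sum(.data$date %in% high_days),
              .groups = "drop")
  n_mean <- mean(cells$n)
  ctr <- grid_cell_center(grid, cells$i, cells$j)
  out <- cells %>%
    mutate(
      lat = ctr$lat, lon = ctr$lon,
      cpf_raw = .data$m / .data$n,
      weight = weight_function(.data$n, n_mean, breaks, weights),
      cpf_weighted = .data$cpf_raw * .data$weight
    ) %>%
    select("i", "j", "lat", "lon", "n", "m", "cpf_raw", "weight", "cpf_weighted")
  attr(out, "threshold") <- thr
  attr(out, "n_high_days") <- length(high_days)
  attr(out, "grid") <- grid
  out
}

#' Cluster trajectories by shape
#'
#' k-means clustering of whole trajectories: each track is resampled to a
#' common number of points by linear interpolation along its point index,
#' coordinates are projected to planar km (longitude scaled by the cosine
#' of the mean latitude), and the concatenated coordinate vectors are
#' clustered with Euclidean k-means. Deterministic for a given seed. The
#' mean path per cluster and the mean silhouette width are reported.
#'
#' @param trajectories Trajectory tibble.
#' @param k Number of clusters (must not exceed the number of
#'   trajectories).
#' @param n_points Points per resampled track (default: the minimum track
#'   length).
#' @param seed Integer seed for the k-means initialisation.
#' @return List with `labels` (tibble `trajectory_id, direction, cluster`),
#'   `mean_paths` (tibble `cluster, point, lat, lon`), `silhouette` (mean
#'   width, `NA` for k = 1), and `sizes`.
#' @export
cluster_trajectories <- function(trajectories, k, n_points = NULL, seed = 1L) {
  tr <- validate_trajectories(trajectories)
  ids <- unique(tr$trajectory_id)
  if (k > length(ids)) {
    abort(paste0("k = ", k, " exceeds the number of trajectories (", length(ids), ")"),
          class = "pm10risk_validation_error")
  }
  lens <- tr %>% count(.data$trajectory_id) %>% pull(.data$n)
  n_points <- n_points %||% min(lens)
  resample <- function(v, n) {
    if (length(v) == n) return(v)
    stats::approx(seq_along(v), v, xout = seq(1, length(v), length.out = n))$y
  }
  by_id <- split(tr[order(tr$trajectory_id, tr$timestamp), ],
                 tr$trajectory_id[order(tr$trajectory_id, tr$timestamp)])
  by_id <- by_id[ids]
  lat_m <- t(vapply(by_id, function(d) resample(d$lat, n_points), numeric(n_points)))
  lon_m <- t(vapply(by_id, function(d) resample(d$lon, n_points), numeric(n_points)))
  coslat <- cos(mean(lat_m) * pi / 180)
  feat <- cbind(lat_m * 110.574, lon_m * 111.320 * coslat)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  km <- kmeans(feat, centers = k, nstart = 10, iter.max = 100)
  dirs <- vapply(by_id, function(d) d$direction[1], character(1))
  labels <- tibble(trajectory_id = ids, direction = unname(dirs),
                   cluster = unname(km$cluster))
  mean_paths <- purrr::map_dfr(seq_len(k), function(cl) {
    tibble(cluster = cl, point = seq_len(n_points),
           lat = colMeans(lat_m[km$cluster == cl, , drop = FALSE]),
           lon = colMeans(lon_m[km$cluster == cl, , drop = FALSE]))
  })
  sil <- if (k > 1 && length(ids) > k) {
    mean(cluster::silhouette(km$cluster, stats::dist(feat))[, "sil_width"])
  } else NA_real_
  list(labels = labels, mean_paths = mean_paths, silhouette = sil,
       sizes = as.integer(km$size))
}
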