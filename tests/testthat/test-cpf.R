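# Small grids use a 0.1-km cell so lat/lon offsets stay tiny and planar.

km_lat <- function(km) km / 110.574
km_lon <- function(km, origin_lat) km / (111.320 * cos(origin_lat * pi / 180))

test_that("endpoints on shared edges go to the cell whose west/south edge is closed", {
  g <- grid_spec(10, -73, cell_km = 1, n_rows = 4, n_cols = 4)
  # a point exactly on the boundary between columns 1 and 2
  tr <- make_track("E", lats = rep(10 + km_lat(0.5), 2),
                   lons = -73 + km_lon(c(1, 1.2), 10))
  a <- assign_endpoints(tr, g)
  expect_equal(a$j[1], 2)  # edge belongs to the eastern cell (its west edge)
  expect_equal(a$i[1], 1)
  # origin corner is in cell (1, 1)
  tr0 <- make_track("O", lats = c(10, 10 + km_lat(0.2)), lons = c(-73, -73))
  expect_equal(assign_endpoints(tr0, g)$i[1], 1)
  expect_error(grid_spec(10, -73, cell_km = 0), class = "pm10risk_validation_error")
})

test_that("a straight track crossing five cells puts one endpoint in each", {
  g <- grid_spec(10, -73, cell_km = 1, n_rows = 6, n_cols = 6)
  tr <- make_track("S", lats = rep(10 + km_lat(0.5), 5),
                   lons = -73 + km_lon(c(0.5, 1.5, 2.5, 3.5, 4.5), 10))
  a <- assign_endpoints(tr, g)
  counts <- dplyr::count(a[a$in_bounds, ], i, j)
  expect_equal(nrow(counts), 5)
  expect_true(all(counts$n == 1))
})

test_that("endpoint conservation holds against brute-force recounts on random grids", {
  set.seed(123)
  for (rep in 1:100) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    g <- grid_spec(10, -73, cell_km = 1, n_rows = nr, n_cols = nc)
    n_tr <- sample(2:5, 1)
    tr <- purrr::map_dfr(seq_len(n_tr), function(t) {
      npts <- sample(2:6, 1)
      make_track(sprintf("T%02d", t),
                 lats = 10 + km_lat(stats::runif(npts, -1, nr + 1)),
                 lons = -73 + km_lon(stats::runif(npts, -1, nc + 1), 10),
                 start = as.POSIXct("2022-02-01", tz = "UTC") + t)
    })
    a <- assign_endpoints(tr, g)
    counts <- dplyr::count(a[a$in_bounds, ], i, j)
    expect_equal(sum(counts$n) + attr(a, "n_out_of_bounds"), nrow(tr))
    # brute-force recount of one random occupied cell
    if (nrow(counts) > 0) {
      pick <- counts[sample(nrow(counts), 1), ]
      x <- (tr$lon + 73) * 111.320 * cos(10 * pi / 180)
      y <- (tr$lat - 10) * 110.574
      brute <- sum(x >= pick$j - 1 & x < pick$j & y >= pick$i - 1 & y < pick$i)
      expect_equal(pick$n, brute)
    }
  }
})

test_that("CPF ratios match a hand-computed toy and extremes behave", {
  g <- grid_spec(10, -73, cell_km = 1, n_rows = 3, n_cols = 3)
  # cell A (1,1) visited on 4 days (2 high); cell B (1,2) on 1 day (high)
  mk_day <- function(d, kmx) {
    make_track(sprintf("D%d", d), lats = rep(10 + km_lat(0.5), 2),
               lons = -73 + km_lon(c(kmx, kmx + 0.05), 10),
               start = as.POSIXct(sprintf("2022-02-%02d", d), tz = "UTC"))
  }
  tr <- dplyr::bind_rows(lapply(1:4, mk_day, kmx = 0.4), mk_day(5, kmx = 1.4))
  a <- assign_endpoints(tr, g)
  risk <- tibble::tibble(date = as.Date("2022-02-01") + 0:4,
                         value = c(1, 1, 9, 9, 9))  # days 3-5 high
  res <- cpf(a, risk, threshold = 5)
  A <- res[res$i == 1 & res$j == 1, ]
  B <- res[res$i == 1 & res$j == 2, ]
  expect_equal(A$cpf_raw, 0.5)   # 4 of 8 endpoints on high days
  expect_equal(B$cpf_raw, 1.0)
  # sparse cell B is down-weighted below A after weighting
  expect_lt(B$cpf_weighted, A$cpf_weighted)

  expect_warning(
    all_high <- cpf(a, dplyr::mutate(risk, value = 1), threshold = 0.5),
    "degenerate")
  expect_true(all(all_high$cpf_raw == 1))
  expect_warning(none <- cpf(a, risk, threshold = 100), "all zero|threshold")
  expect_true(all(none$cpf_raw == 0))
})

test_that("the step weighting is bounded, monotone and matches its definition", {
  expect_equal(weight_function(10 * 7, 7), 1)
  expect_equal(weight_function(0.1 * 7, 7), 0.05)
  expect_equal(weight_function(c(15, 10, 5, 2), 7), c(1, 0.7, 0.42, 0.05))
  set.seed(5)
  for (rep in 1:20) {
    n <- sort(sample(0:50, 10))
    w <- weight_function(n, n_mean = stats::runif(1, 1, 20))
    expect_true(all(w >= 0 & w <= 1))
    expect_true(!is.unsorted(w))
  }
})

test_that("raising the percentile threshold never increases any cell's m", {
  set.seed(77)
  g <- grid_spec(10, -73, cell_km = 1, n_rows = 5, n_cols = 5)
  tr <- purrr::map_dfr(1:12, function(d) {
    make_track(sprintf("T%02d", d),
               lats = 10 + km_lat(stats::runif(4, 0, 5)),
               lons = -73 + km_lon(stats::runif(4, 0, 5), 10),
               start = as.POSIXct("2022-02-01", tz = "UTC") + (d - 1) * 86400)
  })
  a <- assign_endpoints(tr, g)
  risk <- tibble::tibble(date = as.Date("2022-02-01") + 0:11,
                         value = stats::rlnorm(12))
  prev <- NULL
  for (pct in c(50, 75, 90)) {
    res <- suppressWarnings(cpf(a, risk, percentile_threshold = pct))
    key <- paste(res$i, res$j)
    if (!is.null(prev)) {
      expect_true(all(res$m <= prev[key]))
    }
    prev <- setNames(res$m, key)
    expect_true(all(res$cpf_weighted <= res$cpf_raw))
    expect_true(all(res$cpf_raw >= 0 & res$cpf_raw <= 1))
    expect_true(all(res$m <= res$n))
  }
})

test_that("clustering recovers well-separated bundles and degenerate cases", {
  tr_e <- gen_trajectories(10, prevailing_deg = 90, spread_deg = 5, seed = 1,
                           directions = "backward")
  tr_n <- gen_trajectories(10, prevailing_deg = 0, spread_deg = 5, seed = 2,
                           directions = "backward")
  tr_n$trajectory_id <- paste0("N", tr_n$trajectory_id)
  both <- dplyr::bind_rows(tr_e, tr_n)
  cl <- cluster_trajectories(both, k = 2, seed = 4)
  lab <- cl$labels
  east_ids <- unique(tr_e$trajectory_id)
  east_cl <- lab$cluster[lab$trajectory_id %in% east_ids]
  north_cl <- lab$cluster[!lab$trajectory_id %in% east_ids]
  expect_equal(length(unique(east_cl)), 1)
  expect_equal(length(unique(north_cl)), 1)
  expect_true(unique(east_cl) != unique(north_cl))
  expect_gt(cl$silhouette, 0.5)

  # k = 1: the mean path is the coordinate-wise average
  one <- cluster_trajectories(tr_e, k = 1, seed = 4)
  first_pts <- dplyr::summarise(dplyr::group_by(tr_e, trajectory_id),
                                lat = dplyr::first(lat), .groups = "drop")
  expect_equal(one$mean_paths$lat[1], mean(first_pts$lat))

  # duplicated trajectories land in the same cluster
  dup <- tr_e
  dup$trajectory_id <- paste0("C", dup$trajectory_id)
  cl2 <- cluster_trajectories(dplyr::bind_rows(tr_e, dup), k = 2, seed = 4)
  l2 <- cl2$labels
  expect_equal(l2$cluster[match(paste0("C", east_ids), l2$trajectory_id)],
               l2$cluster[match(east_ids, l2$trajectory_id)])
  expect_error(cluster_trajectories(tr_e, k = 99), class = "pm10risk_validation_error")
})
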