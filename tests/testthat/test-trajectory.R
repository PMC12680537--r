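test_that("haversine distance matches analytic and library references", {
  expect_equal(haversine_km(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-9)
  expect_equal(haversine_km(12.3, 45.6, 12.3, 45.6), 0)
  expect_equal(haversine_km(10, 20, -30, 40), haversine_km(-30, 40, 10, 20))
  # independent reference: geosphere on the same sphere radius
  set.seed(5)
  lat <- runif(20, -90, 90); lon <- runif(20, -180, 180)
  lat2 <- runif(20, -90, 90); lon2 <- runif(20, -180, 180)
  ref <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                  r = 6371000) / 1000
  expect_equal(haversine_km(lat, lon, lat2, lon2), ref, tolerance = 1e-9)
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 200, 0, 0), "longitude")
})

test_that("triangle inequality holds on random point triples", {
  set.seed(8)
  for (i in 1:50) {
    p <- cbind(runif(3, -90, 90), runif(3, -180, 180))
    ab <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    ac <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("path length sums consecutive fixes and tracks coverage", {
  trk <- meridian_track(4, step_km = 10, dt_s = 3600)
  s <- path_length(trk)
  expect_equal(s$path_km, 30, tolerance = 1e-6)
  expect_equal(s$covered_days, 3 / 24)
  expect_equal(s$coverage_fraction, 1)
  expect_equal(s$annual_distance_km, 30 * 365 / (3 / 24), tolerance = 1e-6)
  # path >= great-circle displacement, for arbitrary tracks
  set.seed(21)
  wander <- track("w", as.POSIXct("2020-01-01", tz = "UTC") + (0:40) * 3600,
                  cumsum(rnorm(41, 0, 0.3)) + 20, cumsum(rnorm(41, 0, 0.3)))
  sw <- path_length(wander)
  disp <- haversine_km(wander$lat[1], wander$lon[1],
                       wander$lat[41], wander$lon[41])
  expect_gte(sw$path_km, disp)
})

test_that("gaps are excluded from path and coverage, and can flag a track unusable", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  # 3 fixes, then a 30-day hole, then 3 more
  trk <- track("g", c(t0 + (0:2) * 3600, t0 + 30 * 86400 + (0:2) * 3600),
               c(0, 0.1, 0.2, 5, 5.1, 5.2), rep(0, 6))
  s <- path_length(trk, max_gap_s = 7 * 86400)
  step <- haversine_km(0, 0, 0.1, 0)
  expect_equal(s$path_km, 4 * step, tolerance = 1e-6)
  expect_equal(s$covered_days, 4 / 24)
  expect_lt(s$coverage_fraction, 0.01)
  expect_false(s$usable)
})

test_that("regularization preserves constant-velocity paths and never lengthens", {
  trk <- meridian_track(49, step_km = 25, dt_s = 3600)  # 1200 km straight
  orig <- path_length(trk)$path_km
  for (interval in c(1800, 7200, 4 * 3600)) {
    reg <- regularize(trk, interval_s = interval)
    expect_equal(path_length(reg)$path_km, orig, tolerance = 1e-3)
  }
  # a wiggly track shortens (never lengthens) on a coarser grid
  set.seed(13)
  wig <- track("w", as.POSIXct("2020-01-01", tz = "UTC") + (0:200) * 600,
               20 + cumsum(rnorm(201, 0, 0.05)), cumsum(rnorm(201, 0, 0.05)))
  for (interval in c(1200, 3600, 2 * 3600)) {
    reg <- regularize(wig, interval_s = interval)
    expect_lte(path_length(reg)$path_km, path_length(wig)$path_km + 1e-9)
  }
})

test_that("regularization splits at large gaps instead of bridging them", {
  t0 <- as.POSIXct("2020-01-01", tz = "UTC")
  trk <- track("g", c(t0 + (0:5) * 3600, t0 + 30 * 86400 + (0:5) * 3600),
               c(seq(0, 0.5, by = 0.1), seq(5, 5.5, by = 0.1)), rep(0, 12))
  reg <- regularize(trk, interval_s = 3600, max_gap_s = 7 * 86400)
  expect_equal(sort(unique(reg$segment)), c(1, 2))
  expect_warning(regularize(trk[1, ]), "fewer than 2")
})

test_that("subsampling a fix sequence never increases the computed path", {
  set.seed(31)
  trk <- track("s", as.POSIXct("2020-01-01", tz = "UTC") + (0:300) * 3600,
               cumsum(rnorm(301, 0.01, 0.05)), cumsum(rnorm(301, 0.02, 0.05)))
  full <- path_length(trk)$path_km
  for (by in c(2, 5, 10)) {
    idx <- unique(c(seq(1, 301, by = by), 301))
    sub <- track("s", trk$timestamp[idx], trk$lat[idx], trk$lon[idx])
    expect_lte(path_length(sub)$path_km, full + 1e-9)
  }
})

test_that("annualization is invariant to splitting a track at a shared fix", {
  set.seed(17)
  trk <- track("a", as.POSIXct("2020-01-01", tz = "UTC") + (0:99) * 3600,
               cumsum(rnorm(100, 0, 0.1)), cumsum(rnorm(100, 0, 0.1)))
  full <- path_length(trk)
  k <- 40
  a <- track("a", trk$timestamp[1:k], trk$lat[1:k], trk$lon[1:k])
  b <- track("a", trk$timestamp[k:100], trk$lat[k:100], trk$lon[k:100])
  pa <- path_length(a); pb <- path_length(b)
  combined_annual <- (pa$path_km + pb$path_km) * 365 /
    (pa$covered_days + pb$covered_days)
  expect_equal(combined_annual, full$annual_distance_km, tolerance = 1e-6)
})

test_that("species-level distance: identical birds give a zero-width interval", {
  trks <- lapply(1:4, function(i) meridian_track(24, step_km = 5, dt_s = 3600,
                                                 id = paste0("b", i)))
  est <- species_annual_distance(trks, seed = 3)
  expect_equal(est$low, est$mean)
  expect_equal(est$high, est$mean)
  expect_equal(est$mean, path_length(trks[[1]])$annual_distance_km)
})

test_that("bootstrap is reproducible under a fixed seed", {
  set.seed(99)
  trks <- lapply(1:8, function(i) {
    meridian_track(24, step_km = runif(1, 2, 20), dt_s = 3600,
                   id = paste0("b", i), lat0 = runif(1, -40, 40))
  })
  e1 <- species_annual_distance(trks, seed = 7)
  e2 <- species_annual_distance(trks, seed = 7)
  expect_identical(e1$low, e2$low)
  expect_identical(e1$high, e2$high)
  e3 <- species_annual_distance(trks, seed = 8)
  expect_false(identical(e3$low, e1$low))
  expect_error(species_annual_distance(list()), "no usable tracks")
})

test_that("movebank-style CSVs round-trip into tracks", {
  tf <- tempfile(fileext = ".csv")
  df <- data.frame(
    `individual-local-identifier` = rep(c("x", "y"), each = 3),
    timestamp = format(as.POSIXct("2020-06-01", tz = "UTC") + (0:5) * 3600,
                       "%Y-%m-%d %H:%M:%S"),
    `location-lat` = c(0, 0.1, 0.2, 50, 50.1, 50.2),
    `location-long` = c(10, 10, 10, 20, 20, 20),
    check.names = FALSE)
  write.csv(df, tf, row.names = FALSE)
  trks <- read_tracks_csv(tf)
  expect_length(trks, 2)
  expect_equal(path_length(trks$x)$path_km, 2 * haversine_km(0, 10, 0.1, 10),
               tolerance = 1e-9)
})
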