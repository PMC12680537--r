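test_that("generators are bit-reproducible given (seed, config)", {
  a <- gen_species_table(seed = 4)
  b <- gen_species_table(seed = 4)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c <- gen_species_table(seed = 5)
  expect_false(identical(a$data$biomass_t, c$data$biomass_t))
  t1 <- gen_tracks(seed = 4, config = list(n_individuals = 2, forage_days = 1))
  t2 <- gen_tracks(seed = 4, config = list(n_individuals = 2, forage_days = 1))
  expect_identical(t1$data, t2$data)
  g1 <- gen_country_table(seed = 4, config = list(n_per_group = 4))
  g2 <- gen_country_table(seed = 4, config = list(n_per_group = 4))
  expect_identical(g1$data, g2$data)
  expect_identical(g1$config, g2$config)
})

test_that("species-table truth is exactly recomputable from the data", {
  bundle <- gen_species_table(seed = 21)
  df <- bundle$data
  expect_equal(sum(df$biomass_t), bundle$truth$total_biomass_t)
  brute <- sum(df$biomass_t * df$daily_distance_km * 365)
  expect_equal(brute, bundle$truth$total_movement_t_km_yr)
  # and the aggregation pipeline reproduces the truth through the real path
  out <- aggregate_movement(df)
  total <- out[out$node == "total", ]
  expect_equal(total$movement_t_km_yr, bundle$truth$total_movement_t_km_yr,
               tolerance = 1e-12)
  expect_equal(total$weighted_daily_km, bundle$truth$weighted_daily_km,
               tolerance = 1e-12)
})

test_that("noise-free generation makes aggregation reproduce allometric truth", {
  bundle <- gen_species_table(seed = 2, config = list(
    day_range_sigma = 0, abundance_sigma = 0))
  df <- bundle$data
  expect_equal(df$daily_distance_km, 1.0 * df$body_mass_kg^0.25)
  out <- aggregate_movement(df)
  expect_equal(out$movement_t_km_yr[out$node == "total"],
               bundle$truth$total_movement_t_km_yr)
})

test_that("positive mass-distance allometry makes large movers punch above their biomass", {
  bundle <- gen_species_table(seed = 8, config = list(groups = list(
    mixed = list(n_species = 300, mass_meanlog = log(5), mass_sdlog = 2.5,
                 n0 = 1e9))))
  df <- bundle$data
  big <- df$body_mass_kg > 50
  mv <- df$biomass_t * df$daily_distance_km
  biomass_share <- sum(df$biomass_t[big]) / sum(df$biomass_t)
  movement_share <- sum(mv[big]) / sum(mv)
  expect_gt(movement_share, biomass_share)
})

test_that("migration-only tracks have truth equal to the leg length and are recoverable", {
  bundle <- gen_tracks(seed = 3, config = list(
    n_individuals = 3, forage_days = 0,
    waypoints = data.frame(lat = c(60, 10), lon = c(5, 15)),
    fix_interval_s = 3600))
  leg <- haversine_km(60, 5, 10, 15)
  for (i in 1:3) {
    expect_equal(bundle$truth$per_individual$path_km[i], leg, tolerance = 5e-3)
  }
  # hourly fixes recover the truth within 1%
  for (i in 1:3) {
    got <- path_length(bundle$data[[i]])$path_km
    expect_lt(abs(got - bundle$truth$per_individual$path_km[i]) /
                bundle$truth$per_individual$path_km[i], 0.01)
  }
})

test_that("coarser sampling of foraging tracks always underestimates the truth", {
  bundle <- gen_tracks(seed = 6, config = list(
    n_individuals = 2, forage_days = 20, fix_interval_s = 3600))
  daily <- gen_tracks(seed = 6, config = list(
    n_individuals = 2, forage_days = 20, fix_interval_s = 86400))
  for (i in 1:2) {
    truth <- bundle$truth$per_individual$path_km[i]
    hourly_est <- path_length(bundle$data[[i]])$path_km
    daily_est <- path_length(daily$data[[i]])$path_km
    expect_lte(hourly_est, truth + 1e-6)
    expect_lt(daily_est, hourly_est)
    expect_lt(daily_est, truth)
  }
  expect_error(gen_tracks(seed = 1, config = list(dropout = 1)), "dropout")
})

test_that("country generator: noiseless fits recover alpha and beta exactly", {
  bundle <- gen_country_table(seed = 11, config = list(
    mask_fraction = 0,
    modes = list(road = list(alpha = 1.5, beta = 0.8, sigma = 0))))
  dem <- harmonize(bundle$data$demands, bundle$data$countries)
  fit <- suppressWarnings(fit_gdp_model(dem, bundle$data$countries, "road"))
  expect_equal(fit$elasticity, 0.8, tolerance = 1e-9)
  expect_equal(exp(fit$intercept), 1.5, tolerance = 1e-9)
})

test_that("GDP-dependent missingness concentrates gaps in poor countries and models diverge", {
  bundle <- gen_country_table(seed = 19)  # logistic missingness
  ctry <- bundle$data$countries
  masked <- bundle$truth$masked
  full <- bundle$truth$full_table
  gdp <- ctry$gdp_per_capita[match(full$country_id, ctry$country_id)]
  expect_gt(mean(masked[gdp < 3500]), mean(masked[gdp > 12000]))
  dem <- harmonize(bundle$data$demands, ctry)
  est <- combine_mobility(dem, ctry)
  gaps <- est$demand$status == "combined" & est$demand$mode == "road"
  m1 <- est$model1$per_capita_km_yr[gaps]
  m2 <- est$model2$per_capita_km_yr[gaps]
  expect_gt(max(abs(m1 - m2) / pmax(m1, m2)), 0.05)
  expect_equal(est$demand$per_capita_km_yr[gaps], (m1 + m2) / 2)
})

test_that("historical series hit their configured endpoints exactly", {
  bundle <- gen_historical_series(seed = 1)
  expect_equal(bundle$truth$marine$marine_total$decline_percent, 62.5)
  expect_equal(bundle$truth$human$human_total$fold_change, 40)
  d <- bundle$data
  marine <- d[d$component == "marine_total", ]
  expect_equal(marine$movement_gt_km_yr[1], 80000)
  expect_equal(marine$movement_gt_km_yr[nrow(marine)], 30000, tolerance = 1e-9)
  human <- d[d$component == "human_total", ]
  expect_equal(human$movement_gt_km_yr[1], 100)
  expect_equal(human$movement_gt_km_yr[nrow(human)], 4000, tolerance = 1e-9)
  expect_true(all(diff(human$movement_gt_km_yr) > 0))
  # flat series: no decline
  flat <- gen_historical_series(config = list(
    marine = list(m = list(start = 500, end = 500))))
  expect_equal(flat$truth$marine$m$decline_percent, 0)
  expect_true(all(flat$data$movement_gt_km_yr[flat$data$component == "m"] == 500))
})
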