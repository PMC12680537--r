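countries4 <- function() {
  country_table(tibble::tibble(
    country_id = c("h1", "h2", "um1", "lm1", "lo1"),
    income_group = c("high", "high", "upper_middle", "lower_middle", "low"),
    population = c(1e7, 5e7, 8e7, 1e8, 3e7),
    gdp_per_capita = c(50000, 40000, 12000, 3000, 900)))
}

test_that("harmonization converts units and rejects unknown rows with reasons", {
  ctry <- countries4()
  raw <- tibble::tibble(
    country_id = c("h1", "h2", "um1", "lo1", "zz"),
    mode = c("road", "road", "road", "road", "road"),
    quantity = c(1e7 * 12000, 9000, 20, 500, 1),
    unit = c("pkm_total_yr", "km_per_capita_yr", "km_per_capita_day",
             "furlongs", "km_per_capita_yr"))
  out <- harmonize(raw, ctry)
  expect_equal(out$per_capita_km_yr[out$country_id == "h1"], 12000)
  expect_equal(out$per_capita_km_yr[out$country_id == "h2"], 9000)
  expect_equal(out$per_capita_km_yr[out$country_id == "um1"], 20 * 365)
  rej <- attr(out, "rejected")
  expect_setequal(rej$country_id, c("lo1", "zz"))
  expect_true("unknown unit" %in% rej$reason)
  expect_true("unknown country" %in% rej$reason)
})

test_that("duplicate country-mode rows resolve to their mean and are logged", {
  ctry <- countries4()
  raw <- tibble::tibble(country_id = c("h1", "h1"), mode = "road",
                        quantity = c(1000, 3000), unit = "km_per_capita_yr")
  out <- harmonize(raw, ctry)
  expect_equal(out$per_capita_km_yr, 2000)
  expect_match(attr(out, "log"), "duplicate")
})

test_that("group-mean imputation fills only gaps, population-weighted", {
  ctry <- countries4()
  reported <- tibble::tibble(
    country_id = c("h1", "um1", "lm1", "lo1"),
    mode = "road",
    per_capita_km_yr = c(1000, 800, 300, 100),
    status = "reported")
  filled <- impute_group_mean(reported, ctry, modes = "road")
  expect_equal(filled$per_capita_km_yr[filled$country_id == "h2"], 1000)
  expect_equal(filled$status[filled$country_id == "h2"], "imputed_group_mean")
  # reported rows pass through bit-identical
  m <- match(reported$country_id, filled$country_id)
  expect_identical(filled$per_capita_km_yr[m], reported$per_capita_km_yr)
  # no-op when everything is reported
  all_rep <- tibble::tibble(country_id = ctry$country_id, mode = "road",
                            per_capita_km_yr = 1:5 * 100, status = "reported")
  expect_equal(impute_group_mean(all_rep, ctry, "road")$per_capita_km_yr,
               all_rep$per_capita_km_yr)
  # an empty income group is a hard error naming the group
  expect_error(impute_group_mean(reported[-4, ], ctry, "road"), "low")
})

test_that("population weighting drives the group mean", {
  ctry <- country_table(tibble::tibble(
    country_id = c("a", "b", "c"), income_group = "high",
    population = c(9e7, 1e7, 1e6), gdp_per_capita = 30000))
  reported <- tibble::tibble(country_id = c("a", "b"), mode = "road",
                             per_capita_km_yr = c(100, 1100), status = "reported")
  filled <- impute_group_mean(reported, ctry, "road")
  expect_equal(filled$per_capita_km_yr[filled$country_id == "c"],
               (9e7 * 100 + 1e7 * 1100) / 1e8)
})

test_that("log-log GDP regression recovers a noiseless elasticity exactly", {
  set.seed(12)
  ctry <- country_table(tibble::tibble(
    country_id = sprintf("c%02d", 1:20), income_group = "high",
    population = 1e6, gdp_per_capita = exp(runif(20, 7, 11))))
  dem <- tibble::tibble(country_id = ctry$country_id, mode = "road",
                        per_capita_km_yr = 0.9 * ctry$gdp_per_capita^1.0,
                        status = "reported")
  fit <- suppressWarnings(fit_gdp_model(dem, ctry, "road"))  # perfect fit
  expect_equal(fit$elasticity, 1.0, tolerance = 1e-10)
  expect_equal(exp(fit$intercept), 0.9, tolerance = 1e-10)
  expect_equal(predict_gdp_model(fit, 10000), 9000, tolerance = 1e-6)
  # prediction monotone increasing in GDP for positive elasticity
  p <- predict_gdp_model(fit, c(1000, 5000, 20000))
  expect_true(all(diff(p) > 0))
  # degenerate design rejected
  ctry2 <- ctry; ctry2$gdp_per_capita <- 10000
  expect_error(fit_gdp_model(dem[1:5, ], ctry2, "road"), "degenerate")
  expect_error(fit_gdp_model(dem[1:2, ], ctry, "road"), ">= 3")
})

test_that("combining keeps reported data bit-identical and averages the models", {
  bundle <- gen_country_table(seed = 42, config = list(mask_fraction = 0.3))
  dem <- harmonize(bundle$data$demands, bundle$data$countries)
  est <- combine_mobility(dem, bundle$data$countries)
  d <- est$demand
  rep_idx <- d$status == "reported"
  key <- paste(d$country_id, d$mode)
  dk <- stats::setNames(dem$per_capita_km_yr, paste(dem$country_id, dem$mode))
  expect_identical(d$per_capita_km_yr[rep_idx], unname(dk[key[rep_idx]]))
  # gap entries equal the model average (above any walk/cycle floor)
  m1 <- est$model1$per_capita_km_yr
  m2 <- est$model2$per_capita_km_yr
  gaps <- !rep_idx & d$mode != "walk_cycle"
  expect_equal(d$per_capita_km_yr[gaps], ((m1 + m2) / 2)[gaps])
  expect_true(all(d$status[!rep_idx] == "combined"))
  # scenario variants bracket the mean
  expect_true(all(d$per_capita_km_yr_low <= d$per_capita_km_yr))
  expect_true(all(d$per_capita_km_yr >= 0))
  mv <- to_biomass_movement(est)
  expect_lte(mv$low, mv$mean); expect_gte(mv$high, mv$mean)
  # combined total >= total over reported entries alone
  ctab <- bundle$data$countries
  pop <- stats::setNames(ctab$population, ctab$country_id)
  reported_total <- sum(dem$per_capita_km_yr * pop[dem$country_id]) * 54 / 1e12
  expect_gte(mv$mean, reported_total)
})

test_that("biomass movement conversion is linear in body mass and population", {
  bundle <- gen_country_table(seed = 5, config = list(mask_fraction = 0.2,
                                                      n_per_group = 6))
  dem <- harmonize(bundle$data$demands, bundle$data$countries)
  est <- combine_mobility(dem, bundle$data$countries)
  base <- to_biomass_movement(est)$mean
  est2 <- est
  est2$countries$avg_body_mass_kg <- est2$countries$avg_body_mass_kg * 2
  expect_equal(to_biomass_movement(est2)$mean, 2 * base, tolerance = 1e-12)
})

test_that("summaries report shares that sum to 100 and per-capita by group", {
  bundle <- gen_country_table(seed = 9, config = list(mask_fraction = 0.25))
  dem <- harmonize(bundle$data$demands, bundle$data$countries)
  est <- combine_mobility(dem, bundle$data$countries)
  s <- mobility_summaries(est)
  expect_equal(sum(s$by_mode$share_pct), 100)
  expect_equal(sum(s$by_income_group$movement_share_pct), 100)
  expect_equal(sum(s$by_income_group$population_share_pct), 100)
  grp <- s$by_income_group
  expect_equal(grp$per_capita_km_yr, grp$person_km_yr / grp$population)
  # richer groups travel further per capita under the GDP-linked generator
  expect_gt(grp$per_capita_km_yr[grp$income_group == "high"],
            grp$per_capita_km_yr[grp$income_group == "low"])
  # a single-mode world concentrates 100% in that mode
  one <- combine_mobility(dem[dem$mode == "road", ], bundle$data$countries,
                          modes = "road")
  expect_equal(mobility_summaries(one)$by_mode$share_pct, 100)
})

test_that("masking 30% of entries still recovers the global total within 10%", {
  bundle <- gen_country_table(seed = 101, config = list(mask_fraction = 0.3))
  dem <- harmonize(bundle$data$demands, bundle$data$countries)
  est <- combine_mobility(dem, bundle$data$countries)
  got <- to_biomass_movement(est)$mean
  truth <- bundle$truth$total_gt_km_yr
  expect_lt(abs(got - truth) / truth, 0.10)
})
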