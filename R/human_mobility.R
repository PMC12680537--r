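#' Country table for human-mobility estimation
#'
#' @param df data frame with `country_id`, `income_group` (one of
#'   `"high"`, `"upper_middle"`, `"lower_middle"`, `"low"`), `population`
#'   (> 0), `gdp_per_capita` (> 0), optional `avg_body_mass_kg`
#'   (default 54, the global mean human body mass).
#' @return Validated tibble.
#' @export
country_table <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("country_id", "income_group", "population", "gdp_per_capita")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("country table missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"avg_body_mass_kg" %in% names(df)) df$avg_body_mass_kg <- 54
  df$avg_body_mass_kg[is.na(df$avg_body_mass_kg)] <- 54
  groups <- c("high", "upper_middle", "lower_middle", "low")
  if (!all(df$income_group %in% groups)) {
    stop("income_group must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(df$population > 0), all(df$gdp_per_capita > 0))
  df
}

mobility_modes <- function() c("road", "rail", "air", "walk_cycle")

#' Harmonize raw travel-demand records to per-capita km per year
#'
#' Raw rows carry a country, a mode, a quantity and a unit. Recognized
#' units: `"km_per_capita_yr"` (passed through), `"km_per_capita_day"`
#' (times 365), `"pkm_total_yr"` (total national passenger-km, divided by
#' population). Rows with unknown units or unknown countries are rejected
#' and logged; duplicate country-mode rows are resolved by their mean (and
#' logged).
#'
#' @param raw data frame with `country_id`, `mode`, `quantity`, `unit`.
#' @param countries a [country_table()].
#' @return Tibble of demands: `country_id`, `mode`, `per_capita_km_yr`,
#'   `status` (`"reported"`), with rejected rows in attribute
#'   `"rejected"` and duplicate notes in attribute `"log"`.
#' @export
harmonize <- function(raw, countries) {
  raw <- tibble::as_tibble(raw)
  stopifnot(all(c("country_id", "mode", "quantity", "unit") %in% names(raw)))
  known_unit <- raw$unit %in% c("km_per_capita_yr", "km_per_capita_day", "pkm_total_yr")
  known_country <- raw$country_id %in% countries$country_id
  ok <- known_unit & known_country & raw$mode %in% mobility_modes() &
    is.finite(raw$quantity) & raw$quantity >= 0
  rejected <- raw[!ok, ]
  rejected$reason <- dplyr::case_when(
    !known_unit[!ok] ~ "unknown unit",
    !known_country[!ok] ~ "unknown country",
    TRUE ~ "invalid quantity or mode")
  kept <- raw[ok, ]
  pop <- stats::setNames(countries$population, countries$country_id)
  kept$per_capita_km_yr <- dplyr::case_when(
    kept$unit == "km_per_capita_yr" ~ kept$quantity,
    kept$unit == "km_per_capita_day" ~ kept$quantity * .units$days_per_year,
    kept$unit == "pkm_total_yr" ~ kept$quantity / unname(pop[kept$country_id]))
  dup_log <- character(0)
  out <- kept |>
    dplyr::group_by(.data$country_id, .data$mode) |>
    dplyr::summarise(per_capita_km_yr = mean(.data$per_capita_km_yr),
                     n = dplyr::n(), .groups = "drop")
  dups <- out[out$n > 1, ]
  if (nrow(dups)) {
    dup_log <- sprintf("duplicate rows averaged: %s/%s (n=%d)",
                       dups$country_id, dups$mode, dups$n)
  }
  out <- dplyr::select(out, -"n")
  out$status <- "reported"
  attr(out, "rejected") <- rejected
  attr(out, "log") <- dup_log
  out
}

# expand demands to the full country x mode grid, keeping reported values
full_demand_grid <- function(demands, countries, modes = mobility_modes()) {
  grid <- tidyr::expand_grid(country_id = countries$country_id, mode = modes)
  dplyr::left_join(grid, demands, by = c("country_id", "mode"))
}

#' Gap-filling model 1: income-group mean extrapolation
#'
#' Missing country-mode demands receive the population-weighted mean
#' per-capita demand of the reported countries in the same World Bank
#' income group, i.e. the average mobility per person of the reported part
#' of the group is extrapolated to its unreported part.
#'
#' @param demands reported demands from [harmonize()].
#' @param countries a [country_table()].
#' @param modes modes to fill (default all four).
#' @return Full country x mode tibble; filled entries have
#'   `status = "imputed_group_mean"`, reported entries pass through
#'   untouched.
#' @export
impute_group_mean <- function(demands, countries, modes = mobility_modes()) {
  grid <- full_demand_grid(demands, countries, modes)
  grid <- dplyr::left_join(grid,
                           countries[, c("country_id", "income_group", "population")],
                           by = "country_id")
  means <- grid |>
    dplyr::filter(!is.na(.data$per_capita_km_yr)) |>
    dplyr::group_by(.data$income_group, .data$mode) |>
    dplyr::summarise(group_mean = stats::weighted.mean(.data$per_capita_km_yr,
                                                       .data$population),
                     .groups = "drop")
  gaps <- grid |> dplyr::filter(is.na(.data$per_capita_km_yr)) |>
    dplyr::distinct(.data$income_group, .data$mode)
  uncovered <- dplyr::anti_join(gaps, means, by = c("income_group", "mode"))
  if (nrow(uncovered)) {
    stop("no reported countries to impute from for: ",
         paste(uncovered$income_group, uncovered$mode, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::left_join(grid, means, by = c("income_group", "mode"))
  filled <- is.na(out$per_capita_km_yr)
  out$per_capita_km_yr[filled] <- out$group_mean[filled]
  out$status[filled] <- "imputed_group_mean"
  dplyr::select(out, "country_id", "mode", "per_capita_km_yr", "status")
}

#' Gap-filling model 2: GDP regression
#'
#' Ordinary least squares of log per-capita demand on log GDP per capita,
#' fitted per mode on reported countries only; predictions are the
#' exponentiated fit. The elasticity (slope) is directly interpretable and
#' predictions are positive by construction.
#'
#' @param demands reported demands.
#' @param countries a [country_table()].
#' @param mode single mode name.
#' @return Object of class `gdp_model`: the `lm` fit, its coefficients
#'   (`intercept` = log alpha, `elasticity` = beta), and diagnostics.
#' @export
fit_gdp_model <- function(demands, countries, mode) {
  d <- demands[demands$mode == mode & !is.na(demands$per_capita_km_yr) &
                 demands$per_capita_km_yr > 0, ]
  d <- dplyr::left_join(d, countries[, c("country_id", "gdp_per_capita")],
                        by = "country_id")
  if (nrow(d) < 3) stop("need >= 3 reported countries for mode ", mode, call. = FALSE)
  if (length(unique(d$gdp_per_capita)) < 2) {
    stop("degenerate design: all GDP per capita equal for mode ", mode, call. = FALSE)
  }
  fit <- stats::lm(log(per_capita_km_yr) ~ log(gdp_per_capita), data = d)
  ci <- stats::confint(fit)
  structure(list(
    mode = mode, fit = fit,
    intercept = unname(stats::coef(fit)[1]),
    elasticity = unname(stats::coef(fit)[2]),
    elasticity_ci95 = unname(ci[2, ]),
    sigma = stats::sigma(fit),
    r_squared = summary(fit)$r.squared,
    n = nrow(d)), class = "gdp_model")
}

#' @rdname fit_gdp_model
#' @param model a fitted `gdp_model`.
#' @param gdp_per_capita GDP per capita value(s) to predict at.
#' @param bias_correct apply the log-normal retransformation factor
#'   `exp(sigma^2 / 2)` so the prediction targets the conditional mean
#'   demand rather than its median (default `TRUE`; totals built from
#'   median predictions are systematically low).
#' @return Predicted per-capita km yr^-1.
#' @export
predict_gdp_model <- function(model, gdp_per_capita, bias_correct = TRUE) {
  stopifnot(inherits(model, "gdp_model"), all(gdp_per_capita > 0))
  smear <- if (bias_correct) exp(model$sigma^2 / 2) else 1
  smear * exp(model$intercept + model$elasticity * log(gdp_per_capita))
}

#' @export
print.gdp_model <- function(x, ...) {
  cat(sprintf("<gdp_model %s> elasticity %.3f [%.3f, %.3f], sigma %.3f, R2 %.3f, n=%d\n",
              x$mode, x$elasticity, x$elasticity_ci95[1], x$elasticity_ci95[2],
              x$sigma, x$r_squared, x$n))
  invisible(x)
}

# fill the gaps of the full grid with GDP-model predictions per mode
impute_regression <- function(demands, countries, modes = mobility_modes()) {
  grid <- full_demand_grid(demands, countries, modes)
  gdp <- stats::setNames(countries$gdp_per_capita, countries$country_id)
  for (m in modes) {
    model <- fit_gdp_model(demands, countries, m)
    gap <- is.na(grid$per_capita_km_yr) & grid$mode == m
    grid$per_capita_km_yr[gap] <- predict_gdp_model(model, unname(gdp[grid$country_id[gap]]))
    grid$status[gap] <- "imputed_regression"
  }
  grid
}

#' Combine reported data with the two gap-filling models
#'
#' Reported country-mode demands pass through bit-identical; each gap
#' entry becomes the average of the income-group-mean extrapolation and
#' the GDP-regression prediction. Low and high scenario variants scale
#' entries by data-quality multipliers (reported entries are firm; imputed
#' entries carry the spread).
#'
#' @param demands reported demands from [harmonize()].
#' @param countries a [country_table()].
#' @param modes modes to cover.
#' @param scenario_multipliers named list with `reported` and `imputed`
#'   `c(low, high)` multipliers.
#' @param walk_cycle_floor_km_day minimum imputed walking/cycling demand,
#'   km per person per day (default 1): walking data are globally sparse
#'   and an imputed value below roughly one daily kilometre on foot is not
#'   credible for any population.
#' @return Object of class `mobility_estimate`: the combined demand table
#'   (with `status` in reported/combined and `low`/`high` variant
#'   columns), the two intermediate model fills, and the country table.
#' @export
combine_mobility <- function(demands, countries, modes = mobility_modes(),
                             scenario_multipliers = list(reported = c(1, 1),
                                                         imputed = c(0.5, 2)),
                             walk_cycle_floor_km_day = 1) {
  m1 <- impute_group_mean(demands, countries, modes)
  m2 <- impute_regression(demands, countries, modes)
  if (!identical(m1[, c("country_id", "mode")], m2[, c("country_id", "mode")])) {
    stop("model fills cover different country-mode sets", call. = FALSE)
  }
  reported <- m1$status == "reported"
  if (!identical(m1$per_capita_km_yr[reported], m2$per_capita_km_yr[reported])) {
    stop("reported entries must pass through both models unchanged", call. = FALSE)
  }
  out <- m1
  out$per_capita_km_yr[!reported] <-
    (m1$per_capita_km_yr[!reported] + m2$per_capita_km_yr[!reported]) / 2
  out$status[!reported] <- "combined"
  floor_idx <- !reported & out$mode == "walk_cycle"
  out$per_capita_km_yr[floor_idx] <-
    pmax(out$per_capita_km_yr[floor_idx],
         walk_cycle_floor_km_day * .units$days_per_year)
  mult <- scenario_multipliers
  out$per_capita_km_yr_low <- out$per_capita_km_yr *
    ifelse(reported, mult$reported[1], mult$imputed[1])
  out$per_capita_km_yr_high <- out$per_capita_km_yr *
    ifelse(reported, mult$reported[2], mult$imputed[2])
  structure(list(demand = out, model1 = m1, model2 = m2,
                 countries = countries), class = "mobility_estimate")
}

#' Human biomass movement from a mobility estimate
#'
#' Per-country person-km per year times the country's average body mass,
#' summed globally: passenger-km times kg is kg km, and 1 Gt km = 1e12
#' kg km.
#'
#' @param estimate a `mobility_estimate`.
#' @return One-row tibble with `low`, `mean`, `high` global biomass
#'   movement in Gt km yr^-1 and total person-km yr^-1 (mean variant).
#' @export
to_biomass_movement <- function(estimate) {
  stopifnot(inherits(estimate, "mobility_estimate"))
  d <- dplyr::left_join(estimate$demand,
                        estimate$countries[, c("country_id", "population",
                                               "avg_body_mass_kg")],
                        by = "country_id")
  gt <- function(pc) sum(pc * d$population * d$avg_body_mass_kg) / 1e12
  tibble::tibble(
    person_km_yr = sum(d$per_capita_km_yr * d$population),
    low = gt(d$per_capita_km_yr_low),
    mean = gt(d$per_capita_km_yr),
    high = gt(d$per_capita_km_yr_high))
}

#' Mode shares, income-group shares and per-capita mobility
#'
#' @param estimate a `mobility_estimate`.
#' @return List of tibbles: `by_mode` (share of biomass movement per
#'   mode, %), `by_income_group` (population share, movement share,
#'   per-capita km yr^-1), and the global `total` (Gt km yr^-1).
#' @export
mobility_summaries <- function(estimate) {
  stopifnot(inherits(estimate, "mobility_estimate"))
  d <- dplyr::left_join(estimate$demand,
                        estimate$countries[, c("country_id", "income_group",
                                               "population", "avg_body_mass_kg")],
                        by = "country_id")
  d$movement_gt <- d$per_capita_km_yr * d$population * d$avg_body_mass_kg / 1e12
  by_mode <- d |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(movement_gt_km_yr = sum(.data$movement_gt), .groups = "drop")
  by_mode$share_pct <- composition_shares(by_mode$movement_gt_km_yr)
  pops <- estimate$countries |>
    dplyr::group_by(.data$income_group) |>
    dplyr::summarise(population = sum(.data$population), .groups = "drop")
  by_group <- d |>
    dplyr::group_by(.data$income_group) |>
    dplyr::summarise(movement_gt_km_yr = sum(.data$movement_gt),
                     person_km_yr = sum(.data$per_capita_km_yr * .data$population),
                     .groups = "drop") |>
    dplyr::left_join(pops, by = "income_group")
  by_group$population_share_pct <- composition_shares(by_group$population)
  by_group$movement_share_pct <- composition_shares(by_group$movement_gt_km_yr)
  by_group$per_capita_km_yr <- by_group$person_km_yr / by_group$population
  list(by_mode = by_mode, by_income_group = by_group,
       total = sum(by_mode$movement_gt_km_yr))
}
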