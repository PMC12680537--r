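#' Synthetic-data generators with exact ground truth
#'
#' Every generator returns a `synthetic_bundle`: the generated data, the
#' generator's exact truth (totals recomputable from the data by brute
#' force — noise realizations are part of the data, not of the truth
#' bookkeeping), the seed, and the full config echo. Identical
#' `(seed, config)` reproduce the bundle bit for bit (Mersenne-Twister via
#' `set.seed`); each generator draws from its own seed offset so adding
#' one generator never perturbs another.
#'
#' @name synthetic_bundle
#' @keywords internal
NULL

new_bundle <- function(data, truth, seed, config) {
  structure(list(data = data, truth = truth, seed = seed, config = config),
            class = "synthetic_bundle")
}

# per-component substream: deterministic offset from the bundle seed
substream <- function(seed, k) set.seed((as.integer(seed) + 104729L * k) %% .Machine$integer.max)

#' Generate a synthetic species table
#'
#' Emulates a literature-synthesis species table: per group, body masses
#' are log-normal, abundances follow a density-mass allometry
#' (`N = n0 * m^-0.75 * lognormal`), and day ranges follow a mass
#' allometry `d = c * m^e * lognormal` (defaults `c = 1` km/d at 1 kg,
#' `e = 0.25`, noise sigma 0.4). Truth holds the exact per-group and total
#' biomass, movement and biomass-weighted daily distance computed directly
#' from the generated rows.
#'
#' @param seed integer.
#' @param config list: `groups` (named list of per-group settings:
#'   `n_species`, `mass_meanlog`, `mass_sdlog`, `n0`), `day_range_c`,
#'   `day_range_e`, `day_range_sigma`, `mass_sigma` (abundance noise).
#' @return A `synthetic_bundle`; `data` is a valid [species_table()].
#' @export
gen_species_table <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    groups = list(
      small_mammals = list(n_species = 40, mass_meanlog = log(0.05), mass_sdlog = 1, n0 = 3e9),
      large_mammals = list(n_species = 20, mass_meanlog = log(100), mass_sdlog = 1, n0 = 3e9),
      birds = list(n_species = 40, mass_meanlog = log(0.08), mass_sdlog = 1, n0 = 2e9)
    ),
    day_range_c = 1.0, day_range_e = 0.25, day_range_sigma = 0.4,
    abundance_sigma = 0.5, abundance_exponent = -0.75
  ), config)
  for (g in cfg$groups) {
    if (g$mass_sdlog < 0 || g$n_species < 1) stop("invalid group config", call. = FALSE)
  }
  if (cfg$day_range_sigma < 0) stop("day_range_sigma must be >= 0", call. = FALSE)
  substream(seed, 1L)
  rows <- lapply(names(cfg$groups), function(gname) {
    g <- cfg$groups[[gname]]
    m <- stats::rlnorm(g$n_species, g$mass_meanlog, g$mass_sdlog)
    n <- g$n0 * m^cfg$abundance_exponent *
      stats::rlnorm(g$n_species, 0, cfg$abundance_sigma)
    d <- cfg$day_range_c * m^cfg$day_range_e *
      stats::rlnorm(g$n_species, 0, cfg$day_range_sigma)
    tibble::tibble(
      id = sprintf("%s_%03d", gname, seq_len(g$n_species)),
      group_path = paste0("land/", gname),
      locomotion_mode = if (gname == "birds") "fly" else "walk_run",
      population = n,
      body_mass_kg = m,
      biomass_t = n * m / 1e3,
      daily_distance_km = d)
  })
  data <- species_table(dplyr::bind_rows(rows))
  per_leaf_mv <- data$biomass_t * data$daily_distance_km * .units$days_per_year
  grp <- vapply(strsplit(data$group_path, "/"), `[`, character(1), 2)
  truth <- list(
    total_biomass_t = sum(data$biomass_t),
    total_movement_t_km_yr = sum(per_leaf_mv),
    weighted_daily_km = sum(per_leaf_mv) / sum(data$biomass_t) / .units$days_per_year,
    by_group = tibble::tibble(
      group = names(cfg$groups),
      biomass_t = vapply(names(cfg$groups), function(g)
        sum(data$biomass_t[grp == g]), numeric(1)),
      movement_t_km_yr = vapply(names(cfg$groups), function(g)
        sum(per_leaf_mv[grp == g]), numeric(1))))
  new_bundle(data, truth, seed, cfg)
}

# move dist_km along the great circle from (lat, lon) towards bearing (deg)
gc_step <- function(lat, lon, bearing_deg, dist_km) {
  rad <- pi / 180
  d <- dist_km / .units$earth_radius_km
  b <- bearing_deg * rad
  la1 <- lat * rad; lo1 <- lon * rad
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(b))
  lo2 <- lo1 + atan2(sin(b) * sin(d) * cos(la1),
                     cos(d) - sin(la1) * sin(la2))
  c(la2 / rad, ((lo2 / rad + 180) %% 360) - 180)
}

gc_bearing <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlon <- (lon2 - lon1) * rad
  y <- sin(dlon) * cos(lat2 * rad)
  x <- cos(lat1 * rad) * sin(lat2 * rad) -
    sin(lat1 * rad) * cos(lat2 * rad) * cos(dlon)
  atan2(y, x) / rad
}

#' Generate synthetic GPS tracks with known path length
#'
#' Each individual alternates migration legs (great-circle flight between
#' waypoints at cruise speed) with foraging bouts (correlated random walk
#' around the current location). The continuous path is built at a fine
#' step; its exact integrated length is the truth. Fixes are the fine path
#' subsampled at the fix interval, with optional uniform dropout.
#'
#' @param seed integer.
#' @param config list: `n_individuals`, `waypoints` (matrix/data frame of
#'   lat, lon), `cruise_speed_km_h`, `forage_days` (bout length at each
#'   waypoint after the first), `forage_step_km` (CRW hourly step),
#'   `forage_turn_sd_deg`, `fix_interval_s`, `dropout` in [0, 1),
#'   `start_time` (POSIXct).
#' @return A `synthetic_bundle`; `data` is a list of `track`s, truth has
#'   per-individual exact `path_km` and span.
#' @export
gen_tracks <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    n_individuals = 5,
    waypoints = data.frame(lat = c(60, 10), lon = c(5, 15)),
    cruise_speed_km_h = 50,
    forage_days = 10,
    forage_step_km = 1,
    forage_turn_sd_deg = 40,
    fix_interval_s = 3600,
    dropout = 0,
    start_time = as.POSIXct("2020-01-01", tz = "UTC")
  ), config)
  if (cfg$dropout >= 1 || cfg$dropout < 0) stop("dropout must be in [0, 1)", call. = FALSE)
  wp <- as.data.frame(cfg$waypoints)
  substream(seed, 2L)
  step_h <- 1  # fine path resolution: one hour
  tracks <- vector("list", cfg$n_individuals)
  truth_rows <- vector("list", cfg$n_individuals)
  for (i in seq_len(cfg$n_individuals)) {
    lat <- wp$lat[1]; lon <- wp$lon[1]
    pts <- list(c(lat, lon))
    # initial foraging bout, then legs to each further waypoint + bout
    n_bout <- round(cfg$forage_days * 24 / step_h)
    do_forage <- function(lat, lon) {
      heading <- stats::runif(1, 0, 360)
      out <- vector("list", n_bout)
      for (j in seq_len(n_bout)) {
        heading <- heading + stats::rnorm(1, 0, cfg$forage_turn_sd_deg)
        p <- gc_step(lat, lon, heading, cfg$forage_step_km * step_h)
        lat <- p[1]; lon <- p[2]
        out[[j]] <- p
      }
      out
    }
    if (cfg$forage_days > 0) {
      fb <- do_forage(lat, lon)
      pts <- c(pts, fb)
      lat <- fb[[n_bout]][1]; lon <- fb[[n_bout]][2]
    }
    if (nrow(wp) > 1) for (w in 2:nrow(wp)) {
      repeat {
        remaining <- haversine_km(lat, lon, wp$lat[w], wp$lon[w])
        step_km <- cfg$cruise_speed_km_h * step_h
        if (remaining <= step_km) {
          pts <- c(pts, list(c(wp$lat[w], wp$lon[w])))
          lat <- wp$lat[w]; lon <- wp$lon[w]
          break
        }
        bear <- gc_bearing(lat, lon, wp$lat[w], wp$lon[w])
        p <- gc_step(lat, lon, bear, step_km)
        lat <- p[1]; lon <- p[2]
        pts <- c(pts, list(p))
      }
      if (cfg$forage_days > 0) {
        fb <- do_forage(lat, lon)
        pts <- c(pts, fb)
        lat <- fb[[n_bout]][1]; lon <- fb[[n_bout]][2]
      }
    }
    path <- do.call(rbind, pts)
    np <- nrow(path)
    fine_times <- cfg$start_time + (seq_len(np) - 1) * step_h * 3600
    true_km <- sum(haversine_km(path[-np, 1], path[-np, 2],
                                path[-1, 1], path[-1, 2]))
    # subsample at the fix interval, always keeping first and last
    keep <- seq(1, np, by = max(1L, round(cfg$fix_interval_s / (step_h * 3600))))
    if (keep[length(keep)] != np) keep <- c(keep, np)
    if (cfg$dropout > 0) {
      drop <- stats::runif(length(keep)) < cfg$dropout
      drop[c(1, length(keep))] <- FALSE
      keep <- keep[!drop]
    }
    id <- sprintf("ind_%02d", i)
    tracks[[i]] <- track(id, fine_times[keep], path[keep, 1], path[keep, 2])
    truth_rows[[i]] <- tibble::tibble(
      individual_id = id, path_km = true_km,
      spanned_days = (np - 1) * step_h / 24)
  }
  truth <- dplyr::bind_rows(truth_rows)
  new_bundle(tracks,
             list(per_individual = truth, mean_path_km = mean(truth$path_km)),
             seed, cfg)
}

#' Generate a synthetic country/mobility table
#'
#' Countries fall into four income groups with log-normal GDP per capita
#' one decade apart; per-mode demand follows `alpha * gdp^beta *
#' lognormal(sigma)`; entries go missing with probability decreasing in
#' GDP (logistic in log GDP), emulating the reporting gap in poorer
#' countries. Truth holds the full unmasked table and exact global totals.
#'
#' @param seed integer.
#' @param config list: `n_per_group`, `gdp_meanlog` (named, per group),
#'   `gdp_sdlog`, `modes` (named list of `list(alpha, beta, sigma)`),
#'   `missing_at_loggdp` (log-GDP where missingness is 50%),
#'   `missing_slope`, `mask_fraction` (overrides the logistic with
#'   uniform masking when non-NULL), `body_mass_kg`.
#' @return A `synthetic_bundle`: `data$countries`, `data$demands` (raw
#'   rows with masked quantities removed), truth with the full table and
#'   `total_gt_km_yr`.
#' @export
gen_country_table <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    n_per_group = 12,
    gdp_meanlog = c(high = log(45000), upper_middle = log(12000),
                    lower_middle = log(3500), low = log(900)),
    gdp_sdlog = 0.4,
    pop_meanlog = log(3e7), pop_sdlog = 1,
    modes = list(
      road = list(alpha = 1.5, beta = 0.8, sigma = 0.3),
      rail = list(alpha = 0.12, beta = 0.8, sigma = 0.3),
      air = list(alpha = 0.015, beta = 1.0, sigma = 0.3),
      walk_cycle = list(alpha = 400, beta = 0.05, sigma = 0.2)),
    missing_at_loggdp = log(2000), missing_slope = 1.2,
    mask_fraction = NULL,
    body_mass_kg = 54
  ), config)
  substream(seed, 3L)
  groups <- names(cfg$gdp_meanlog)
  countries <- dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(
      country_id = sprintf("%s_%02d", g, seq_len(cfg$n_per_group)),
      income_group = g,
      population = stats::rlnorm(cfg$n_per_group, cfg$pop_meanlog, cfg$pop_sdlog),
      gdp_per_capita = stats::rlnorm(cfg$n_per_group, cfg$gdp_meanlog[[g]],
                                     cfg$gdp_sdlog),
      avg_body_mass_kg = cfg$body_mass_kg)
  }))
  countries <- country_table(countries)
  full <- dplyr::bind_rows(lapply(names(cfg$modes), function(m) {
    p <- cfg$modes[[m]]
    tibble::tibble(
      country_id = countries$country_id,
      mode = m,
      per_capita_km_yr = p$alpha * countries$gdp_per_capita^p$beta *
        stats::rlnorm(nrow(countries), 0, p$sigma))
  }))
  lg <- log(countries$gdp_per_capita)[match(full$country_id, countries$country_id)]
  miss_p <- if (is.null(cfg$mask_fraction)) {
    stats::plogis(-(lg - cfg$missing_at_loggdp) * cfg$missing_slope)
  } else {
    rep(cfg$mask_fraction, nrow(full))
  }
  masked <- stats::runif(nrow(full)) < miss_p
  demands_raw <- tibble::tibble(
    country_id = full$country_id[!masked],
    mode = full$mode[!masked],
    quantity = full$per_capita_km_yr[!masked],
    unit = "km_per_capita_yr")
  pop <- countries$population[match(full$country_id, countries$country_id)]
  truth <- list(
    full_table = full,
    masked = masked,
    total_person_km_yr = sum(full$per_capita_km_yr * pop),
    total_gt_km_yr = sum(full$per_capita_km_yr * pop * cfg$body_mass_kg) / 1e12,
    params = cfg$modes)
  new_bundle(list(countries = countries, demands = demands_raw), truth, seed, cfg)
}

#' Generate a synthetic historical movement series
#'
#' Marine components decline exponentially from their start values to
#' configured end values; human modes grow logistically. Truth records the
#' exact endpoint decline percentage and fold change.
#'
#' @param seed integer (the series is deterministic given config; the seed
#'   is recorded for bundle bookkeeping).
#' @param config list: `years` (range), `marine` (named list of
#'   `list(start, end)` Gt km yr^-1), `human` (named list of
#'   `list(start, end, midpoint_year, rate)` logistic settings).
#' @return A `synthetic_bundle`; `data` is a tidy year/component/value
#'   tibble.
#' @export
gen_historical_series <- function(seed = 1L, config = list()) {
  cfg <- utils::modifyList(list(
    years = c(1850, 2020),
    marine = list(marine_total = list(start = 80000, end = 30000)),
    human = list(human_total = list(start = 100, end = 4000,
                                    midpoint_year = 1980, rate = 0.07))
  ), config)
  yrs <- seq(cfg$years[1], cfg$years[2])
  span <- cfg$years[2] - cfg$years[1]
  marine <- dplyr::bind_rows(lapply(names(cfg$marine), function(nm) {
    p <- cfg$marine[[nm]]
    stopifnot(p$start > 0, p$end >= 0)
    rate <- if (p$end > 0) log(p$end / p$start) / span else -Inf
    tibble::tibble(year = yrs, component = nm,
                   movement_gt_km_yr = p$start * exp(rate * (yrs - yrs[1])))
  }))
  human <- dplyr::bind_rows(lapply(names(cfg$human), function(nm) {
    p <- cfg$human[[nm]]
    # logistic through the configured endpoints: solve the asymptote pair
    f <- stats::plogis(p$rate * (yrs - p$midpoint_year))
    f0 <- f[1]; f1 <- f[length(f)]
    a <- (p$end - p$start) / (f1 - f0)
    b <- p$start - a * f0
    tibble::tibble(year = yrs, component = nm,
                   movement_gt_km_yr = a * f + b)
  }))
  data <- dplyr::bind_rows(marine, human)
  ends <- function(d) c(d$movement_gt_km_yr[1], d$movement_gt_km_yr[nrow(d)])
  truth <- list(
    marine = lapply(stats::setNames(names(cfg$marine), names(cfg$marine)), function(nm) {
      e <- ends(marine[marine$component == nm, ])
      list(start = e[1], end = e[2],
           decline_percent = decline_percent(e[1], e[2]))
    }),
    human = lapply(stats::setNames(names(cfg$human), names(cfg$human)), function(nm) {
      e <- ends(human[human$component == nm, ])
      list(start = e[1], end = e[2], fold_change = fold_change(e[2], e[1]))
    }))
  new_bundle(data, truth, seed, cfg)
}
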