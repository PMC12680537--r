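#' Biomass movement of a group
#'
#' The central metric: the product of a group's total biomass and the
#' average distance its individuals actively travel per year, in units of
#' mass times distance per time (t km yr^-1; headline display Gt km yr^-1).
#'
#' @param biomass_t total biomass in tonnes (>= 0, finite).
#' @param annual_distance_km average distance travelled per individual per
#'   year, km yr^-1 (>= 0, finite).
#' @return Biomass movement in t km yr^-1, exact product, no rounding.
#' @examples
#' biomass_movement(2e7, 4 * 365) / 1e9  # wild land mammals, ~30 Gt km/yr
#' @export
biomass_movement <- function(biomass_t, annual_distance_km) {
  check_nonneg(biomass_t, "biomass_t")
  check_nonneg(annual_distance_km, "annual_distance_km")
  biomass_t * annual_distance_km
}

#' Biomass movement from population, body mass and distance
#'
#' @param population number of individuals (>= 0).
#' @param body_mass_kg individual body mass, kg (>= 0).
#' @param annual_distance_km km yr^-1 per individual (>= 0).
#' @return Biomass movement in t km yr^-1.
#' @examples
#' movement_from_population(2e6, 0.1, 8e4)  # arctic terns, ~1.6e7 t km/yr
#' @export
movement_from_population <- function(population, body_mass_kg, annual_distance_km) {
  check_nonneg(population, "population")
  check_nonneg(body_mass_kg, "body_mass_kg")
  check_nonneg(annual_distance_km, "annual_distance_km")
  population * body_mass_kg / .units$kg_per_tonne * annual_distance_km
}

#' Movement upper bound from activity time and characteristic speed
#'
#' For groups with too little movement data for a central estimate, an
#' upper bound robust to under-sampling: the whole biomass moving at its
#' characteristic speed for its whole daily activity window, every day.
#'
#' @param biomass_t tonnes.
#' @param activity_hours_per_day hours in [0, 24].
#' @param speed_km_h characteristic speed, km h^-1 (>= 0).
#' @return Upper-bound movement, t km yr^-1.
#' @examples
#' # prokaryotes at 10 um/s around the clock
#' upper_bound_movement(2e11, 24, 3.6e-5) / 1e9  # ~63 Gt km/yr
#' @export
upper_bound_movement <- function(biomass_t, activity_hours_per_day, speed_km_h) {
  check_nonneg(biomass_t, "biomass_t")
  check_nonneg(speed_km_h, "speed_km_h")
  if (!is.numeric(activity_hours_per_day) || any(!is.finite(activity_hours_per_day)) ||
      any(activity_hours_per_day < 0) || any(activity_hours_per_day > 24)) {
    stop("activity_hours_per_day must lie in [0, 24]", call. = FALSE)
  }
  biomass_t * activity_hours_per_day * speed_km_h * .units$days_per_year
}

#' Biomass-weighted average daily distance
#'
#' Total movement divided by total biomass and by days per year: the mean
#' daily distance per unit biomass of the group.
#'
#' @param movement_t_km_yr t km yr^-1 (>= 0).
#' @param biomass_t tonnes (> 0).
#' @return km d^-1.
#' @examples
#' weighted_mean_daily_distance(30e9, 20e6)  # ~4.1 km/d
#' @export
weighted_mean_daily_distance <- function(movement_t_km_yr, biomass_t) {
  check_nonneg(movement_t_km_yr, "movement_t_km_yr")
  if (!all(biomass_t > 0)) stop("biomass must be positive", call. = FALSE)
  movement_t_km_yr / biomass_t / .units$days_per_year
}

#' Share of a part in a whole; composition shares
#'
#' @param part,whole same units; `whole > 0`, `part >= 0`.
#' @return `relative_share`: fraction in [0, Inf); `composition_shares`:
#'   percentages summing to exactly 100 before any display rounding.
#' @examples
#' relative_share(600, 4000)              # walking share of human movement
#' composition_shares(c(70, 15, 10, 5))   # marine composition
#' @export
relative_share <- function(part, whole) {
  check_nonneg(part, "part")
  if (!all(whole > 0)) stop("whole must be positive", call. = FALSE)
  part / whole
}

#' @rdname relative_share
#' @param parts nonnegative vector with positive sum.
#' @export
composition_shares <- function(parts) {
  check_nonneg(parts, "parts")
  tot <- sum(parts)
  if (tot <= 0) stop("total must be positive", call. = FALSE)
  100 * parts / tot
}

#' Decline percentage and fold change between two epochs
#'
#' @param initial,final same units; `initial > 0` for both functions.
#' @return `decline_percent`: `(1 - final/initial) * 100`;
#'   `fold_change`: `final / initial`.
#' @examples
#' decline_percent(80000, 30000)  # marine movement since 1850, 62.5%
#' @export
decline_percent <- function(initial, final) {
  if (!all(initial > 0)) stop("initial must be positive", call. = FALSE)
  check_nonneg(final, "final")
  (1 - final / initial) * 100
}

#' @rdname decline_percent
#' @export
fold_change <- function(final, initial) {
  if (!all(initial > 0)) stop("initial must be positive", call. = FALSE)
  check_nonneg(final, "final")
  final / initial
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be nonnegative and finite", name), call. = FALSE)
  }
  invisible(x)
}
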