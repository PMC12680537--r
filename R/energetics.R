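#' Allometric cost-of-transport registry
#'
#' The cost of transport (COT) is the energy needed to move one kilogram
#' of body mass one metre (J kg^-1 m^-1). Within a locomotion mode it
#' follows an allometric power law `COT(m) = a * m^b` with b <= 0: larger
#' animals move a unit of mass more cheaply. The shipped defaults are
#' literature-style scaling constants per mode; every entry is
#' configurable, and fixed group-average COTs are expressed as `b = 0`
#' entries.
#'
#' Defaults: terrestrial running/walking `a = 10.7, b = -0.316` (a 70-kg
#' walker lands at ~2.8, i.e. ~3 J kg^-1 m^-1, ~0.7 kcal kg^-1 km^-1);
#' flapping flight `a = 5.0, b = -0.25`; swimming `a = 0.5, b = -0.25`;
#' motorized modes carry flat per-passenger-mass costs.
#'
#' @param overrides named list of `list(a=, b=)` entries replacing or
#'   extending the defaults.
#' @return Named list of mode entries with elements `a` and `b`.
#' @export
cot_registry <- function(overrides = list()) {
  defaults <- list(
    walk_run  = list(a = 10.7, b = -0.316),
    fly       = list(a = 5.0,  b = -0.25),
    swim      = list(a = 0.5,  b = -0.25),
    crawl     = list(a = 20,   b = -0.25),
    vertical_migration = list(a = 0.5, b = -0.25),
    vehicle_road = list(a = 30, b = 0),
    vehicle_rail = list(a = 5,  b = 0),
    vehicle_air  = list(a = 20, b = 0),
    vehicle_ship = list(a = 0.5, b = 0)
  )
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  for (p in defaults) stopifnot(p$a > 0, p$b <= 0)
  defaults
}

#' Cost of transport for a body mass and locomotion mode
#'
#' @param body_mass_kg body mass, kg (> 0).
#' @param params one registry entry, `list(a, b)`.
#' @return COT in J kg^-1 m^-1.
#' @examples
#' cot(70, cot_registry()$walk_run)  # ~2.8 J/kg/m, a comfortable walk
#' @export
cot <- function(body_mass_kg, params) {
  if (any(!is.finite(body_mass_kg)) || any(body_mass_kg <= 0)) {
    stop("body mass must be positive", call. = FALSE)
  }
  params$a * body_mass_kg^params$b
}

#' Convert COT between J kg^-1 m^-1 and kcal kg^-1 km^-1
#'
#' @param cot_j_kg_m COT in J kg^-1 m^-1 (>= 0).
#' @return kcal kg^-1 km^-1 (1 kcal = 4184 J).
#' @examples
#' cot_to_kcal_per_kg_km(3)  # ~0.72
#' @export
cot_to_kcal_per_kg_km <- function(cot_j_kg_m) {
  check_nonneg(cot_j_kg_m, "cot")
  cot_j_kg_m * 1000 / .units$joules_per_kcal
}

#' Movement-weighted mean cost of transport
#'
#' A group's effective COT is the biomass-movement-weighted mean of its
#' members' COTs: cheap large movers that dominate the movement dominate
#' the average.
#'
#' @param movement nonnegative weights (any movement unit), positive sum.
#' @param cot_values COTs, J kg^-1 m^-1, same length.
#' @return Weighted mean COT.
#' @export
biomass_weighted_cot <- function(movement, cot_values) {
  check_nonneg(movement, "movement")
  stopifnot(length(movement) == length(cot_values))
  if (sum(movement) <= 0) stop("total movement weight must be positive", call. = FALSE)
  sum(movement * cot_values) / sum(movement)
}

#' Locomotion energy and power from biomass movement
#'
#' 1 Gt km = 1e15 kg m, and 1 TWh = 3.6e15 J, so energy in TWh yr^-1 is
#' movement (Gt km yr^-1) times COT (J kg^-1 m^-1) divided by 3.6. Mean
#' power spreads that energy over the 3.1536e7-second year.
#'
#' @param movement_gt_km_yr Gt km yr^-1 (>= 0).
#' @param cot_j_kg_m J kg^-1 m^-1 (>= 0).
#' @return `energy_twh`: TWh yr^-1. `mean_power_gw`: GW.
#' @examples
#' energy_twh(600, 3)      # humans walking: 500 TWh/yr
#' mean_power_gw(500)      # ~57 GW
#' @export
energy_twh <- function(movement_gt_km_yr, cot_j_kg_m) {
  check_nonneg(movement_gt_km_yr, "movement")
  check_nonneg(cot_j_kg_m, "cot")
  movement_gt_km_yr * cot_j_kg_m / 3.6
}

#' @rdname energy_twh
#' @param energy_twh_yr TWh yr^-1.
#' @export
mean_power_gw <- function(energy_twh_yr) {
  check_nonneg(energy_twh_yr, "energy")
  energy_twh_yr * .units$joules_per_twh / .units$seconds_per_year / 1e9
}

#' Build a locomotion-energy table
#'
#' One row per group: biomass movement, average COT, the energy spent on
#' locomotion per year and the corresponding mean power, both raw and
#' rounded to one significant figure.
#'
#' Two rounding paths are provided. The default derives power from the
#' unrounded energy and then rounds both. The `"round_then_derive"`
#' compatibility mode derives power from the already-rounded energy, which
#' matters only at one significant figure (e.g. 200 TWh yr^-1 -> 23 -> 20
#' GW versus 222 -> 25 -> 30 GW).
#'
#' @param groups data frame with columns `group`, `movement_gt_km_yr`,
#'   `cot_avg`, and optionally `analogue_label`.
#' @param rounding `"derive_then_round"` (default) or `"round_then_derive"`.
#' @return Tibble of energy records with raw and 1-sig-fig columns.
#' @export
build_energy_table <- function(groups,
                               rounding = c("derive_then_round", "round_then_derive")) {
  rounding <- match.arg(rounding)
  groups <- tibble::as_tibble(groups)
  if (nrow(groups) == 0) {
    return(tibble::tibble(group = character(), movement_gt_km_yr = numeric(),
                          cot_avg = numeric(), energy_twh_yr = numeric(),
                          power_gw = numeric(), energy_twh_yr_1sf = numeric(),
                          power_gw_1sf = numeric(), analogue_label = character()))
  }
  if (!"analogue_label" %in% names(groups)) groups$analogue_label <- NA_character_
  energy <- energy_twh(groups$movement_gt_km_yr, groups$cot_avg)
  energy_1sf <- round_sigfig(energy, 1)
  power <- if (rounding == "round_then_derive") {
    mean_power_gw(energy_1sf)
  } else {
    mean_power_gw(energy)
  }
  tibble::tibble(
    group = groups$group,
    movement_gt_km_yr = groups$movement_gt_km_yr,
    cot_avg = groups$cot_avg,
    energy_twh_yr = energy,
    power_gw = mean_power_gw(energy),
    energy_twh_yr_1sf = energy_1sf,
    power_gw_1sf = round_sigfig(power, 1),
    analogue_label = groups$analogue_label)
}
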