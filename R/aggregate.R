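#' Build and validate a species/group record table
#'
#' One row per taxon or subgroup. `group_path` is a slash-separated
#' hierarchy (e.g. `"land/mammals/wild"`); biomass and distances carry
#' mean/low/high columns. A row must provide at least one distance source:
#' an annual distance, a daily distance, or an activity-hours + speed pair
#' (the last yields only an upper bound, not a central estimate).
#'
#' Expected columns (missing optional ones are added as `NA`): `id`,
#' `group_path`, `locomotion_mode`, `population`, `body_mass_kg`,
#' `biomass_t`, `biomass_t_low`, `biomass_t_high`, `daily_distance_km`,
#' `daily_distance_km_low`, `daily_distance_km_high`, `annual_distance_km`,
#' `annual_distance_km_low`, `annual_distance_km_high`,
#' `activity_hours_per_day`, `characteristic_speed_km_h`.
#'
#' @param df data frame of species records.
#' @param biomass_rel_tol when both `population` and `body_mass_kg` are
#'   present, `population * body_mass_kg / 1000` must agree with
#'   `biomass_t` within this relative tolerance (default 0.25).
#' @return A validated tibble (class `species_table`).
#' @export
species_table <- function(df, biomass_rel_tol = 0.25) {
  df <- tibble::as_tibble(df)
  required <- c("id", "group_path", "biomass_t")
  missing_req <- setdiff(required, names(df))
  if (length(missing_req)) {
    stop("species table missing columns: ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  optional <- c("locomotion_mode", "population", "body_mass_kg",
                "biomass_t_low", "biomass_t_high",
                "daily_distance_km", "daily_distance_km_low", "daily_distance_km_high",
                "annual_distance_km", "annual_distance_km_low", "annual_distance_km_high",
                "activity_hours_per_day", "characteristic_speed_km_h")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (all(is.na(df$locomotion_mode))) df$locomotion_mode <- "walk_run"
  df$biomass_t_low <- ifelse(is.na(df$biomass_t_low), df$biomass_t, df$biomass_t_low)
  df$biomass_t_high <- ifelse(is.na(df$biomass_t_high), df$biomass_t, df$biomass_t_high)

  stopifnot(all(df$biomass_t >= 0, na.rm = TRUE))
  if (any(df$biomass_t_low > df$biomass_t | df$biomass_t > df$biomass_t_high, na.rm = TRUE)) {
    stop("biomass range must satisfy low <= mean <= high", call. = FALSE)
  }
  both <- !is.na(df$population) & !is.na(df$body_mass_kg) & df$biomass_t > 0
  if (any(both)) {
    implied <- df$population[both] * df$body_mass_kg[both] / .units$kg_per_tonne
    rel <- abs(implied - df$biomass_t[both]) / df$biomass_t[both]
    if (any(rel > biomass_rel_tol)) {
      bad <- df$id[both][rel > biomass_rel_tol]
      stop("population x body mass disagrees with biomass beyond tolerance for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  act <- !is.na(df$activity_hours_per_day)
  if (any(df$activity_hours_per_day[act] < 0 | df$activity_hours_per_day[act] > 24)) {
    stop("activity_hours_per_day must lie in [0, 24]", call. = FALSE)
  }
  class(df) <- c("species_table", class(df))
  df
}

# Per-leaf annual-distance uncertain value, or NULL when only an upper
# bound can be formed. Daily distances convert at 365 d/yr.
leaf_annual_distance <- function(row) {
  if (!is.na(row$annual_distance_km)) {
    lo <- if (!is.na(row$annual_distance_km_low)) row$annual_distance_km_low else row$annual_distance_km
    hi <- if (!is.na(row$annual_distance_km_high)) row$annual_distance_km_high else row$annual_distance_km
    return(uncertain(row$annual_distance_km, lo, hi))
  }
  if (!is.na(row$daily_distance_km)) {
    lo <- if (!is.na(row$daily_distance_km_low)) row$daily_distance_km_low else row$daily_distance_km
    hi <- if (!is.na(row$daily_distance_km_high)) row$daily_distance_km_high else row$daily_distance_km
    return(uncertain_scale(uncertain(row$daily_distance_km, lo, hi), .units$days_per_year))
  }
  NULL
}

#' Aggregate biomass movement over a group hierarchy
#'
#' Computes each leaf's biomass movement (biomass x annual distance, with
#' endpoint-product uncertainty), then sums up every level of the
#' `group_path` hierarchy with arithmetic-sum range propagation. Leaves
#' that carry only activity time and speed contribute an upper bound but
#' no central estimate; leaves with no usable distance information at all
#' are skipped with a warning and counted in the coverage columns, never
#' silently dropped.
#'
#' @param df a `species_table` (or data frame coercible to one).
#' @param method uncertainty propagation for sums, see
#'   [propagate_uncertainty()].
#' @return A tibble with one row per hierarchy node (plus the leaf rows,
#'   `is_leaf = TRUE`): biomass and movement mean/low/high (t, t km yr^-1),
#'   activity-based `upper_bound_t_km_yr` where available, the
#'   biomass-weighted `weighted_daily_km`, and coverage counts
#'   (`n_leaves`, `n_estimated`, `n_bound_only`, `n_skipped`).
#' @export
aggregate_movement <- function(df, method = c("arithmetic_sum", "quadrature")) {
  method <- match.arg(method)
  if (!inherits(df, "species_table")) df <- species_table(df)
  n <- nrow(df)
  if (n == 0) stop("empty species table", call. = FALSE)

  leaves <- vector("list", n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    row <- df[i, ]
    biomass <- uncertain(row$biomass_t, row$biomass_t_low, row$biomass_t_high)
    dist <- leaf_annual_distance(row)
    has_act <- !is.na(row$activity_hours_per_day) && !is.na(row$characteristic_speed_km_h)
    ub <- if (has_act) {
      upper_bound_movement(row$biomass_t, row$activity_hours_per_day,
                           row$characteristic_speed_km_h)
    } else NA_real_
    if (is.null(dist) && !has_act) {
      skipped <- c(skipped, row$id)
      leaves[[i]] <- list(status = "skipped", id = row$id, path = row$group_path)
      next
    }
    if (is.null(dist)) {
      # bound-only record: contributes to the upper bound, not the mean
      leaves[[i]] <- list(status = "bound_only", id = row$id, path = row$group_path,
                          biomass = biomass, upper_bound = ub)
    } else {
      mv <- uncertain_product(biomass, dist)
      leaves[[i]] <- list(status = "estimated", id = row$id, path = row$group_path,
                          biomass = biomass, movement = mv,
                          upper_bound = if (has_act) max(ub, mv$high) else mv$high)
    }
  }
  if (length(skipped)) {
    warning("skipped ", length(skipped), " leaf record(s) with no usable distance: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }

  # every node = every proper prefix of every leaf path, plus a root "total"
  paths <- vapply(leaves, function(l) l$path, character(1))
  node_paths <- unique(unlist(lapply(strsplit(paths, "/", fixed = TRUE), function(p) {
    vapply(seq_along(p), function(k) paste(p[seq_len(k)], collapse = "/"), character(1))
  })))
  node_paths <- c("total", sort(node_paths))

  rows <- lapply(node_paths, function(np) {
    if (np == "total") {
      in_node <- rep(TRUE, n)
    } else {
      in_node <- paths == np | startsWith(paths, paste0(np, "/"))
    }
    members <- leaves[in_node]
    status <- vapply(members, function(l) l$status, character(1))
    est <- members[status == "estimated"]
    bnd <- members[status == "bound_only"]
    usable <- c(est, bnd)
    if (length(usable) == 0) {
      return(tibble::tibble(
        node = np, is_leaf = FALSE, n_leaves = length(members),
        n_estimated = 0L, n_bound_only = 0L, n_skipped = sum(status == "skipped"),
        biomass_t = NA_real_, biomass_t_low = NA_real_, biomass_t_high = NA_real_,
        movement_t_km_yr = NA_real_, movement_t_km_yr_low = NA_real_,
        movement_t_km_yr_high = NA_real_, upper_bound_t_km_yr = NA_real_,
        weighted_daily_km = NA_real_))
    }
    biomass <- propagate_uncertainty(lapply(usable, `[[`, "biomass"), method)
    if (length(est)) {
      mv <- propagate_uncertainty(lapply(est, `[[`, "movement"), method)
      wdd <- if (biomass$mean > 0)
        weighted_mean_daily_distance(mv$mean, biomass$mean)
      else NA_real_
    } else {
      mv <- NULL
      wdd <- NA_real_
    }
    ubs <- vapply(usable, function(l)
      if (!is.null(l$upper_bound)) l$upper_bound else NA_real_, numeric(1))
    tibble::tibble(
      node = np,
      is_leaf = np %in% paths & sum(in_node) == 1,
      n_leaves = length(members),
      n_estimated = length(est), n_bound_only = length(bnd),
      n_skipped = sum(status == "skipped"),
      biomass_t = biomass$mean, biomass_t_low = biomass$low,
      biomass_t_high = biomass$high,
      movement_t_km_yr = if (is.null(mv)) NA_real_ else mv$mean,
      movement_t_km_yr_low = if (is.null(mv)) NA_real_ else mv$low,
      movement_t_km_yr_high = if (is.null(mv)) NA_real_ else mv$high,
      upper_bound_t_km_yr = if (all(is.na(ubs))) NA_real_ else sum(ubs, na.rm = TRUE),
      weighted_daily_km = wdd)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_ids") <- skipped
  out
}
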