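#' Load the bundled headline-value fixtures
#'
#' The package ships the published headline values (group movements with
#' ranges and bounds, the locomotion-energy table inputs, historical
#' endpoints, composition shares and the case studies) as a structured
#' YAML file. Every entry carries units and a provenance string naming
#' where in the source synthesis it was printed. The report functions
#' recompute all derived numbers from these inputs through the accounting
#' and energetics operations; nothing derived is copied.
#'
#' @param path fixture file; defaults to the bundled one.
#' @return Nested list of fixture entries.
#' @export
load_fixtures <- function(path = system.file("extdata", "paper_values.yaml",
                                             package = "biomovr")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("fixture file not found: ", path, call. = FALSE)
  }
  fx <- yaml::read_yaml(path)
  validate_fixtures(fx)
  fx
}

validate_fixtures <- function(fx) {
  problems <- character(0)
  check_entry <- function(e, where) {
    if (!is.list(e) || is.null(e$value)) {
      problems <<- c(problems, paste0(where, ": missing value"))
      return()
    }
    lo <- e$low %||% e$value
    hi <- e$high %||% e$value
    if (!(lo <= e$value && e$value <= hi)) {
      problems <<- c(problems, paste0(where, ": range must satisfy low <= value <= high"))
    }
    if (!is.null(e$bound) && e$bound < hi) {
      problems <<- c(problems, paste0(where, ": bound below high"))
    }
  }
  for (g in names(fx$groups)) {
    check_entry(fx$groups[[g]]$movement, paste0("groups/", g, "/movement"))
  }
  for (nm in c("movement_total", "walking", "air", "biomass")) {
    if (!is.null(fx$humans[[nm]])) check_entry(fx$humans[[nm]], paste0("humans/", nm))
  }
  if (length(problems)) {
    stop("fixture validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(fx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived report outputs must fail loudly when an input entry is gone
need <- function(x, where) {
  if (is.null(x)) stop("missing fixture entry: ", where, call. = FALSE)
  x
}

fixture_uncertain <- function(e, basis = "ci95") {
  uncertain(e$value, e$low %||% e$value, e$high %||% e$value, basis = basis,
            hard_upper_bound = e$bound %||% NULL)
}

#' Assemble the headline report from fixtures
#'
#' Recomputes, through the package's accounting and energetics operations:
#' (a) the land-group table with ranges, bounds and biomass-weighted daily
#' distances plus the wildlife total; (b) the locomotion-energy table; (c)
#' the historical change summary (marine decline, human fold change,
#' composition shares); (d) the case-study comparison table, each entry's
#' movement recomputed from its population, mass and distance where those
#' are given.
#'
#' @param fixtures output of [load_fixtures()].
#' @param energy_rounding passed to [build_energy_table()].
#' @return List of tibbles: `land_groups`, `energy`, `change`,
#'   `composition`, `case_studies`, and headline `ratios`.
#' @export
run_report <- function(fixtures = load_fixtures(),
                       energy_rounding = "derive_then_round") {
  fx <- fixtures
  if (length(fx) == 0) {
    return(list(land_groups = tibble::tibble(), energy = tibble::tibble(),
                change = tibble::tibble(), composition = tibble::tibble(),
                case_studies = tibble::tibble(), ratios = tibble::tibble()))
  }

  # (a) land groups: ranges, bounds, weighted daily distance, wildlife sum
  wild_names <- c("wild_land_mammals", "land_arthropods", "wild_birds")
  gvals <- lapply(fx$groups[wild_names], function(g) fixture_uncertain(g$movement))
  wildlife <- propagate_uncertainty(gvals)
  land_groups <- dplyr::bind_rows(lapply(names(fx$groups), function(nm) {
    g <- fx$groups[[nm]]
    mv <- fixture_uncertain(g$movement)
    biomass_t <- g$biomass$value %||% NA_real_
    tibble::tibble(
      group = nm,
      movement_gt_km_yr = mv$mean, low = mv$low, high = mv$high,
      upper_bound = g$movement$bound %||% NA_real_,
      biomass_t = biomass_t,
      weighted_daily_km = if (!is.na(biomass_t) && biomass_t > 0)
        weighted_mean_daily_distance(mv$mean * .units$tonnes_per_gt, biomass_t)
      else NA_real_)
  }))
  land_groups <- dplyr::bind_rows(
    land_groups,
    tibble::tibble(group = "wildlife_combined_recomputed",
                   movement_gt_km_yr = wildlife$mean, low = wildlife$low,
                   high = wildlife$high,
                   upper_bound = wildlife$hard_upper_bound %||% NA_real_,
                   biomass_t = NA_real_, weighted_daily_km = NA_real_))

  # (b) energy table
  energy <- build_energy_table(
    dplyr::bind_rows(lapply(fx$energy_table, tibble::as_tibble)),
    rounding = energy_rounding)

  # (c) historical change
  total_now <- need(fx$humans$movement_total$value, "humans/movement_total")
  human_fold <- fold_change(total_now,
                            total_now /
                              need(fx$humans$fold_change_since_1850$value,
                                   "humans/fold_change_since_1850"))
  change <- tibble::tibble(
    quantity = c("marine_decline_pct", "human_fold_change"),
    value = c(decline_percent(need(fx$marine$movement_1850$value,
                                   "marine/movement_1850"),
                              need(fx$marine$movement_present$value,
                                   "marine/movement_present")),
              human_fold))

  comp_tbl <- function(lst, domain) {
    vals <- vapply(lst, function(e) e$value, numeric(1))
    tibble::tibble(domain = domain, component = names(vals),
                   share_pct = composition_shares(vals))
  }
  composition <- dplyr::bind_rows(
    comp_tbl(fx$marine$composition_pct, "marine"),
    comp_tbl(fx$humans$mode_shares_pct, "human"))

  # (d) case studies, movement recomputed where inputs allow
  cs <- fx$case_studies
  case_rows <- lapply(names(cs), function(nm) {
    e <- cs[[nm]]
    mv_t <- if (!is.null(e$population) && !is.null(e$body_mass_kg) &&
                !is.null(e$annual_distance_km)) {
      movement_from_population(e$population, e$body_mass_kg, e$annual_distance_km)
    } else if (!is.null(e$biomass_t) && !is.null(e$daily_distance_km)) {
      biomass_movement(e$biomass_t, e$daily_distance_km * .units$days_per_year)
    } else if (!is.null(e$biomass_t) && !is.null(e$speed_km_h)) {
      upper_bound_movement(e$biomass_t, e$activity_hours_per_day, e$speed_km_h)
    } else if (!is.null(e$movement_gt_km_yr)) {
      e$movement_gt_km_yr * .units$tonnes_per_gt
    } else NA_real_
    tibble::tibble(case = nm,
                   mass_t = e$biomass_t %||%
                     (if (!is.null(e$population) && !is.null(e$body_mass_kg))
                       e$population * e$body_mass_kg / .units$kg_per_tonne
                      else NA_real_),
                   annual_distance_km = e$annual_distance_km %||% NA_real_,
                   movement_t_km_yr = mv_t,
                   movement_gt_km_yr = mv_t / .units$tonnes_per_gt)
  })
  case_studies <- dplyr::bind_rows(case_rows)
  # the Serengeti entry is printed as a multiple of the wolf total
  if (!is.null(cs$serengeti_migration$wolves_multiple) &&
      !is.null(cs$grey_wolves$movement_gt_km_yr)) {
    idx <- case_studies$case == "serengeti_migration"
    mv <- cs$grey_wolves$movement_gt_km_yr * cs$serengeti_migration$wolves_multiple
    case_studies$movement_gt_km_yr[idx] <- mv
    case_studies$movement_t_km_yr[idx] <- mv * .units$tonnes_per_gt
  }

  ratios <- tibble::tibble(
    quantity = c("human_to_wildlife_ratio", "walking_share_pct",
                 "human_biomass_gt", "human_daily_km"),
    value = c(
      relative_share(total_now, wildlife$mean),
      100 * relative_share(need(fx$humans$walking$value, "humans/walking"),
                           total_now),
      need(fx$humans$population$value, "humans/population") *
        need(fx$humans$body_mass_kg$value, "humans/body_mass_kg") /
        .units$kg_per_tonne / .units$tonnes_per_gt,
      weighted_mean_daily_distance(
        total_now * .units$tonnes_per_gt,
        need(fx$humans$biomass$value, "humans/biomass"))))

  list(land_groups = land_groups, energy = energy, change = change,
       composition = composition, case_studies = case_studies, ratios = ratios)
}

#' Write a report to CSV files plus a JSON summary
#'
#' @param report output of [run_report()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]) && nrow(report[[nm]])) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
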