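# shared builders for tests: tiny species tables and analytic tracks

# leaf rows whose movement is exactly biomass * annual distance
make_leaves <- function(paths, biomass_t, annual_km, ids = NULL) {
  tibble::tibble(
    id = ids %||% sprintf("leaf_%02d", seq_along(paths)),
    group_path = paths,
    biomass_t = biomass_t,
    annual_distance_km = annual_km)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# track of fixes marching north along a meridian: step_km apart, dt_s spacing
meridian_track <- function(n_fixes, step_km = 10, dt_s = 3600, id = "m1",
                           lat0 = 0, lon = 0,
                           t0 = as.POSIXct("2020-01-01", tz = "UTC")) {
  dlat <- step_km / (pi * 6371 / 180)
  track(id,
        t0 + (seq_len(n_fixes) - 1) * dt_s,
        lat0 + (seq_len(n_fixes) - 1) * dlat,
        rep(lon, n_fixes))
}

# random species table with multi-level group paths, for aggregation props
random_species_table <- function(n, seed) {
  set.seed(seed)
  depth1 <- sample(c("land", "sea"), n, replace = TRUE)
  depth2 <- sample(c("a", "b", "c"), n, replace = TRUE)
  depth3 <- ifelse(runif(n) < 0.5, "", paste0("/", sample(c("x", "y"), n, TRUE)))
  make_leaves(paste0(depth1, "/", depth2, depth3),
              biomass_t = rlnorm(n, 10, 2),
              annual_km = rlnorm(n, 6, 1),
              ids = sprintf("sp_%03d", seq_len(n)))
}
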