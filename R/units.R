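#' Unit conventions shared across the package
#'
#' One shared record of the unit constants every computation reads: the
#' day/year and second/year conversions used to annualize distances and turn
#' energy into power, the Joule equivalents of a terawatt-hour and a dietary
#' kilocalorie, mass-unit conversions, and the spherical Earth radius used
#' for great-circle geometry.
#'
#' All internal arithmetic runs in tonnes, kilometres and years; headline
#' display is in Gt km yr^-1. A year is 365 days for daily-to-annual
#' conversion and 3.1536e7 seconds for power.
#'
#' @return A named list of positive numeric constants:
#'   `days_per_year` (365), `seconds_per_year` (3.1536e7),
#'   `joules_per_twh` (3.6e15), `joules_per_kcal` (4184),
#'   `tonnes_per_gt` (1e9), `kg_per_tonne` (1e3), `earth_radius_km` (6371).
#' @examples
#' unit_conventions()$days_per_year
#' @export
unit_conventions <- function() {
  list(
    days_per_year   = 365,
    seconds_per_year = 3.1536e7,
    joules_per_twh  = 3.6e15,
    joules_per_kcal = 4184,
    tonnes_per_gt   = 1e9,
    kg_per_tonne    = 1e3,
    earth_radius_km = 6371
  )
}

# single shared instance read by every operation
.units <- unit_conventions()

#' Round to n significant figures, half away from zero
#'
#' Headline values are reported at one significant figure. `round()` in R
#' rounds half to even; published headline figures use half-away-from-zero
#' (75 -> 80 at one significant figure), so this is implemented directly.
#'
#' @param x numeric vector.
#' @param n number of significant figures (>= 1).
#' @return `x` rounded at the n-th significant digit; 0 maps to 0.
#' @examples
#' round_sigfig(75, 1)     # 80
#' round_sigfig(33333, 1)  # 30000
#' round_sigfig(4.1, 1)    # 4
#' @export
round_sigfig <- function(x, n = 1) {
  stopifnot(is.numeric(x), length(n) == 1, n >= 1, n == as.integer(n))
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz]))) - (n - 1)
    scaled <- abs(x[nz]) / 10^e
    out[nz] <- sign(x[nz]) * floor(scaled + 0.5) * 10^e
  }
  out
}
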