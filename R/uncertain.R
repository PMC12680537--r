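#' Uncertain value: mean with range and optional hard upper bound
#'
#' The basic quantity carried through the accounting: a mean with a lower
#' and upper range, tagged by the basis of the range (95% CI, extrema, or a
#' bound-only record with no central estimate), and an optional hard upper
#' bound that must dominate the range.
#'
#' @param mean central estimate (>= 0); may be `NA` for `basis = "bound_only"`.
#' @param low,high range endpoints; default to `mean` (zero-width range).
#' @param basis one of `"ci95"`, `"extrema"`, `"bound_only"`.
#' @param hard_upper_bound optional hard upper bound, `>= high` when both
#'   are present.
#' @return An object of class `uncertain_value` (a named list).
#' @examples
#' uncertain(30, 10, 70, basis = "ci95", hard_upper_bound = 150)
#' @export
uncertain <- function(mean, low = mean, high = mean,
                      basis = c("ci95", "extrema", "bound_only"),
                      hard_upper_bound = NULL) {
  basis <- match.arg(basis)
  if (basis == "bound_only") {
    if (is.null(hard_upper_bound) || !is.finite(hard_upper_bound)) {
      stop("bound_only values require a finite hard_upper_bound", call. = FALSE)
    }
  } else {
    stopifnot(is.finite(mean), is.finite(low), is.finite(high))
    if (mean < 0 || low < 0) stop("uncertain values must be nonnegative", call. = FALSE)
    if (!(low <= mean && mean <= high)) {
      stop("uncertain value requires low <= mean <= high", call. = FALSE)
    }
  }
  if (!is.null(hard_upper_bound)) {
    stopifnot(is.finite(hard_upper_bound), hard_upper_bound >= 0)
    if (basis != "bound_only" && hard_upper_bound < high) {
      stop("hard_upper_bound must be >= high", call. = FALSE)
    }
  }
  structure(
    list(mean = if (basis == "bound_only" && missing(mean)) NA_real_ else mean,
         low = if (basis == "bound_only" && missing(mean)) NA_real_ else low,
         high = if (basis == "bound_only" && missing(mean)) NA_real_ else high,
         basis = basis,
         hard_upper_bound = hard_upper_bound),
    class = "uncertain_value"
  )
}

#' @export
print.uncertain_value <- function(x, ...) {
  cat(sprintf("<uncertain> mean %g [%g, %g] (%s)%s\n",
              x$mean, x$low, x$high, x$basis,
              if (!is.null(x$hard_upper_bound))
                sprintf(", bound %g", x$hard_upper_bound) else ""))
  invisible(x)
}

is_uncertain <- function(x) inherits(x, "uncertain_value")

#' Sum uncertain values with conservative range propagation
#'
#' Group-level ranges are the arithmetic sum of the ranges of the
#' subgroups: the lower (upper) offset of the sum is the sum of the
#' children's lower (upper) offsets. This deliberately over-covers relative
#' to independent-error quadrature so that systematic biases shared across
#' subgroups are not understated. Quadrature (root-sum-square offsets) is
#' available as an explicit alternative and is never the default.
#'
#' @param children nonempty list of `uncertain_value` objects.
#' @param method `"arithmetic_sum"` (default) or `"quadrature"`.
#' @return An `uncertain_value` for the sum. Hard upper bounds sum when all
#'   children carry one; otherwise the result has none.
#' @examples
#' propagate_uncertainty(list(uncertain(10, 8, 12), uncertain(20, 15, 25)))
#' @export
propagate_uncertainty <- function(children,
                                  method = c("arithmetic_sum", "quadrature")) {
  method <- match.arg(method)
  if (!is.list(children) || length(children) == 0) {
    stop("children must be a nonempty list of uncertain values", call. = FALSE)
  }
  stopifnot(all(vapply(children, is_uncertain, logical(1))))
  m <- vapply(children, function(x) x$mean, numeric(1))
  lo_off <- vapply(children, function(x) x$mean - x$low, numeric(1))
  hi_off <- vapply(children, function(x) x$high - x$mean, numeric(1))
  mean_sum <- sum(m)
  if (method == "arithmetic_sum") {
    low <- mean_sum - sum(lo_off)
    high <- mean_sum + sum(hi_off)
  } else {
    low <- mean_sum - sqrt(sum(lo_off^2))
    high <- mean_sum + sqrt(sum(hi_off^2))
  }
  bounds <- lapply(children, function(x) x$hard_upper_bound)
  hub <- if (all(!vapply(bounds, is.null, logical(1)))) {
    sum(unlist(bounds))
  } else NULL
  basis <- unique(vapply(children, function(x) x$basis, character(1)))
  uncertain(mean_sum, max(low, 0), high,
            basis = if (length(basis) == 1) basis else "extrema",
            hard_upper_bound = hub)
}

#' Multiply two uncertain values by endpoint products
#'
#' Product uncertainty for biomass x distance uses endpoint products
#' (low x low, high x high): conservative and monotone, matching the
#' package's arithmetic-sum stance on shared systematic bias.
#'
#' @param a,b `uncertain_value` objects (nonnegative).
#' @return An `uncertain_value` with mean `a$mean * b$mean` and endpoint
#'   product range.
#' @export
uncertain_product <- function(a, b) {
  stopifnot(is_uncertain(a), is_uncertain(b))
  uncertain(a$mean * b$mean, a$low * b$low, a$high * b$high,
            basis = if (a$basis == b$basis) a$basis else "extrema")
}

#' Scale an uncertain value by a nonnegative constant
#' @param x an `uncertain_value`.
#' @param k nonnegative finite scalar.
#' @return The scaled `uncertain_value`; the hard upper bound scales too.
#' @export
uncertain_scale <- function(x, k) {
  stopifnot(is_uncertain(x), is.finite(k), k >= 0)
  uncertain(x$mean * k, x$low * k, x$high * k, basis = x$basis,
            hard_upper_bound = if (!is.null(x$hard_upper_bound))
              x$hard_upper_bound * k else NULL)
}
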