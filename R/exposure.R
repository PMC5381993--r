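#' Airborne-concentration coefficients for the quantitative exposure metric
#'
#' Work-area exposure is recorded as years employed in light, medium, or heavy
#' exposed jobs. The quantitative metric (in mg/m^3-years) multiplies the
#' duration in each category by its time-weighted airborne concentration, with
#' the heavy category down-weighted by `gamma` to reflect the use of
#' filtration masks in the most heavily exposed work areas:
#'
#' \deqn{d = c_L \cdot y_L + c_M \cdot y_M + \gamma \, c_H \cdot y_H}
#'
#' Defaults are the concentrations 0.29 (light), 0.58 (medium) and
#' 11.4 mg/m^3 (heavy) with \eqn{\gamma = 0.1}.
#'
#' @param conc_light,conc_medium,conc_heavy airborne concentrations, mg/m^3;
#'   must be positive and strictly increasing.
#' @param gamma heavy-category discount weight, in (0, 1].
#' @return an object of class `exposure_coefficients`.
#' @export
#' @examples
#' exposure_coefficients()
exposure_coefficients <- function(conc_light = 0.29, conc_medium = 0.58,
                                  conc_heavy = 11.4, gamma = 0.1) {
  stopifnot(is.numeric(conc_light), is.numeric(conc_medium),
            is.numeric(conc_heavy), is.numeric(gamma))
  if (!(conc_light > 0 && conc_medium > conc_light && conc_heavy > conc_medium))
    stop("category concentrations must be positive and strictly increasing")
  if (!(gamma > 0 && gamma <= 1))
    stop("gamma must lie in (0, 1]")
  structure(list(conc_light = conc_light, conc_medium = conc_medium,
                 conc_heavy = conc_heavy, gamma = gamma),
            class = "exposure_coefficients")
}

#' @export
print.exposure_coefficients <- function(x, ...) {
  cat(sprintf(
    "Exposure metric coefficients (mg/m^3): light %.3g, medium %.3g, heavy %.3g (gamma = %.3g)\n",
    x$conc_light, x$conc_medium, x$conc_heavy, x$gamma))
  invisible(x)
}

#' Cumulative exposure metric from category-specific durations
#'
#' @param years_light,years_medium,years_heavy years employed in each category
#'   (non-negative; vectors are recycled to a common length).
#' @param coeffs an [exposure_coefficients()] object.
#' @return cumulative exposure in mg/m^3-years.
#' @export
#' @examples
#' exposure_metric(1, 1, 1)  # 0.29 + 0.58 + 0.1 * 11.4 = 2.01
exposure_metric <- function(years_light, years_medium, years_heavy,
                            coeffs = exposure_coefficients()) {
  stopifnot(inherits(coeffs, "exposure_coefficients"))
  if (any(years_light < 0) || any(years_medium < 0) || any(years_heavy < 0))
    stop("durations must be non-negative")
  coeffs$conc_light * years_light + coeffs$conc_medium * years_medium +
    coeffs$gamma * coeffs$conc_heavy * years_heavy
}

#' One-year exposure increment for an exposure category
#'
#' @param category character vector with values in
#'   `c("none", "light", "medium", "heavy")`.
#' @param coeffs an [exposure_coefficients()] object.
#' @return mg/m^3-years accrued in one year at that category.
#' @export
#' @examples
#' annual_increment(c("none", "light", "heavy"))
annual_increment <- function(category, coeffs = exposure_coefficients()) {
  stopifnot(inherits(coeffs, "exposure_coefficients"))
  category <- as.character(category)
  bad <- setdiff(unique(category), c("none", "light", "medium", "heavy"))
  if (length(bad))
    stop("unknown exposure category: ", paste(bad, collapse = ", "))
  inc <- c(none = 0, light = coeffs$conc_light, medium = coeffs$conc_medium,
           heavy = coeffs$gamma * coeffs$conc_heavy)
  unname(inc[category])
}

#' Lag/window specification for time-windowed cumulative exposure
#'
#' Exposure enters the hazard models lagged by `lag` whole years, with separate
#' coefficients for exposure accrued `(2,5]`, `(5,10]` and `(10,20]` years
#' before the current period, and no contribution beyond `truncation` years.
#' Windows are half-open on the left and closed on the right, interpreted on
#' whole-year distances: the increment accrued in the annual period
#' `[a-k-1, a-k)` lies `k` years before age `a`, so window `(2,5]` collects
#' `k` in `{3,4,5}`.
#'
#' @param lag lag in whole years before exposure becomes active (default 2).
#' @param windows list of `(start, stop]` pairs in years-before-now; must be
#'   non-overlapping, contiguous, ordered, with the first starting at `lag`.
#' @param truncation distance beyond which exposure never contributes.
#' @return an object of class `lag_spec`.
#' @export
lag_spec <- function(lag = 2,
                     windows = list(c(2, 5), c(5, 10), c(10, 20)),
                     truncation = 20) {
  stopifnot(length(lag) == 1, lag >= 0, is.list(windows), length(windows) >= 1)
  w <- do.call(rbind, lapply(windows, function(x) {
    stopifnot(length(x) == 2, x[1] < x[2]); as.numeric(x)
  }))
  if (w[1, 1] != lag)
    stop("first window must start at the lag (", lag, ")")
  if (nrow(w) > 1 && any(w[-1, 1] != w[-nrow(w), 2]))
    stop("windows must be contiguous and ordered")
  if (w[nrow(w), 2] != truncation)
    stop("last window must end at the truncation distance")
  structure(list(lag = lag, windows = w, truncation = truncation),
            class = "lag_spec")
}

#' Time-windowed sums of an annual exposure-increment history
#'
#' @param increments numeric vector of annual increments (mg/m^3-years), one
#'   per contiguous annual period.
#' @param ages integer start ages of the periods in `increments`; must be
#'   contiguous (unemployed years carry increment 0, never a gap) and cover
#'   ages up to `current_age - 1`.
#' @param current_age the age "now" at which windows are evaluated.
#' @param spec a [lag_spec()].
#' @return named numeric vector, one window sum per window, e.g.
#'   `c(w_2_5 = ..., w_5_10 = ..., w_10_20 = ...)`.
#' @export
#' @examples
#' # a single unit increment accrued 3 years before now falls in (2,5]
#' lagged_window_sums(1, ages = 37, current_age = 41)
lagged_window_sums <- function(increments, ages, current_age,
                               spec = lag_spec()) {
  stopifnot(inherits(spec, "lag_spec"), length(increments) == length(ages))
  if (length(ages) > 1 && any(diff(ages) != 1))
    stop("exposure history has gaps: ages must be contiguous")
  if (length(ages) && max(ages) > current_age - 1)
    stop("history extends beyond current_age - 1")
  k <- current_age - ages - 1  # whole-year distance of period [age, age+1)
  w <- spec$windows
  out <- vapply(seq_len(nrow(w)), function(j) {
    sum(increments[k >= w[j, 1] + 1 & k <= w[j, 2]])
  }, numeric(1))
  names(out) <- sprintf("w_%g_%g", w[, 1], w[, 2])
  out
}
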