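#' Restricted cubic spline basis (truncated power form)
#'
#' Harrell's restricted cubic spline: cubic between the boundary knots and
#' constrained to be linear beyond them. For `k` knots the basis has `k - 1`
#' columns: the linear term `x` followed by `k - 2` nonlinear terms, each
#' scaled by `(t_k - t_1)^2` so coefficients are on comparable scales.
#' Choosing all nonlinear coefficients zero reproduces a linear function of
#' `x` exactly.
#'
#' @param x numeric vector at which to evaluate the basis.
#' @param knots increasing numeric vector of at least 3 knot locations.
#' @return matrix with `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3) stop("restricted cubic spline needs at least 3 knots")
  if (anyDuplicated(knots)) stop("knots must be distinct")
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm2 <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(out) <- c("rcs1", if (k > 2) paste0("rcs", 1 + seq_len(k - 2)))
  out
}

#' Default spline knots from observed event ages
#'
#' Knots at the 5, 27.5, 50, 72.5 and 95 percentiles of ages at death in a
#' person-period table (conventional quantile placement).
#'
#' @param pp a person-period table.
#' @return numeric vector of 5 knot locations (deduplicated; an error if fewer
#'   than 3 distinct locations remain).
#' @export
default_knots <- function(pp) {
  ev <- pp$age[pp$d_resp == 1L | pp$d_heart == 1L | pp$d_other == 1L]
  if (!length(ev)) stop("no death events; cannot place spline knots")
  kn <- unique(unname(quantile(ev, c(0.05, 0.275, 0.5, 0.725, 0.95))))
  if (length(kn) < 3) stop("fewer than 3 distinct knot locations")
  kn
}

## covariate vocabulary -------------------------------------------------------

## Each covariate name maps to one or more design-matrix columns built from a
## covariate environment `env` (a list or data.table exposing age,
## calendar_year, employed, cum_work, the lag windows and baseline fields).
## Age and calendar time are centred (age 50, year 1950) and scaled by a
## decade so coefficients are log-odds per 10 years.
.cov_expand <- function(name, env, knots = NULL) {
  g <- function(f) {
    v <- env[[f]]
    if (is.null(v)) stop("missing covariate: ", f)
    v
  }
  switch(name,
    age_c     = list(age_c = (g("age") - 50) / 10),
    year_c    = list(year_c = (g("calendar_year") - 1950) / 10),
    age_year  = list(age_year = (g("age") - 50) / 10 *
                       (g("calendar_year") - 1950) / 10),
    age_spline = {
      if (is.null(knots)) stop("age_spline requires knot locations")
      b <- rcs_basis(g("age"), knots)
      b[, 1] <- (b[, 1] - 50) / 10  # linear term on the age_c scale
      cols <- lapply(seq_len(ncol(b)), function(j) b[, j])
      names(cols) <- paste0("age_", colnames(b))
      cols
    },
    employed  = list(employed = as.numeric(g("employed"))),
    cum_work_c = list(cum_work_c = g("cum_work") / 10),
    us_born   = list(us_born = as.numeric(g("us_born"))),
    pre_entry_years = list(pre_entry_years = g("pre_entry_years_worked")),
    pre_entry_exposure = list(pre_entry_exposure = g("pre_entry_exposure")),
    w_2_5     = list(w_2_5 = g("w_2_5")),
    w_5_10    = list(w_5_10 = g("w_5_10")),
    w_10_20   = list(w_10_20 = g("w_10_20")),
    w_recent_1_5 = list(w_recent_1_5 = g("w_recent_1_5")),
    stop("unknown covariate name in model spec: ", name)
  )
}

.cov_columns <- function(covariates, env, knots = NULL) {
  out <- list()
  for (nm in covariates) out <- c(out, .cov_expand(nm, env, knots))
  out
}

#' Build a design matrix for a discrete-time hazard model
#'
#' Expands a covariate name list into named numeric columns. Available names:
#' `age_c` ((age-50)/10), `year_c` ((year-1950)/10), `age_year` (product),
#' `age_spline` (restricted cubic spline of age; linear term on the `age_c`
#' scale), `employed`, `cum_work_c` (post-entry years worked / 10), `us_born`,
#' `pre_entry_years`, `pre_entry_exposure`, `w_2_5`, `w_5_10`, `w_10_20`
#' (lagged exposure windows, mg/m^3-years) and `w_recent_1_5` (exposure in the
#' preceding 1-5 whole years, used by the employment models).
#'
#' @param pp person-period table (or any list-like with the needed fields).
#' @param covariates character vector of covariate names.
#' @param knots spline knots, required when `age_spline` is used.
#' @param intercept prepend an intercept column (default TRUE).
#' @return numeric matrix with stable, documented column names.
#' @export
design_matrix <- function(pp, covariates, knots = NULL, intercept = TRUE) {
  cols <- .cov_columns(covariates, pp, knots)
  n <- max(vapply(cols, length, 1L), if (is.data.frame(pp)) nrow(pp) else 1L)
  m <- if (length(cols))
    do.call(cbind, lapply(cols, function(v) rep_len(v, n)))
  else matrix(numeric(0), n, 0)
  if (intercept) m <- cbind(`(Intercept)` = 1, m)
  m
}

#' Expand baseline + annual history tables into a person-period table
#'
#' One row per worker-year at risk, from entry to the earliest of death,
#' `max_age`, or the administrative end of follow-up, with engineered
#' covariates: annual exposure increments, lagged exposure windows, cumulative
#' post-entry work time, previous-period employment status, and cause-specific
#' death indicators set on the final row only.
#'
#' @param baseline data.frame with columns `worker_id`, `entry_age`,
#'   `entry_year`, `birth_year`, `us_born`, `pre_entry_years_worked`,
#'   `pre_entry_exposure`.
#' @param history data.frame with columns `worker_id`, `age`, `calendar_year`,
#'   `employed`, `exposure_category` (none/light/medium/heavy), `death_cause`
#'   (none/resp_cancer/heart/other); rows contiguous in age within worker.
#' @param coeffs an [exposure_coefficients()] object.
#' @param spec a [lag_spec()] (fixed default windows (2,5], (5,10], (10,20]).
#' @param max_age,admin_end_year censoring bounds; a death recorded beyond
#'   either is an error.
#' @return a `data.table` of class `person_period`.
#' @export
expand_to_person_periods <- function(baseline, history,
                                     coeffs = exposure_coefficients(),
                                     spec = lag_spec(),
                                     max_age = 90, admin_end_year = 1990) {
  b <- data.table::as.data.table(baseline)
  h <- data.table::as.data.table(history)
  req_b <- c("worker_id", "entry_age", "entry_year", "birth_year", "us_born",
             "pre_entry_years_worked", "pre_entry_exposure")
  req_h <- c("worker_id", "age", "calendar_year", "employed",
             "exposure_category", "death_cause")
  if (!all(req_b %in% names(b))) stop("baseline table missing columns")
  if (!all(req_h %in% names(h))) stop("history table missing columns")
  data.table::setkeyv(h, c("worker_id", "age"))
  if (anyDuplicated(h, by = c("worker_id", "age")))
    stop("overlapping rows: duplicate (worker_id, age)")
  gap <- h[, any(diff(age) != 1L), by = worker_id][V1 == TRUE]
  if (nrow(gap)) stop("history has age gaps for worker(s): ",
                      paste(head(gap$worker_id, 5), collapse = ", "))
  dead <- h[death_cause != "none"]
  if (nrow(dead)) {
    if (any(dead$age >= max_age) || any(dead$calendar_year > admin_end_year))
      stop("death recorded after administrative end of follow-up")
    n_dead <- dead[, .N, by = worker_id]
    if (any(n_dead$N > 1)) stop("more than one death recorded for a worker")
    last <- h[, .(last_age = max(age)), by = worker_id]
    chk <- merge(dead[, .(worker_id, age)], last, by = "worker_id")
    if (any(chk$age != chk$last_age))
      stop("death must occur on a worker's final history row")
  }
  if (h[employed == 0L & exposure_category != "none", .N] > 0)
    stop("exposure category present in an unemployed year")

  pp <- h[, {
    inc <- annual_increment(exposure_category, coeffs)
    S <- cumsum(inc)
    sh <- function(k) data.table::shift(S, k, fill = 0)
    list(age = age, calendar_year = calendar_year, employed = employed,
         exposure_category = exposure_category, increment = inc,
         cum_exposure = S,
         cum_work = data.table::shift(cumsum(employed), 1L, fill = 0),
         employed_prev = data.table::shift(employed, 1L, fill = 1L),
         w_2_5 = sh(4) - sh(7),
         w_5_10 = sh(7) - sh(12),
         w_10_20 = sh(12) - sh(22),
         w_recent_1_5 = sh(2) - sh(7),
         d_resp = as.integer(death_cause == "resp_cancer"),
         d_heart = as.integer(death_cause == "heart"),
         d_other = as.integer(death_cause == "other"))
  }, by = worker_id]
  pp <- merge(pp, b[, .(worker_id, entry_age, us_born,
                        pre_entry_years_worked, pre_entry_exposure)],
              by = "worker_id", sort = FALSE)
  pp[, at_risk := 1L]
  data.table::setkeyv(pp, c("worker_id", "age"))
  data.table::setattr(pp, "class", c("person_period", class(pp)))
  data.table::setattr(pp, "coeffs", coeffs)
  data.table::setattr(pp, "lag_spec", spec)
  pp[]
}

#' @export
print.person_period <- function(x, ...) {
  cat(sprintf("Person-period table: %d worker-years, %d workers, ages %d-%d\n",
              nrow(x), data.table::uniqueN(x$worker_id),
              min(x$age), max(x$age)))
  cat(sprintf("  deaths: resp_cancer %d, heart %d, other %d\n",
              sum(x$d_resp), sum(x$d_heart), sum(x$d_other)))
  NextMethod()
}
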