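#' Specify a hypothetical workplace intervention on exposure
#'
#' Five interventions are supported. `natural_course` simulates exposure from
#' the fitted ordinal model while employed. `never_exposed` forces a zero
#' exposure increment in every period. `always_light`, `always_medium` and
#' `always_heavy` force the named category whenever the pseudo-worker is
#' employed (and `none` when not). Employment dynamics are always simulated
#' from the fitted employment models with the *intervened* exposure history as
#' input: exposure keeps affecting who stays at work, which is precisely the
#' healthy-worker-survivor pathway the g-formula standardizes over.
#'
#' @param kind one of `"natural_course"`, `"never_exposed"`, `"always_light"`,
#'   `"always_medium"`, `"always_heavy"`.
#' @return an object of class `intervention_spec`.
#' @export
intervention_spec <- function(kind = c("natural_course", "never_exposed",
                                       "always_light", "always_medium",
                                       "always_heavy")) {
  kind <- match.arg(kind)
  forced <- switch(kind, natural_course = NA_character_,
                   never_exposed = "none", always_light = "light",
                   always_medium = "medium", always_heavy = "heavy")
  structure(list(kind = kind, forced_category = forced),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("Intervention:", x$kind, "\n"); invisible(x)
}

#' Resample baseline rows with replacement
#'
#' Monte Carlo pseudo-workers are drawn by resampling observed baseline rows
#' (entry age, entry year, baseline covariates, pre-entry history) with
#' replacement, preserving their joint distribution.
#'
#' @param baseline baseline table.
#' @param mc_size number of pseudo-workers.
#' @param identity if `TRUE` (test hook) and `mc_size == nrow(baseline)`,
#'   return the table unresampled.
#' @return a baseline table with `mc_size` rows.
#' @export
sample_baselines <- function(baseline, mc_size, identity = FALSE) {
  if (!nrow(baseline)) stop("empty baseline table")
  if (mc_size <= 0) stop("mc_size must be positive")
  if (identity) {
    if (mc_size != nrow(baseline))
      stop("identity mode requires mc_size == nrow(baseline)")
    return(data.table::as.data.table(baseline))
  }
  idx <- sample.int(nrow(baseline), mc_size, replace = TRUE)
  data.table::as.data.table(baseline)[idx]
}

## ---------------------------------------------------------------------------
## The forward simulation core. Used both by the g-formula engine (with fitted
## models) and by the synthetic-cohort generator (with truth models), so the
## covariate bookkeeping of generation and fitting cannot drift apart.
##
## Per-period update order (fixed):
##   1. employment transition from leave/return models (previous-period state,
##      exposure windows lagged >= 1 year);
##   2. exposure category: ordinal draw (natural course) or forced by the
##      intervention; annual increment recorded;
##   3. death resolved among the three causes by a single categorical draw
##      with P(cause k) = h_k and P(survive) = 1 - sum(h) (renormalized in
##      the rare event that the annual hazards sum past one), so each cause's
##      marginal probability given the covariates equals its model hazard;
##   4. age and calendar year advance; administrative censoring at max_age or
##      the admin end year.
## Dead states are absorbing; no exposure accrues after death or while
## unemployed.
.simulate_forward <- function(suite, baseline, intervention,
                              max_age = 90, admin_end_year = 1990,
                              coeffs = exposure_coefficients(),
                              record_matrices = TRUE) {
  n <- nrow(baseline)
  entry_age <- as.integer(baseline$entry_age)
  birth_year <- as.integer(baseline$birth_year)
  us_born <- as.numeric(baseline$us_born)
  pre_years <- as.numeric(baseline$pre_entry_years_worked)
  pre_exp <- as.numeric(baseline$pre_entry_exposure)

  a0 <- min(entry_age)
  ages <- a0:(max_age - 1L)
  nA <- length(ages)
  col_of <- function(a) a - a0 + 1L

  inc <- matrix(0, n, nA)
  emp_mat <- if (record_matrices) matrix(NA_integer_, n, nA)
  cat_mat <- if (record_matrices) matrix(0L, n, nA)

  alive <- rep(TRUE, n)
  cause <- rep(0L, n)              # 0 none, 1 resp, 2 heart, 3 other
  exit_age <- rep(NA_integer_, n)
  employed_prev <- rep(1L, n)      # entered after >= 1 year of employment
  cum_work <- numeric(n)
  cat_codes <- c("none", "light", "medium", "heavy")
  inc_by_code <- c(0, coeffs$conc_light, coeffs$conc_medium,
                   coeffs$gamma * coeffs$conc_heavy)
  forced_code <- if (is.na(intervention$forced_category)) NA_integer_ else
    match(intervention$forced_category, cat_codes) - 1L

  wsum <- function(act, a, k1, k2) {
    ## increments accrued at whole-year distances k1..k2 before age a,
    ## i.e. periods starting at ages a-k2-1 .. a-k1-1
    lo <- col_of(a - k2 - 1L); hi <- col_of(a - k1 - 1L)
    if (hi < 1L) return(numeric(length(act)))
    lo <- max(lo, 1L)
    .rowSums(inc[act, lo:hi, drop = FALSE], length(act), hi - lo + 1L)
  }

  ## spline basis (if any model uses one) is a per-step scalar set
  knots <- NULL
  for (m in suite) if (!is.null(m) && !is.null(m$knots)) { knots <- m$knots; break }

  for (a in ages) {
    act <- which(alive & is.na(exit_age) & entry_age <= a &
                   (birth_year + a) <= admin_end_year)
    if (!length(act)) next
    na <- length(act)
    ia <- col_of(a)
    age_c <- (a - 50) / 10
    year_c <- (birth_year[act] + a - 1950) / 10
    cols <- list(age_c = age_c, year_c = year_c, age_year = age_c * year_c,
                 us_born = us_born[act],
                 pre_entry_years = pre_years[act],
                 pre_entry_exposure = pre_exp[act],
                 cum_work_c = cum_work[act] / 10,
                 w_2_5 = wsum(act, a, 3L, 5L),
                 w_5_10 = wsum(act, a, 6L, 10L),
                 w_10_20 = wsum(act, a, 11L, 20L),
                 w_recent_1_5 = wsum(act, a, 1L, 5L))
    if (!is.null(knots)) {
      b <- rcs_basis(a, knots)
      b[1] <- age_c
      cols[paste0("age_rcs", seq_along(b))] <- as.list(b)
    }

    ## 1. employment
    ep <- employed_prev[act]
    p_emp <- numeric(na)
    if (any(ep == 1L)) {
      sub <- which(ep == 1L)
      m <- suite$leave_work
      p_emp[sub] <- 1 - plogis(m$coef[["(Intercept)"]] +
                                 .eta_cols(m, cols, sub))
    }
    if (any(ep == 0L)) {
      sub <- which(ep == 0L)
      m <- suite$return_work
      p_emp[sub] <- plogis(m$coef[["(Intercept)"]] + .eta_cols(m, cols, sub))
    }
    employed <- as.integer(runif(na) < p_emp)

    ## 2. exposure category and increment
    cat_now <- integer(na)  # code 0..3
    if (is.na(forced_code)) {
      if (any(employed == 1L)) {
        m <- suite$exposure_category
        if (is.null(m))
          stop("natural_course requires a fitted exposure model")
        sub <- which(employed == 1L)
        eta <- .eta_cols(m, cols, sub)
        F1 <- plogis(m$coef[["zeta_1"]] - eta)
        F2 <- plogis(m$coef[["zeta_2"]] - eta)
        u <- runif(length(sub))
        cat_now[sub] <- 1L + (u > F1) + (u > F2)
      }
    } else if (forced_code > 0L) {
      cat_now[employed == 1L] <- forced_code
    }
    inc[act, ia] <- inc_by_code[cat_now + 1L]

    ## 3. death (covariates include current employment status)
    cols$employed <- as.numeric(employed)
    h_r <- plogis(suite$d_resp$coef[["(Intercept)"]] +
                    .eta_cols(suite$d_resp, cols))
    h_h <- plogis(suite$d_heart$coef[["(Intercept)"]] +
                    .eta_cols(suite$d_heart, cols))
    h_o <- plogis(suite$d_other$coef[["(Intercept)"]] +
                    .eta_cols(suite$d_other, cols))
    ## one categorical draw per period with P(cause k) equal to the model
    ## hazard h_k itself, so each cause's marginal probability given the
    ## covariates is exactly its binary-model hazard; if the three annual
    ## hazards ever sum past one they are renormalized (survival zero)
    tot <- h_r + h_h + h_o
    s <- ifelse(tot > 1, 1 / tot, 1)
    p1 <- h_r * s; p2 <- h_h * s; p3 <- h_o * s
    u <- runif(na)
    dd <- 1L * (u < p1) + 2L * (u >= p1 & u < p1 + p2) +
      3L * (u >= p1 + p2 & u < p1 + p2 + p3)
    died <- dd > 0L
    cause[act[died]] <- dd[died]
    alive[act[died]] <- FALSE
    exit_age[act[died]] <- a

    if (record_matrices) {
      emp_mat[act, ia] <- employed
      cat_mat[act, ia] <- cat_now
    }
    employed_prev[act] <- employed
    cum_work[act] <- cum_work[act] + employed
  }

  ## administrative exits for survivors
  surv <- which(is.na(exit_age))
  if (length(surv))
    exit_age[surv] <- pmin(max_age - 1L, admin_end_year - birth_year[surv])

  structure(list(entry_age = entry_age, exit_age = exit_age,
                 cause = factor(c("none", "resp_cancer", "heart",
                                  "other")[cause + 1L],
                                levels = c("none", "resp_cancer", "heart",
                                           "other")),
                 birth_year = birth_year, ages = ages,
                 increments = inc, employed = emp_mat, category = cat_mat,
                 cum_work = cum_work,
                 intervention = intervention$kind,
                 mc_size = n, max_age = max_age,
                 admin_end_year = admin_end_year),
            class = "simulated_histories")
}

#' Simulate a pseudo-cohort under an intervention (parametric g-formula)
#'
#' Resamples baselines with replacement and simulates forward annual histories
#' under the intervention using the fitted model suite (Monte Carlo
#' approximation of the g-formula standardization). Deterministic given
#' `seed`.
#'
#' @param suite a [model_suite()]; un-converged component models are refused
#'   unless `allow_unconverged = TRUE`.
#' @param baseline baseline table to resample from.
#' @param intervention an [intervention_spec()] or its kind string.
#' @param mc_size number of pseudo-workers (default 20000).
#' @param seed integer seed.
#' @param max_age,admin_end_year censoring bounds.
#' @param coeffs [exposure_coefficients()] mapping categories to increments.
#' @param identity_baseline test hook: use the baseline rows as-is
#'   (requires `mc_size == nrow(baseline)`).
#' @param allow_unconverged proceed despite non-converged models.
#' @return an object of class `simulated_histories`: per-pseudo-worker entry
#'   and exit ages, cause of death (`none` iff administratively censored),
#'   and per-age exposure-increment and employment matrices.
#' @export
simulate_pseudo_cohort <- function(suite, baseline, intervention,
                                   mc_size = 20000, seed = 1L,
                                   max_age = 90, admin_end_year = 1990,
                                   coeffs = exposure_coefficients(),
                                   identity_baseline = FALSE,
                                   allow_unconverged = FALSE) {
  stopifnot(inherits(suite, "model_suite"))
  if (is.character(intervention)) intervention <- intervention_spec(intervention)
  conv <- vapply(suite, function(m) is.null(m) || isTRUE(m$converged), TRUE)
  if (!all(conv) && !allow_unconverged)
    stop("un-converged model(s): ", paste(names(suite)[!conv], collapse = ", "),
         " (set allow_unconverged = TRUE to override)")
  set.seed(seed)
  b <- sample_baselines(baseline, mc_size, identity = identity_baseline)
  .simulate_forward(suite, b, intervention, max_age = max_age,
                    admin_end_year = admin_end_year, coeffs = coeffs)
}

#' Advance a single simulation state by one person-year
#'
#' Single-worker version of the per-period update used by
#' [simulate_pseudo_cohort()] (employment transition, exposure assignment,
#' lag-window rebuild, competing-cause death resolution, clock advance).
#' Mainly useful for inspection and for hand-checked transition tests.
#'
#' @param state list with `age`, `entry_age`, `birth_year`, `employed_prev`,
#'   `cum_work`, `increments` (named by period start age), baseline fields
#'   `us_born`, `pre_entry_years_worked`, `pre_entry_exposure`, `alive`,
#'   and `cause`.
#' @param suite a [model_suite()].
#' @param intervention an [intervention_spec()].
#' @param coeffs [exposure_coefficients()].
#' @return the updated state; death sets `alive = FALSE` and `cause`.
#' @export
step_person_year <- function(state, suite, intervention,
                             coeffs = exposure_coefficients()) {
  if (!isTRUE(state$alive)) stop("cannot step a dead state")
  if (is.character(intervention)) intervention <- intervention_spec(intervention)
  a <- state$age
  hist_ages <- as.integer(names(state$increments))
  winc <- function(k1, k2) {
    k <- a - hist_ages - 1L
    sum(state$increments[k >= k1 & k <= k2])
  }
  env <- list(age = a, calendar_year = state$birth_year + a,
              us_born = state$us_born,
              pre_entry_years_worked = state$pre_entry_years_worked,
              pre_entry_exposure = state$pre_entry_exposure,
              cum_work = state$cum_work,
              w_2_5 = winc(3L, 5L), w_5_10 = winc(6L, 10L),
              w_10_20 = winc(11L, 20L), w_recent_1_5 = winc(1L, 5L))
  p_emp <- if (state$employed_prev == 1L)
    1 - predict_hazard(suite$leave_work, env)
  else predict_hazard(suite$return_work, env)
  employed <- as.integer(runif(1) < p_emp)
  cat_now <- "none"
  if (employed == 1L) {
    if (is.na(intervention$forced_category)) {
      pr <- predict_category_probs(suite$exposure_category, env)
      u <- runif(1)
      cat_now <- c("light", "medium", "heavy")[1L + (u > pr[1]) +
                                                 (u > pr[1] + pr[2])]
    } else cat_now <- intervention$forced_category
  }
  inc_now <- annual_increment(cat_now, coeffs)
  env$employed <- as.numeric(employed)
  h_r <- predict_hazard(suite$d_resp, env)
  h_h <- predict_hazard(suite$d_heart, env)
  h_o <- predict_hazard(suite$d_other, env)
  u <- runif(1)
  tot <- h_r + h_h + h_o
  s <- if (tot > 1) 1 / tot else 1
  p1 <- h_r * s; p2 <- h_h * s; p3 <- h_o * s
  cause <- if (u < p1) "resp_cancer" else if (u < p1 + p2) "heart"
  else if (u < p1 + p2 + p3) "other" else "none"
  state$increments <- c(state$increments, setNames(inc_now, a))
  state$employed_prev <- employed
  state$cum_work <- state$cum_work + employed
  state$age <- a + 1L
  if (cause != "none") {
    state$alive <- FALSE
    state$cause <- cause
    state$exit_age <- a
  }
  state
}

#' @export
print.simulated_histories <- function(x, ...) {
  cat(sprintf("Simulated histories: %d pseudo-workers under '%s'\n",
              x$mc_size, x$intervention))
  print(round(prop.table(table(cause = x$cause)), 4))
  invisible(x)
}

#' Convert simulated histories to the annual history-table schema
#'
#' @param histories a `simulated_histories` object (with recorded matrices).
#' @return data.table in the same schema as the synthetic generator's history
#'   table (plus a `pseudo_id` column).
#' @export
histories_to_table <- function(histories) {
  stopifnot(inherits(histories, "simulated_histories"))
  if (is.null(histories$employed))
    stop("histories were simulated without recorded matrices")
  n <- histories$mc_size
  a0 <- histories$ages[1]
  len <- histories$exit_age - histories$entry_age + 1L
  id <- rep(seq_len(n), len)
  age <- unlist(lapply(seq_len(n), function(i)
    histories$entry_age[i]:histories$exit_age[i]))
  colix <- age - a0 + 1L
  flat <- cbind(id, colix)
  cat_codes <- c("none", "light", "medium", "heavy")
  out <- data.table::data.table(
    worker_id = id, age = age,
    calendar_year = histories$birth_year[id] + age,
    employed = histories$employed[flat],
    exposure_category = cat_codes[histories$category[flat] + 1L],
    death_cause = "none")
  last <- cumsum(len)
  out$death_cause[last] <- as.character(histories$cause)
  out
}
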