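## shared fixtures, all generated in code

small_cohort <- function(n = 800, seed = 42, profile = "default", ...) {
  generate_cohort(generator_params(n_workers = n, seed = seed,
                                   effect_profile = profile, ...))
}

## lean model specifications used for fast refit-heavy simulations
lean_specs <- function() {
  list(
    d_resp = model_spec("d_resp", c("age_c", "w_2_5", "w_5_10", "w_10_20")),
    d_heart = model_spec("d_heart", c("age_c", "w_2_5", "w_5_10", "w_10_20")),
    d_other = model_spec("d_other", c("age_c", "w_2_5", "w_5_10", "w_10_20")),
    leave_work = model_spec("leave_work", c("age_c", "w_recent_1_5")),
    return_work = model_spec("return_work", "age_c"),
    exposure_category = model_spec("exposure_category", "age_c"))
}

## a confounded two-period toy: employment (l2) depends on prior exposure,
## death depends on employment and exposure; hand-enumerated risks are frozen
## in the tests
confounded_toy <- function() {
  p_y2 <- array(0, c(2, 2, 2))
  for (a1 in 0:1) for (l2 in 0:1) for (a2 in 0:1)
    p_y2[a1 + 1, l2 + 1, a2 + 1] <- 0.06 + 0.05 * a1 - 0.04 * l2 + 0.08 * a2
  toy_spec(p_a1 = 0.5, p_y1 = c(0.05, 0.10), p_l2 = c(0.7, 0.3),
           p_a2 = matrix(c(0.2, 0.6, 0.3, 0.8), 2, 2), p_y2 = p_y2)
}

## toy where death is independent of everything (uniform over histories)
uniform_toy <- function() {
  toy_spec(p_a1 = 0.5, p_y1 = c(0.5, 0.5), p_l2 = c(0.5, 0.5),
           p_a2 = matrix(0.5, 2, 2), p_y2 = array(0.5, c(2, 2, 2)))
}

## intercept-only model suite with given per-period probabilities, for
## hand-enumerable engine tests
flat_suite <- function(p_leave, p_return, p_resp, p_heart, p_other,
                       cat_probs = c(0.5, 0.25, 0.25)) {
  specs <- lean_specs()
  con <- function(outcome, p) {
    s <- model_spec(outcome, character(0))
    hazard_model(setNames(qlogis(p), "(Intercept)"), s)
  }
  z1 <- qlogis(cat_probs[1]); z2 <- qlogis(cat_probs[1] + cat_probs[2])
  model_suite(
    d_resp = con("d_resp", p_resp), d_heart = con("d_heart", p_heart),
    d_other = con("d_other", p_other),
    leave_work = con("leave_work", p_leave),
    return_work = con("return_work", p_return),
    exposure_category = hazard_model(
      numeric(0), model_spec("exposure_category", character(0)),
      zeta = c(z1, z2)))
}

## tiny baseline table for engine tests
tiny_baseline <- function(n, entry_age = 60L, entry_year = 1950L) {
  data.table::data.table(
    worker_id = seq_len(n), entry_age = entry_age, entry_year = entry_year,
    birth_year = entry_year - entry_age, us_born = 1L,
    pre_entry_years_worked = 1, pre_entry_exposure = 0.29)
}

## rebuild a simulated_histories object from observed cohort tables, so the
## calibration report can compare the observed data with itself
histories_from_cohort <- function(cohort, max_age = 90, admin_end = 1990) {
  h <- data.table::as.data.table(cohort$history)
  data.table::setkeyv(h, c("worker_id", "age"))
  b <- cohort$baseline
  last <- h[, .(entry_age = age[1], exit_age = age[.N],
                cause = death_cause[.N]), by = worker_id]
  a0 <- min(last$entry_age)
  ages <- a0:(max_age - 1L)
  n <- nrow(last)
  inc <- matrix(0, n, length(ages))
  emp <- matrix(NA_integer_, n, length(ages))
  idx <- cbind(match(h$worker_id, last$worker_id), h$age - a0 + 1L)
  inc[idx] <- annual_increment(h$exposure_category)
  emp[idx] <- h$employed
  structure(list(entry_age = last$entry_age, exit_age = last$exit_age,
                 cause = factor(last$cause,
                                levels = c("none", "resp_cancer", "heart",
                                           "other")),
                 birth_year = b$birth_year[match(last$worker_id, b$worker_id)],
                 ages = ages, increments = inc, employed = emp,
                 category = NULL, cum_work = NULL,
                 intervention = "observed", mc_size = n, max_age = max_age,
                 admin_end_year = admin_end),
            class = "simulated_histories")
}
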