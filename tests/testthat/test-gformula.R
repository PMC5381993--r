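test_that("baseline resampling preserves the joint distribution", {
  co <- small_cohort(n = 500, seed = 20)
  b <- co$baseline
  # identity test hook returns the table unresampled
  expect_equal(as.data.frame(sample_baselines(b, nrow(b), identity = TRUE)),
               as.data.frame(b))
  expect_error(sample_baselines(b, 10, identity = TRUE), "identity mode")
  expect_error(sample_baselines(b[0, ], 10), "empty")
  expect_equal(nrow(sample_baselines(b, 1)), 1)
  # large resamples reproduce covariate means within 3 SEs
  set.seed(1)
  s <- sample_baselines(b, 50000)
  for (v in c("entry_age", "us_born", "pre_entry_exposure")) {
    se <- stats::sd(b[[v]]) / sqrt(50000)
    expect_lt(abs(mean(s[[v]]) - mean(b[[v]])), 3 * se + 1e-12)
  }
})

test_that("never_exposed forces zero increments along every employment path", {
  co <- small_cohort(n = 200, seed = 21)
  suite <- truth_suite(co$params)
  h <- simulate_pseudo_cohort(suite, co$baseline, "never_exposed",
                              mc_size = 500, seed = 2)
  expect_equal(sum(h$increments), 0)
  expect_true(any(h$employed == 1L, na.rm = TRUE))  # employment still happens
})

test_that("zero death hazards let every pseudo-worker reach administrative censoring", {
  s <- flat_suite(p_leave = 0.1, p_return = 0.2, p_resp = 1e-12,
                  p_heart = 1e-12, p_other = 1e-12)
  b <- tiny_baseline(300, entry_age = 40L, entry_year = 1950L)
  h <- simulate_pseudo_cohort(s, b, "natural_course", mc_size = 300, seed = 3,
                              identity_baseline = TRUE)
  expect_true(all(h$cause == "none"))
  # admin end 1990, born 1910 -> last period at age 80
  expect_true(all(h$exit_age == 80L))
})

test_that("the same seed reproduces simulated histories exactly", {
  co <- small_cohort(n = 200, seed = 22)
  suite <- truth_suite(co$params)
  h1 <- simulate_pseudo_cohort(suite, co$baseline, "natural_course",
                               mc_size = 400, seed = 9)
  h2 <- simulate_pseudo_cohort(suite, co$baseline, "natural_course",
                               mc_size = 400, seed = 9)
  expect_identical(h1$increments, h2$increments)
  expect_identical(h1$cause, h2$cause)
  h3 <- simulate_pseudo_cohort(suite, co$baseline, "natural_course",
                               mc_size = 400, seed = 10)
  expect_false(identical(h1$cause, h3$cause))
})

test_that("death is absorbing: no exposure or employment after exit", {
  co <- small_cohort(n = 300, seed = 23)
  suite <- truth_suite(co$params)
  h <- simulate_pseudo_cohort(suite, co$baseline, "natural_course",
                              mc_size = 600, seed = 4)
  a0 <- h$ages[1]
  for (i in which(h$cause != "none")[1:50]) {
    beyond <- (h$exit_age[i] - a0 + 2):ncol(h$increments)
    if (beyond[1] > ncol(h$increments)) next
    expect_equal(sum(h$increments[i, beyond]), 0)
    expect_true(all(is.na(h$employed[i, beyond])))
  }
})

test_that("engine transition frequencies match hand-computed tree products", {
  ## two periods (ages 88, 89 under a 90 cap), intercept-only models:
  ## hand enumeration of the per-period update gives every outcome probability
  p_leave <- 0.3; p_resp <- 0.05; p_heart <- 0.10; p_other <- 0.15
  s <- flat_suite(p_leave, 0.2, p_resp, p_heart, p_other,
                  cat_probs = c(0.5, 0.3, 0.2))
  n <- 2e5
  b <- tiny_baseline(n, entry_age = 88L, entry_year = 1978L)  # born 1890
  h <- simulate_pseudo_cohort(s, b, "natural_course", mc_size = n, seed = 5,
                              identity_baseline = TRUE)
  ## per-period death probabilities (categorical competing-cause draw)
  q1 <- p_resp
  q2 <- p_heart
  q3 <- p_other
  q_die <- q1 + q2 + q3
  p_cause <- c(resp_cancer = q1, heart = q2, other = q3)
  exp_cause <- p_cause + (1 - q_die) * p_cause   # die in period 1 or 2
  obs <- table(h$cause) / n
  for (k in names(p_cause)) {
    se <- sqrt(exp_cause[[k]] * (1 - exp_cause[[k]]) / n)
    expect_lt(abs(obs[[k]] - exp_cause[[k]]), 3.5 * se)
  }
  p_none <- (1 - q_die)^2
  expect_lt(abs(obs[["none"]] - p_none), 3.5 * sqrt(p_none * (1 - p_none) / n))
  ## employment in period 1: everyone enters employed-prev, leaves w.p. 0.3
  emp1 <- mean(h$employed[, 88 - h$ages[1] + 1], na.rm = TRUE)
  expect_lt(abs(emp1 - (1 - p_leave)), 3.5 * sqrt(0.21 / n))
})

test_that("single-state stepping matches the vectorized engine contracts", {
  co <- small_cohort(n = 50, seed = 24)
  suite <- truth_suite(co$params)
  state <- list(age = 45L, entry_age = 45L, birth_year = 1910L,
                employed_prev = 1L, cum_work = 0,
                increments = setNames(numeric(0), character(0)),
                us_born = 1, pre_entry_years_worked = 1,
                pre_entry_exposure = 0.29, alive = TRUE, cause = "none")
  set.seed(11)
  s2 <- step_person_year(state, suite, "natural_course")
  expect_equal(s2$age, 46L)
  expect_equal(length(s2$increments), 1L)
  # forced-zero intervention never accrues exposure
  set.seed(12)
  s3 <- step_person_year(state, suite, "never_exposed")
  expect_equal(unname(s3$increments), 0)
  # stepping a dead state is an error
  dead <- state; dead$alive <- FALSE
  expect_error(step_person_year(dead, suite, "natural_course"), "dead state")
})

test_that("parametric MC g-formula converges to the exact oracle on the toy", {
  spec <- confounded_toy()
  s <- sample_toy(spec, 2e5, seed = 31)
  models <- fit_toy_models(s)
  for (iv in c("natural_course", "never_exposed", "always_exposed")) {
    risk <- toy_gformula(models, iv, mc_size = 1e5, seed = 32)
    expect_lt(abs(risk - toy_oracle(spec, iv)), 0.01)
  }
})

test_that("unconverged models are refused unless overridden", {
  co <- small_cohort(n = 150, seed = 25)
  suite <- truth_suite(co$params)
  suite$d_resp$converged <- FALSE
  expect_error(simulate_pseudo_cohort(suite, co$baseline, "never_exposed",
                                      mc_size = 50, seed = 1),
               "un-converged")
  h <- simulate_pseudo_cohort(suite, co$baseline, "never_exposed",
                              mc_size = 50, seed = 1,
                              allow_unconverged = TRUE)
  expect_s3_class(h, "simulated_histories")
})
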