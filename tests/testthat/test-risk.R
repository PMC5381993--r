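test_that("closed no-censoring cohorts reduce to empirical cause proportions", {
  set.seed(41)
  n <- 400
  exit <- sample(20:88, n, replace = TRUE)
  cause <- sample(c("resp_cancer", "heart", "other"), n, replace = TRUE)
  x <- data.frame(entry_age = 20L, exit_age = exit, cause = cause)
  cif <- cumulative_incidence(x)
  for (k in c("resp_cancer", "heart", "other")) {
    for (a in c(40, 60, 89, 90)) {
      expect_equal(cif_at(cif, a, k), mean(cause == k & exit < a),
                   tolerance = 1e-12)
    }
  }
  # everyone dead by the cap: survival reaches exactly zero
  expect_equal(cif$surv[nrow(cif)], 0)
})

test_that("late-entry worked example matches the hand-computed Aalen-Johansen table", {
  ## A dies resp at 21; B censored at 23; C enters late (22), dies heart at
  ## 23; D dies heart at 23. Hand table: h_resp(21) = 1/3; h_heart(23) = 2/3;
  ## S(22+) = 2/3; CIF_resp = 1/3; CIF_heart = (2/3)(2/3) = 4/9; S = 2/9.
  x <- data.frame(entry_age = c(20, 20, 22, 20),
                  exit_age = c(21, 23, 23, 23),
                  cause = c("resp_cancer", "none", "heart", "heart"))
  cif <- cumulative_incidence(x, causes = c("resp_cancer", "heart"),
                              max_age = 25)
  expect_equal(cif_at(cif, 22, "resp_cancer"), 1 / 3)
  expect_equal(cif_at(cif, 24, "resp_cancer"), 1 / 3)
  expect_equal(cif_at(cif, 24, "heart"), 4 / 9)
  expect_equal(cif$surv[cif$age == 24], 2 / 9)
  expect_equal(cif$n_risk[cif$age == 22], 3)  # B, C, D at risk
})

test_that("single-cause estimator equals one minus Kaplan-Meier", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 300
  entry <- sample(20:50, n, replace = TRUE)
  dur <- rpois(n, 15)
  exit <- pmin(entry + dur, 89L)
  cause <- ifelse(runif(n) < 0.6, "other", "none")
  x <- data.frame(entry_age = entry, exit_age = exit, cause = cause)
  cif <- cumulative_incidence(x, causes = "other")
  km <- survival::survfit(
    survival::Surv(entry, exit + 1, cause == "other") ~ 1)
  at <- km$time  # event/censoring times on the age+1 scale
  mine <- cif$surv[match(at, cif$age)]
  ok <- !is.na(mine)
  expect_equal(mine[ok], km$surv[ok], tolerance = 1e-12)
  expect_equal(1 - mine[ok], cif$cif_other[match(at, cif$age)][ok],
               tolerance = 1e-12)
})

test_that("cause-specific curves and survival partition probability exactly", {
  co <- small_cohort(n = 600, seed = 43)
  obs <- workergf:::.observed_outcomes(co$history)
  cif <- cumulative_incidence(obs)
  tot <- cif$surv + cif$cif_resp_cancer + cif$cif_heart + cif$cif_other
  expect_lt(max(abs(tot - 1)), 1e-10)
  expect_equal(cif$cif_all,
               cif$cif_resp_cancer + cif$cif_heart + cif$cif_other,
               tolerance = 1e-12)
  # each CIF is non-decreasing; survival non-increasing
  expect_true(all(diff(cif$cif_all) >= 0))
  expect_true(all(diff(cif$surv) <= 0))
  expect_equal(cif$cif_all[1], 0)  # nobody has died by first entry
})

test_that("duplicating every individual leaves the estimator unchanged", {
  co <- small_cohort(n = 300, seed = 44)
  obs <- workergf:::.observed_outcomes(co$history)
  cif1 <- cumulative_incidence(obs)
  cif2 <- cumulative_incidence(rbind(obs, obs))
  for (cl in c("surv", "cif_resp_cancer", "cif_heart", "cif_other"))
    expect_equal(cif1[[cl]], cif2[[cl]], tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  expect_error(cumulative_incidence(
    data.frame(entry_age = 30, exit_age = 25, cause = "none")),
    "exit < entry")
  expect_error(cumulative_incidence(
    data.frame(entry_age = 20, exit_age = 25, cause = "plague")),
    "unknown cause")
  expect_error(cif_at(cumulative_incidence(
    data.frame(entry_age = 20, exit_age = 25, cause = "other")), 20.5),
    "not on the grid")
})

test_that("risk differences and per-1,000 scaling behave as documented", {
  x <- data.frame(entry_age = 20, exit_age = c(25, 30, 40),
                  cause = c("other", "none", "other"))
  cif <- cumulative_incidence(x, causes = "other")
  expect_equal(risk_difference(cif, cif, 40, "other"), 0)
  expect_equal(risk_difference(cif, cif, 70), 0)
  y <- data.frame(entry_age = 20, exit_age = c(25, 30, 40),
                  cause = c("other", "other", "other"))
  cif2 <- cumulative_incidence(y, causes = "other")
  expect_equal(risk_difference(cif2, cif, 35, "other"), 2 / 3 - 1 / 3)
  short <- cumulative_incidence(y, causes = "other", max_age = 60)
  expect_error(risk_difference(short, cif, 50), "mismatched")
  expect_equal(per_1000(0), 0)
  expect_equal(per_1000(0.046), 46)
  expect_equal(per_1000(-0.001), -1)
  expect_error(per_1000(1.2), "outside")
})

test_that("years of life lost reflects constructed survival shifts", {
  mk <- function(exit, cause) {
    structure(list(entry_age = rep(20L, length(exit)), exit_age = exit,
                   cause = factor(cause, c("none", "resp_cancer", "heart",
                                           "other")),
                   mc_size = length(exit), max_age = 90),
              class = "simulated_histories")
  }
  a <- mk(c(50L, 60L, 89L), c("other", "heart", "none"))
  expect_equal(years_of_life_lost(a, a), 0)
  # delaying each death by one year gains exactly (fraction dying) years
  b <- mk(c(51L, 61L, 89L), c("other", "heart", "none"))
  expect_equal(years_of_life_lost(a, b), 2 / 3)
  expect_error(years_of_life_lost(a, mk(c(50L, 60L), c("other", "none"))),
               "differing cohort sizes")
})

test_that("the contrast table mirrors the per-1,000 conventions", {
  x <- data.frame(entry_age = 20, exit_age = c(25, 30, 40, 89),
                  cause = c("heart", "other", "resp_cancer", "none"))
  y <- data.frame(entry_age = 20, exit_age = c(25, 30, 40, 89),
                  cause = c("heart", "heart", "resp_cancer", "none"))
  cifs <- list(never_exposed = cumulative_incidence(x),
               natural_course = cumulative_incidence(y))
  tab <- contrast_table(cifs, ages = 70)
  expect_equal(tab$deaths_per_1000_reference[tab$cause == "all"], 750)
  ex <- tab$excess_natural_course
  # all-cause excess equals the sum of cause-specific excesses
  expect_equal(ex[tab$cause == "all"],
               sum(ex[tab$cause != "all"]), tolerance = 1e-9)
  expect_error(contrast_table(cifs, reference = "always_light"),
               "not among")
})
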