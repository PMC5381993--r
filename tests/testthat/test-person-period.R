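mini_tables <- function() {
  baseline <- data.table::data.table(
    worker_id = 1:2, entry_age = c(30L, 40L), entry_year = c(1945L, 1950L),
    birth_year = c(1915L, 1910L), us_born = c(1L, 0L),
    pre_entry_years_worked = c(1, 3), pre_entry_exposure = c(0.29, 1.74))
  history <- data.table::data.table(
    worker_id = c(rep(1L, 4), rep(2L, 3)),
    age = c(30:33, 40:42),
    calendar_year = c(1945:1948, 1950:1952),
    employed = c(1L, 1L, 0L, 0L, 1L, 1L, 1L),
    exposure_category = c("light", "heavy", "none", "none",
                          "medium", "medium", "light"),
    death_cause = c("none", "none", "none", "heart", "none", "none", "none"))
  list(baseline = baseline, history = history)
}

test_that("expansion yields one at-risk row per worker-year with death on the last row", {
  tb <- mini_tables()
  pp <- expand_to_person_periods(tb$baseline, tb$history)
  expect_equal(nrow(pp), 7)
  w1 <- pp[pp$worker_id == 1L, ]
  expect_equal(w1$age, 30:33)                      # entry 30, death at 33
  expect_equal(w1$d_heart, c(0L, 0L, 0L, 1L))
  expect_equal(sum(pp$d_resp) + sum(pp$d_other), 0)
  # survivor: all outcome indicators zero on the final row
  w2 <- pp[pp$worker_id == 2L, ]
  expect_equal(w2$d_resp + w2$d_heart + w2$d_other, rep(0L, 3))
  # at most one outcome indicator per row
  expect_true(all(pp$d_resp + pp$d_heart + pp$d_other <= 1))
})

test_that("engineered covariates track the exposure history", {
  tb <- mini_tables()
  pp <- expand_to_person_periods(tb$baseline, tb$history)
  w1 <- pp[pp$worker_id == 1L, ]
  expect_equal(w1$increment, c(0.29, 1.14, 0, 0))
  expect_equal(w1$cum_exposure, cumsum(c(0.29, 1.14, 0, 0)))
  expect_equal(w1$cum_work, c(0, 1, 2, 2))         # employed periods before a
  expect_equal(w1$employed_prev, c(1L, 1L, 1L, 0L))
  # lag-2 windows: the age-30 increment is only 2 whole years before age 33,
  # so nothing has reached the (2,5] window yet
  expect_equal(w1$w_2_5, c(0, 0, 0, 0))
  expect_equal(w1$w_recent_1_5, c(0, 0, 0.29, 0.29 + 1.14))
})

test_that("window columns agree with lagged_window_sums on a simulated worker", {
  co <- small_cohort(n = 60, seed = 9)
  pp <- expand_to_person_periods(co$baseline, co$history)
  ids <- unique(pp$worker_id)[1:10]
  for (w in ids) {
    rows <- pp[pp$worker_id == w, ]
    i <- nrow(rows)
    ws <- lagged_window_sums(rows$increment[seq_len(i - 1)],
                             rows$age[seq_len(i - 1)], rows$age[i])
    expect_equal(c(rows$w_2_5[i], rows$w_5_10[i], rows$w_10_20[i]),
                 unname(ws))
  }
})

test_that("row counts match total follow-up across workers", {
  co <- small_cohort(n = 150, seed = 10)
  pp <- expand_to_person_periods(co$baseline, co$history)
  spans <- co$history[, .(len = max(age) - min(age) + 1L), by = worker_id]
  expect_equal(nrow(pp), sum(spans$len))
})

test_that("malformed histories are rejected", {
  tb <- mini_tables()
  h <- tb$history
  expect_error(expand_to_person_periods(tb$baseline, rbind(h, h[1, ])),
               "overlapping")
  h2 <- data.table::copy(h); h2$age[2] <- 35L
  expect_error(expand_to_person_periods(tb$baseline, h2), "gaps")
  h3 <- data.table::copy(h); h3$exposure_category[3] <- "light"
  expect_error(expand_to_person_periods(tb$baseline, h3), "unemployed")
  h4 <- data.table::copy(h); h4$death_cause[5] <- "other"
  expect_error(expand_to_person_periods(tb$baseline, h4), "final history row")
  h5 <- data.table::copy(h); h5$calendar_year[4] <- 1995L
  expect_error(expand_to_person_periods(tb$baseline, h5),
               "administrative end")
})

test_that("restricted cubic spline basis is linear-reproducing and linear in the tails", {
  kn <- c(40, 50, 60, 70, 80)
  x <- seq(20, 95, by = 0.5)
  b <- rcs_basis(x, kn)
  # choosing zero nonlinear coefficients reproduces a linear function exactly
  expect_equal(drop(b %*% c(2, 0, 0, 0)), 2 * x)
  # linearity beyond the boundary knots: second differences vanish
  for (j in 2:4) {
    lo <- b[x < 40, j]
    hi <- b[x > 80, j]
    expect_lt(max(abs(diff(diff(lo)))), 1e-9)
    expect_lt(max(abs(diff(diff(hi)))), 1e-9)
  }
  expect_error(rcs_basis(x, c(40, 50)), "at least 3 knots")
})

test_that("spline fits agree with an independent natural-spline basis", {
  skip_if_not_installed("splines")
  co <- small_cohort(n = 400, seed = 3)
  pp <- expand_to_person_periods(co$baseline, co$history)
  y <- pp$d_other
  kn <- default_knots(pp)
  X1 <- design_matrix(pp, "age_spline", knots = kn)
  f1 <- glm.fit(X1, y, family = binomial())
  ns_b <- splines::ns(pp$age, knots = kn[2:4], Boundary.knots = kn[c(1, 5)])
  f2 <- glm.fit(cbind(1, ns_b), y, family = binomial())
  # the two bases span the same function space -> identical fitted hazards
  expect_equal(f1$fitted.values, f2$fitted.values, tolerance = 1e-6)
})

test_that("design matrix columns are stable and validated", {
  tb <- mini_tables()
  pp <- expand_to_person_periods(tb$baseline, tb$history)
  X <- design_matrix(pp, c("age_c", "year_c", "age_year", "employed",
                           "w_2_5"))
  expect_equal(colnames(X), c("(Intercept)", "age_c", "year_c", "age_year",
                              "employed", "w_2_5"))
  expect_equal(X[, "age_c"], (pp$age - 50) / 10)
  expect_equal(X[, "age_year"], X[, "age_c"] * X[, "year_c"])
  expect_error(design_matrix(pp, "smoking"), "unknown covariate")
  # rows differing only in calendar year differ only in year-linked columns
  p2 <- pp[c(1, 1), ]
  p2$calendar_year[2] <- p2$calendar_year[2] + 7L
  X2 <- design_matrix(p2, c("age_c", "year_c", "age_year", "w_2_5",
                            "us_born"))
  same <- setdiff(colnames(X2), c("year_c", "age_year"))
  expect_equal(X2[1, same], X2[2, same])
  expect_false(X2[1, "year_c"] == X2[2, "year_c"])
})
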