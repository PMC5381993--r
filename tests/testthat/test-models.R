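## a small person-period table for closed-form checks
pp_fix <- local({
  co <- small_cohort(n = 500, seed = 14)
  expand_to_person_periods(co$baseline, co$history)
})

test_that("intercept-only pooled logistic recovers the logit event fraction", {
  f <- fit_pooled_logistic(pp_fix, model_spec("d_other", character(0)))
  p <- mean(pp_fix$d_other)
  expect_equal(unname(coef(f)), qlogis(p), tolerance = 1e-8)
  expect_true(f$converged)
  # any prediction equals the event fraction
  expect_equal(unname(predict_hazard(f, pp_fix[1:3, ])), rep(p, 3),
               tolerance = 1e-8)
})

test_that("single binary covariate fit equals the 2x2 log odds ratio", {
  f <- fit_pooled_logistic(pp_fix, model_spec("d_other", "employed"))
  tab <- table(pp_fix$employed, pp_fix$d_other)
  lor <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(unname(coef(f)["employed"]), lor, tolerance = 1e-7)
})

test_that("pooled logistic agrees with glm to high precision", {
  spec <- model_spec("d_heart", c("age_c", "year_c", "employed", "w_2_5",
                                  "w_5_10", "w_10_20"))
  f <- fit_pooled_logistic(pp_fix, spec)
  Z <- design_matrix(pp_fix, spec$covariates, intercept = FALSE)
  g <- glm(pp_fix$d_heart ~ Z, family = binomial())
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  # standard errors from the information matrix match glm's
  expect_equal(unname(sqrt(diag(vcov(f)))), unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-4)
  # AIC identity holds exactly
  expect_identical(f$aic, 2 * length(coef(f)) - 2 * f$loglik)
})

test_that("degenerate outcomes are rejected with a named error", {
  pp0 <- data.table::copy(pp_fix)
  pp0$d_resp <- 0L
  expect_error(fit_pooled_logistic(pp0, model_spec("d_resp", "age_c")),
               "d_resp.*no events")
})

test_that("proportional odds with no covariates recovers closed-form thresholds", {
  ## construct employed person-periods with category frequencies 1/2, 1/4, 1/4
  pp <- data.table::copy(pp_fix[pp_fix$employed == 1L, ])
  n <- nrow(pp)
  k <- rep(c("light", "light", "medium", "heavy"), length.out = n)
  pp$exposure_category <- k
  f <- fit_proportional_odds(pp, model_spec("exposure_category", character(0)))
  p1 <- mean(k == "light"); p12 <- mean(k != "heavy")
  expect_equal(unname(f$zeta), c(qlogis(p1), qlogis(p12)), tolerance = 1e-6)
  pr <- predict_category_probs(f, pp[1, ])
  expect_equal(unname(drop(pr)), c(p1, p12 - p1, 1 - p12), tolerance = 1e-6)
})

test_that("proportional odds agrees with MASS::polr", {
  skip_if_not_installed("MASS")
  spec <- model_spec("exposure_category", c("age_c", "w_recent_1_5"))
  f <- fit_proportional_odds(pp_fix, spec)
  emp <- pp_fix[pp_fix$employed == 1L, ]
  d <- data.frame(y = factor(emp$exposure_category,
                             c("light", "medium", "heavy"), ordered = TRUE),
                  age_c = (emp$age - 50) / 10,
                  w_recent_1_5 = emp$w_recent_1_5)
  m <- MASS::polr(y ~ age_c + w_recent_1_5, data = d, method = "logistic",
                  Hess = TRUE)
  expect_equal(unname(f$zeta), unname(m$zeta), tolerance = 1e-3)
  expect_equal(unname(coef(f)[c("age_c", "w_recent_1_5")]),
               unname(coef(m)), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  # SEs from the empirical information agree with polr's observed information
  se_polr <- sqrt(diag(vcov(m)))[1:2]
  expect_equal(unname(sqrt(diag(vcov(f)))[3:4]), unname(se_polr),
               tolerance = 0.05)
})

test_that("ordinal fit requires all three categories", {
  pp1 <- data.table::copy(pp_fix)
  pp1$exposure_category[pp1$employed == 1L] <- "light"
  expect_error(fit_proportional_odds(
    pp1, model_spec("exposure_category", "age_c")), "three ordered categories")
})

test_that("hazard predictions follow the inverse-logit of the linear predictor", {
  s <- model_spec("d_resp", "w_2_5")
  m <- hazard_model(c(`(Intercept)` = -3, w_2_5 = 0.5), s)
  expect_equal(unname(predict_hazard(m, list(w_2_5 = 2))), plogis(-2))
  expect_equal(unname(predict_hazard(m, list(w_2_5 = 6))), 0.5)  # eta = 0
  expect_error(predict_hazard(m, list(w_5_10 = 1)), "missing covariate")
})

test_that("category probabilities sum to one and respond monotonically", {
  s <- model_spec("exposure_category", "w_recent_1_5")
  m <- hazard_model(c(w_recent_1_5 = 0.8), s, zeta = c(qlogis(0.5), qlogis(0.75)))
  x <- seq(-4, 4, by = 0.25)
  pr <- predict_category_probs(m, list(w_recent_1_5 = x))
  expect_equal(unname(rowSums(pr)), rep(1, length(x)), tolerance = 1e-12)
  expect_true(all(pr > 0))
  # raising the exposure-propensity linear predictor never lowers P(heavy)
  expect_true(all(diff(pr[, "heavy"]) >= 0))
  # zero slope reproduces the threshold probabilities
  m0 <- hazard_model(c(w_recent_1_5 = 0), s, zeta = c(qlogis(0.5), qlogis(0.75)))
  expect_equal(unname(drop(predict_category_probs(m0, list(w_recent_1_5 = 0)))),
               c(0.5, 0.25, 0.25))
})

test_that("the likelihood at the MLE dominates the generating truth", {
  co <- small_cohort(n = 1500, seed = 15)
  pp <- expand_to_person_periods(co$baseline, co$history)
  spec <- default_model_specs("linear")$d_heart
  f <- fit_pooled_logistic(pp, spec)
  X <- design_matrix(pp, spec$covariates)
  truth <- co$truth$d_heart[colnames(X)]
  eta <- drop(X %*% truth)
  ll_truth <- sum(pp$d_heart * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  expect_gte(f$loglik, ll_truth)
})
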