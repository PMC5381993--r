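#' A two-period toy problem with an exact g-formula oracle
#'
#' A fully discrete, enumeration-ready data-generating process used to verify
#' the parametric Monte Carlo g-formula against exact nonparametric
#' standardization. Structure: binary exposure `a1` in period 1; death `y1`
#' may occur in period 1; among survivors, a binary time-varying confounder
#' `l2` (employment) is realized with a distribution that may depend on `a1`
#' (the confounder affected by prior exposure), then exposure `a2` given
#' `(a1, l2)`, then death `y2` given `(a1, l2, a2)`.
#'
#' @param p_a1 scalar `P(a1 = 1)`.
#' @param p_y1 length-2 vector `P(y1 = 1 | a1 = 0, 1)`.
#' @param p_l2 length-2 vector `P(l2 = 1 | a1 = 0, 1)` among survivors.
#' @param p_a2 2x2 matrix `P(a2 = 1 | a1, l2)`, rows `a1 = 0,1`, cols
#'   `l2 = 0,1`.
#' @param p_y2 2x2x2 array `P(y2 = 1 | a1, l2, a2)`, dims `[a1, l2, a2]`.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(p_a1, p_y1, p_l2, p_a2, p_y2) {
  p_a2 <- matrix(p_a2, 2, 2)
  p_y2 <- array(p_y2, c(2, 2, 2))
  all_p <- c(p_a1, p_y1, p_l2, p_a2, p_y2)
  if (any(all_p < 0 | all_p > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(length(p_a1) == 1, length(p_y1) == 2, length(p_l2) == 2)
  structure(list(p_a1 = p_a1, p_y1 = p_y1, p_l2 = p_l2, p_a2 = p_a2,
                 p_y2 = p_y2),
            class = "toy_spec")
}

#' Exact joint distribution of the toy histories
#'
#' Enumerates every covariate history with its probability (2 period-1 death
#' histories plus 16 full histories). Probabilities sum to 1 by construction;
#' this is validated to machine precision.
#'
#' @param spec a [toy_spec()].
#' @return data.frame with columns `a1, y1, l2, a2, y2, prob` (`NA` after
#'   death in period 1).
#' @export
toy_joint <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  rows <- list()
  for (a1 in 0:1) {
    pa <- if (a1 == 1) spec$p_a1 else 1 - spec$p_a1
    rows[[length(rows) + 1L]] <- data.frame(
      a1 = a1, y1 = 1L, l2 = NA, a2 = NA, y2 = NA,
      prob = pa * spec$p_y1[a1 + 1])
    for (l2 in 0:1) for (a2 in 0:1) for (y2 in 0:1) {
      pl <- if (l2 == 1) spec$p_l2[a1 + 1] else 1 - spec$p_l2[a1 + 1]
      pa2 <- if (a2 == 1) spec$p_a2[a1 + 1, l2 + 1] else
        1 - spec$p_a2[a1 + 1, l2 + 1]
      py2 <- if (y2 == 1) spec$p_y2[a1 + 1, l2 + 1, a2 + 1] else
        1 - spec$p_y2[a1 + 1, l2 + 1, a2 + 1]
      rows[[length(rows) + 1L]] <- data.frame(
        a1 = a1, y1 = 0L, l2 = l2, a2 = a2, y2 = y2,
        prob = pa * (1 - spec$p_y1[a1 + 1]) * pl * pa2 * py2)
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(abs(sum(out$prob) - 1) < 1e-12)
  out
}

#' Sample a finite toy cohort
#'
#' @param spec a [toy_spec()].
#' @param n sample size.
#' @param seed integer seed.
#' @return data.frame `a1, y1, l2, a2, y2` with `NA` after a period-1 death.
#' @export
sample_toy <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(seed)
  a1 <- rbinom(n, 1L, spec$p_a1)
  y1 <- rbinom(n, 1L, spec$p_y1[a1 + 1])
  l2 <- a2 <- y2 <- rep(NA_integer_, n)
  s <- y1 == 0L
  l2[s] <- rbinom(sum(s), 1L, spec$p_l2[a1[s] + 1])
  a2[s] <- rbinom(sum(s), 1L, spec$p_a2[cbind(a1[s] + 1, l2[s] + 1)])
  y2[s] <- rbinom(sum(s), 1L, spec$p_y2[cbind(a1[s] + 1, l2[s] + 1, a2[s] + 1)])
  data.frame(a1 = a1, y1 = y1, l2 = l2, a2 = a2, y2 = y2)
}

.toy_intervention <- function(intervention) {
  if (inherits(intervention, "intervention_spec")) intervention <- intervention$kind
  if (intervention %in% c("always_light", "always_medium", "always_heavy"))
    stop("intervention '", intervention,
         "' references exposure levels absent from the binary toy; ",
         "use 'always_exposed'")
  match.arg(intervention, c("natural_course", "never_exposed", "always_exposed"))
}

#' Exact nonparametric g-formula on the toy problem
#'
#' Plug-in standardized two-period death risk under an intervention, computed
#' by exhaustive enumeration over all covariate histories (time-varying
#' standardization; no simulation, exact to machine precision).
#'
#' @param spec a [toy_spec()].
#' @param intervention `"natural_course"`, `"never_exposed"` or
#'   `"always_exposed"`.
#' @return the standardized risk `P(death by end of period 2)`.
#' @export
toy_oracle <- function(spec, intervention = "natural_course") {
  stopifnot(inherits(spec, "toy_spec"))
  intervention <- .toy_intervention(intervention)
  risk <- 0
  for (a1_nat in 0:1) {
    w1 <- if (a1_nat == 1) spec$p_a1 else 1 - spec$p_a1
    a1 <- switch(intervention, natural_course = a1_nat,
                 never_exposed = 0L, always_exposed = 1L)
    r <- spec$p_y1[a1 + 1]
    for (l2 in 0:1) {
      pl <- if (l2 == 1) spec$p_l2[a1 + 1] else 1 - spec$p_l2[a1 + 1]
      for (a2_nat in 0:1) {
        w2 <- if (a2_nat == 1) spec$p_a2[a1 + 1, l2 + 1] else
          1 - spec$p_a2[a1 + 1, l2 + 1]
        a2 <- switch(intervention, natural_course = a2_nat,
                     never_exposed = 0L, always_exposed = 1L)
        if (intervention != "natural_course" && a2_nat == 1L) next
        if (intervention != "natural_course") w2 <- 1
        r <- r + (1 - spec$p_y1[a1 + 1]) * pl * w2 *
          spec$p_y2[a1 + 1, l2 + 1, a2 + 1]
      }
    }
    risk <- risk + w1 * r
  }
  risk
}

## saturated logistic fits for the toy parametric path
.toy_design <- function(a1, l2 = NULL, a2 = NULL) {
  if (is.null(l2)) return(cbind(`(Intercept)` = 1, a1 = a1))
  if (is.null(a2)) return(cbind(`(Intercept)` = 1, a1 = a1, l2 = l2,
                                a1l2 = a1 * l2))
  cbind(`(Intercept)` = 1, a1 = a1, l2 = l2, a2 = a2, a1l2 = a1 * l2,
        a1a2 = a1 * a2, l2a2 = l2 * a2, a1l2a2 = a1 * l2 * a2)
}

#' Fit saturated pooled logistic models to a toy sample
#'
#' Saturated models for `P(a1)`, `P(y1 | a1)`, `P(l2 | a1)`,
#' `P(a2 | a1, l2)` and `P(y2 | a1, l2, a2)` via the package's Newton
#' maximum-likelihood fitter. Saturation means the parametric g-formula run on
#' these fits converges (in `mc_size`) to the plug-in standardization of the
#' sample's empirical distribution.
#'
#' @param toy a toy sample from [sample_toy()].
#' @return list of coefficient vectors, class `toy_models`.
#' @export
fit_toy_models <- function(toy) {
  s <- toy$y1 == 0L
  fit <- function(X, y) .newton_logit(X, y)$coef
  structure(list(
    p_a1 = mean(toy$a1),
    y1 = fit(.toy_design(toy$a1), toy$y1),
    l2 = fit(.toy_design(toy$a1[s]), toy$l2[s]),
    a2 = fit(.toy_design(toy$a1[s], toy$l2[s]), toy$a2[s]),
    y2 = fit(.toy_design(toy$a1[s], toy$l2[s], toy$a2[s]), toy$y2[s])),
    class = "toy_models")
}

#' Parametric Monte Carlo g-formula on the toy problem
#'
#' Simulates `mc_size` two-period histories from the fitted toy models under
#' an intervention and returns the Monte Carlo death risk.
#'
#' @param models a [fit_toy_models()] result.
#' @param intervention `"natural_course"`, `"never_exposed"` or
#'   `"always_exposed"`.
#' @param mc_size number of simulated histories.
#' @param seed integer seed.
#' @return simulated risk (proportion dead by end of period 2).
#' @export
toy_gformula <- function(models, intervention = "natural_course",
                         mc_size = 5e5, seed = 1L) {
  stopifnot(inherits(models, "toy_models"))
  intervention <- .toy_intervention(intervention)
  set.seed(seed)
  pr <- function(cf, X) plogis(drop(X %*% cf))
  a1 <- switch(intervention,
               natural_course = rbinom(mc_size, 1L, models$p_a1),
               never_exposed = rep(0L, mc_size),
               always_exposed = rep(1L, mc_size))
  y1 <- rbinom(mc_size, 1L, pr(models$y1, .toy_design(a1)))
  s <- y1 == 0L
  ns <- sum(s)
  l2 <- rbinom(ns, 1L, pr(models$l2, .toy_design(a1[s])))
  a2 <- switch(intervention,
               natural_course = rbinom(ns, 1L,
                                       pr(models$a2, .toy_design(a1[s], l2))),
               never_exposed = rep(0L, ns), always_exposed = rep(1L, ns))
  y2 <- rbinom(ns, 1L, pr(models$y2, .toy_design(a1[s], l2, a2)))
  (sum(y1) + sum(y2)) / mc_size
}
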