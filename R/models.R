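#' Specify a discrete-time model
#'
#' @param outcome one of `d_resp`, `d_heart`, `d_other` (cause-specific death,
#'   fit on all at-risk person-periods, competitors treated as non-events),
#'   `leave_work` (event: not employed this period; risk set: employed in the
#'   previous period), `return_work` (event: employed this period; risk set:
#'   unemployed in the previous period) or `exposure_category` (ordered
#'   light < medium < heavy; risk set: employed periods).
#' @param covariates character vector of design-matrix covariate names
#'   (see [design_matrix()]).
#' @param family `"binary_logit"` or `"proportional_odds"`; defaults to the
#'   family matching the outcome.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome, covariates, family = NULL) {
  outcomes <- c("d_resp", "d_heart", "d_other", "leave_work", "return_work",
                "exposure_category")
  if (!outcome %in% outcomes)
    stop("unknown outcome: ", outcome)
  fam_default <- if (outcome == "exposure_category") "proportional_odds" else "binary_logit"
  family <- if (is.null(family)) fam_default else match.arg(family, c("binary_logit", "proportional_odds"))
  if ((outcome == "exposure_category") != (family == "proportional_odds"))
    stop("family does not match outcome arity")
  structure(list(outcome = outcome, covariates = covariates, family = family),
            class = "model_spec")
}

## risk-set filter + outcome construction for a spec
.model_frame <- function(pp, spec) {
  switch(spec$outcome,
    d_resp = ,
    d_heart = ,
    d_other = list(rows = which(pp$at_risk == 1L),
                   y = pp[[spec$outcome]][pp$at_risk == 1L]),
    leave_work = {
      r <- which(pp$employed_prev == 1L)
      list(rows = r, y = 1L - pp$employed[r])
    },
    return_work = {
      r <- which(pp$employed_prev == 0L)
      list(rows = r, y = pp$employed[r])
    },
    exposure_category = {
      r <- which(pp$employed == 1L)
      list(rows = r,
           y = match(pp$exposure_category[r], c("light", "medium", "heavy")))
    })
}

## Newton-Raphson for the binary logit; gradient-norm tolerance and iteration
## cap are fixed and reported in the fit object so refits are reproducible.
.newton_logit <- function(X, y, start = NULL, tol = 1e-8, maxit = 50) {
  p <- ncol(X)
  beta <- if (is.null(start)) {
    b0 <- numeric(p)
    if (colnames(X)[1] == "(Intercept)")
      b0[1] <- qlogis(min(max(mean(y), 1e-8), 1 - 1e-8))
    b0
  } else start
  ll_of <- function(eta) sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  gnorm <- Inf; it <- 0L
  eta <- drop(X %*% beta)
  ll <- ll_of(eta)
  for (it in seq_len(maxit)) {
    mu <- plogis(eta)
    g <- crossprod(X, y - mu)
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) break
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(drop(solve(H, g)), error = function(e)
      stop("singular information matrix (separation or collinearity?)"))
    ## damped Newton: halve the step until the likelihood does not decrease.
    ## Near the optimum (small gradient) the full step is taken untested:
    ## there the log-likelihood is flat to within summation round-off and a
    ## line search would stall on noise, while pure Newton is quadratically
    ## convergent.
    eta_step <- drop(X %*% step)
    if (gnorm < 1) {
      eta <- eta + eta_step
      beta <- beta + step
      ll <- ll_of(eta)
    } else {
      lam <- 1
      repeat {
        eta_c <- eta + lam * eta_step
        llc <- ll_of(eta_c)
        if (llc >= ll - 1e-12 || lam < 1e-8) break
        lam <- lam / 2
      }
      beta <- beta + lam * step; eta <- eta_c; ll <- llc
    }
    if (max(abs(beta)) > 1e3)
      stop("diverging coefficients: likely complete separation")
  }
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X * w, X)
  list(coef = setNames(drop(beta), colnames(X)), vcov = solve(H),
       loglik = ll, iterations = it, grad_norm = gnorm,
       converged = gnorm < tol)
}

## Fisher scoring (empirical information) for the cumulative-logit
## proportional-odds model: P(Y <= k | x) = plogis(zeta_k - x'beta).
.newton_polr <- function(X, y, K, tol = 1e-8, maxit = 100, start = NULL) {
  n <- length(y)
  if (is.null(start)) {
    cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / n
    par <- c(qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6)), numeric(ncol(X)))
  } else par <- start
  iz <- seq_len(K - 1)
  gnorm <- Inf; it <- 0L
  score <- function(par) {
    zeta <- par[iz]; beta <- par[-iz]
    eta <- if (length(beta)) drop(X %*% beta) else numeric(n)
    Fm <- vapply(zeta, function(z) plogis(z - eta), numeric(n))  # n x (K-1)
    Fa <- cbind(0, Fm, 1)
    pk <- Fa[cbind(seq_len(n), y + 1L)] - Fa[cbind(seq_len(n), y)]
    pk <- pmax(pk, 1e-12)
    fm <- Fm * (1 - Fm)
    ## d loglik / d zeta_j: +f_j if y == j, -f_j if y == j + 1
    Sz <- matrix(0, n, K - 1)
    for (j in iz) {
      Sz[y == j, j] <- fm[y == j, j] / pk[y == j]
      Sz[y == j + 1L, j] <- -fm[y == j + 1L, j] / pk[y == j + 1L]
    }
    ## d loglik / d eta = -(f_{y} - f_{y-1}) / p_y  (f_0 = f_K = 0)
    fa <- cbind(0, fm, 0)
    ce <- -(fa[cbind(seq_len(n), y + 1L)] - fa[cbind(seq_len(n), y)]) / pk
    list(Sz = Sz, ce = ce, pk = pk)
  }
  for (it in seq_len(maxit)) {
    s <- score(par)
    g <- c(colSums(s$Sz), if (ncol(X)) crossprod(X, s$ce))
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol) break
    S <- cbind(s$Sz, if (ncol(X)) X * s$ce)
    H <- crossprod(S)
    step <- tryCatch(drop(solve(H, g)), error = function(e)
      stop("singular information matrix in proportional-odds fit"))
    if (gnorm < 1) {
      cand <- par + step   # near the optimum: untested full step (see above)
    } else {
      ll_cur <- sum(log(s$pk))
      lam <- 1
      repeat {
        cand <- par + lam * step
        ok <- all(diff(cand[iz]) > 0)
        llc <- if (ok) sum(log(score(cand)$pk)) else -Inf
        if ((ok && llc >= ll_cur - 1e-12) || lam < 1e-8) break
        lam <- lam / 2
      }
    }
    if (!all(diff(cand[iz]) > 0)) {
      warning("threshold crossing during optimization; reordering")
      cand[iz] <- sort(cand[iz]) + (seq_len(K - 1) - 1) * 1e-6
    }
    par <- cand
  }
  s <- score(par)
  ll <- sum(log(s$pk))
  S <- cbind(s$Sz, if (ncol(X)) X * s$ce)
  H <- crossprod(S)
  nm <- c(paste0("zeta_", seq_len(K - 1)), colnames(X))
  V <- solve(H)
  dimnames(V) <- list(nm, nm)
  list(coef = setNames(par, nm), vcov = V, loglik = ll,
       iterations = it, grad_norm = gnorm, converged = gnorm < tol)
}

.make_fit <- function(res, spec, knots, n, extra = list()) {
  k <- length(res$coef)
  structure(c(list(coef = res$coef, vcov = res$vcov, loglik = res$loglik,
                   aic = 2 * k - 2 * res$loglik, n = n,
                   converged = res$converged, iterations = res$iterations,
                   grad_norm = res$grad_norm, spec = spec, knots = knots,
                   slope_names = setdiff(names(res$coef),
                                         c("(Intercept)", "zeta_1", "zeta_2"))),
              extra),
            class = "wgf_fit")
}

#' Fit a pooled logistic discrete-time hazard model
#'
#' Maximum-likelihood logistic regression on stacked person-period records
#' (Newton-Raphson, gradient-norm tolerance 1e-8, iteration cap 50), with
#' standard errors from the observed information matrix. Non-convergence and
#' separation are reported, never silently absorbed.
#'
#' @param pp a person-period table from [expand_to_person_periods()].
#' @param spec a [model_spec()] with a binary outcome.
#' @param knots spline knots when the spec uses `age_spline`;
#'   default [default_knots()] on `pp`.
#' @param start optional warm-start coefficient vector.
#' @return an object of class `wgf_fit` with elements `coef`, `vcov`,
#'   `loglik`, `aic`, `n`, `converged`.
#' @export
fit_pooled_logistic <- function(pp, spec, knots = NULL, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binary_logit") stop("spec is not a binary model")
  if (is.null(knots) && "age_spline" %in% spec$covariates)
    knots <- default_knots(pp)
  mf <- .model_frame(pp, spec)
  if (!length(mf$rows)) stop("risk-set filter leaves no rows for ", spec$outcome)
  y <- mf$y
  if (all(y == 0L)) stop("outcome ", spec$outcome, " has no events")
  if (all(y == 1L)) stop("outcome ", spec$outcome, " has no non-events")
  X <- design_matrix(pp[mf$rows], spec$covariates, knots)
  res <- .newton_logit(X, y, start = start)
  if (!res$converged)
    warning("pooled logistic for ", spec$outcome, " did not converge (grad ",
            format(res$grad_norm), ")")
  .make_fit(res, spec, knots, length(y))
}

#' Fit a pooled proportional-odds model for exposure category
#'
#' Cumulative-logit ordinal regression for the 3-level exposure category
#' (light < medium < heavy) on employed person-periods, parameterized as
#' \eqn{P(Y \le k \mid x) = \mathrm{expit}(\zeta_k - x'\beta)} with ordered
#' thresholds \eqn{\zeta_1 < \zeta_2} and a shared slope vector (the
#' convention used by `MASS::polr`). Fit by Fisher scoring on the empirical
#' information.
#'
#' @inheritParams fit_pooled_logistic
#' @return a `wgf_fit` with `coef = c(zeta_1, zeta_2, beta...)` and a `zeta`
#'   element holding the thresholds.
#' @export
fit_proportional_odds <- function(pp, spec, knots = NULL, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "proportional_odds") stop("spec is not an ordinal model")
  if (is.null(knots) && "age_spline" %in% spec$covariates)
    knots <- default_knots(pp)
  mf <- .model_frame(pp, spec)
  if (!length(mf$rows)) stop("no employed person-periods to fit exposure model")
  y <- mf$y
  if (anyNA(y)) stop("exposure_category outside light/medium/heavy on employed rows")
  if (length(unique(y)) < 3L)
    stop("exposure model needs all three ordered categories present")
  X <- design_matrix(pp[mf$rows], spec$covariates, knots, intercept = FALSE)
  res <- .newton_polr(X, y, K = 3L, start = start)
  if (!res$converged)
    warning("proportional-odds fit did not converge (grad ",
            format(res$grad_norm), ")")
  .make_fit(res, spec, knots, length(y),
            extra = list(zeta = unname(res$coef[1:2])))
}

#' Construct a hazard model from known coefficients
#'
#' Builds a model object usable by the simulation engine directly from
#' coefficient values (e.g. a generating truth, or a hand-built example),
#' bypassing fitting.
#'
#' @param coef named coefficient vector; names are design-matrix columns, with
#'   `"(Intercept)"` for the intercept of binary models.
#' @param spec the [model_spec()] the coefficients belong to.
#' @param zeta ordered thresholds for proportional-odds models.
#' @param knots spline knots when the spec uses `age_spline`.
#' @return a `wgf_fit` (with `NA` likelihood metadata).
#' @export
hazard_model <- function(coef, spec, zeta = NULL, knots = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "proportional_odds") {
    stopifnot(length(zeta) == 2, diff(zeta) > 0)
    coef <- c(setNames(zeta, c("zeta_1", "zeta_2")), coef)
  }
  structure(list(coef = coef, vcov = NULL, loglik = NA_real_, aic = NA_real_,
                 n = NA_integer_, converged = TRUE, iterations = 0L,
                 grad_norm = NA_real_, spec = spec, knots = knots,
                 slope_names = setdiff(names(coef),
                                       c("(Intercept)", "zeta_1", "zeta_2")),
                 zeta = zeta),
            class = "wgf_fit")
}

#' @export
print.wgf_fit <- function(x, ...) {
  cat(sprintf("Discrete-time %s model for '%s' (%s)\n",
              x$spec$family, x$spec$outcome,
              if (isTRUE(x$converged)) "converged" else "NOT CONVERGED"))
  if (!is.na(x$loglik))
    cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f\n", x$n, x$loglik, x$aic))
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, length(x$coef))
  print(data.frame(estimate = round(x$coef, 4), se = round(se, 4)))
  invisible(x)
}

#' @export
coef.wgf_fit <- function(object, ...) object$coef

#' @export
vcov.wgf_fit <- function(object, ...) object$vcov

#' @export
logLik.wgf_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

## linear predictor x'beta for the slope part (no intercept/thresholds)
.fit_eta <- function(model, env) {
  cf <- model$coef
  slope_names <- model$slope_names
  cols <- .cov_columns(model$spec$covariates, env, model$knots)
  if (!setequal(names(cols), slope_names))
    stop("covariates available do not match model coefficients: need ",
         paste(slope_names, collapse = ", "))
  eta <- 0
  for (nm in slope_names) eta <- eta + cf[[nm]] * cols[[nm]]
  if (length(eta) == 1L && is.data.frame(env)) eta <- rep(eta, nrow(env))
  eta
}

## fast path for the simulation engine: `cols` is keyed by design-matrix
## column names (spline already expanded); `idx` optionally subsets vector
## columns while leaving per-step scalars alone
.eta_cols <- function(model, cols, idx = NULL) {
  cf <- model$coef
  eta <- 0
  for (nm in model$slope_names) {
    v <- cols[[nm]]
    if (is.null(v)) stop("simulation state lacks covariate column: ", nm)
    if (!is.null(idx) && length(v) > 1L) v <- v[idx]
    eta <- eta + cf[[nm]] * v
  }
  eta
}

#' Predicted discrete-time hazard from a binary model
#'
#' @param model a binary `wgf_fit`.
#' @param newdata person-period rows or a named list of covariate vectors.
#' @return predicted event probabilities in (0, 1).
#' @export
predict_hazard <- function(model, newdata) {
  stopifnot(inherits(model, "wgf_fit"))
  if (model$spec$family != "binary_logit") stop("model is not binary")
  plogis(model$coef[["(Intercept)"]] + .fit_eta(model, newdata))
}

#' Predicted exposure-category probabilities from a proportional-odds model
#'
#' @param model an ordinal `wgf_fit`.
#' @param newdata person-period rows or a named list of covariate vectors.
#' @return matrix with columns `light`, `medium`, `heavy`; rows sum to 1.
#' @export
predict_category_probs <- function(model, newdata) {
  stopifnot(inherits(model, "wgf_fit"))
  if (model$spec$family != "proportional_odds") stop("model is not ordinal")
  eta <- .fit_eta(model, newdata)
  F1 <- plogis(model$coef[["zeta_1"]] - eta)
  F2 <- plogis(model$coef[["zeta_2"]] - eta)
  cbind(light = F1, medium = F2 - F1, heavy = 1 - F2)
}

#' Bundle the six fitted models used by the g-formula engine
#'
#' @param d_resp,d_heart,d_other binary cause-specific mortality models.
#' @param leave_work,return_work binary employment-transition models.
#' @param exposure_category proportional-odds exposure model (may be `NULL`
#'   when only forced-exposure interventions will be simulated).
#' @return an object of class `model_suite`.
#' @export
model_suite <- function(d_resp, d_heart, d_other, leave_work, return_work,
                        exposure_category = NULL) {
  m <- list(d_resp = d_resp, d_heart = d_heart, d_other = d_other,
            leave_work = leave_work, return_work = return_work,
            exposure_category = exposure_category)
  for (nm in names(m)) {
    if (nm == "exposure_category" && is.null(m[[nm]])) next
    if (!inherits(m[[nm]], "wgf_fit")) stop(nm, " is not a wgf_fit")
    if (m[[nm]]$spec$outcome != nm) stop(nm, " slot holds a model for ",
                                         m[[nm]]$spec$outcome)
  }
  structure(m, class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("g-formula model suite:\n")
  for (nm in names(x)) {
    m <- x[[nm]]
    if (is.null(m)) { cat(sprintf("  %-18s <absent>\n", nm)); next }
    cat(sprintf("  %-18s %s, %d coef%s%s\n", nm, m$spec$family,
                length(m$coef),
                if (!is.na(m$aic)) sprintf(", AIC %.1f", m$aic) else "",
                if (isTRUE(m$converged)) "" else "  [NOT CONVERGED]"))
  }
  invisible(x)
}

#' Default model specifications
#'
#' Two built-in specification sets. `"flexible"` mirrors a typical analysis
#' model: restricted cubic spline age intercepts, linear calendar time, an
#' age-by-time interaction, baseline covariates, employment status, cumulative
#' work time and the three lagged exposure windows. `"linear"` replaces the
#' spline and interaction with a linear age term; it is the form under which
#' generating coefficients of the synthetic cohort are directly recoverable.
#'
#' @param form `"flexible"` or `"linear"`.
#' @return named list of six [model_spec()] objects.
#' @export
default_model_specs <- function(form = c("flexible", "linear")) {
  form <- match.arg(form)
  age <- if (form == "flexible") "age_spline" else "age_c"
  extra <- if (form == "flexible") c("year_c", "age_year") else "year_c"
  death_cov <- c(age, extra, "us_born", "pre_entry_years",
                 "pre_entry_exposure", "employed", "cum_work_c",
                 "w_2_5", "w_5_10", "w_10_20")
  list(
    d_resp = model_spec("d_resp", death_cov),
    d_heart = model_spec("d_heart", death_cov),
    d_other = model_spec("d_other", death_cov),
    leave_work = model_spec("leave_work", c(age, "w_recent_1_5")),
    return_work = model_spec("return_work", age),
    exposure_category = model_spec("exposure_category", "age_c")
  )
}

#' Fit all six discrete-time models
#'
#' @param pp person-period table.
#' @param specs named list of six [model_spec()]s (see
#'   [default_model_specs()]).
#' @param knots shared spline knots; computed by [default_knots()] when any
#'   spec needs them and none are given.
#' @return a [model_suite()].
#' @export
fit_model_suite <- function(pp, specs = default_model_specs(), knots = NULL) {
  needs_spline <- any(vapply(specs, function(s) "age_spline" %in% s$covariates, TRUE))
  if (is.null(knots) && needs_spline) knots <- default_knots(pp)
  fit1 <- function(s) {
    if (s$family == "proportional_odds") fit_proportional_odds(pp, s, knots)
    else fit_pooled_logistic(pp, s, knots)
  }
  model_suite(d_resp = fit1(specs$d_resp), d_heart = fit1(specs$d_heart),
              d_other = fit1(specs$d_other), leave_work = fit1(specs$leave_work),
              return_work = fit1(specs$return_work),
              exposure_category = if (!is.null(specs$exposure_category))
                fit1(specs$exposure_category))
}

#' Serialize a model suite to a delimited text file
#'
#' One row per coefficient: model, family, term, estimate, se, plus per-model
#' loglik/AIC/n/convergence columns.
#'
#' @param suite a [model_suite()].
#' @param file output path (tab-separated).
#' @return the table, invisibly.
#' @export
write_model_suite <- function(suite, file) {
  rows <- lapply(names(suite), function(nm) {
    m <- suite[[nm]]
    if (is.null(m)) return(NULL)
    se <- if (!is.null(m$vcov)) sqrt(diag(m$vcov)) else rep(NA_real_, length(m$coef))
    data.frame(model = nm, family = m$spec$family, term = names(m$coef),
               estimate = unname(m$coef), se = unname(se),
               loglik = m$loglik, aic = m$aic, n = m$n,
               converged = m$converged)
  })
  out <- do.call(rbind, rows)
  write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
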