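#' Configuration for the full g-formula pipeline
#'
#' @param interventions character vector of intervention kinds to simulate.
#' @param reference the no-exposure reference intervention for contrasts.
#' @param eval_ages ages at which risks and excesses are reported
#'   (default 60 and 70).
#' @param causes cause-of-death labels.
#' @param mc_size Monte Carlo pseudo-cohort size per intervention.
#' @param B bootstrap replicates (1500 for full runs; 200 is a practical
#'   test-scale default). Must be at least 2.
#' @param bootstrap run the worker-level bootstrap inside [run_analysis()].
#' @param seed master seed; every source of randomness (simulation seeds per
#'   intervention, bootstrap resampling, per-replicate simulation seeds)
#'   is derived from it.
#' @param specs_form model-specification set, see [default_model_specs()].
#' @param max_age,admin_end_year censoring bounds.
#' @param coeffs an [exposure_coefficients()] object.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(interventions = c("natural_course", "never_exposed",
                                              "always_light", "always_medium",
                                              "always_heavy"),
                            reference = "never_exposed",
                            eval_ages = c(60, 70),
                            causes = c("resp_cancer", "heart", "other"),
                            mc_size = 20000, B = 200, bootstrap = FALSE,
                            seed = 1L, specs_form = "flexible",
                            max_age = 90, admin_end_year = 1990,
                            coeffs = exposure_coefficients()) {
  if (B < 2) stop("B must be at least 2")
  if (any(eval_ages <= 20 | eval_ages > max_age))
    stop("evaluation ages must lie in (20, max_age]")
  if (!reference %in% interventions)
    interventions <- c(interventions, reference)
  structure(list(interventions = interventions, reference = reference,
                 eval_ages = eval_ages, causes = causes, mc_size = mc_size,
                 B = B, bootstrap = bootstrap, seed = as.integer(seed),
                 specs_form = specs_form, max_age = max_age,
                 admin_end_year = admin_end_year, coeffs = coeffs),
            class = "pipeline_config")
}

## one sub-seed per named consumer, derived deterministically from the master
.derive_seeds <- function(seed, names) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

## simulate all configured interventions and return CIFs (+ histories)
.simulate_interventions <- function(suite, baseline, config, seeds,
                                    keep_histories = FALSE) {
  cifs <- list(); hists <- list()
  for (iv in config$interventions) {
    h <- simulate_pseudo_cohort(suite, baseline, iv,
                                mc_size = config$mc_size, seed = seeds[[iv]],
                                max_age = config$max_age,
                                admin_end_year = config$admin_end_year,
                                coeffs = config$coeffs,
                                allow_unconverged = TRUE)
    cifs[[iv]] <- cumulative_incidence(h, config$causes,
                                       max_age = config$max_age)
    if (keep_histories) hists[[iv]] <- h else
      if (iv == "natural_course") hists[[iv]] <- h
  }
  list(cifs = cifs, histories = hists)
}

## flatten the contrast table into a named estimand vector
.estimand_vector <- function(cifs, config) {
  out <- c()
  ref <- config$reference
  for (a in config$eval_ages) for (k in c("all", config$causes)) {
    out[sprintf("deaths_per_1000.%s.age%d.%s", k, a, ref)] <-
      per_1000(cif_at(cifs[[ref]], a, k))
    for (iv in setdiff(names(cifs), ref))
      out[sprintf("excess_per_1000.%s.age%d.%s", k, a, iv)] <-
        per_1000(risk_difference(cifs[[iv]], cifs[[ref]], a, k))
  }
  out
}

## Pre-built fitting frames for fast worker-level bootstrap refits: the design
## matrix of every model is built once; a replicate only gathers rows.
.prepare_fit_data <- function(pp, specs, knots) {
  ids <- pp$worker_id
  uids <- unique(ids)
  frames <- lapply(specs, function(s) {
    mf <- .model_frame(pp, s)
    X <- design_matrix(pp[mf$rows], s$covariates, knots,
                       intercept = s$family == "binary_logit")
    w <- ids[mf$rows]
    list(spec = s, X = X, y = mf$y,
         rows_by_worker = split(seq_along(mf$rows), factor(w, levels = uids)))
  })
  list(frames = frames, uids = uids)
}

.refit_suite <- function(prep, workers_idx, knots, warm = NULL) {
  fits <- lapply(names(prep$frames), function(nm) {
    fr <- prep$frames[[nm]]
    rows <- unlist(fr$rows_by_worker[workers_idx], use.names = FALSE)
    X <- fr$X[rows, , drop = FALSE]
    y <- fr$y[rows]
    st <- if (!is.null(warm)) warm[[nm]]$coef
    if (fr$spec$family == "binary_logit") {
      if (all(y == 0L) || all(y == 1L)) stop("degenerate outcome in replicate")
      res <- .newton_logit(X, y, start = st)
    } else {
      if (length(unique(y)) < 3L) stop("missing exposure category in replicate")
      res <- .newton_polr(X, y, K = 3L, start = st)
    }
    f <- .make_fit(res, fr$spec, knots, length(y))
    if (fr$spec$family == "proportional_odds") f$zeta <- unname(res$coef[1:2])
    f
  })
  names(fits) <- names(prep$frames)
  do.call(model_suite, fits)
}

#' Worker-level percentile bootstrap for all pipeline estimands
#'
#' For each of `B` replicates: resample workers with replacement (carrying all
#' their person-periods — person-periods within a worker are dependent), refit
#' all six models (warm-started from the original fit), rerun every
#' intervention on the replicate's baseline sample, and recompute all
#' estimands. Point estimates come from the original sample; intervals are
#' the 2.5th/97.5th percentiles across replicates (percentile method, no bias
#' correction). Deterministic given the master seed. Replicate-level fit
#' failures are logged and counted; the run aborts if more than 5% fail.
#'
#' @param baseline,history cohort tables (see [expand_to_person_periods()]).
#' @param config a [pipeline_config()].
#' @param specs model specifications (default per `config$specs_form`).
#' @param knots spline knots; resolved once on the original sample and held
#'   fixed across replicates.
#' @return object of class `wgf_boot`: data.table with `estimand`, `point`,
#'   `lower`, `upper`; attributes `B`, `n_failed`, `replicates` (matrix of
#'   replicate draws).
#' @export
bootstrap_cis <- function(baseline, history, config = pipeline_config(),
                          specs = NULL, knots = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$B < 100)
    warning("B = ", config$B, " is very low for percentile intervals")
  baseline <- data.table::as.data.table(baseline)
  pp <- expand_to_person_periods(baseline, history, coeffs = config$coeffs,
                                 max_age = config$max_age,
                                 admin_end_year = config$admin_end_year)
  if (is.null(specs)) specs <- default_model_specs(config$specs_form)
  needs_spline <- any(vapply(specs, function(s) "age_spline" %in% s$covariates, TRUE))
  if (is.null(knots) && needs_spline) knots <- default_knots(pp)

  suite0 <- fit_model_suite(pp, specs, knots)
  seeds <- .derive_seeds(config$seed,
                         c("bootstrap", paste0("point.", config$interventions)))
  point <- .estimand_vector(
    .simulate_interventions(suite0, baseline, config,
                            setNames(seeds[paste0("point.", config$interventions)],
                                     config$interventions))$cifs,
    config)

  prep <- .prepare_fit_data(pp, specs, knots)
  n_workers <- length(prep$uids)
  set.seed(seeds[["bootstrap"]])
  draws <- matrix(NA_real_, config$B, length(point),
                  dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(config$B)) {
    widx <- sample.int(n_workers, n_workers, replace = TRUE)
    rep_seeds <- setNames(sample.int(.Machine$integer.max - 1L,
                                     length(config$interventions)),
                          config$interventions)
    est <- tryCatch({
      suite_b <- .refit_suite(prep, widx, knots, warm = suite0)
      base_b <- baseline[match(prep$uids[widx], baseline$worker_id)]
      .estimand_vector(
        .simulate_interventions(suite_b, base_b, config, rep_seeds)$cifs,
        config)
    }, error = function(e) {
      message("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(est)) n_failed <- n_failed + 1L else draws[b, ] <- est
  }
  if (n_failed > 0.05 * config$B)
    stop("more than 5% of bootstrap replicates failed (", n_failed, "/",
         config$B, ")")
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.table::data.table(estimand = names(point), point = unname(point),
                                lower = qs[1, ], upper = qs[2, ])
  viol <- out[point < lower | point > upper]
  if (nrow(viol))
    warning("percentile interval does not contain the point estimate for: ",
            paste(viol$estimand, collapse = ", "))
  structure(out, class = c("wgf_boot", class(out)), B = config$B,
            n_failed = n_failed, replicates = draws)
}

#' @export
print.wgf_boot <- function(x, ...) {
  cat(sprintf("Percentile bootstrap (B = %d, %d failed replicates)\n",
              attr(x, "B"), attr(x, "n_failed")))
  NextMethod()
}

## observed entry/exit/cause per worker from a history table
.observed_outcomes <- function(history) {
  h <- data.table::as.data.table(history)
  h[order(age), .(entry_age = age[1], exit_age = age[.N],
                  cause = death_cause[.N]), by = worker_id]
}

#' Natural-course calibration diagnostics
#'
#' Side-by-side comparison of the observed cohort and its simulated natural
#' course: cause-specific cumulative incidence curves, median and IQR of
#' cumulative (post-entry) exposure over all person-time, and employment
#' prevalence by age; reports the maximum cumulative-incidence discrepancy up
#' to `eval_age`.
#'
#' @param baseline,history the observed cohort tables.
#' @param nc_histories `simulated_histories` from a natural-course run.
#' @param eval_age age up to which the maximum CIF discrepancy is reported.
#' @param causes cause labels.
#' @param coeffs an [exposure_coefficients()] object.
#' @return object of class `wgf_calibration`.
#' @export
calibration_report <- function(baseline, history, nc_histories,
                               eval_age = 70,
                               causes = c("resp_cancer", "heart", "other"),
                               coeffs = exposure_coefficients()) {
  stopifnot(inherits(nc_histories, "simulated_histories"))
  max_age <- nc_histories$max_age
  obs <- .observed_outcomes(history)
  cif_obs <- cumulative_incidence(obs, causes, max_age = max_age)
  cif_sim <- cumulative_incidence(nc_histories, causes, max_age = max_age)
  cols <- c(paste0("cif_", causes), "cif_all")
  upto <- cif_obs$age <= eval_age
  disc <- vapply(cols, function(cl)
    max(abs(cif_obs[[cl]][upto] - cif_sim[[cl]][upto])), numeric(1))

  h <- data.table::as.data.table(history)
  h <- h[order(worker_id, age)]
  obs_cum <- h[, cumsum(annual_increment(exposure_category, coeffs)),
               by = worker_id]$V1
  inc <- nc_histories$increments
  sim_cum <- unlist(lapply(seq_len(nrow(inc)), function(i) {
    j <- (nc_histories$entry_age[i]:nc_histories$exit_age[i]) -
      nc_histories$ages[1] + 1L
    cumsum(inc[i, j])
  }))
  qs <- c(0.25, 0.5, 0.75)
  emp_obs <- h[, .(observed = mean(employed)), by = age]
  a0 <- nc_histories$ages[1]
  at_risk <- outer(nc_histories$entry_age, nc_histories$ages, `<=`) &
    outer(nc_histories$exit_age, nc_histories$ages, `>=`)
  emp_sim <- data.table::data.table(
    age = nc_histories$ages,
    simulated = colSums(nc_histories$employed * at_risk, na.rm = TRUE) /
      pmax(colSums(at_risk), 1L))
  structure(list(
    max_cif_discrepancy = disc,
    max_cif_discrepancy_overall = max(disc),
    eval_age = eval_age,
    cif_observed = cif_obs, cif_simulated = cif_sim,
    exposure_quantiles = rbind(observed = quantile(obs_cum, qs),
                               simulated = quantile(sim_cum, qs)),
    employment_by_age = merge(emp_obs, emp_sim, by = "age", all = TRUE)),
    class = "wgf_calibration")
}

#' @export
print.wgf_calibration <- function(x, ...) {
  cat(sprintf("Natural-course calibration (through age %d)\n", x$eval_age))
  cat("  max |observed - simulated| cumulative incidence:\n")
  print(round(x$max_cif_discrepancy, 4))
  cat("  cumulative exposure quantiles (mg/m^3-years, all person-time):\n")
  print(round(x$exposure_quantiles, 2))
  invisible(x)
}

#' Run the full g-formula analysis pipeline
#'
#' Expand to person-periods, fit the six discrete-time models, simulate every
#' configured intervention, estimate cumulative incidence and contrasts,
#' optionally bootstrap, and run the natural-course calibration check. When
#' `output_dir` is given, writes `results.tsv` (the age-by-cause deaths /
#' excess-deaths-per-1,000 table), `models.tsv`, `cifs.tsv`,
#' `calibration.tsv`, `bootstrap.tsv` (if run) and `run_log.txt` (seeds,
#' versions, timings). Result tables are byte-identical across runs with the
#' same master seed.
#'
#' @param baseline,history cohort tables.
#' @param config a [pipeline_config()].
#' @param output_dir optional output directory.
#' @return a results bundle (list) with the fitted suite, CIFs, contrast
#'   table, bootstrap result (or NULL), calibration report (or NULL).
#' @export
run_analysis <- function(baseline, history, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time(); timings <- c()
  stage <- function(nm, expr) {
    ts <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[nm]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 2)
    r
  }
  pp <- stage("expand", expand_to_person_periods(
    baseline, history, coeffs = config$coeffs, max_age = config$max_age,
    admin_end_year = config$admin_end_year))
  specs <- default_model_specs(config$specs_form)
  suite <- stage("fit", fit_model_suite(pp, specs))
  seeds <- .derive_seeds(config$seed, config$interventions)
  sim <- stage("simulate", .simulate_interventions(suite, baseline, config,
                                                   seeds))
  contrasts <- stage("estimate",
                     if (length(sim$cifs) > 1)
                       contrast_table(sim$cifs, config$reference,
                                      config$eval_ages, config$causes)
                     else data.table::data.table())
  boot <- if (config$bootstrap)
    stage("bootstrap", bootstrap_cis(baseline, history, config, specs))
  calib <- if ("natural_course" %in% names(sim$histories))
    stage("calibration", calibration_report(
      baseline, history, sim$histories$natural_course,
      causes = config$causes, coeffs = config$coeffs))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) write.table(d, file.path(output_dir, f), sep = "\t",
                                     row.names = FALSE, quote = FALSE)
    if (nrow(contrasts)) wt(contrasts, "results.tsv")
    write_model_suite(suite, file.path(output_dir, "models.tsv"))
    cif_long <- data.table::rbindlist(
      lapply(names(sim$cifs), function(iv)
        data.table::data.table(intervention = iv, sim$cifs[[iv]])))
    wt(cif_long, "cifs.tsv")
    if (!is.null(boot)) wt(boot, "bootstrap.tsv")
    if (!is.null(calib)) {
      wt(data.table::data.table(
        series = names(calib$max_cif_discrepancy),
        max_discrepancy = unname(calib$max_cif_discrepancy)),
        "calibration.tsv")
    }
    log <- c(sprintf("workergf %s | R %s", packageVersion("workergf"),
                     getRversion()),
             sprintf("master seed: %d", config$seed),
             sprintf("interventions: %s",
                     paste(config$interventions, collapse = ", ")),
             sprintf("mc_size: %d", config$mc_size),
             sprintf("stage timings (s): %s",
                     paste(names(timings), unlist(timings), sep = "=",
                           collapse = ", ")),
             sprintf("total (s): %.2f",
                     as.numeric(Sys.time() - t0, units = "secs")))
    writeLines(log, file.path(output_dir, "run_log.txt"))
  }
  list(person_periods = pp, suite = suite, cifs = sim$cifs,
       natural_course_histories = sim$histories$natural_course,
       contrasts = contrasts, bootstrap = boot, calibration = calib,
       config = config)
}
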