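#' Generating parameters for the synthetic occupational cohort
#'
#' Defaults are read from the versioned config shipped at
#' `system.file("extdata", "generator-defaults.yaml", package = "workergf")`;
#' they encode a mid-century male smelter workforce with light/medium/heavy
#' exposure intensity categories while at work, leaving-work hazards that
#' increase with recent exposure (the confounding loop behind healthy worker
#' survivor bias), and cause-of-death proportions by the end of follow-up near
#' 5.6% respiratory cancer / 21% heart disease / 34% other causes.
#'
#' @param n_workers,seed,max_age,admin_end_year scalar overrides of the
#'   corresponding config entries.
#' @param effect_profile `"default"` keeps all generating effects;
#'   `"null"` severs every pathway from post-entry exposure to death (the
#'   exposure-window, employment-status and cumulative-work-time coefficients
#'   of the three death models are set to zero) while keeping the positive
#'   exposure-to-leaving-work coefficient, so the survivor-bias structure is
#'   present but the true intervention contrasts are exactly null.
#' @param overrides named list merged recursively over the config (e.g.
#'   `list(models = list(leave_work = list(w_recent_1_5 = 0)))`).
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_workers = NULL, seed = NULL, max_age = NULL,
                             admin_end_year = NULL,
                             effect_profile = c("default", "null"),
                             overrides = list()) {
  effect_profile <- match.arg(effect_profile)
  path <- system.file("extdata", "generator-defaults.yaml",
                      package = "workergf")
  p <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  p <- merge_rec(p, overrides)
  if (!is.null(n_workers)) p$n_workers <- n_workers
  if (!is.null(seed)) p$seed <- seed
  if (!is.null(max_age)) p$max_age <- max_age
  if (!is.null(admin_end_year)) p$admin_end_year <- admin_end_year
  if (effect_profile == "null") {
    for (m in c("d_resp", "d_heart", "d_other"))
      for (term in c("w_2_5", "w_5_10", "w_10_20", "employed", "cum_work_c"))
        p$models[[m]][[term]] <- 0
  }
  p$effect_profile <- effect_profile
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (!is.numeric(p$n_workers) || p$n_workers <= 0)
    stop("n_workers must be positive")
  cc <- p$category_concentrations
  if (!(cc$light > 0 && cc$medium > cc$light && cc$heavy > cc$medium))
    stop("category concentrations must be strictly increasing")
  if (!(p$gamma > 0 && p$gamma <= 1)) stop("gamma must lie in (0, 1]")
  if (p$entry_calendar_window$end_year >= p$admin_end_year)
    stop("entry calendar window must precede the administrative end year")
  if (!is.numeric(p$entry_age_distribution$spread) ||
      p$entry_age_distribution$spread <= 0)
    stop("degenerate entry-age distribution: spread must be > 0")
  if (p$models$exposure_category$zeta_1 >= p$models$exposure_category$zeta_2)
    stop("ordinal thresholds must be increasing")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort generator: n = %d, entry %d-%d, follow-up to %d (age cap %d)\n",
    x$n_workers, x$entry_calendar_window$start_year,
    x$entry_calendar_window$end_year, x$admin_end_year, x$max_age))
  cat("  effect profile:", x$effect_profile, "\n")
  invisible(x)
}

#' Exact generating coefficients, keyed like fitted-model coefficients
#'
#' Every coefficient fit by the `"linear"`-form model suite has a counterpart
#' here, enabling parameter-recovery tests.
#'
#' @param params a [generator_params()] object.
#' @return named list (one element per model) of named coefficient vectors;
#'   the ordinal model additionally carries its `zeta` thresholds.
#' @export
truth_record <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  tr <- function(m) {
    v <- unlist(params$models[[m]])
    names(v)[names(v) == "intercept"] <- "(Intercept)"
    v
  }
  out <- lapply(c("d_resp", "d_heart", "d_other", "leave_work", "return_work"),
                tr)
  names(out) <- c("d_resp", "d_heart", "d_other", "leave_work", "return_work")
  ex <- unlist(params$models$exposure_category)
  out$exposure_category <- ex
  out
}

#' Model suite built from the generating truth
#'
#' Packages the generating coefficients as a [model_suite()] so the simulation
#' engine (and calibration diagnostics) can run directly from the truth.
#'
#' @param params a [generator_params()] object.
#' @return a [model_suite()].
#' @export
truth_suite <- function(params) {
  tr <- truth_record(params)
  specs <- default_model_specs("linear")
  mk <- function(nm) {
    cf <- tr[[nm]]
    hazard_model(cf[setdiff(names(cf), c("zeta_1", "zeta_2"))], specs[[nm]])
  }
  ex <- tr$exposure_category
  model_suite(
    d_resp = mk("d_resp"), d_heart = mk("d_heart"), d_other = mk("d_other"),
    leave_work = mk("leave_work"), return_work = mk("return_work"),
    exposure_category = hazard_model(
      ex[setdiff(names(ex), c("zeta_1", "zeta_2"))],
      specs$exposure_category, zeta = unname(ex[c("zeta_1", "zeta_2")])))
}

.exposure_coeffs_from_params <- function(params) {
  cc <- params$category_concentrations
  exposure_coefficients(cc$light, cc$medium, cc$heavy, params$gamma)
}

#' Generate a synthetic occupational cohort with known truth
#'
#' Draws worker baselines (entry age and calendar year, birthplace indicator,
#' pre-entry work and exposure history) and simulates annual
#' employment/exposure/mortality histories forward from the generating models,
#' using the same simulation engine the g-formula uses, under the natural
#' course. Every worker enters after at least one year of employment; annual
#' records run from entry age to the earliest of death, the age cap, or the
#' administrative end of follow-up; identical seeds give bit-identical output.
#'
#' @param params a [generator_params()] object.
#' @return an object of class `synthetic_cohort`: list with `baseline` and
#'   `history` tables (see [expand_to_person_periods()] for schemas), the
#'   [truth_record()], and the params.
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  validate_generator_params(params)
  n <- as.integer(params$n_workers)
  set.seed(params$seed)

  ead <- params$entry_age_distribution
  entry_age <- as.integer(pmin(pmax(round(
    18 + rlnorm(n, log(ead$median - 18), ead$spread)), 20L), 65L))
  win <- params$entry_calendar_window
  entry_year <- sample(win$start_year:win$end_year, n, replace = TRUE)
  birth_year <- entry_year - entry_age
  bl <- params$baseline
  us_born <- rbinom(n, 1L, bl$p_us_born)
  long <- rbinom(n, 1L, bl$p_long_tenure)
  pre_years <- round(1 + long * rgamma(n, bl$tenure_shape, scale = bl$tenure_scale), 2)
  pcat <- unlist(bl$pre_entry_category_probs)
  p_none <- bl$p_unexposed_pre_entry
  cat0 <- sample(c("none", "light", "medium", "heavy"), n, replace = TRUE,
                 prob = c(p_none, (1 - p_none) * pcat / sum(pcat)))
  coeffs <- .exposure_coeffs_from_params(params)
  pre_exp <- round(pre_years * annual_increment(cat0, coeffs), 4)

  baseline <- data.table::data.table(
    worker_id = seq_len(n), entry_age = entry_age, entry_year = entry_year,
    birth_year = birth_year, us_born = us_born,
    pre_entry_years_worked = pre_years, pre_entry_exposure = pre_exp)

  sim <- .simulate_forward(truth_suite(params), baseline,
                           intervention_spec("natural_course"),
                           max_age = params$max_age,
                           admin_end_year = params$admin_end_year,
                           coeffs = coeffs, record_matrices = TRUE)
  history <- histories_to_table(sim)
  structure(list(baseline = baseline, history = history,
                 truth = truth_record(params), params = params),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  last <- x$history[, .SD[.N], by = worker_id]
  tab <- table(last$death_cause)
  cat(sprintf("Synthetic occupational cohort: %d workers, %d worker-years\n",
              n, nrow(x$history)))
  cat(sprintf("  vital status: alive %.1f%%, resp_cancer %.1f%%, heart %.1f%%, other %.1f%%\n",
              100 * tab[["none"]] / n, 100 * tab[["resp_cancer"]] / n,
              100 * tab[["heart"]] / n, 100 * tab[["other"]] / n))
  invisible(x)
}

#' Write / read a cohort as delimiter-separated tables
#'
#' Writes `baseline.tsv`, `history.tsv` and `truth.tsv` (generating
#' coefficients) into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$baseline, file.path(dir, "baseline.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cohort$history, file.path(dir, "history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  truth_df <- do.call(rbind, lapply(names(tr), function(m)
    data.frame(model = m, term = names(tr[[m]]), value = unname(tr[[m]]))))
  write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) data.table::fread(file.path(dir, f))
  list(baseline = rd("baseline.tsv"), history = rd("history.tsv"),
       truth = rd("truth.tsv"))
}
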