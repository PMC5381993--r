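#' Read model specifications from a YAML config
#'
#' The config maps each outcome to a covariate list, e.g.
#'
#' ```yaml
#' d_resp: [age_spline, year_c, employed, w_2_5, w_5_10, w_10_20]
#' d_heart: [age_spline, year_c, employed, w_2_5, w_5_10, w_10_20]
#' d_other: [age_spline, year_c, employed, w_2_5, w_5_10, w_10_20]
#' leave_work: [age_c, w_recent_1_5]
#' return_work: [age_c]
#' exposure_category: [age_c]
#' ```
#'
#' Outcomes and covariate names are validated by [model_spec()] /
#' [design_matrix()].
#'
#' @param file path to a YAML file with one entry per outcome.
#' @return named list of [model_spec()] objects.
#' @export
read_model_specs <- function(file) {
  cfg <- yaml::read_yaml(file)
  need <- c("d_resp", "d_heart", "d_other", "leave_work", "return_work",
            "exposure_category")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("model-spec config lacks outcome(s): ", paste(missing, collapse = ", "))
  out <- lapply(need, function(nm) model_spec(nm, unlist(cfg[[nm]])))
  names(out) <- need
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]:
#' `interventions`, `reference`, `eval_ages`, `causes`, `mc_size`, `B`,
#' `bootstrap`, `seed`, `specs_form`, `max_age`, `admin_end_year`. Unknown
#' keys are an error.
#'
#' @param file path to a YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  allowed <- setdiff(names(formals(pipeline_config)), "coeffs")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("interventions", "eval_ages", "causes"))
    if (!is.null(cfg[[k]])) cfg[[k]] <- unlist(cfg[[k]])
  do.call(pipeline_config, cfg)
}

#' Write a person-period table as a delimiter-separated file
#'
#' @param pp a person-period table from [expand_to_person_periods()].
#' @param file output path (tab-separated, header row).
#' @return `file`, invisibly.
#' @export
write_person_periods <- function(pp, file) {
  stopifnot(inherits(pp, "person_period"))
  write.table(pp, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
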