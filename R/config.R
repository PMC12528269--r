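#' Load the versioned default generator parameter set
#'
#' The package ships its default synthetic-cohort parameters in a YAML file so
#' that the study conditions (age-band weights, sex fractions, per-deficit
#' prevalence models, latent-factor loadings, and the generating coefficient
#' set for the frailty-score linear model) are pinned and versioned rather
#' than scattered through code. The EHR-style cohort carries 36 deficits
#' (including polypharmacy); the survey-style cohort carries 58.
#'
#' @param path optional path to an alternative YAML parameter file.
#' @return a list with elements `version`, `index_date`, `latent_sd`,
#'   `linear_truth`, and per-source blocks `ehr` and `survey`, each holding
#'   `prob_female`, `age_band_weights`, `registration_years_range`,
#'   `survey_missing_prob` and a `deficits` model table (see
#'   [deficit_models()]).
#' @export
default_generator_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "generator_defaults.yaml",
                                package = "ficompare", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  cfg$index_date <- as.Date(cfg$index_date)
  for (src in c("ehr", "survey")) {
    cfg[[src]]$deficits <- dplyr::bind_rows(lapply(cfg[[src]]$deficits, tibble::as_tibble))
    names(cfg[[src]]$deficits)[names(cfg[[src]]$deficits) == "name"] <- "deficit_name"
  }
  structure(cfg, class = "fi_generator_config")
}

#' Per-deficit prevalence models of a generator configuration
#'
#' Each deficit's presence probability follows a logistic model in age
#' (centred at 65), sex (0 = male, 1 = female), data source (0 = survey,
#' 1 = EHR) and a shared per-person latent factor u:
#' logit(p) = beta0 + beta_age (age - 65) + beta_sex sex + beta_source source
#' + lambda_load u.
#'
#' @param config a generator configuration from [default_generator_config()].
#' @param source `"ehr"` or `"survey"`.
#' @return tibble with columns `deficit_name`, `beta0`, `beta_age`,
#'   `beta_sex`, `beta_source`, `lambda_load`.
#' @export
deficit_models <- function(config, source = c("ehr", "survey")) {
  source <- match.arg(source)
  models <- config[[source]]$deficits
  validate_deficit_models(models)
  models
}

validate_deficit_models <- function(models) {
  req <- c("deficit_name", "beta0", "beta_age", "beta_sex", "beta_source", "lambda_load")
  miss <- setdiff(req, names(models))
  if (length(miss)) abort(paste0("deficit model table lacks columns: ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(models$deficit_name)) {
    abort("deficit_name must be unique within a model set")
  }
  num <- as.matrix(models[setdiff(req, "deficit_name")])
  if (!all(is.finite(num))) abort("all deficit model coefficients must be finite")
  invisible(models)
}

#' Configuration for one synthetic cohort
#'
#' @param n_persons number of individuals to generate (>= 1).
#' @param source_label `"EHR"` (routine records; source coded 1) or
#'   `"SURVEY"` (survey responses; source coded 0).
#' @param prob_female probability that an individual is female.
#' @param age_band_weights named probabilities over the six 5-year age bands
#'   65-69 ... 90+; must sum to 1 (tolerance 1e-9).
#' @param index_date the date at which deficits are ascertained.
#' @param registration_years_range length-2 numeric, minimum and maximum
#'   years of registration before `index_date` (EHR cohorts only).
#' @param seed integer seed; identical configurations produce identical
#'   cohorts.
#' @return a validated `fi_cohort_config` list.
#' @export
cohort_config <- function(n_persons,
                          source_label = c("EHR", "SURVEY"),
                          prob_female = 0.5,
                          age_band_weights = NULL,
                          index_date = as.Date("2018-01-01"),
                          registration_years_range = c(9, 30),
                          seed = 1L) {
  source_label <- match.arg(source_label)
  if (is.null(age_band_weights)) {
    age_band_weights <- setNames(rep(1 / 6, 6), AGE_BANDS)
  }
  cfg <- structure(list(
    n_persons = n_persons, source_label = source_label,
    prob_female = prob_female,
    age_band_weights = unlist(age_band_weights),
    index_date = as.Date(index_date),
    registration_years_range = as.numeric(registration_years_range),
    seed = as.integer(seed)
  ), class = "fi_cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 1) {
    abort("`n_persons` must be >= 1")
  }
  stopifnot_scalar_prob(cfg$prob_female, "prob_female")
  w <- cfg$age_band_weights
  if (!setequal(names(w), AGE_BANDS)) {
    abort(paste0("age_band_weights must be named over bands: ",
                 paste(AGE_BANDS, collapse = ", ")))
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort("age_band_weights must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  if (length(cfg$registration_years_range) != 2 ||
      cfg$registration_years_range[1] > cfg$registration_years_range[2]) {
    abort("registration_years_range must be (min, max) with min <= max")
  }
  invisible(cfg)
}

#' Item-missingness configuration for survey responses
#'
#' Missingness is applied completely at random (MCAR) after the presence
#' draw, independently per cell, at a per-deficit probability.
#'
#' @param per_deficit_missing_prob either a single probability applied to all
#'   deficits or a named vector keyed by deficit name.
#' @param mode only `"MCAR"` is supported.
#' @return an `fi_missingness_config` list.
#' @export
missingness_config <- function(per_deficit_missing_prob = 0, mode = "MCAR") {
  if (!identical(mode, "MCAR")) abort("only MCAR missingness is supported")
  p <- per_deficit_missing_prob
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("missingness probabilities must lie in [0, 1]")
  }
  structure(list(per_deficit_missing_prob = p, mode = mode),
            class = "fi_missingness_config")
}

#' Generating coefficients for the frailty-score linear model
#'
#' Returns the default coefficient set used when simulating frailty scores
#' directly from the linear model (intercept; age - 65; sex; data source;
#' and the three pairwise interactions), as stored in the generator
#' parameter file.
#'
#' @inheritParams deficit_models
#' @return named numeric vector of the seven coefficients.
#' @export
linear_truth <- function(config = default_generator_config()) {
  unlist(config$linear_truth)
}
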