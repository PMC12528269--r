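#' Configuration for an end-to-end comparison run
#'
#' Bundles every knob of the generate - ascertain - score - harmonise -
#' compare pipeline. All randomness flows from the single `seed`, split
#' deterministically per stage.
#'
#' @param n_ehr,n_survey cohort sizes per source.
#' @param seed root integer seed.
#' @param index_date ascertainment date.
#' @param thresholds a [frailty_thresholds()].
#' @param generator generator parameter set
#'   ([default_generator_config()]).
#' @param mapping_path path to the deficit-mapping CSV; defaults to the
#'   shipped fixture.
#' @param survey_missing_prob overrides the generator default item
#'   missingness when not `NULL`.
#' @param max_missing completeness-filter bound on missing items per survey
#'   row.
#' @param output_dir optional directory; when set, report tables are
#'   written as CSV with a JSON metadata sidecar.
#' @return an `fi_run_config` list.
#' @export
run_config <- function(n_ehr = 2000, n_survey = 2000, seed = 1L,
                       index_date = NULL,
                       thresholds = frailty_thresholds(),
                       generator = default_generator_config(),
                       mapping_path = NULL,
                       survey_missing_prob = NULL,
                       max_missing = 20,
                       output_dir = NULL) {
  mapping_path <- mapping_path %||%
    system.file("extdata", "deficit_mapping.csv", package = "ficompare",
                mustWork = TRUE)
  structure(list(
    n_ehr = n_ehr, n_survey = n_survey, seed = as.integer(seed),
    index_date = as.Date(index_date %||% generator$index_date),
    thresholds = thresholds, generator = generator,
    mapping_path = mapping_path,
    survey_missing_prob = survey_missing_prob %||%
      generator$survey$survey_missing_prob,
    max_missing = max_missing, output_dir = output_dir
  ), class = "fi_run_config")
}

#' Validate a run configuration
#'
#' @param config an `fi_run_config`.
#' @return tibble of violations (`field`, `message`); zero rows means valid.
#' @export
validate_run_config <- function(config) {
  v <- list()
  add <- function(field, message) v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  if (!is.numeric(config$n_ehr) || config$n_ehr < 1) add("n_ehr", "must be >= 1")
  if (!is.numeric(config$n_survey) || config$n_survey < 1) add("n_survey", "must be >= 1")
  th <- config$thresholds
  if (!inherits(th, "fi_thresholds")) {
    t3 <- unlist(th)[1:3]
    if (any(diff(t3) <= 0) || any(t3 <= 0) || any(t3 >= 1)) {
      add("thresholds", "must be strictly increasing inside (0, 1)")
    }
  }
  if (!file.exists(config$mapping_path)) add("mapping_path", "file does not exist")
  if (is.na(config$index_date)) add("index_date", "not a parseable date")
  if (!is.numeric(config$max_missing) || config$max_missing < 0) {
    add("max_missing", "must be >= 0")
  }
  p <- config$survey_missing_prob
  if (!is.numeric(p) || any(p < 0 | p > 1)) add("survey_missing_prob", "must lie in [0, 1]")
  if (length(v)) dplyr::bind_rows(v) else tibble::tibble(field = character(), message = character())
}

#' Run the full two-source comparison pipeline
#'
#' Generates an EHR-style and a survey-style cohort, writes raw records,
#' ascertains deficits under the package's rules, applies eligibility and
#' completeness filters, scores and categorises the frailty index,
#' harmonises the two deficit lists, and runs the comparison battery
#' (standardised prevalence, per-deficit adjusted ORs, K-S distribution
#' comparison, interaction linear model, distribution report).
#'
#' @param config an [run_config()].
#' @return an `fi_report_bundle` list: `persons` (pooled, with `cohort`
#'   membership flags), `results` per source, `summaries`, `mapping`,
#'   `relation_counts`, `std_prevalence`, `or_fit`, `ks`, `linear_fit`,
#'   `distribution`, and a `manifest` tibble of stage-by-stage row counts.
#' @export
run_frailty_pipeline <- function(config) {
  viol <- validate_run_config(config)
  if (nrow(viol)) {
    abort(paste0("invalid run configuration:\n",
                 paste0("- ", viol$field, ": ", viol$message, collapse = "\n")))
  }
  gen <- config$generator
  manifest <- list()
  log_stage <- function(stage, rows, note = "") {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(stage = stage,
                                                        rows = rows, note = note)
  }

  # -- generate ---------------------------------------------------------
  cfg_ehr <- cohort_config(config$n_ehr, "EHR",
                           prob_female = gen$ehr$prob_female,
                           age_band_weights = gen$ehr$age_band_weights,
                           index_date = config$index_date,
                           registration_years_range = gen$ehr$registration_years_range,
                           seed = derive_seed(config$seed, "population"))
  cfg_survey <- cohort_config(config$n_survey, "SURVEY",
                              prob_female = gen$survey$prob_female,
                              age_band_weights = gen$survey$age_band_weights,
                              index_date = config$index_date,
                              seed = derive_seed(config$seed, "population") + 1L)
  persons_ehr <- generate_population(cfg_ehr)
  persons_survey <- generate_population(cfg_survey)
  log_stage("generate_population", nrow(persons_ehr) + nrow(persons_survey))

  models_ehr <- deficit_models(gen, "ehr")
  models_survey <- deficit_models(gen, "survey")
  codelists <- toy_codelists(setdiff(models_ehr$deficit_name, "polypharmacy"))
  records <- generate_ehr_records(persons_ehr, models_ehr, codelists,
                                  index_date = config$index_date,
                                  seed = derive_seed(config$seed, "ehr_records"))
  log_stage("generate_ehr_records",
            nrow(records$coded_events) + nrow(records$prescriptions))
  survey_wide <- generate_survey_responses(
    persons_survey, models_survey,
    missingness = missingness_config(config$survey_missing_prob),
    seed = derive_seed(config$seed, "survey"))
  log_stage("generate_survey_responses", nrow(survey_wide))

  # -- ascertain --------------------------------------------------------
  elig_ehr <- apply_cohort_criteria(persons_ehr, config$index_date)
  elig_survey <- apply_cohort_criteria(persons_survey, config$index_date)
  log_stage("apply_cohort_criteria", nrow(elig_ehr) + nrow(elig_survey),
            paste0("excluded ", nrow(persons_ehr) - nrow(elig_ehr), " EHR, ",
                   nrow(persons_survey) - nrow(elig_survey), " survey"))
  ehr_matrix <- build_ehr_matrix(records$coded_events, records$prescriptions,
                                 codelists, elig_ehr$person_id,
                                 config$index_date)
  survey_matrix <- build_survey_matrix(
    survey_wide[survey_wide$person_id %in% elig_survey$person_id, ])
  filt <- filter_survey_completeness(survey_matrix,
                                     total_deficits = nrow(models_survey),
                                     max_missing = config$max_missing)
  survey_matrix <- filt$matrix
  log_stage("filter_survey_completeness", nrow(survey_matrix),
            paste0("excluded ", filt$n_excluded))

  # -- score ------------------------------------------------------------
  res_ehr <- compute_frailty_index(ehr_matrix, config$thresholds)
  res_survey <- compute_frailty_index(survey_matrix, config$thresholds)
  log_stage("compute_frailty_index", nrow(res_ehr) + nrow(res_survey))
  pooled_persons <- dplyr::bind_rows(
    elig_ehr[elig_ehr$person_id %in% res_ehr$person_id, ],
    elig_survey[elig_survey$person_id %in% res_survey$person_id, ]) |>
    dplyr::select(-"latent_u")
  summaries <- list(
    overall = dplyr::bind_rows(
      EHR = summarize_frailty(res_ehr), SURVEY = summarize_frailty(res_survey),
      .id = "source_label"),
    by_age = summarize_frailty(dplyr::bind_rows(res_ehr, res_survey),
                               pooled_persons, by = c("source", "age_band"))
  )

  # -- harmonise --------------------------------------------------------
  mapping <- load_deficit_mapping(config$mapping_path,
                                  ehr_deficits = setdiff(names(ehr_matrix), "person_id"),
                                  survey_deficits = setdiff(names(survey_matrix), "person_id"))
  paired <- select_comparable(mapping, ehr_matrix, survey_matrix,
                              elig_ehr, elig_survey)
  log_stage("select_comparable", nrow(paired))

  # -- compare ----------------------------------------------------------
  scheme <- standardization_scheme(pooled_persons)
  std_prev <- dplyr::bind_rows(
    standardized_prevalence_table(ehr_matrix, elig_ehr, scheme) |>
      dplyr::mutate(source = "EHR"),
    standardized_prevalence_table(survey_matrix, elig_survey, scheme) |>
      dplyr::mutate(source = "SURVEY"))
  or_fit <- fit_deficit_logistic(paired)
  ks <- ks_two_sample(res_ehr$score, res_survey$score)
  linear_fit <- fit_frailty_linear(dplyr::bind_rows(res_ehr, res_survey),
                                   pooled_persons)
  dist_report <- distribution_report(res_ehr, res_survey, elig_ehr, elig_survey,
                                     bins_ehr = nrow(models_ehr),
                                     bins_survey = nrow(models_survey))
  log_stage("comparison_battery", nrow(tidy(or_fit)))

  bundle <- structure(list(
    persons = pooled_persons,
    ehr_matrix = ehr_matrix, survey_matrix = survey_matrix,
    results = list(ehr = res_ehr, survey = res_survey),
    summaries = summaries,
    mapping = mapping, relation_counts = relation_counts(mapping),
    std_prevalence = std_prev, or_fit = or_fit, ks = ks,
    linear_fit = linear_fit, distribution = dist_report,
    n_survey_excluded = filt$n_excluded,
    manifest = dplyr::bind_rows(manifest),
    seed = config$seed
  ), class = "fi_report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config)
  bundle
}

#' @export
print.fi_report_bundle <- function(x, ...) {
  cat("Frailty comparison report bundle (seed ", x$seed, ")\n", sep = "")
  print(x$manifest)
  print(x$ks)
  invisible(x)
}

# report tables as CSV plus a JSON metadata sidecar
write_report_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  readr::write_csv(bundle$results$ehr, p("frailty_ehr.csv"))
  readr::write_csv(bundle$results$survey, p("frailty_survey.csv"))
  readr::write_csv(bundle$summaries$overall, p("summary_overall.csv"))
  readr::write_csv(bundle$std_prevalence, p("standardized_prevalence.csv"))
  readr::write_csv(tidy(bundle$or_fit), p("odds_ratios.csv"))
  readr::write_csv(tidy(bundle$linear_fit), p("linear_fit.csv"))
  readr::write_csv(bundle$distribution$histogram, p("histogram.csv"))
  readr::write_csv(bundle$distribution$ecdf, p("ecdf.csv"))
  readr::write_csv(bundle$distribution$quartiles_by_age, p("quartiles_by_age.csv"))
  readr::write_csv(bundle$manifest, p("manifest.csv"))
  meta <- list(seed = bundle$seed,
               index_date = as.character(config$index_date),
               thresholds = unclass(config$thresholds),
               n_ehr = config$n_ehr, n_survey = config$n_survey,
               n_survey_excluded = bundle$n_survey_excluded,
               quartile_convention = "linear interpolation (type 7)",
               multiple_testing = "none (per-deficit p-values)",
               ks = list(statistic = bundle$ks$statistic,
                         p_value = bundle$ks$p_value),
               package_version = as.character(utils::packageVersion("ficompare")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, p("metadata.json"), auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(yaml::as.yaml(meta), p("metadata.yaml"))
  }
  invisible(bundle)
}

#' Export cohort inputs as delimited text
#'
#' Writes the analysis-facing inputs of a generated cohort: persons (without
#' the generator-internal latent factor), coded events, prescriptions and
#' the survey wide table (missing cells as empty strings).
#'
#' @param dir output directory.
#' @param persons person tibble.
#' @param records optional `fi_ehr_records`.
#' @param survey_wide optional survey response table.
#' @return invisibly, the paths written.
#' @export
write_cohort_csvs <- function(dir, persons, records = NULL, survey_wide = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(df, f) {
    readr::write_csv(df, file.path(dir, f), na = "")
    paths <<- c(paths, file.path(dir, f))
  }
  w(dplyr::select(persons, -dplyr::any_of("latent_u")), "persons.csv")
  if (!is.null(records)) {
    w(records$coded_events, "coded_events.csv")
    w(records$prescriptions, "prescriptions.csv")
  }
  if (!is.null(survey_wide)) {
    sw <- survey_wide
    attributes(sw)[c("truth", "fi_source")] <- NULL
    w(sw, "survey_wide.csv")
  }
  invisible(paths)
}
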