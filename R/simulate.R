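#' Generate a synthetic population of older adults
#'
#' Draws `n_persons` individuals aged 65+ with ages sampled uniformly (as
#' integers) within 5-year bands weighted by `age_band_weights` (the 90+ band
#' is uniform on 90-99), sex from `prob_female`, and - for EHR cohorts - a
#' registration start date placing each person inside the configured
#' registration window before the index date. Every person also carries a
#' standard-normal latent factor `latent_u`, the shared liability that
#' induces positive correlation between deficits; it is generator-internal
#' and is dropped when cohorts are exported as analysis inputs.
#'
#' @param config an [cohort_config()] object.
#' @return tibble of persons: `person_id`, `age`, `sex` (0 = male,
#'   1 = female), `source` (0 = survey, 1 = EHR), `registration_start`
#'   (`NA` for survey cohorts), `latent_u`.
#' @export
generate_population <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_persons)
  is_ehr <- config$source_label == "EHR"
  prefix <- if (is_ehr) "E" else "S"
  band_lo <- c(65L, 70L, 75L, 80L, 85L, 90L)
  band_hi <- c(69L, 74L, 79L, 84L, 89L, 99L)
  with_seed(config$seed, {
    band <- sample.int(6L, n, replace = TRUE,
                       prob = config$age_band_weights[AGE_BANDS])
    age <- band_lo[band] +
      floor(runif(n) * (band_hi[band] - band_lo[band] + 1L))
    sex <- rbinom(n, 1L, config$prob_female)
    u <- rnorm(n)
    reg <- as.Date(rep(NA, n))
    if (is_ehr) {
      yrs <- runif(n, config$registration_years_range[1],
                   config$registration_years_range[2])
      reg <- config$index_date - round(yrs * 365.25)
    }
    tibble::tibble(
      person_id = sprintf("%s%06d", prefix, seq_len(n)),
      age = as.integer(age),
      sex = as.integer(sex),
      source = as.integer(is_ehr),
      registration_start = reg,
      latent_u = u
    )
  })
}

#' Per-person deficit presence probability
#'
#' Evaluates the logistic prevalence model
#' logit(p) = beta0 + beta_age (age - 65) + beta_sex sex +
#' beta_source source + lambda_load u for one or more deficits crossed with
#' one or more persons.
#'
#' @param model one- or multi-row deficit model table (see
#'   [deficit_models()]).
#' @param person one- or multi-row person table with `age`, `sex`, `source`
#'   and `latent_u` columns.
#' @return if both inputs have a single row, a probability; otherwise a
#'   persons x deficits matrix of probabilities, dimnames set.
#' @export
deficit_probability <- function(model, person) {
  validate_deficit_models(model)
  req <- c("age", "sex", "source", "latent_u")
  miss <- setdiff(req, names(person))
  if (length(miss)) abort(paste0("person table lacks columns: ",
                                 paste(miss, collapse = ", ")))
  eta <- outer(rep(1, nrow(person)), model$beta0) +
    outer(person$age - 65, model$beta_age) +
    outer(person$sex, model$beta_sex) +
    outer(person$source, model$beta_source) +
    outer(person$latent_u, model$lambda_load)
  p <- plogis(eta)
  if (nrow(person) == 1 && nrow(model) == 1) return(as.numeric(p))
  dimnames(p) <- list(person$person_id, model$deficit_name)
  p
}

# Bernoulli presence draws for every person x deficit pair; the ground truth
# that ascertainment must recover.
draw_deficit_presence <- function(persons, models, seed) {
  p <- deficit_probability(models, persons)
  p <- matrix(p, nrow = nrow(persons), ncol = nrow(models),
              dimnames = list(persons$person_id, models$deficit_name))
  with_seed(seed, {
    draws <- matrix(rbinom(length(p), 1L, as.vector(p)), nrow = nrow(p),
                    dimnames = dimnames(p))
    dplyr::bind_cols(tibble::tibble(person_id = persons$person_id),
                     tibble::as_tibble(draws))
  })
}

#' Generate deterministic toy codelists
#'
#' Builds a flat codelist table assigning each deficit a small set of
#' synthetic clinical codes (e.g. `C03_01`). These stand in for real
#' primary-care codelists, which are licensed artefacts outside this
#' package's scope; code matching downstream is exact string equality.
#'
#' @param deficit_names character vector of deficit names.
#' @param codes_per_deficit codes generated per deficit.
#' @return tibble with columns `deficit_name`, `code`.
#' @export
toy_codelists <- function(deficit_names, codes_per_deficit = 3) {
  tidyr::crossing(i = seq_along(deficit_names), j = seq_len(codes_per_deficit)) |>
    dplyr::mutate(deficit_name = deficit_names[.data$i],
                  code = sprintf("C%02d_%02d", .data$i, .data$j)) |>
    dplyr::select("deficit_name", "code")
}

#' Ascertainment rule for the polypharmacy deficit
#'
#' Polypharmacy is present when prescriptions issued in the window
#' `[index_date, index_date + window_days)` span at least `min_paragraphs`
#' distinct British National Formulary (chapter, paragraph) pairs, counting
#' only chapters inside `chapter_range` and excluding listed non-medication
#' paragraphs.
#'
#' @param window_days length of the half-open ascertainment window in days.
#' @param min_paragraphs minimum number of distinct BNF paragraphs.
#' @param chapter_range inclusive integer range of medication chapters.
#' @param excluded_paragraphs character keys `"chapter_paragraph"` (e.g.
#'   `"9_4"`) treated as non-medications.
#' @param missing_bnf how to treat prescription rows without a BNF
#'   paragraph: `"drop"` discards them (count reported via message);
#'   `"count_distinct"` treats each such row as its own paragraph, an upper
#'   bound.
#' @return an `fi_polypharmacy_spec` list.
#' @export
polypharmacy_spec <- function(window_days = 84L, min_paragraphs = 5L,
                              chapter_range = c(1L, 15L),
                              excluded_paragraphs = character(),
                              missing_bnf = c("drop", "count_distinct")) {
  missing_bnf <- match.arg(missing_bnf)
  if (window_days <= 0) abort("window_days must be > 0")
  if (min_paragraphs < 1) abort("min_paragraphs must be >= 1")
  structure(list(window_days = as.integer(window_days),
                 min_paragraphs = as.integer(min_paragraphs),
                 chapter_range = as.integer(chapter_range),
                 excluded_paragraphs = as.character(excluded_paragraphs),
                 missing_bnf = missing_bnf),
            class = "fi_polypharmacy_spec")
}

#' Generate coded events and prescriptions for an EHR-style cohort
#'
#' For every person drawn as having a coded deficit, at least one event with
#' a code from that deficit's codelist is written, dated strictly before the
#' index date (uniform over the 9 preceding years). For persons drawn as
#' having polypharmacy, prescriptions spanning at least `min_paragraphs`
#' distinct BNF paragraphs (chapters 1-15) are issued inside the 84-day
#' window from the index date; persons drawn negative receive fewer distinct
#' paragraphs. Distractor codes absent from every codelist, and distractor
#' prescriptions outside the medication chapters, are interleaved so that
#' ascertainment cannot succeed by accident.
#'
#' @param persons EHR persons from [generate_population()] (`source == 1`).
#' @param models deficit model table including a `polypharmacy` row.
#' @param codelists flat codelist tibble (`deficit_name`, `code`) covering
#'   every non-polypharmacy deficit in `models`.
#' @param index_date ascertainment date.
#' @param pp_spec a [polypharmacy_spec()].
#' @param seed integer seed.
#' @param distractor_rate expected distractor events per person.
#' @return an `fi_ehr_records` list: `coded_events` (`person_id`, `code`,
#'   `event_date`), `prescriptions` (`person_id`, `bnf_chapter`,
#'   `bnf_paragraph`, `issue_date`) and `truth`, the drawn person x deficit
#'   presence table.
#' @export
generate_ehr_records <- function(persons, models, codelists,
                                 index_date = as.Date("2018-01-01"),
                                 pp_spec = polypharmacy_spec(),
                                 seed = 1L, distractor_rate = 0.3) {
  if (!all(persons$source == 1L)) abort("generate_ehr_records expects an EHR cohort (source == 1)")
  index_date <- as.Date(index_date)
  coded_names <- setdiff(models$deficit_name, "polypharmacy")
  missing_cl <- setdiff(coded_names, unique(codelists$deficit_name))
  if (length(missing_cl)) {
    abort(paste0("no codelist for deficit(s): ", paste(missing_cl, collapse = ", ")))
  }
  truth <- draw_deficit_presence(persons, models, seed)
  tmat <- as.matrix(truth[coded_names])
  code_pool <- split(stringr::str_trim(codelists$code), codelists$deficit_name)

  with_seed(derive_seed(seed, "ehr_records"), {
    # coded events for drawn-present deficits
    idx <- which(tmat == 1L, arr.ind = TRUE)
    ev <- NULL
    if (nrow(idx)) {
      n_events <- 1L + rpois(nrow(idx), 0.5)
      who <- rep(truth$person_id[idx[, 1]], n_events)
      def <- rep(coded_names[idx[, 2]], n_events)
      code <- vapply(def, function(d) sample(code_pool[[d]], 1L), character(1))
      ev <- tibble::tibble(
        person_id = who, code = unname(code),
        event_date = index_date - 1L - floor(runif(length(who)) * (9 * 365.25 - 1))
      )
    }
    # distractor codes matching no codelist, some dated after index
    n_dis <- rpois(1L, distractor_rate * nrow(persons))
    if (n_dis > 0) {
      dis <- tibble::tibble(
        person_id = sample(persons$person_id, n_dis, replace = TRUE),
        code = sprintf("ZZ_%03d", sample.int(999L, n_dis, replace = TRUE)),
        event_date = index_date + sample(c(-30L, -400L, 5L, 40L), n_dis, replace = TRUE)
      )
      ev <- dplyr::bind_rows(ev, dis)
    }
    coded_events <- if (is.null(ev)) {
      tibble::tibble(person_id = character(), code = character(),
                     event_date = as.Date(character()))
    } else dplyr::arrange(ev, .data$person_id, .data$event_date)

    # prescriptions: distinct BNF paragraphs in/out of the window
    pp_present <- if ("polypharmacy" %in% names(truth)) truth$polypharmacy else rep(0L, nrow(persons))
    chap_grid <- tidyr::crossing(bnf_chapter = seq(pp_spec$chapter_range[1],
                                                   pp_spec$chapter_range[2]),
                                 bnf_paragraph = 1:8)
    key <- paste(chap_grid$bnf_chapter, chap_grid$bnf_paragraph, sep = "_")
    chap_grid <- chap_grid[!key %in% pp_spec$excluded_paragraphs, ]
    n_para <- ifelse(pp_present == 1L,
                     pp_spec$min_paragraphs + rpois(nrow(persons), 1),
                     pmin(rpois(nrow(persons), 1.2), pp_spec$min_paragraphs - 1L))
    rows <- lapply(seq_len(nrow(persons)), function(i) {
      k <- n_para[i]
      if (k <= 0) return(NULL)
      pick <- chap_grid[sample.int(nrow(chap_grid), k), ]
      pick$person_id <- persons$person_id[i]
      pick$issue_date <- index_date + floor(runif(k) * pp_spec$window_days)
      pick
    })
    rx <- dplyr::bind_rows(rows)
    # distractors: chapter outside 1-15 in window, and in-chapter but outside window
    n_rx_dis <- rpois(1L, distractor_rate * nrow(persons))
    if (n_rx_dis > 0) {
      rx <- dplyr::bind_rows(rx, tibble::tibble(
        bnf_chapter = sample(c(20L, 21L, 22L, 23L), n_rx_dis, replace = TRUE),
        bnf_paragraph = sample.int(8L, n_rx_dis, replace = TRUE),
        person_id = sample(persons$person_id, n_rx_dis, replace = TRUE),
        issue_date = index_date + sample(c(2L, 10L, pp_spec$window_days + 30L, -20L),
                                         n_rx_dis, replace = TRUE)
      ))
    }
    prescriptions <- if (is.null(rx) || !nrow(rx)) {
      tibble::tibble(person_id = character(), bnf_chapter = integer(),
                     bnf_paragraph = integer(), issue_date = as.Date(character()))
    } else {
      tibble::as_tibble(rx[c("person_id", "bnf_chapter", "bnf_paragraph", "issue_date")]) |>
        dplyr::arrange(.data$person_id, .data$issue_date)
    }
    structure(list(coded_events = coded_events, prescriptions = prescriptions,
                   truth = truth),
              class = "fi_ehr_records")
  })
}

#' Generate survey-style deficit responses
#'
#' Draws deficit presence for a survey cohort from the logistic prevalence
#' models and then blanks cells completely at random per the missingness
#' configuration. Responses reflect only the current draw - there is no
#' carry-forward channel.
#'
#' @param persons survey persons from [generate_population()]
#'   (`source == 0`).
#' @param models survey deficit model table.
#' @param missingness a [missingness_config()].
#' @param seed integer seed.
#' @return wide tibble `person_id` x deficit with cells in {0, 1, NA}; the
#'   drawn (pre-missingness) presence table is attached as attribute
#'   `"truth"` (see [deficit_truth()]).
#' @export
generate_survey_responses <- function(persons, models,
                                      missingness = missingness_config(0),
                                      seed = 1L) {
  if (!all(persons$source == 0L)) abort("generate_survey_responses expects a survey cohort (source == 0)")
  truth <- draw_deficit_presence(persons, models, seed)
  p_miss <- missingness$per_deficit_missing_prob
  if (length(p_miss) == 1L) {
    p_miss <- setNames(rep(p_miss, nrow(models)), models$deficit_name)
  }
  miss_named <- setdiff(models$deficit_name, names(p_miss))
  if (length(miss_named)) {
    abort(paste0("missingness probabilities lack deficit(s): ",
                 paste(miss_named, collapse = ", ")))
  }
  out <- truth
  with_seed(derive_seed(seed, "survey"), {
    for (d in models$deficit_name) {
      gone <- runif(nrow(out)) < p_miss[[d]]
      out[[d]][gone] <- NA_integer_
    }
  })
  attr(out, "truth") <- truth
  attr(out, "fi_source") <- "SURVEY"
  out
}

#' Ground-truth presence draws behind generated records
#'
#' @param x an `fi_ehr_records` object or a survey response table.
#' @return tibble of drawn presence flags (person x deficit).
#' @export
deficit_truth <- function(x) {
  if (inherits(x, "fi_ehr_records")) return(x$truth)
  t <- attr(x, "truth")
  if (is.null(t)) abort("object carries no generator ground truth")
  t
}
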