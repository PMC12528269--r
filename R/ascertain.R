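#' Apply cohort eligibility criteria
#'
#' Retains persons aged at least `min_age` at the index date and - for EHR
#' persons only - with at least `min_registration_years` of registration
#' before it (both thresholds inclusive). Survey persons are exempt from the
#' registration criterion.
#'
#' @param persons person tibble with `age`, `source` and (for EHR rows)
#'   `registration_start`.
#' @param index_date ascertainment date.
#' @param min_age minimum age in whole years.
#' @param min_registration_years minimum completed years of registration.
#' @return the eligible subset of `persons`, in the original order.
#' @export
apply_cohort_criteria <- function(persons, index_date,
                                  min_age = 65, min_registration_years = 9) {
  index_date <- as.Date(index_date)
  ehr <- persons$source == 1L
  if (any(ehr & is.na(persons$registration_start))) {
    bad <- persons$person_id[ehr & is.na(persons$registration_start)]
    abort(paste0("EHR person(s) missing registration_start: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  keep_age <- persons$age >= min_age
  keep_reg <- !ehr |
    (add_years(persons$registration_start, min_registration_years) <= index_date)
  persons[keep_age & keep_reg, , drop = FALSE]
}

#' Read a flat codelist file
#'
#' @param path CSV with columns `deficit_name`, `code`; code strings are
#'   whitespace-trimmed on read and matched exactly (case-sensitive)
#'   thereafter.
#' @return tibble (`deficit_name`, `code`).
#' @export
read_codelists <- function(path) {
  cl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("deficit_name", "code") %in% names(cl))) {
    abort("codelist file must have columns deficit_name, code")
  }
  cl$code <- stringr::str_trim(cl$code)
  empty <- cl |> dplyr::count(.data$deficit_name) |> dplyr::filter(.data$n == 0)
  if (nrow(empty)) abort("codelists must be non-empty")
  cl
}

#' Ascertain one coded deficit
#'
#' A deficit is present (1) for a person with at least one coded event whose
#' code belongs to the deficit's codelist and whose date is strictly before
#' the index date; otherwise absent (0) - in routine records, not recorded
#' means absent.
#'
#' @param coded_events tibble (`person_id`, `code`, `event_date`).
#' @param codes character vector, the deficit's codelist.
#' @param index_date ascertainment date.
#' @param person_ids the persons to score (absences are emitted for persons
#'   with no events).
#' @return tibble (`person_id`, `present`), one row per `person_ids` entry.
#' @export
ascertain_coded_deficit <- function(coded_events, codes, index_date, person_ids) {
  index_date <- as.Date(index_date)
  dates <- as.Date(coded_events$event_date)
  if (anyNA(dates) || anyNA(coded_events$event_date)) {
    abort(paste0("unparseable event_date at row(s): ",
                 paste(utils::head(which(is.na(dates)), 5), collapse = ", ")))
  }
  hit <- coded_events$person_id[
    stringr::str_trim(coded_events$code) %in% stringr::str_trim(codes) &
      dates < index_date]
  tibble::tibble(person_id = person_ids,
                 present = as.integer(person_ids %in% hit))
}

#' Ascertain the polypharmacy deficit from prescriptions
#'
#' Counts, per person, the distinct BNF (chapter, paragraph) pairs among
#' prescriptions issued in the half-open window
#' `[index_date, index_date + window_days)`, restricted to the medication
#' chapters and excluding configured non-medication paragraphs; flags 1 when
#' the count reaches `min_paragraphs`.
#'
#' @param prescriptions tibble (`person_id`, `bnf_chapter`, `bnf_paragraph`,
#'   `issue_date`).
#' @param index_date window start (the baseline date).
#' @param spec a [polypharmacy_spec()].
#' @param person_ids persons to score.
#' @return tibble (`person_id`, `present`).
#' @export
ascertain_polypharmacy <- function(prescriptions, index_date,
                                   spec = polypharmacy_spec(), person_ids) {
  index_date <- as.Date(index_date)
  rx <- prescriptions
  dates <- as.Date(rx$issue_date)
  if (anyNA(dates) && any(is.na(dates) != is.na(rx$issue_date))) {
    abort("unparseable issue_date in prescriptions")
  }
  miss <- is.na(rx$bnf_paragraph) | is.na(rx$bnf_chapter)
  if (any(miss)) {
    inform(paste0(sum(miss), " prescription row(s) without a BNF paragraph (",
                  spec$missing_bnf, ")"))
    if (spec$missing_bnf == "drop") {
      rx <- rx[!miss, ]
      dates <- dates[!miss]
    } else {
      # upper bound: each unresolved row counts as its own paragraph
      rx$bnf_chapter[miss] <- spec$chapter_range[1]
      rx$bnf_paragraph[miss] <- -seq_len(sum(miss))
    }
  }
  in_window <- dates >= index_date & dates < index_date + spec$window_days
  in_chapter <- rx$bnf_chapter >= spec$chapter_range[1] &
    rx$bnf_chapter <= spec$chapter_range[2]
  key <- paste(rx$bnf_chapter, rx$bnf_paragraph, sep = "_")
  ok <- in_window & in_chapter & !(key %in% spec$excluded_paragraphs)
  counts <- tibble::tibble(person_id = rx$person_id[ok], key = key[ok]) |>
    dplyr::distinct() |>
    dplyr::count(.data$person_id)
  flagged <- counts$person_id[counts$n >= spec$min_paragraphs]
  tibble::tibble(person_id = person_ids,
                 present = as.integer(person_ids %in% flagged))
}

#' Build the EHR deficit matrix
#'
#' Ascertains every coded deficit plus polypharmacy for an EHR cohort,
#' yielding a complete (no missing cells) person x deficit 0/1 matrix.
#'
#' @param coded_events,prescriptions record tibbles (see
#'   [generate_ehr_records()] for layouts).
#' @param codelists flat codelist tibble.
#' @param person_ids persons to score.
#' @param index_date ascertainment date.
#' @param pp_spec a [polypharmacy_spec()]; set `NULL` to skip the
#'   polypharmacy column.
#' @return wide tibble `person_id` x deficit, tagged with source `"EHR"`.
#' @export
build_ehr_matrix <- function(coded_events, prescriptions, codelists, person_ids,
                             index_date, pp_spec = polypharmacy_spec()) {
  cols <- lapply(split(codelists$code, codelists$deficit_name), function(codes) {
    ascertain_coded_deficit(coded_events, codes, index_date, person_ids)$present
  })
  out <- dplyr::bind_cols(tibble::tibble(person_id = person_ids),
                          tibble::as_tibble(cols[sort(names(cols))]))
  if (!is.null(pp_spec)) {
    out$polypharmacy <- ascertain_polypharmacy(prescriptions, index_date,
                                               pp_spec, person_ids)$present
  }
  attr(out, "fi_source") <- "EHR"
  out
}

#' Validate a survey wide table as a deficit matrix
#'
#' Survey items pass through unchanged: present (1), absent (0) or missing
#' (`NA`). Missing responses stay missing - they are never recoded to
#' absent, in contrast with the EHR rule - and no information is carried
#' forward from earlier waves.
#'
#' @param survey_wide tibble with `person_id` plus one column per deficit.
#' @return the validated matrix, tagged with source `"SURVEY"`.
#' @export
build_survey_matrix <- function(survey_wide) {
  cells <- as.matrix(survey_wide[setdiff(names(survey_wide), "person_id")])
  bad <- !(is.na(cells) | cells %in% c(0, 1))
  if (any(bad)) {
    abort(paste0("survey cells must be 0, 1 or missing; offending value(s): ",
                 paste(utils::head(unique(cells[bad]), 3), collapse = ", ")))
  }
  if (anyDuplicated(survey_wide$person_id)) abort("duplicate person_id in survey table")
  out <- tibble::as_tibble(survey_wide)
  attr(out, "truth") <- NULL
  attr(out, "fi_source") <- "SURVEY"
  out
}

#' Exclude survey rows with excessive item missingness
#'
#' Rows missing more than `max_missing` of the `total_deficits` items are
#' excluded (equivalently, retained rows have at least
#' `total_deficits - max_missing` assessed items).
#'
#' @param matrix survey deficit matrix from [build_survey_matrix()].
#' @param total_deficits expected number of deficit columns.
#' @param max_missing largest tolerated missing-item count.
#' @return list with `matrix` (retained rows), `n_excluded` and
#'   `excluded_ids`.
#' @export
filter_survey_completeness <- function(matrix, total_deficits = 58,
                                       max_missing = 20) {
  cols <- setdiff(names(matrix), "person_id")
  if (length(cols) != total_deficits) {
    warn(paste0("matrix has ", length(cols), " deficit columns, expected ",
                total_deficits))
  }
  n_missing <- rowSums(is.na(as.matrix(matrix[cols])))
  keep <- n_missing <= max_missing
  out <- matrix[keep, , drop = FALSE]
  attr(out, "fi_source") <- attr(matrix, "fi_source")
  list(matrix = out,
       n_excluded = sum(!keep),
       excluded_ids = matrix$person_id[!keep])
}
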