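#' Load and validate a cross-source deficit mapping
#'
#' The mapping relates deficits of the EHR index to deficits of the survey
#' index through three relation types: `one_to_one` (directly comparable
#' pairs), `one_to_many` (a broader deficit on one side matched by several
#' finer items on the other) and `one_to_none` (a deficit with no
#' counterpart). An optional `note` column may mark rows; the value
#' `"overlap"` exempts that deficit from the partition check (for items
#' known to overlap another deficit's capture).
#'
#' @param path CSV with columns `ehr_deficit`, `survey_deficit`, `relation`
#'   and optionally `note`.
#' @param ehr_deficits,survey_deficits optional deficit universes; when
#'   given, the mapping is validated as an exact partition of each.
#' @return a validated `deficit_mapping` tibble.
#' @export
load_deficit_mapping <- function(path, ehr_deficits = NULL, survey_deficits = NULL) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_deficit_mapping(m, ehr_deficits, survey_deficits)
}

#' @rdname load_deficit_mapping
#' @param mapping a mapping data frame to validate.
#' @export
validate_deficit_mapping <- function(mapping, ehr_deficits = NULL,
                                     survey_deficits = NULL) {
  m <- tibble::as_tibble(mapping)
  if (!all(c("ehr_deficit", "survey_deficit", "relation") %in% names(m))) {
    abort("mapping needs columns ehr_deficit, survey_deficit, relation")
  }
  if (!"note" %in% names(m)) m$note <- NA_character_
  m$ehr_deficit[m$ehr_deficit %in% c("", NA)] <- NA_character_
  m$survey_deficit[m$survey_deficit %in% c("", NA)] <- NA_character_
  errs <- character()
  row_of <- function(i) paste0("row ", i, ": ")

  bad_rel <- which(!m$relation %in% c("one_to_one", "one_to_many", "one_to_none"))
  for (i in bad_rel) errs <- c(errs, paste0(row_of(i), "unknown relation '", m$relation[i], "'"))

  both_empty <- which(is.na(m$ehr_deficit) & is.na(m$survey_deficit))
  for (i in both_empty) errs <- c(errs, paste0(row_of(i), "both sides empty"))

  oto <- m$relation == "one_to_one"
  bad_oto <- which(oto & (is.na(m$ehr_deficit) | is.na(m$survey_deficit)))
  for (i in bad_oto) errs <- c(errs, paste0(row_of(i), "one_to_one must name both sides"))

  otn <- m$relation == "one_to_none"
  bad_otn <- which(otn & !xor(is.na(m$ehr_deficit), is.na(m$survey_deficit)))
  for (i in bad_otn) errs <- c(errs, paste0(row_of(i), "one_to_none must name exactly one side"))

  # no deficit may appear under two relations (overlap-annotated rows exempt)
  chk <- m[is.na(m$note) | m$note != "overlap", ]
  for (side in c("ehr_deficit", "survey_deficit")) {
    rel_by <- chk[!is.na(chk[[side]]), c(side, "relation")] |> dplyr::distinct()
    dup <- rel_by[[side]][duplicated(rel_by[[side]])]
    for (d in unique(dup)) {
      errs <- c(errs, paste0("deficit '", d, "' (", side, ") appears in multiple relations"))
    }
    dup_one <- chk[[side]][!is.na(chk[[side]]) & chk$relation %in% c("one_to_one", "one_to_none")]
    for (d in unique(dup_one[duplicated(dup_one)])) {
      errs <- c(errs, paste0("deficit '", d, "' (", side, ") duplicated within relation"))
    }
  }

  part_err <- function(universe, side) {
    mapped <- unique(chk[[side]][!is.na(chk[[side]])])
    c(
      if (length(setdiff(universe, mapped)))
        paste0(side, " not covered by mapping: ",
               paste(setdiff(universe, mapped), collapse = ", ")),
      if (length(setdiff(mapped, universe)))
        paste0(side, " unknown to matrix: ",
               paste(setdiff(mapped, universe), collapse = ", "))
    )
  }
  if (!is.null(ehr_deficits)) errs <- c(errs, part_err(ehr_deficits, "ehr_deficit"))
  if (!is.null(survey_deficits)) errs <- c(errs, part_err(survey_deficits, "survey_deficit"))

  if (length(errs)) {
    abort(paste0("invalid deficit mapping:\n", paste0("- ", errs, collapse = "\n")))
  }
  class(m) <- c("deficit_mapping", class(m))
  m
}

#' Relation counts of a deficit mapping
#'
#' @param mapping a validated `deficit_mapping`.
#' @return tibble with one row per metric: number of one-to-one pairs,
#'   distinct EHR and survey deficits involved in one-to-many groups, and
#'   the per-side one-to-none counts.
#' @export
relation_counts <- function(mapping) {
  otm <- mapping[mapping$relation == "one_to_many", ]
  otn <- mapping[mapping$relation == "one_to_none", ]
  tibble::tibble(
    metric = c("one_to_one_pairs", "ehr_in_one_to_many", "survey_in_one_to_many",
               "ehr_only", "survey_only"),
    count = c(sum(mapping$relation == "one_to_one"),
              dplyr::n_distinct(otm$ehr_deficit[!is.na(otm$ehr_deficit)]),
              dplyr::n_distinct(otm$survey_deficit[!is.na(otm$survey_deficit)]),
              sum(!is.na(otn$ehr_deficit)),
              sum(!is.na(otn$survey_deficit)))
  )
}

#' Stack directly comparable deficits into a paired long table
#'
#' For each one-to-one deficit pair, emits one row per person per source
#' carrying the presence value and the modelling covariates; survey cells
#' that are missing for a pair are dropped from that pair only.
#'
#' @param mapping a validated `deficit_mapping`.
#' @param ehr_matrix,survey_matrix deficit matrices containing every mapped
#'   one-to-one column.
#' @param ehr_persons,survey_persons person tables supplying `age` and `sex`.
#' @return long tibble (`person_id`, `deficit_pair`, `present`, `age`,
#'   `sex`, `source`); `deficit_pair` is labelled by the EHR-side name.
#' @export
select_comparable <- function(mapping, ehr_matrix, survey_matrix,
                              ehr_persons, survey_persons) {
  pairs <- mapping[mapping$relation == "one_to_one", c("ehr_deficit", "survey_deficit")]
  if (!nrow(pairs)) {
    return(tibble::tibble(person_id = character(), deficit_pair = character(),
                          present = integer(), age = integer(), sex = integer(),
                          source = integer()))
  }
  miss_e <- setdiff(pairs$ehr_deficit, names(ehr_matrix))
  miss_s <- setdiff(pairs$survey_deficit, names(survey_matrix))
  if (length(c(miss_e, miss_s))) {
    abort(paste0("mapped deficit(s) absent from matrix: ",
                 paste(c(miss_e, miss_s), collapse = ", ")))
  }
  one_side <- function(matrix, persons, cols, src) {
    matrix[c("person_id", cols)] |>
      tidyr::pivot_longer(-"person_id", names_to = "deficit",
                          values_to = "present") |>
      dplyr::filter(!is.na(.data$present)) |>
      dplyr::left_join(persons[c("person_id", "age", "sex")], by = "person_id") |>
      dplyr::mutate(source = src)
  }
  long_e <- one_side(ehr_matrix, ehr_persons, unique(pairs$ehr_deficit), 1L)
  long_s <- one_side(survey_matrix, survey_persons, unique(pairs$survey_deficit), 0L) |>
    dplyr::left_join(setNames(pairs, c("pair_label", "deficit")), by = "deficit") |>
    dplyr::mutate(deficit = .data$pair_label) |>
    dplyr::select(-"pair_label")
  dplyr::bind_rows(long_e, long_s) |>
    dplyr::rename(deficit_pair = "deficit") |>
    dplyr::mutate(present = as.integer(.data$present)) |>
    dplyr::select("person_id", "deficit_pair", "present", "age", "sex", "source")
}
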