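#' Frailty category cut points
#'
#' The conventional electronic-frailty-index cut points: scores below
#' `mild_at` are fit; `[mild_at, moderate_at)` mild; `[moderate_at,
#' severe_at)` moderate; `severe_at` and above severe.
#'
#' @param mild_at,moderate_at,severe_at strictly increasing thresholds in
#'   (0, 1).
#' @return an `fi_thresholds` list.
#' @export
frailty_thresholds <- function(mild_at = 0.12, moderate_at = 0.24,
                               severe_at = 0.36) {
  t <- c(mild_at, moderate_at, severe_at)
  if (any(diff(t) <= 0) || any(t <= 0) || any(t >= 1)) {
    abort("thresholds must be strictly increasing and inside (0, 1)")
  }
  structure(list(mild_at = mild_at, moderate_at = moderate_at,
                 severe_at = severe_at), class = "fi_thresholds")
}

FRAILTY_LEVELS <- c("fit", "mild", "moderate", "severe")

#' Categorise frailty scores
#'
#' @param score numeric scores in `[0, 1]`.
#' @param thresholds a [frailty_thresholds()].
#' @return factor with levels fit, mild, moderate, severe. Each interval is
#'   closed on the left: a score exactly at a cut point takes the higher
#'   category.
#' @export
categorize_frailty <- function(score, thresholds = frailty_thresholds()) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("frailty scores must lie in [0, 1]")
  }
  cut(score,
      breaks = c(-Inf, thresholds$mild_at, thresholds$moderate_at,
                 thresholds$severe_at, Inf),
      labels = FRAILTY_LEVELS, right = FALSE)
}

#' Compute the cumulative-deficit frailty index
#'
#' The frailty index is the proportion of measured deficits present:
#' `n_present / n_assessed`, where `n_assessed` counts the person's
#' non-missing deficits (the default) or, optionally, the full deficit list.
#'
#' @param matrix a person x deficit matrix tibble with cells in {0, 1, NA}.
#' @param thresholds a [frailty_thresholds()].
#' @param denominator `"assessed"` divides by the person's non-missing item
#'   count (standard cumulative-deficit practice under item missingness);
#'   `"total"` divides by the full column count.
#' @return tibble (`person_id`, `n_present`, `n_assessed`, `score`,
#'   `category`).
#' @export
compute_frailty_index <- function(matrix, thresholds = frailty_thresholds(),
                                  denominator = c("assessed", "total")) {
  denominator <- match.arg(denominator)
  cols <- setdiff(names(matrix), "person_id")
  cells <- as.matrix(matrix[cols])
  n_present <- rowSums(cells == 1, na.rm = TRUE)
  n_assessed <- rowSums(!is.na(cells))
  if (any(n_assessed == 0)) {
    abort(paste0("person(s) with no assessed deficits: ",
                 paste(utils::head(matrix$person_id[n_assessed == 0], 5),
                       collapse = ", ")))
  }
  denom <- if (denominator == "assessed") n_assessed else length(cols)
  score <- n_present / denom
  tibble::tibble(person_id = matrix$person_id,
                 n_present = as.integer(n_present),
                 n_assessed = as.integer(n_assessed),
                 score = score,
                 category = categorize_frailty(score, thresholds))
}

#' Summarise frailty results, optionally by group
#'
#' Reports, per group, the cohort size, mean, sample (n - 1) standard
#' deviation, median and quartiles (linear-interpolation convention) of the
#' score, the four category counts with percentages, and the combined
#' percentage with any frailty (mild or worse).
#'
#' @param results output of [compute_frailty_index()].
#' @param persons optional person table joined on `person_id`; required when
#'   grouping.
#' @param by `NULL` for a whole-cohort summary, or any of `"age_band"`,
#'   `"sex"`, `"source"`.
#' @return tibble with one row per group.
#' @export
summarize_frailty <- function(results, persons = NULL, by = NULL) {
  df <- results
  if (!is.null(persons)) {
    joinable <- intersect(c("age", "sex", "source"), names(persons))
    df <- dplyr::left_join(df, persons[c("person_id", joinable)], by = "person_id")
  }
  if (!is.null(by)) {
    bad <- setdiff(by, c("age_band", "sex", "source"))
    if (length(bad)) abort(paste0("cannot group by: ", paste(bad, collapse = ", ")))
    if ("age_band" %in% by) df$age_band <- age_band(df$age)
    df <- dplyr::group_by(df, dplyr::across(dplyr::all_of(by)), .drop = FALSE)
  }
  out <- dplyr::summarise(
    df,
    n = dplyr::n(),
    mean = if (dplyr::n() > 0) mean(.data$score) else NA_real_,
    sd = if (dplyr::n() > 1) sd(.data$score) else 0,
    median = if (dplyr::n() > 0) median(.data$score) else NA_real_,
    q1 = if (dplyr::n() > 0) quantile(.data$score, 0.25, names = FALSE) else NA_real_,
    q3 = if (dplyr::n() > 0) quantile(.data$score, 0.75, names = FALSE) else NA_real_,
    n_fit = sum(.data$category == "fit"),
    n_mild = sum(.data$category == "mild"),
    n_moderate = sum(.data$category == "moderate"),
    n_severe = sum(.data$category == "severe"),
    .groups = "drop"
  )
  out <- out |>
    dplyr::mutate(
      pct_fit = 100 * .data$n_fit / .data$n,
      pct_mild = 100 * .data$n_mild / .data$n,
      pct_moderate = 100 * .data$n_moderate / .data$n,
      pct_severe = 100 * .data$n_severe / .data$n,
      pct_any_frailty = 100 * (.data$n - .data$n_fit) / .data$n
    )
  # empty groups (possible with factor grouping) carry null statistics
  stat_cols <- c("mean", "sd", "median", "q1", "q3", "pct_fit", "pct_mild",
                 "pct_moderate", "pct_severe", "pct_any_frailty")
  out[out$n == 0, stat_cols] <- NA_real_
  out
}
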