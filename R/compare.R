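#' Build a direct-standardisation scheme
#'
#' Strata are the six 5-year age bands crossed with sex; the reference
#' weights default to the stratum distribution of the supplied (typically
#' pooled two-source) population, so both sources are treated symmetrically.
#'
#' @param persons reference population with `age` and `sex`.
#' @return an `fi_standardization_scheme` tibble (`age_band`, `sex`,
#'   `weight`) whose weights sum to 1.
#' @export
standardization_scheme <- function(persons) {
  sc <- persons |>
    dplyr::mutate(age_band = age_band(.data$age)) |>
    dplyr::count(.data$age_band, .data$sex, .drop = FALSE) |>
    dplyr::mutate(weight = .data$n / sum(.data$n)) |>
    dplyr::select("age_band", "sex", "weight")
  class(sc) <- c("fi_standardization_scheme", class(sc))
  sc
}

#' Age-sex standardised prevalence of one deficit
#'
#' Computes the direct-standardised prevalence: the weighted sum over strata
#' of the stratum-specific prevalence among persons with a non-missing value.
#' Strata with no observed persons are removed and the remaining weights
#' renormalised (with a warning), keeping the weights summing to 1.
#'
#' @param values per-person deficit values in {0, 1, NA}, aligned with
#'   `persons` rows.
#' @param persons person table with `age` and `sex`.
#' @param scheme an [standardization_scheme()]; weights must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @return a single standardised prevalence in `[0, 1]`.
#' @export
standardized_prevalence <- function(values, persons, scheme) {
  if (any(scheme$weight < 0) || abs(sum(scheme$weight) - 1) > 1e-9) {
    abort("scheme weights must be non-negative and sum to 1")
  }
  df <- tibble::tibble(value = values,
                       age_band = age_band(persons$age),
                       sex = persons$sex) |>
    dplyr::filter(!is.na(.data$value))
  obs <- df |>
    dplyr::group_by(.data$age_band, .data$sex) |>
    dplyr::summarise(prev = mean(.data$value), .groups = "drop")
  joined <- dplyr::inner_join(scheme, obs, by = c("age_band", "sex"))
  if (!nrow(joined)) abort("no stratum holds any observed value")
  if (nrow(joined) < sum(scheme$weight > 0)) {
    dropped <- sum(scheme$weight) - sum(joined$weight)
    if (dropped > 0) {
      warn(sprintf("renormalising over observed strata (weight %.3f unobserved)",
                   dropped))
    }
  }
  sum(joined$weight * joined$prev) / sum(joined$weight)
}

#' Standardised prevalence for every deficit column of a matrix
#'
#' @param matrix a deficit matrix tibble (`person_id` + deficit columns).
#' @param persons matching person table.
#' @param scheme an [standardization_scheme()].
#' @return tibble (`deficit`, `prevalence`).
#' @export
standardized_prevalence_table <- function(matrix, persons, scheme) {
  persons <- persons[match(matrix$person_id, persons$person_id), ]
  cols <- setdiff(names(matrix), "person_id")
  renorm <- character()
  out <- tibble::tibble(
    deficit = cols,
    prevalence = vapply(cols, function(d) {
      withCallingHandlers(
        standardized_prevalence(matrix[[d]], persons, scheme),
        warning = function(w) {
          if (grepl("renormalising", conditionMessage(w))) {
            renorm <<- c(renorm, d)
            invokeRestart("muffleWarning")
          }
        })
    }, numeric(1))
  )
  if (length(renorm)) {
    warn(paste0("weights renormalised over observed strata for ",
                length(renorm), " deficit(s)"))
  }
  out
}

#' Per-deficit age-sex-adjusted odds ratios for data source
#'
#' Fits, for each directly comparable deficit pair, the logistic model
#' logit(p) = beta0 + beta_age (age - 65) + beta_sex sex +
#' beta_source source by maximum likelihood and reports the data-source
#' odds ratio exp(beta_source) with a Wald 95% interval. Degenerate pairs
#' (constant outcome, or apparent separation) are flagged rather than
#' returned as silent NaNs.
#'
#' @param paired long table from [select_comparable()].
#' @return an `fi_or_fit` object; [generics::tidy()] returns the per-pair
#'   table (`deficit_pair`, `or`, `ci_low`, `ci_high`, `p_value`, the four
#'   log-odds coefficients, `se_source`, `flag`).
#' @export
fit_deficit_logistic <- function(paired) {
  fits <- paired |>
    dplyr::group_by(.data$deficit_pair) |>
    dplyr::group_map(function(df, key) {
      pair <- key$deficit_pair[[1]]
      base <- tibble::tibble(deficit_pair = pair, or = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p_value = NA_real_, beta0 = NA_real_,
                             beta_age = NA_real_, beta_sex = NA_real_,
                             beta_source = NA_real_, se_source = NA_real_,
                             flag = "ok")
      if (dplyr::n_distinct(df$present) < 2) {
        base$flag <- "constant_outcome"
        return(base)
      }
      if (dplyr::n_distinct(df$source) < 2) {
        base$flag <- "single_source"
        return(base)
      }
      fit <- suppressWarnings(
        glm(present ~ I(age - 65) + sex + source, family = binomial(), data = df))
      b <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      if (!fit$converged || abs(b[["source"]]) > 10 || se[["source"]] > 10) {
        base$flag <- "separation"
        return(base)
      }
      z <- b[["source"]] / se[["source"]]
      base$or <- exp(b[["source"]])
      base$ci_low <- exp(b[["source"]] - 1.959964 * se[["source"]])
      base$ci_high <- exp(b[["source"]] + 1.959964 * se[["source"]])
      base$p_value <- 2 * pnorm(-abs(z))
      base$beta0 <- b[["(Intercept)"]]
      base$beta_age <- b[["I(age - 65)"]]
      base$beta_sex <- b[["sex"]]
      base$beta_source <- b[["source"]]
      base$se_source <- se[["source"]]
      base
    }) |>
    dplyr::bind_rows()
  structure(list(table = fits, n = nrow(paired)), class = "fi_or_fit")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The statistic D is the supremum absolute difference between the two
#' empirical cumulative distribution functions, evaluated exactly over the
#' pooled jump points; the two-sided p-value uses the asymptotic Kolmogorov
#' distribution with the standard two-sample effective size.
#'
#' @param scores_a,scores_b non-empty numeric samples.
#' @return an `fi_ks` object with `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b)) {
    abort("both samples must be non-empty")
  }
  pooled <- sort(unique(c(scores_a, scores_b)))
  ecdf_a <- stats::ecdf(scores_a)
  ecdf_b <- stats::ecdf(scores_b)
  d <- max(abs(ecdf_a(pooled) - ecdf_b(pooled)))
  p <- suppressWarnings(
    stats::ks.test(scores_a, scores_b, exact = FALSE)$p.value)
  structure(list(statistic = d, p_value = p,
                 n_a = length(scores_a), n_b = length(scores_b)),
            class = "fi_ks")
}

#' Interaction linear model for frailty scores
#'
#' Least-squares fit of
#' score ~ (age - 65) + sex + source + (age - 65):sex +
#' (age - 65):source + sex:source on the pooled two-source cohort.
#'
#' @param results frailty results (from [compute_frailty_index()]) for both
#'   sources combined, or any tibble with `person_id` and `score`.
#' @param persons pooled person table with `age`, `sex`, `source`.
#' @return an `fi_lm` object wrapping the `lm` fit; `tidy()` reports the
#'   seven coefficients with standard errors and p-values, `glance()` the
#'   R-squared and residual standard deviation.
#' @export
fit_frailty_linear <- function(results, persons) {
  df <- dplyr::inner_join(results[c("person_id", "score")],
                          persons[c("person_id", "age", "sex", "source")],
                          by = "person_id") |>
    dplyr::mutate(age_c = .data$age - 65)
  for (v in c("age_c", "sex", "source")) {
    if (dplyr::n_distinct(df[[v]]) < 2) {
      abort(paste0("degenerate design: term '", v, "' takes a single value"))
    }
  }
  fit <- lm(score ~ age_c + sex + source + age_c:sex + age_c:source + sex:source,
            data = df)
  structure(list(fit = fit, n = nrow(df)), class = "fi_lm")
}

#' Distribution comparison report
#'
#' Produces the tables behind the usual distribution figures: normalised
#' histograms with source-specific bin counts (by default one bin per
#' possible deficit count: 36 for the EHR index, 58 for the survey index),
#' ECDF tables over each sample's jump points, and score quartiles by
#' 5-year age band and source.
#'
#' @param results_ehr,results_survey frailty results per source.
#' @param persons_ehr,persons_survey matching person tables.
#' @param bins_ehr,bins_survey histogram bin counts over `[0, 1]`.
#' @return an `fi_distribution_report` list of tibbles: `histogram`
#'   (`source`, `bin_mid`, `bin_lo`, `bin_hi`, `mass`), `ecdf` (`source`,
#'   `score`, `ecdf`), `quartiles_by_age` (`source`, `age_band`, `n`, `q1`,
#'   `median`, `q3`).
#' @export
distribution_report <- function(results_ehr, results_survey,
                                persons_ehr, persons_survey,
                                bins_ehr = 36, bins_survey = 58) {
  hist_one <- function(scores, bins, src) {
    breaks <- seq(0, 1, length.out = bins + 1)
    idx <- pmin(findInterval(scores, breaks, rightmost.closed = TRUE), bins)
    mass <- tabulate(idx, nbins = bins) / length(scores)
    tibble::tibble(source = src,
                   bin_lo = breaks[-(bins + 1)], bin_hi = breaks[-1],
                   bin_mid = (breaks[-(bins + 1)] + breaks[-1]) / 2,
                   mass = mass)
  }
  ecdf_one <- function(scores, src) {
    x <- sort(unique(scores))
    tibble::tibble(source = src, score = x, ecdf = stats::ecdf(scores)(x))
  }
  quart_one <- function(results, persons, src) {
    dplyr::inner_join(results, persons[c("person_id", "age")], by = "person_id") |>
      dplyr::mutate(age_band = age_band(.data$age)) |>
      dplyr::group_by(.data$age_band) |>
      dplyr::summarise(n = dplyr::n(),
                       q1 = quantile(.data$score, 0.25, names = FALSE),
                       median = median(.data$score),
                       q3 = quantile(.data$score, 0.75, names = FALSE),
                       .groups = "drop") |>
      dplyr::mutate(source = src, .before = 1)
  }
  structure(list(
    histogram = dplyr::bind_rows(hist_one(results_ehr$score, bins_ehr, "EHR"),
                                 hist_one(results_survey$score, bins_survey, "SURVEY")),
    ecdf = dplyr::bind_rows(ecdf_one(results_ehr$score, "EHR"),
                            ecdf_one(results_survey$score, "SURVEY")),
    quartiles_by_age = dplyr::bind_rows(
      quart_one(results_ehr, persons_ehr, "EHR"),
      quart_one(results_survey, persons_survey, "SURVEY"))
  ), class = "fi_distribution_report")
}

#' Simulate frailty scores directly from the linear model
#'
#' Draws scores from the seven-coefficient generating model plus Gaussian
#' noise. Values are deliberately not clamped to `[0, 1]`, so least squares
#' remains unbiased for the generating coefficients; the helper exists for
#' parameter-recovery checks of the linear fit, not as a cohort simulator.
#'
#' @param persons person table with `age`, `sex`, `source`.
#' @param truth named coefficient vector as returned by [linear_truth()].
#' @param sigma residual standard deviation.
#' @param seed integer seed.
#' @return tibble (`person_id`, `score`).
#' @export
simulate_linear_scores <- function(persons, truth = linear_truth(),
                                   sigma = 0.071, seed = 1L) {
  a <- persons$age - 65
  mu <- truth[["beta0"]] + truth[["beta_age"]] * a +
    truth[["beta_sex"]] * persons$sex + truth[["beta_source"]] * persons$source +
    truth[["beta_age_sex"]] * a * persons$sex +
    truth[["beta_age_source"]] * a * persons$source +
    truth[["beta_sex_source"]] * persons$sex * persons$source
  with_seed(derive_seed(seed, "linear"), {
    tibble::tibble(person_id = persons$person_id,
                   score = mu + rnorm(nrow(persons), 0, sigma))
  })
}
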