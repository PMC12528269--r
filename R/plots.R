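#' Plot normalised frailty-score histograms per source
#'
#' @param report an `fi_distribution_report`.
#' @return a ggplot object.
#' @export
plot_score_histogram <- function(report) {
  ggplot2::ggplot(report$histogram,
                  ggplot2::aes(xmin = .data$bin_lo, xmax = .data$bin_hi,
                               ymin = 0, ymax = .data$mass,
                               fill = .data$source)) +
    ggplot2::geom_rect(alpha = 0.5) +
    ggplot2::labs(x = "Frailty index score", y = "Probability mass",
                  fill = "Source") +
    ggplot2::theme_minimal()
}

#' Plot empirical cumulative distribution functions per source
#'
#' @param report an `fi_distribution_report`.
#' @return a ggplot object.
#' @export
plot_score_ecdf <- function(report) {
  ggplot2::ggplot(report$ecdf,
                  ggplot2::aes(x = .data$score, y = .data$ecdf,
                               colour = .data$source)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Frailty index score", y = "ECDF", colour = "Source") +
    ggplot2::theme_minimal()
}

#' Plot score quartiles by age band and source
#'
#' @param report an `fi_distribution_report`.
#' @return a ggplot object.
#' @export
plot_quartiles_by_age <- function(report) {
  df <- tidyr::pivot_longer(report$quartiles_by_age,
                            c("q1", "median", "q3"),
                            names_to = "quartile", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_band, y = .data$score,
                                   colour = .data$source,
                                   linetype = .data$quartile,
                                   group = interaction(.data$source, .data$quartile))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age band", y = "Frailty index score",
                  colour = "Source", linetype = "Quartile") +
    ggplot2::theme_minimal()
}

#' Forest plot of data-source odds ratios
#'
#' Pairs left of OR = 1 are more prevalent in the survey source, right of 1
#' more prevalent in the EHR source.
#'
#' @param or_fit an `fi_or_fit`.
#' @return a ggplot object.
#' @export
plot_or_forest <- function(or_fit) {
  df <- tidy(or_fit) |>
    dplyr::filter(.data$flag == "ok") |>
    dplyr::arrange(.data$or) |>
    dplyr::mutate(deficit_pair = factor(.data$deficit_pair,
                                        levels = .data$deficit_pair))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$deficit_pair)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (EHR vs survey, age-sex adjusted)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
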