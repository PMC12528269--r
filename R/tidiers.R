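#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.fi_or_fit <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.fi_or_fit <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$table),
                 n_rows = x$n,
                 n_flagged = sum(x$table$flag != "ok"))
}

#' @export
print.fi_or_fit <- function(x, ...) {
  cat("Age-sex-adjusted data-source odds ratios (", nrow(x$table),
      " deficit pairs, ", x$n, " rows)\n", sep = "")
  print(x$table)
  invisible(x)
}

# canonical display names for the seven linear-model terms
FI_LM_TERMS <- c("(Intercept)" = "beta0", "age_c" = "beta_age",
                 "sex" = "beta_sex", "source" = "beta_source",
                 "age_c:sex" = "beta_age_sex", "age_c:source" = "beta_age_source",
                 "sex:source" = "beta_sex_source")

#' @exportS3Method generics::tidy
tidy.fi_lm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = unname(FI_LM_TERMS[rownames(s)]),
                 estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p_value = s[, "Pr(>|t|)"])
}

#' @exportS3Method generics::glance
glance.fi_lm <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 residual_sd = s$sigma,
                 p_value = unname(stats::pf(f[1], f[2], f[3], lower.tail = FALSE)),
                 n = x$n)
}

#' @export
print.fi_lm <- function(x, ...) {
  g <- glance(x)
  cat("Frailty-score interaction linear model (n = ", g$n,
      ", R-squared = ", signif(g$r_squared, 3), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fi_ks <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_a = x$n_a, n_b = x$n_b)
}

#' @export
print.fi_ks <- function(x, ...) {
  cat("Two-sample Kolmogorov-Smirnov: D = ", signif(x$statistic, 4),
      ", p = ", format.pval(x$p_value, digits = 3),
      " (n = ", x$n_a, " vs ", x$n_b, ")\n", sep = "")
  invisible(x)
}
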