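test_that("standardised prevalence is a weighted stratum average", {
  # constant prevalence across strata is invariant to any weights
  set.seed(3)
  persons <- make_persons(240, age = rep(c(66, 71, 76, 81, 86, 91), each = 40),
                          sex = rep(c(0, 1), 120))
  scheme <- standardization_scheme(persons)
  values <- rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 24)  # 0.1 in every stratum
  expect_equal(standardized_prevalence(values, persons, scheme), 0.1,
               tolerance = 1e-12)
  # two strata, weights 0.6 / 0.4, prevalences 0.1 / 0.2
  p2 <- make_persons(20, age = c(rep(66, 10), rep(71, 10)), sex = 0)
  sc2 <- tibble::tibble(age_band = factor(c("65-69", "70-74"),
                                          levels = levels(age_band(66))),
                        sex = 0L, weight = c(0.6, 0.4))
  v2 <- c(1, rep(0, 9), 1, 1, rep(0, 8))
  expect_equal(standardized_prevalence(v2, p2, sc2), 0.6 * 0.1 + 0.4 * 0.2,
               tolerance = 1e-12)
})

test_that("standardised prevalence matches a brute-force oracle on 12 strata", {
  set.seed(47)
  persons <- make_persons(600, age = sample(65:99, 600, replace = TRUE),
                          sex = sample(0:1, 600, replace = TRUE))
  values <- rbinom(600, 1, 0.25)
  values[sample(600, 40)] <- NA
  scheme <- standardization_scheme(persons)
  got <- standardized_prevalence(values, persons, scheme)
  # oracle: loop over the 12 strata explicitly
  band <- as.character(age_band(persons$age))
  acc <- 0; wacc <- 0
  for (b in unique(scheme$age_band)) {
    for (s in 0:1) {
      sel <- band == as.character(b) & persons$sex == s & !is.na(values)
      w <- scheme$weight[scheme$age_band == b & scheme$sex == s]
      if (any(sel)) {
        acc <- acc + w * mean(values[sel])
        wacc <- wacc + w
      }
    }
  }
  expect_equal(got, acc / wacc, tolerance = 1e-12)
})

test_that("empty strata renormalise with a warning; all-empty errors", {
  persons <- make_persons(20, age = 66, sex = 0)
  scheme <- tibble::tibble(age_band = factor(c("65-69", "90+"),
                                             levels = levels(age_band(66))),
                           sex = 0L, weight = c(0.5, 0.5))
  expect_warning(p <- standardized_prevalence(rbinom(20, 1, .4), persons, scheme),
                 "renormalising")
  expect_true(p >= 0 && p <= 1)
  expect_error(standardized_prevalence(rep(NA_integer_, 20), persons, scheme),
               "no stratum")
})

test_that("logistic null case: equal prevalence sources give OR near 1", {
  set.seed(53)
  n <- 4000
  df <- tibble::tibble(
    person_id = as.character(1:n),
    deficit_pair = "d",
    age = sample(65:95, n, replace = TRUE),
    sex = sample(0:1, n, replace = TRUE),
    source = rep(0:1, each = n / 2))
  df$present <- rbinom(n, 1, plogis(-1 + 0.03 * (df$age - 65) + 0.2 * df$sex))
  fit <- tidy(fit_deficit_logistic(df))
  expect_true(fit$ci_low <= 1 & 1 <= fit$ci_high)
})

test_that("logistic fit recovers a known source effect", {
  set.seed(59)
  n <- 20000
  df <- tibble::tibble(
    person_id = as.character(1:n), deficit_pair = "d",
    age = sample(65:95, n, replace = TRUE),
    sex = sample(0:1, n, replace = TRUE),
    source = rep(0:1, each = n / 2))
  df$present <- rbinom(n, 1, plogis(-1.5 + 0.02 * (df$age - 65) + 0.1 * df$sex +
                                      log(2) * df$source))
  fit <- tidy(fit_deficit_logistic(df))
  expect_true(fit$or > 1.8 && fit$or < 2.2)
  expect_lt(abs(fit$beta_source - log(2)), 3 * fit$se_source)
})

test_that("degenerate 2x2 without covariates reproduces the cross-product ratio", {
  df <- tibble::tibble(
    person_id = as.character(1:200), deficit_pair = "d",
    age = 70L, sex = 0L,
    source = rep(c(1L, 0L), c(100, 100)),
    present = c(rep(1L, 20), rep(0L, 80), rep(1L, 50), rep(0L, 50)))
  fit <- tidy(fit_deficit_logistic(df))
  expect_equal(fit$or, (20 / 80) / (50 / 50), tolerance = 1e-6)
})

test_that("constant outcomes and single-source pairs are flagged, not NaN", {
  df <- tibble::tibble(person_id = as.character(1:40), deficit_pair = "d",
                       age = sample(65:90, 40, replace = TRUE),
                       sex = rep(0:1, 20), source = rep(0:1, each = 20),
                       present = 0L)
  out <- tidy(fit_deficit_logistic(df))
  expect_equal(out$flag, "constant_outcome")
  expect_true(is.na(out$or))
  df2 <- dplyr::mutate(df, present = rbinom(40, 1, .5), source = 1L)
  expect_equal(tidy(fit_deficit_logistic(df2))$flag, "single_source")
})

test_that("K-S statistic is the exact pooled-jump-point supremum", {
  a <- c(0.1, 0.2, 0.5)
  expect_equal(ks_two_sample(a, a)$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0.5), c(1, 1.5))$statistic, 1)
  set.seed(61)
  x <- round(rbeta(200, 2, 9), 3)  # many ties, like frailty scores
  y <- round(rbeta(300, 2, 6), 3)
  got <- ks_two_sample(x, y)
  # dense-grid oracle over the pooled points
  grid <- sort(unique(c(x, y, seq(0, 1, by = 1e-3))))
  d_oracle <- max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t),
                             numeric(1))))
  expect_lt(abs(got$statistic - d_oracle), 1e-12)
  # agrees with the standard two-sample test implementation
  expect_equal(got$statistic, unname(suppressWarnings(ks.test(x, y))$statistic),
               tolerance = 1e-12)
  # symmetry and invariance under strictly monotone transforms
  expect_equal(ks_two_sample(y, x)$statistic, got$statistic)
  expect_equal(ks_two_sample(exp(x), exp(y))$statistic, got$statistic)
  expect_error(ks_two_sample(numeric(0), y), "non-empty")
})

test_that("linear fit interpolates noiseless planar data exactly", {
  persons <- make_persons(64)
  grid <- expand.grid(age = c(65, 70, 75, 80), sex = 0:1, source = 0:1)
  grid <- grid[rep(1:16, 4), ]
  persons$age <- as.integer(grid$age)
  persons$sex <- as.integer(grid$sex)
  persons$source <- as.integer(grid$source)
  truth <- c(beta0 = 0.1, beta_age = 0.004, beta_sex = 0.02,
             beta_source = -0.003, beta_age_sex = 0.0002,
             beta_age_source = 0.0009, beta_sex_source = -0.016)
  scores <- simulate_linear_scores(persons, truth, sigma = 0, seed = 1)
  fit <- fit_frailty_linear(scores, persons)
  # summary() warns about the essentially perfect fit; that is the point here
  td <- suppressWarnings(tidy(fit))
  est <- setNames(td$estimate, td$term)
  expect_equal(est[names(truth)], truth, tolerance = 1e-10)
  g <- suppressWarnings(glance(fit))
  expect_equal(g$r_squared, 1, tolerance = 1e-10)
  expect_lt(g$residual_sd, 1e-10)
})

test_that("linear fit matches an explicit normal-equations oracle on 8 rows", {
  persons <- make_persons(8,
                          age = c(65, 70, 80, 90, 67, 75, 85, 95),
                          sex = c(0, 1, 0, 1, 1, 0, 1, 0),
                          source = c(0, 0, 0, 0, 1, 1, 1, 1))
  set.seed(67)
  scores <- tibble::tibble(person_id = persons$person_id,
                           score = runif(8, 0, 0.5))
  fit <- fit_frailty_linear(scores, persons)
  a <- persons$age - 65
  X <- cbind(1, a, persons$sex, persons$source, a * persons$sex,
             a * persons$source, persons$sex * persons$source)
  beta <- solve(t(X) %*% X, t(X) %*% scores$score)
  est <- tidy(fit)$estimate
  expect_equal(unname(est), as.numeric(beta), tolerance = 1e-8)
})

test_that("collinear designs raise an error naming the degenerate term", {
  persons <- make_persons(20, age = sample(65:90, 20, replace = TRUE),
                          sex = rep(0:1, 10), source = 1L)
  scores <- tibble::tibble(person_id = persons$person_id, score = runif(20))
  expect_error(fit_frailty_linear(scores, persons), "source")
})

test_that("distribution report normalises histograms and matches quartile oracle", {
  set.seed(71)
  pe <- make_persons(500, age = sample(65:99, 500, replace = TRUE), prefix = "E")
  ps <- make_persons(500, age = sample(65:99, 500, replace = TRUE), source = 0,
                     prefix = "S")
  re <- tibble::tibble(person_id = pe$person_id,
                       score = round(rbeta(500, 2, 10), 3))
  rs <- tibble::tibble(person_id = ps$person_id,
                       score = round(rbeta(500, 2, 8), 3))
  rep <- distribution_report(re, rs, pe, ps)
  masses <- tapply(rep$histogram$mass, rep$histogram$source, sum)
  expect_equal(as.numeric(masses), c(1, 1))
  expect_equal(sum(rep$histogram$source == "EHR"), 36)
  expect_equal(sum(rep$histogram$source == "SURVEY"), 58)
  # single score lands all mass in one bin
  single <- distribution_report(re[1, ] |> dplyr::mutate(score = 0.5), rs,
                                pe[1, ], ps)
  m <- single$histogram[single$histogram$source == "EHR", ]
  expect_equal(sum(m$mass > 0), 1)
  expect_equal(m$mass[m$bin_lo <= 0.5 & m$bin_hi > 0.5], 1)
  # per-band medians equal a sort-based oracle
  band <- as.character(age_band(pe$age))
  for (b in unique(band)) {
    sel <- re$score[band == b]
    med_o <- sort(sel)[ceiling(length(sel) / 2)]
    if (length(sel) %% 2 == 0) {
      med_o <- mean(sort(sel)[length(sel) / 2 + 0:1])
    }
    got <- rep$quartiles_by_age$median[rep$quartiles_by_age$source == "EHR" &
                                         rep$quartiles_by_age$age_band == b]
    expect_equal(got, med_o, tolerance = 1e-12)
  }
  # ECDF table ends at 1 for both sources
  expect_equal(as.numeric(tapply(rep$ecdf$ecdf, rep$ecdf$source, max)), c(1, 1))
})

test_that("plot builders return ggplot objects", {
  set.seed(73)
  pe <- make_persons(50, age = sample(65:99, 50, TRUE), prefix = "E")
  ps <- make_persons(50, age = sample(65:99, 50, TRUE), source = 0, prefix = "S")
  re <- tibble::tibble(person_id = pe$person_id, score = rbeta(50, 2, 10))
  rs <- tibble::tibble(person_id = ps$person_id, score = rbeta(50, 2, 8))
  rep <- distribution_report(re, rs, pe, ps)
  expect_s3_class(plot_score_histogram(rep), "ggplot")
  expect_s3_class(plot_score_ecdf(rep), "ggplot")
  expect_s3_class(plot_quartiles_by_age(rep), "ggplot")
})
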