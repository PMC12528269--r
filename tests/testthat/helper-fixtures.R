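# Shared fixtures built in code: tiny deficit model sets, hand-made person
# tables and record tables used across the module tests.

tiny_models <- function(names = c("diabetes", "arthritis", "falls"),
                        beta0 = -1, beta_age = 0.03, beta_sex = 0.2,
                        beta_source = 0, lambda_load = 0) {
  tibble::tibble(deficit_name = names,
                 beta0 = beta0, beta_age = beta_age, beta_sex = beta_sex,
                 beta_source = beta_source, lambda_load = lambda_load)
}

make_persons <- function(n, age = 70L, sex = 0L, source = 1L, latent_u = 0,
                         registration_start = as.Date("2000-01-01"),
                         prefix = "P") {
  tibble::tibble(person_id = sprintf("%s%04d", prefix, seq_len(n)),
                 age = as.integer(rep_len(age, n)),
                 sex = as.integer(rep_len(sex, n)),
                 source = as.integer(rep_len(source, n)),
                 registration_start = rep_len(registration_start, n),
                 latent_u = rep_len(latent_u, n))
}

# a generator config whose latent loading is zeroed: under it the fitted
# logistic model is exactly the data-generating model
no_latent_config <- function() {
  gen <- default_generator_config()
  for (src in c("ehr", "survey")) {
    gen[[src]]$deficits$lambda_load <- 0
  }
  gen
}

# independent brute-force scan: present iff any row matches person, code set
# and strict date cutoff
oracle_coded_flag <- function(events, codes, index_date, ids) {
  vapply(ids, function(pid) {
    hit <- FALSE
    for (i in seq_len(nrow(events))) {
      if (events$person_id[i] == pid &&
          trimws(events$code[i]) %in% trimws(codes) &&
          events$event_date[i] < index_date) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

oracle_polypharmacy_flag <- function(rx, index_date, spec, ids) {
  vapply(ids, function(pid) {
    paras <- character()
    for (i in seq_len(nrow(rx))) {
      if (rx$person_id[i] != pid) next
      if (is.na(rx$bnf_paragraph[i]) || is.na(rx$bnf_chapter[i])) next
      if (rx$issue_date[i] < index_date ||
          rx$issue_date[i] >= index_date + spec$window_days) next
      if (rx$bnf_chapter[i] < spec$chapter_range[1] ||
          rx$bnf_chapter[i] > spec$chapter_range[2]) next
      key <- paste(rx$bnf_chapter[i], rx$bnf_paragraph[i], sep = "_")
      if (key %in% spec$excluded_paragraphs) next
      paras <- union(paras, key)
    }
    as.integer(length(paras) >= spec$min_paragraphs)
  }, integer(1))
}
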