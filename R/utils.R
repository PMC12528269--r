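#' @importFrom rlang %||% .data abort warn inform
#' @importFrom stats plogis qlogis quantile median sd glm lm binomial coef vcov
#'   pnorm rnorm rbinom runif rpois setNames complete.cases
NULL

AGE_BANDS <- c("65-69", "70-74", "75-79", "80-84", "85-89", "90+")

#' Assign 5-year age bands used throughout the package
#'
#' Ages 65 and over are banded into 65-69, 70-74, 75-79, 80-84, 85-89 and 90+,
#' the strata used for direct standardisation and for age-stratified summaries.
#'
#' @param age integer vector of ages in years (>= 65).
#' @return factor with the six band levels.
#' @export
age_band <- function(age) {
  if (any(age < 65, na.rm = TRUE)) {
    abort("age_band() is defined for ages 65 and over")
  }
  cut(age, breaks = c(65, 70, 75, 80, 85, 90, Inf),
      labels = AGE_BANDS, right = FALSE)
}

# run code with a temporary RNG state; never perturbs the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# calendar-aware year offset; Feb 29 rolls forward when the target year
# has no leap day
add_years <- function(date, n) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + n
  as.Date(lt)
}

# stage seeds derived from one root seed, kept inside 32-bit integer range
derive_seed <- function(seed, stage) {
  offsets <- c(population = 11L, ehr_records = 23L, survey = 37L,
               pipeline = 53L, linear = 71L, paragraphs = 89L)
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% .Machine$integer.max)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must be a single probability in [0, 1]"))
  }
}
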