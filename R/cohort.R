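#' Cohort generation settings
#'
#' @param n_patients Number of appointment records to draw (default 1073,
#'   the size of the reference cohort).
#' @param seed Integer seed; all generator randomness flows through it.
#' @param start_date,end_date Calendar range appointments are drawn from.
#' @param n_locations Number of residence zones (default 66).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1073L, seed = 1L,
                          start_date = as.Date("2023-01-01"),
                          end_date = as.Date("2023-12-31"),
                          n_locations = 66L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (n_patients < 1) rlang::abort("n_patients must be >= 1")
  if (start_date > end_date) rlang::abort("start_date must be <= end_date")
  if (n_locations < 1) rlang::abort("n_locations must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 start_date = start_date, end_date = end_date,
                 n_locations = as.integer(n_locations)),
            class = "cohort_config")
}

is_weekend <- function(date) {
  as.integer(as.POSIXlt(as.Date(date))$wday %in% c(0L, 6L))
}

# Truncated-normal ages by inverse-CDF on the truncated quantile range.
draw_ages <- function(n, spec) {
  lo <- stats::pnorm(spec$min, spec$mean, spec$sd)
  hi <- stats::pnorm(spec$max, spec$mean, spec$sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), spec$mean, spec$sd)
  pmin(pmax(as.integer(round(age)), spec$min), spec$max)
}

#' Generate a synthetic appointment cohort
#'
#' Draws `n_patients` appointment records with independent covariates at
#' the marginals of `effects` and a Bernoulli show-up outcome under the
#' logistic model of [attendance_probability()]. The weekend flag is
#' derived from the drawn calendar date, not sampled. Identical
#' `(config, effects)` give byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param effects An [effect_spec()]; defaults to [default_effects()].
#' @return A tibble with the 13 covariates, the latent `show_prob` used to
#'   draw the outcome, and `outcome` in `{"show_up", "no_show"}`. The
#'   generator seed is recorded in `attr(, "seed")`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' table(coh$outcome)
generate_cohort <- function(config, effects = default_effects()) {
  stopifnot(inherits(config, "cohort_config"), inherits(effects, "effect_spec"))
  m <- effects$covariate_marginals
  n <- config$n_patients
  withr::with_seed(config$seed, {
    days <- seq(config$start_date, config$end_date, by = "day")
    date <- sample(days, n, replace = TRUE)
    df <- tibble::tibble(
      date = date,
      weekend_flag = is_weekend(date),
      age = draw_ages(n, m$age),
      gender = ifelse(stats::runif(n) < effects$gender_split,
                      "female", "male"),
      own_vehicle = stats::rbinom(n, 1, m$own_vehicle),
      companion = stats::rbinom(n, 1, m$companion),
      insurance = stats::rbinom(n, 1, m$insurance),
      sms_received = stats::rbinom(n, 1, m$sms_received),
      health_issue = stats::rbinom(n, 1, m$health_issue),
      treatment_change = stats::rbinom(n, 1, m$treatment_change),
      department = sample(department_levels(), n, replace = TRUE,
                          prob = effects$department_weights),
      citizen = stats::rbinom(n, 1, m$citizen),
      location_id = sample.int(config$n_locations, n, replace = TRUE))
    p <- stats::plogis(
      linear_predictor(df, effects, n_locations = config$n_locations))
    df$show_prob <- p
    df$outcome <- ifelse(stats::runif(n) < p, "show_up", "no_show")
    attr(df, "seed") <- config$seed
    df
  })
}
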