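# Covariate vocabulary shared by the generator, the models and the ANOVA.
covariate_names <- function() {
  c("date", "weekend_flag", "age", "gender", "own_vehicle", "companion",
    "insurance", "sms_received", "health_issue", "treatment_change",
    "department", "citizen", "location_id")
}

binary_covariates <- function() {
  c("weekend_flag", "own_vehicle", "companion", "insurance", "sms_received",
    "health_issue", "treatment_change", "citizen")
}

#' Department labels of the appointment system
#'
#' The nine outpatient departments the cohort is drawn from, in a fixed
#' order used by all pattern effects and one-hot encodings.
#'
#' @return Character vector of length 9.
#' @export
department_levels <- function() {
  c("Allergy and Immunology", "Cardiology", "Dermatology",
    "Gastroenterology", "Hematology", "Nephrology", "Orthopedics",
    "Radiology", "Urology")
}

# Patient counts per department at the default cohort size of 1073.
department_counts <- function() {
  stats::setNames(c(111L, 124L, 126L, 113L, 104L, 123L, 118L, 137L, 117L),
                  department_levels())
}

#' Seasonal score of an appointment date
#'
#' Maps a calendar date to `sin(2 * pi * day_of_year / 365.25)`, the single
#' degree of freedom through which the date enters both the outcome model of
#' the generator and the attendance-factor ANOVA.
#'
#' @param date A `Date` vector.
#' @return Numeric vector in `[-1, 1]`.
#' @export
season_score <- function(date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  sin(2 * pi * doy / 365.25)
}

# Fixed deterministic patterns giving categorical blocks a 1-df "dial":
# the block's log-odds contribution is coefficient * pattern[level].
category_pattern <- function(k) sin(2 * pi * seq_len(k) / k)

#' Construct an outcome-effect specification
#'
#' Bundles the parameters of the Bernoulli-logistic outcome model used by
#' the cohort generator: an intercept, one log-odds coefficient per
#' covariate, the department mix, the gender split and the covariate
#' marginals.
#'
#' Coefficients are interpreted as follows: binary covariates contribute
#' `coef * x`; `age` contributes `coef * (age - 45)` per year; `date`
#' contributes `coef * season_score(date)`; `gender` contributes `coef`
#' for female patients; `department` and `location_id` contribute
#' `coef * pattern[level]` with a fixed sinusoidal level pattern.
#'
#' @param intercept Log-odds of show-up at reference levels.
#' @param coefficients Named numeric vector, one entry per covariate
#'   (see [covariate_names()]).
#' @param department_weights Probability vector over the nine departments.
#' @param gender_split Probability that a patient is female.
#' @param covariate_marginals Named list: one probability per binary
#'   covariate plus an `age` entry `list(mean, sd, min, max)` in years.
#' @return An object of class `effect_spec`.
#' @seealso [default_effects()], [attendance_probability()]
#' @export
effect_spec <- function(intercept, coefficients, department_weights,
                        gender_split, covariate_marginals) {
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  missing_coef <- setdiff(covariate_names(), names(coefficients))
  if (length(missing_coef) > 0) {
    rlang::abort(paste0("missing coefficients for: ",
                        paste(missing_coef, collapse = ", ")))
  }
  if (length(department_weights) != 9 ||
      abs(sum(department_weights) - 1) > 1e-9) {
    rlang::abort("department_weights must be 9 probabilities summing to 1")
  }
  if (gender_split < 0 || gender_split > 1) {
    rlang::abort("gender_split must lie in [0, 1]")
  }
  for (nm in binary_covariates()) {
    p <- covariate_marginals[[nm]]
    if (is.null(p) || p < 0 || p > 1) {
      rlang::abort(paste0("marginal probability for '", nm,
                          "' missing or outside [0, 1]"))
    }
  }
  if (is.null(covariate_marginals$age)) {
    rlang::abort("covariate_marginals must contain an 'age' entry")
  }
  structure(
    list(intercept = intercept,
         coefficients = coefficients[covariate_names()],
         department_weights = department_weights,
         gender_split = gender_split,
         covariate_marginals = covariate_marginals),
    class = "effect_spec")
}

#' Default outcome-effect specification
#'
#' The package's stated world: the SMS reminder carries the dominant
#' log-odds effect; age, season (date), weekend, own vehicle, health issue
#' and residence zone carry smaller nonzero effects; gender, insurance,
#' companion, citizenship, treatment change and department are null.
#' The gender split is 706/1073 female and the department weights are the
#' per-department patient counts at n = 1073.
#'
#' @return An `effect_spec`.
#' @export
#' @examples
#' eff <- default_effects()
#' eff$coefficients["gender"]       # 0: gender is a null factor
#' names(which.max(abs(eff$coefficients)))  # "sms_received"
default_effects <- function() {
  coefs <- stats::setNames(numeric(length(covariate_names())),
                           covariate_names())
  coefs["sms_received"] <- 2.5
  coefs["age"] <- 0.025
  coefs["weekend_flag"] <- -0.9
  coefs["own_vehicle"] <- 0.35
  coefs["health_issue"] <- -0.45
  coefs["date"] <- 0.3
  coefs["location_id"] <- 0.4
  effect_spec(
    intercept = -0.95,
    coefficients = coefs,
    department_weights = department_counts() / sum(department_counts()),
    gender_split = 706 / 1073,
    covariate_marginals = list(
      weekend_flag = 2 / 7,  # overridden by the calendar when dates are drawn
      own_vehicle = 0.5,
      companion = 0.4,
      insurance = 0.8,
      sms_received = 0.5,
      health_issue = 0.3,
      treatment_change = 0.2,
      citizen = 0.9,
      age = list(mean = 45, sd = 18, min = 0, max = 95)))
}

# Vectorised linear predictor over a cohort-shaped data frame.
linear_predictor <- function(df, effects, n_locations = 66L) {
  cf <- effects$coefficients
  dept_pat <- category_pattern(9)
  dept_idx <- match(df$department, department_levels())
  if (anyNA(dept_idx)) rlang::abort("unknown department label")
  if (max(df$location_id) > n_locations) {
    rlang::abort("location_id exceeds n_locations")
  }
  loc_pat <- category_pattern(n_locations)
  effects$intercept +
    cf[["date"]] * season_score(df$date) +
    cf[["weekend_flag"]] * df$weekend_flag +
    cf[["age"]] * (df$age - 45) +
    cf[["gender"]] * (df$gender == "female") +
    cf[["own_vehicle"]] * df$own_vehicle +
    cf[["companion"]] * df$companion +
    cf[["insurance"]] * df$insurance +
    cf[["sms_received"]] * df$sms_received +
    cf[["health_issue"]] * df$health_issue +
    cf[["treatment_change"]] * df$treatment_change +
    cf[["department"]] * dept_pat[dept_idx] +
    cf[["citizen"]] * df$citizen +
    cf[["location_id"]] * loc_pat[df$location_id]
}

#' Show-up probability of a patient record
#'
#' Evaluates the logistic outcome model for one appointment record:
#' `plogis(intercept + sum of covariate effects)`. Deterministic in
#' `(record, effects)`.
#'
#' @param record A one-row data frame or named list with the cohort
#'   covariate fields (see [generate_cohort()]).
#' @param effects An [effect_spec()].
#' @param n_locations Number of residence zones the `location_id` pattern
#'   spans (66 by default, as in the default cohort).
#' @return Probability of show-up in `[0, 1]`.
#' @export
#' @examples
#' eff <- default_effects()
#' rec <- list(date = as.Date("2023-06-01"), weekend_flag = 0L, age = 45L,
#'             gender = "male", own_vehicle = 1L, companion = 0L,
#'             insurance = 1L, sms_received = 1L, health_issue = 0L,
#'             treatment_change = 0L, department = "Radiology",
#'             citizen = 1L, location_id = 5L)
#' attendance_probability(rec, eff)
attendance_probability <- function(record, effects, n_locations = 66L) {
  df <- tibble::as_tibble(record[covariate_names()])
  df$location_id <- as.integer(df$location_id)
  eta <- linear_predictor(df, effects, n_locations = n_locations)
  unname(stats::plogis(eta))
}
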