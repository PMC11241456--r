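test_that("default effects encode the attendance-factor pattern", {
  eff <- default_effects()
  cf <- eff$coefficients

  # null factors carry exactly zero log-odds
  for (nm in c("gender", "insurance", "companion", "citizen",
               "treatment_change", "department")) {
    expect_identical(unname(cf[nm]), 0)
  }
  # active factors are nonzero, SMS dominant
  for (nm in c("sms_received", "age", "date", "weekend_flag",
               "own_vehicle", "health_issue", "location_id")) {
    expect_true(abs(cf[nm]) > 0)
  }
  expect_identical(names(which.max(abs(cf))), "sms_received")

  expect_equal(eff$gender_split, 706 / 1073)
  expect_equal(sum(eff$department_weights), 1, tolerance = 1e-12)
  expect_length(eff$department_weights, 9)
})

test_that("attendance probability matches the logistic link", {
  eff <- default_effects()
  eff$coefficients[] <- 0
  eff$intercept <- 0
  rec <- list(date = as.Date("2023-03-15"), weekend_flag = 0L, age = 45L,
              gender = "male", own_vehicle = 0L, companion = 0L,
              insurance = 0L, sms_received = 1L, health_issue = 0L,
              treatment_change = 0L, department = "Cardiology",
              citizen = 0L, location_id = 3L)

  expect_equal(attendance_probability(rec, eff), 0.5)

  eff$intercept <- 50  # saturation
  expect_equal(attendance_probability(rec, eff), 1.0, tolerance = 1e-12)

  # single active binary covariate: hand evaluation of the link
  for (c_val in c(-1.3, 0.4, 2.5)) {
    eff$intercept <- 0
    eff$coefficients[] <- 0
    eff$coefficients["sms_received"] <- c_val
    expect_equal(attendance_probability(rec, eff),
                 1 / (1 + exp(-c_val)), tolerance = 1e-12)
  }

  # strictly increasing in a favourable coefficient's direction
  eff$coefficients["sms_received"] <- 1
  p1 <- attendance_probability(rec, eff)
  eff$coefficients["sms_received"] <- 2
  expect_gt(attendance_probability(rec, eff), p1)
})

test_that("generated cohorts are seeded, sized and marginally faithful", {
  cfg <- cohort_config(n_patients = 1073, seed = 7)
  coh <- generate_cohort(cfg)
  expect_identical(nrow(coh), 1073L)
  expect_identical(coh, generate_cohort(cfg))  # byte-identical rerun

  # female count within 3 binomial standard errors of 706
  se <- sqrt(1073 * (706 / 1073) * (367 / 1073))
  expect_lt(abs(sum(coh$gender == "female") - 706), 3 * se)

  # weekend flag consistent with the calendar
  expect_identical(coh$weekend_flag,
                   as.integer(as.POSIXlt(coh$date)$wday %in% c(0, 6)))
  expect_true(all(coh$department %in% department_levels()))
  expect_true(all(coh$age >= 0 & coh$age <= 95))

  # empirical show-up rate within 3 SE of the mean latent probability
  pbar <- mean(coh$show_prob)
  se_rate <- sqrt(pbar * (1 - pbar) / 1073)
  expect_lt(abs(mean(coh$outcome == "show_up") - pbar), 3 * se_rate)
})

test_that("a planted SMS effect raises the show-up rate of reminded patients", {
  eff <- default_effects()
  eff$coefficients[] <- 0
  eff$coefficients["sms_received"] <- 3
  coh <- generate_cohort(cohort_config(n_patients = 10000, seed = 3), eff)
  r1 <- mean(coh$outcome[coh$sms_received == 1] == "show_up")
  r0 <- mean(coh$outcome[coh$sms_received == 0] == "show_up")
  expect_gt(r1, r0)
})

test_that("categorical marginals are recovered within 1% at n = 100,000", {
  eff <- default_effects()
  coh <- generate_cohort(cohort_config(n_patients = 100000, seed = 21), eff)
  m <- eff$covariate_marginals
  for (nm in c("own_vehicle", "companion", "insurance", "sms_received",
               "health_issue", "treatment_change", "citizen")) {
    expect_lt(abs(mean(coh[[nm]]) - m[[nm]]), 0.01)
  }
  expect_lt(abs(mean(coh$gender == "female") - eff$gender_split), 0.01)
  dept_emp <- as.numeric(table(factor(coh$department,
                                      department_levels()))) / nrow(coh)
  expect_true(all(abs(dept_emp - eff$department_weights) < 0.01))
})

test_that("logistic regression recovers the planted coefficients", {
  eff <- default_effects()
  cfg <- cohort_config(n_patients = 30000, seed = 17)
  coh <- generate_cohort(cfg, eff)
  # correctly specified design: one column per generator term
  zone_pattern <- sin(2 * pi * seq_len(66) / 66)
  df <- data.frame(
    y = outcome_to_binary(coh$outcome),
    sms = coh$sms_received,
    age_c = coh$age - 45,
    weekend = coh$weekend_flag,
    vehicle = coh$own_vehicle,
    health = coh$health_issue,
    season = season_score(coh$date),
    zone = zone_pattern[coh$location_id])
  fit <- glm(y ~ sms + age_c + weekend + vehicle + health + season + zone,
             family = binomial(), data = df)
  est <- summary(fit)$coefficients
  planted <- c("(Intercept)" = eff$intercept,
               sms = unname(eff$coefficients["sms_received"]),
               age_c = unname(eff$coefficients["age"]),
               weekend = unname(eff$coefficients["weekend_flag"]),
               vehicle = unname(eff$coefficients["own_vehicle"]),
               health = unname(eff$coefficients["health_issue"]),
               season = unname(eff$coefficients["date"]),
               zone = unname(eff$coefficients["location_id"]))
  for (nm in names(planted)) {
    expect_lt(abs(est[nm, "Estimate"] - planted[nm]),
              3 * est[nm, "Std. Error"])
  }
})

test_that("invalid configurations and marginals are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(start_date = "2023-06-01",
                             end_date = "2023-01-01"), "start_date")
  eff <- default_effects()
  eff$covariate_marginals$sms_received <- 1.4
  expect_error(
    effect_spec(eff$intercept, eff$coefficients, eff$department_weights,
                eff$gender_split, eff$covariate_marginals),
    "sms_received")
  expect_error(
    effect_spec(0, eff$coefficients, rep(0.2, 9), 0.5,
                default_effects()$covariate_marginals),
    "department_weights")
})
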