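#' Assemble a full-run configuration
#'
#' Bundles the per-stage settings of the three-stage analysis (factor
#' ANOVA, attendance prediction, penalty pricing) with explicit seeds.
#' Any component can be overridden; defaults are recorded in the manifest
#' so under-specified choices stay auditable.
#'
#' @param cohort A [cohort_config()].
#' @param effects An [effect_spec()].
#' @param split A [split_config()].
#' @param models List of [model_spec()]s (default: RF, GB and AB with
#'   small demonstration grids).
#' @param anova_factors Covariates entering the ANOVA screen.
#' @param anova_alpha Significance level of the screen.
#' @param horizon A [horizon_config()].
#' @param output_dir Directory artifacts are written into.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       effects = default_effects(),
                       split = split_config(),
                       models = default_model_specs(),
                       anova_factors = covariate_names(),
                       anova_alpha = 0.05,
                       horizon = horizon_config(),
                       output_dir = tempfile("noshow_run_")) {
  structure(list(cohort = cohort, effects = effects, split = split,
                 models = models, anova_factors = anova_factors,
                 anova_alpha = anova_alpha, horizon = horizon,
                 output_dir = output_dir),
            class = "run_config")
}

#' Demonstration model specs for the pipeline default
#'
#' One spec per algorithm with a single-configuration grid, so a default
#' end-to-end run stays fast; pass full grids via [model_spec()] for a
#' real search.
#'
#' @param seed Shared model seed.
#' @return Named list of three [model_spec()]s.
#' @export
default_model_specs <- function(seed = 42L) {
  list(
    RF = model_spec("RF", grid = list(n_estimators = 100,
                                      max_features = "sqrt",
                                      max_depth = NA,
                                      min_samples_split = 2),
                    cv_folds = 3L, seed = seed),
    GB = model_spec("GB", grid = list(n_estimators = 100,
                                      learning_rate = 0.1,
                                      max_depth = 3, subsample = 1.0),
                    cv_folds = 3L, seed = seed),
    AB = model_spec("AB", grid = list(n_estimators = 100,
                                      learning_rate = 1.0),
                    cv_folds = 3L, seed = seed))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  path
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage '", stage, "' failed: ",
                        conditionMessage(e)),
                 class = "pipeline_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes generate -> split -> tune/fit -> evaluate -> anova -> price
#' from one configuration, writing every artifact (cohort CSV, per-model
#' predictions and tuning tables, metric and confusion-matrix tables, the
#' ANOVA table, the penalty series and summary) plus a manifest JSON with
#' an MD5 per file. Identical configurations and seeds yield identical
#' manifest hashes. A stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return The manifest as a named list (also written to
#'   `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  files <- character(0)
  add <- function(path) files[length(files) + 1] <<- path

  cohort <- run_stage("generate", {
    coh <- generate_cohort(config$cohort, config$effects)
    write_cohort(coh, out("cohort.csv"),
                 metadata = list(seed = config$cohort$seed,
                                 n_patients = config$cohort$n_patients))
    add(out("cohort.csv")); add(out("cohort.csv.meta.json"))
    coh
  })

  parts <- run_stage("split", stratified_split(cohort, config$split))

  model_runs <- run_stage("models", {
    lapply(config$models, function(spec) {
      tuned <- tune_model(spec, parts$train)
      fp <- fit_predict(spec, tuned$best_params, parts$train, parts$test)
      readr::write_csv(fp$predictions,
                       out(paste0("predictions_", spec$algorithm, ".csv")),
                       progress = FALSE)
      readr::write_csv(tuned$results,
                       out(paste0("tuning_", spec$algorithm, ".csv")),
                       progress = FALSE)
      add(out(paste0("predictions_", spec$algorithm, ".csv")))
      add(out(paste0("tuning_", spec$algorithm, ".csv")))
      list(spec = spec, tuned = tuned, fit = fp)
    })
  })

  betas <- run_stage("evaluate", {
    metrics <- dplyr::bind_rows(lapply(model_runs, function(mr) {
      dplyr::bind_rows(lapply(c("train", "test"), function(ph) {
        p <- mr$fit$predictions[mr$fit$predictions$phase == ph, ]
        dplyr::bind_cols(
          tibble::tibble(algorithm = mr$spec$algorithm, phase = ph),
          metric_report(p$actual, p$predicted, p$score))
      }))
    }))
    readr::write_csv(metrics, out("metrics.csv"), progress = FALSE)
    add(out("metrics.csv"))
    conf <- dplyr::bind_rows(lapply(model_runs, function(mr) {
      p <- mr$fit$predictions[mr$fit$predictions$phase == "test", ]
      cm <- confusion_from_labels(p$actual, p$predicted)
      cr <- column_rates(cm)
      tibble::tibble(algorithm = mr$spec$algorithm, tp = cm$tp, tn = cm$tn,
                     fp = cm$fp, fn = cm$fn,
                     alpha_pct = 100 * cr$alpha, beta_pct = 100 * cr$beta)
    }))
    readr::write_csv(conf, out("confusion.csv"), progress = FALSE)
    add(out("confusion.csv"))
    stats::setNames(conf$beta_pct / 100, conf$algorithm)
  })

  run_stage("anova", {
    tab <- regression_anova(cohort, factors = config$anova_factors)
    readr::write_csv(tab, out("anova.csv"), progress = FALSE)
    add(out("anova.csv"))
    screen <- significance_screen(tab, config$anova_alpha)
    write_json_file(screen, out("anova_screen.json"))
    add(out("anova_screen.json"))
  })

  run_stage("price", {
    usable <- betas[betas > 0 & betas < 1]
    if (length(usable) == 0) rlang::abort("no usable beta in (0, 1)")
    series <- simulate_horizon(usable, config$horizon,
                               seed = config$cohort$seed)
    readr::write_csv(series$daily, out("penalty_series.csv"),
                     progress = FALSE)
    add(out("penalty_series.csv"))
    write_json_file(list(average_rate_pct = as.list(series$average_rate),
                         beta = as.list(usable),
                         horizon = unclass(config$horizon)),
                    out("pricing_summary.json"))
    add(out("pricing_summary.json"))
  })

  manifest <- list(
    seeds = list(cohort = config$cohort$seed, split = config$split$seed,
                 models = vapply(config$models, `[[`, integer(1), "seed")),
    artifacts = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  write_json_file(manifest, out("manifest.json"))
  invisible(manifest)
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML key tree with optional blocks `cohort`, `split`, `anova`,
#' `horizon` and `output_dir`, each overriding the corresponding
#' [run_config()] default.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  if (!is.null(raw$cohort)) {
    cfg$cohort <- do.call(cohort_config, raw$cohort)
  }
  if (!is.null(raw$split)) cfg$split <- do.call(split_config, raw$split)
  if (!is.null(raw$anova$factors)) cfg$anova_factors <- raw$anova$factors
  if (!is.null(raw$anova$alpha)) cfg$anova_alpha <- raw$anova$alpha
  if (!is.null(raw$horizon)) cfg$horizon <- do.call(horizon_config, raw$horizon)
  if (!is.null(raw$output_dir)) cfg$output_dir <- raw$output_dir
  cfg
}
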