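#' Cohort table schema
#'
#' Ordered column names and semantic types of the on-disk cohort table:
#' the 13 appointment covariates plus the binary outcome. Dates are
#' ISO-8601, binary covariates 0/1 integers, the outcome one of
#' `"show_up"` / `"no_show"` (show-up is the positive class).
#'
#' @return Named character vector mapping column name to type, one of
#'   `"date"`, `"integer"`, `"binary"`, `"category"`, `"outcome"`.
#' @export
cohort_schema <- function() {
  c(date = "date", weekend_flag = "binary", age = "integer",
    gender = "category", own_vehicle = "binary", companion = "binary",
    insurance = "binary", sms_received = "binary", health_issue = "binary",
    treatment_change = "binary", department = "category",
    citizen = "binary", location_id = "integer", outcome = "outcome")
}

#' Write a cohort table to CSV
#'
#' Writes the schema columns (dropping generator-internal columns such as
#' `show_prob`) as UTF-8 RFC-4180 CSV with a header row. The written file
#' round-trips losslessly through [read_cohort()].
#'
#' @param cohort A cohort tibble conforming to [cohort_schema()].
#' @param path Output file path.
#' @param metadata Optional named list (seed, config, ...) written as a
#'   JSON sidecar at `<path>.meta.json` together with a content hash.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, metadata = NULL) {
  cols <- names(cohort_schema())
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  readr::write_csv(cohort[cols], path, progress = FALSE)
  if (!is.null(metadata)) {
    meta <- c(metadata, list(md5 = unname(tools::md5sum(path))))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

schema_abort <- function(msg) rlang::abort(msg, class = "cohort_schema_error")

#' Read and validate a cohort table
#'
#' Reads a CSV written by [write_cohort()] and validates it against
#' [cohort_schema()]: all columns present, binary columns in {0, 1},
#' department among the nine known labels, outcome one of
#' `"show_up"` / `"no_show"`, and the weekend flag consistent with the
#' date. Violations raise a `cohort_schema_error` naming the offending
#' column and (where applicable) the first offending row.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) schema_abort(paste0("no such file: ", path))
  sch <- cohort_schema()
  col_types <- readr::cols(
    date = readr::col_date(), gender = readr::col_character(),
    department = readr::col_character(), outcome = readr::col_character(),
    .default = readr::col_integer())
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(names(sch), names(df))
  if (length(missing) > 0) {
    schema_abort(paste0("missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df <- df[names(sch)]
  if (nrow(df) == 0) return(df)

  check_levels <- function(col, allowed) {
    bad <- which(!(df[[col]] %in% allowed))
    if (length(bad) > 0) {
      schema_abort(paste0("column '", col, "': invalid value '",
                          df[[col]][bad[1]], "' at row ", bad[1]))
    }
  }
  for (col in names(sch)[sch == "binary"]) check_levels(col, c(0L, 1L))
  check_levels("gender", c("female", "male"))
  check_levels("department", department_levels())
  check_levels("outcome", c("show_up", "no_show"))
  if (anyNA(df$date)) schema_abort("column 'date': unparseable date")
  if (any(df$age < 0, na.rm = TRUE)) schema_abort("column 'age': negative age")
  bad_wk <- which(df$weekend_flag != is_weekend(df$date))
  if (length(bad_wk) > 0) {
    schema_abort(paste0("column 'weekend_flag': inconsistent with date at row ",
                        bad_wk[1]))
  }
  df
}

#' Map the outcome column to 0/1
#'
#' @param outcome Character vector of `"show_up"` / `"no_show"`.
#' @return Integer vector; show-up (the positive class) is 1.
#' @export
outcome_to_binary <- function(outcome) {
  as.integer(outcome == "show_up")
}
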