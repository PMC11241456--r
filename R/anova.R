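# Build the ANOVA/model design columns from a cohort table. The date
# enters as its 1-df seasonal sine score; department and residence zone as
# factors; everything else as numeric.
anova_frame <- function(cohort, factors) {
  unknown <- setdiff(factors, covariate_names())
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown factor(s): ", paste(unknown, collapse = ", ")))
  }
  cols <- lapply(factors, function(f) {
    switch(f,
           date = season_score(cohort$date),
           gender = factor(cohort$gender),
           department = factor(cohort$department),
           location_id = factor(cohort$location_id),
           cohort[[f]])
  })
  names(cols) <- factors
  as.data.frame(cols, check.names = FALSE)
}

#' Regression analysis of variance of attendance factors
#'
#' Fits a linear probability model of the 0/1 show-up outcome on the
#' requested covariates and reports, per model term, the adjusted
#' (Type-III / partial) sum of squares — the SS increase from dropping
#' that term from the full model — with the partial F test against the
#' residual mean square. An overall `Regression` row and the `Error`
#' (residual) row complete the table.
#'
#' @param cohort A cohort tibble (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param outcome Name of the outcome column (default `"outcome"`).
#' @param factors Covariates to include (default all 13).
#' @return A tibble with columns `source`, `df`, `adj_ss`, `adj_ms`,
#'   `f_value`, `p_value`.
#' @export
regression_anova <- function(cohort, outcome = "outcome",
                             factors = covariate_names()) {
  y <- outcome_to_binary(cohort[[outcome]])
  df <- anova_frame(cohort, factors)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    rlang::abort(paste0("rank-deficient model; aliased term(s): ",
                        paste(unique(bad), collapse = ", ")))
  }
  n <- nrow(df)
  df_res <- fit$df.residual
  if (df_res < 1) rlang::abort("no residual degrees of freedom")
  ss_res <- sum(stats::resid(fit)^2)
  ms_res <- ss_res / df_res
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- n - 1 - df_res

  d1 <- stats::drop1(fit, scope = stats::formula(fit), test = "F")
  terms <- rownames(d1)[-1]
  rows <- tibble::tibble(
    source = terms,
    df = as.integer(d1$Df[-1]),
    adj_ss = d1$`Sum of Sq`[-1],
    f_value = d1$`F value`[-1],
    p_value = d1$`Pr(>F)`[-1])
  rows$adj_ms <- rows$adj_ss / rows$df

  out <- dplyr::bind_rows(
    tibble::tibble(source = "Regression", df = as.integer(df_mod),
                   adj_ss = ss_mod, adj_ms = ss_mod / df_mod,
                   f_value = (ss_mod / df_mod) / ms_res,
                   p_value = stats::pf((ss_mod / df_mod) / ms_res,
                                       df_mod, df_res, lower.tail = FALSE)),
    rows,
    tibble::tibble(source = "Error", df = as.integer(df_res),
                   adj_ss = ss_res, adj_ms = ms_res,
                   f_value = NA_real_, p_value = NA_real_))
  out[c("source", "df", "adj_ss", "adj_ms", "f_value", "p_value")]
}

#' Screen ANOVA rows for statistical significance
#'
#' Partitions factor rows by the rule "significant iff p <= alpha";
#' summary rows (`Regression`, `Error`) are ignored.
#'
#' @param rows Output of [regression_anova()].
#' @param alpha Significance level in `(0, 1)`, default 0.05. A p-value
#'   exactly equal to `alpha` counts as significant.
#' @return List with character vectors `significant` and
#'   `non_significant`.
#' @export
significance_screen <- function(rows, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie in (0, 1)")
  }
  if (nrow(rows) == 0) rlang::abort("rows must be non-empty")
  fac <- rows[!(rows$source %in% c("Regression", "Error")), ]
  list(significant = fac$source[fac$p_value <= alpha],
       non_significant = fac$source[fac$p_value > alpha])
}
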