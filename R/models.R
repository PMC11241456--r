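# ---- feature encoding ------------------------------------------------------

# One-hot for department (fixed 9 levels) and residence zone (levels seen at
# training time); numeric passthrough for everything else. The calendar date
# contributes both a raw day number and its seasonal sine score.
build_encoder <- function(cohort) {
  structure(list(locations = sort(unique(cohort$location_id))),
            class = "cohort_encoder")
}

encode_features <- function(cohort, encoder) {
  unseen <- setdiff(unique(cohort$location_id), encoder$locations)
  if (length(unseen) > 0) {
    rlang::abort(paste0("unseen location_id level(s) at predict time: ",
                        paste(utils::head(unseen, 5), collapse = ", ")),
                 class = "encoding_error")
  }
  dept <- outer(cohort$department, department_levels(), `==`) * 1
  colnames(dept) <- paste0("dept_", seq_len(9))
  loc <- outer(cohort$location_id, encoder$locations, `==`) * 1
  colnames(loc) <- paste0("loc_", encoder$locations)
  X <- cbind(
    date_num = as.numeric(cohort$date),
    season = season_score(cohort$date),
    weekend_flag = cohort$weekend_flag,
    age = cohort$age,
    female = as.integer(cohort$gender == "female"),
    own_vehicle = cohort$own_vehicle,
    companion = cohort$companion,
    insurance = cohort$insurance,
    sms_received = cohort$sms_received,
    health_issue = cohort$health_issue,
    treatment_change = cohort$treatment_change,
    citizen = cohort$citizen,
    dept, loc)
  storage.mode(X) <- "double"
  X
}

resolve_mtry <- function(max_features, p) {
  if (is.na(max_features) || is.null(max_features)) return(p)
  if (is.character(max_features)) {
    return(switch(max_features,
                  sqrt = max(1L, ceiling(sqrt(p))),
                  log2 = max(1L, floor(log2(p))),
                  rlang::abort("max_features must be 'sqrt', 'log2' or a count")))
  }
  max(1L, min(as.integer(max_features), p))
}

cart_depth <- function(max_depth) {
  if (is.null(max_depth) || is.na(max_depth)) -1L else as.integer(max_depth)
}

# ---- the three ensembles ---------------------------------------------------

fit_rf <- function(X, y, n_estimators = 100, max_features = "sqrt",
                   max_depth = NA, min_samples_split = 2) {
  n <- nrow(X)
  mtry <- resolve_mtry(max_features, ncol(X))
  trees <- lapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .cart_fit(X[idx, , drop = FALSE], y[idx], rep(1, n),
              cart_depth(max_depth), as.integer(min_samples_split), 1L, mtry)
  })
  structure(list(algorithm = "RF", trees = trees), class = "noshow_model")
}

fit_gb <- function(X, y, n_estimators = 100, learning_rate = 0.1,
                   max_depth = 3, subsample = 1.0) {
  n <- nrow(X)
  pbar <- min(max(mean(y), 1e-10), 1 - 1e-10)
  f0 <- log(pbar / (1 - pbar))
  fx <- rep(f0, n)
  trees <- vector("list", n_estimators)
  for (m in seq_len(n_estimators)) {
    p <- stats::plogis(fx)
    r <- y - p
    idx <- if (subsample < 1) {
      sample.int(n, max(2L, floor(subsample * n)))
    } else seq_len(n)
    tr <- .cart_fit(X[idx, , drop = FALSE], r[idx], rep(1, length(idx)),
                    cart_depth(max_depth), 2L, 1L, ncol(X))
    # one Newton step per leaf on the fitted subsample
    leaf_sub <- .cart_predict(tr, X[idx, , drop = FALSE])$leaf
    num <- tapply(r[idx], leaf_sub, sum)
    den <- tapply(p[idx] * (1 - p[idx]), leaf_sub, sum)
    gamma <- num / pmax(den, 1e-10)
    leaf_all <- .cart_predict(tr, X)$leaf
    step <- as.numeric(gamma[as.character(leaf_all)])
    step[is.na(step)] <- 0  # leaves unseen in the subsample (cannot occur
                            # when idx spans the tree's own training rows)
    fx <- fx + learning_rate * step
    trees[[m]] <- list(tree = tr, gamma = gamma)
  }
  structure(list(algorithm = "GB", f0 = f0, learning_rate = learning_rate,
                 trees = trees), class = "noshow_model")
}

fit_ab <- function(X, y, n_estimators = 50, learning_rate = 1.0) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tr <- .cart_fit(X, y, w, 1L, 2L, 1L, ncol(X))
    pred <- as.integer(.cart_predict(tr, X)$value >= 0.5)
    err <- sum(w[pred != y]) / sum(w)
    if (err <= 0) {         # perfect stump dominates the vote
      stumps <- c(stumps, list(tr))
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break   # no better than chance: stop boosting
    a <- learning_rate * log((1 - err) / err)
    stumps <- c(stumps, list(tr))
    alphas <- c(alphas, a)
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {  # degenerate: fall back to the prior
    structure(list(algorithm = "AB", stumps = list(), alphas = numeric(0),
                   prior = mean(y)), class = "noshow_model")
  } else {
    structure(list(algorithm = "AB", stumps = stumps, alphas = alphas,
                   prior = mean(y)), class = "noshow_model")
  }
}

#' Predict show-up scores from a fitted ensemble
#'
#' @param object A fitted model from [fit_predict()] internals.
#' @param X Encoded feature matrix.
#' @param ... Unused.
#' @return Numeric show-up scores in `[0, 1]`.
#' @keywords internal
predict_scores <- function(object, X) {
  switch(object$algorithm,
    RF = {
      preds <- vapply(object$trees,
                      function(tr) .cart_predict(tr, X)$value,
                      numeric(nrow(X)))
      if (nrow(X) == 1) mean(preds) else rowMeans(preds)
    },
    GB = {
      fx <- rep(object$f0, nrow(X))
      for (t in object$trees) {
        leaf <- .cart_predict(t$tree, X)$leaf
        step <- as.numeric(t$gamma[as.character(leaf)])
        step[is.na(step)] <- 0
        fx <- fx + object$learning_rate * step
      }
      stats::plogis(fx)
    },
    AB = {
      if (length(object$stumps) == 0) return(rep(object$prior, nrow(X)))
      votes <- vapply(object$stumps,
                      function(tr) as.numeric(.cart_predict(tr, X)$value >= 0.5),
                      numeric(nrow(X)))
      if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
      # weighted vote share for show-up: in [0, 1], 0.5 = tied vote
      as.numeric(votes %*% object$alphas) / sum(object$alphas)
    },
    rlang::abort("unknown algorithm"))
}

# ---- specs, split, tuning, fit/predict -------------------------------------

default_grid <- function(algorithm) {
  switch(algorithm,
    RF = list(n_estimators = c(100, 300, 500),
              max_features = c("sqrt", "log2"),
              max_depth = c(NA, 5, 10),
              min_samples_split = c(2, 5, 10)),
    GB = list(n_estimators = c(100, 300),
              learning_rate = c(0.01, 0.1, 0.3),
              max_depth = c(2, 3, 5),
              subsample = c(0.7, 1.0)),
    AB = list(n_estimators = c(50, 100, 300),
              learning_rate = c(0.5, 1.0)))
}

grid_keys <- function(algorithm) {
  switch(algorithm,
    RF = c("n_estimators", "max_features", "max_depth", "min_samples_split"),
    GB = c("n_estimators", "learning_rate", "max_depth", "subsample"),
    AB = c("n_estimators", "learning_rate"))
}

#' Model and tuning specification
#'
#' @param algorithm One of `"RF"` (random forest), `"GB"` (gradient
#'   boosting) or `"AB"` (AdaBoost).
#' @param grid Named list of candidate hyperparameter values; keys are
#'   restricted per algorithm to the standard tuning set (`n_estimators`,
#'   `max_features`, `max_depth`, `min_samples_split` for RF;
#'   `n_estimators`, `learning_rate`, `max_depth`, `subsample` for GB;
#'   `n_estimators`, `learning_rate` for AB).
#' @param cv_folds Number of stratified CV folds (>= 2, default 5).
#' @param scoring Tuning metric, `"ca"` (default) or `"auc"`.
#' @param seed Integer seed governing fold assignment and fitting.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("RF", "GB", "AB"), grid = NULL,
                       cv_folds = 5L, scoring = c("ca", "auc"), seed = 42L) {
  algorithm <- match.arg(algorithm)
  scoring <- match.arg(scoring)
  if (is.null(grid)) grid <- default_grid(algorithm)
  bad <- setdiff(names(grid), grid_keys(algorithm))
  if (length(bad) > 0) {
    rlang::abort(paste0("invalid ", algorithm, " hyperparameter(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    rlang::abort("grid must be non-empty")
  }
  if (cv_folds < 2) rlang::abort("cv_folds must be >= 2")
  structure(list(algorithm = algorithm, grid = grid,
                 cv_folds = as.integer(cv_folds), scoring = scoring,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Train/test split settings
#'
#' @param test_fraction Fraction of rows held out, in `(0, 1)`.
#' @param stratify Preserve the outcome class mix (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.3, stratify = TRUE, seed = 42L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("test_fraction must lie in (0, 1)")
  }
  structure(list(test_fraction = test_fraction, stratify = isTRUE(stratify),
                 seed = as.integer(seed)),
            class = "split_config")
}

# Largest-remainder allocation of the test count across classes, so the
# overall test size is exactly round(n * f) and each class is within one
# count of its proportional share.
allocate_counts <- function(class_sizes, n_test) {
  exact <- class_sizes * n_test / sum(class_sizes)
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, class_sizes, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified train/test split
#'
#' Splits a cohort into disjoint, exhaustive train and test sets. With
#' stratification the test set carries each outcome class within one count
#' of its cohort proportion; the overall test size is exactly
#' `round(n * test_fraction)`. Seed-reproducible.
#'
#' @param cohort A cohort tibble containing both outcome classes.
#' @param split A [split_config()].
#' @return List with `train` and `test` tibbles and the `test_idx` rows.
#' @export
stratified_split <- function(cohort, split = split_config()) {
  y <- cohort$outcome
  if (length(unique(y)) < 2) {
    rlang::abort("cohort must contain both outcome classes")
  }
  n <- nrow(cohort)
  n_test <- round(n * split$test_fraction)
  if (n_test < 1 || n_test >= n) rlang::abort("degenerate split size")
  test_idx <- withr::with_seed(split$seed, {
    if (split$stratify) {
      sizes <- table(y)
      counts <- allocate_counts(as.numeric(sizes), n_test)
      unlist(lapply(seq_along(sizes), function(k) {
        rows <- which(y == names(sizes)[k])
        sample(rows, counts[k])
      }), use.names = FALSE)
    } else {
      sample.int(n, n_test)
    }
  })
  test_idx <- sort(test_idx)
  list(train = cohort[-test_idx, ], test = cohort[test_idx, ],
       test_idx = test_idx)
}

fit_algorithm <- function(algorithm, X, y, params) {
  args <- c(list(X = X, y = y), params)
  switch(algorithm,
         RF = do.call(fit_rf, args),
         GB = do.call(fit_gb, args),
         AB = do.call(fit_ab, args))
}

score_predictions <- function(scoring, y, scores) {
  if (scoring == "auc") {
    roc_auc(scores, y)$auc
  } else {
    mean((scores >= 0.5) == (y == 1))
  }
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    fold[rows] <- sample(rep(seq_len(k), length.out = length(rows)))
  }
  fold
}

#' Cross-validated hyperparameter search
#'
#' Exhaustively evaluates the spec's grid by stratified k-fold
#' cross-validation on the training set and returns the configuration with
#' the highest mean score; ties break to the first configuration in
#' enumeration order (the grid's cross product with the first key varying
#' fastest). A fold whose training part contains a single class marks the
#' configuration as failed: it is logged with a warning and excluded.
#'
#' @param spec A [model_spec()].
#' @param train Training cohort tibble.
#' @return List with `best_params` (named list), `best_score`, and
#'   `results` (one row per configuration with per-fold and mean scores).
#' @export
tune_model <- function(spec, train) {
  configs <- expand.grid(spec$grid, stringsAsFactors = FALSE)
  y <- outcome_to_binary(train$outcome)
  encoder <- build_encoder(train)
  X <- encode_features(train, encoder)
  k <- spec$cv_folds

  withr::with_seed(spec$seed, {
    fold <- stratified_folds(y, k)
    fold_scores <- matrix(NA_real_, nrow(configs), k)
    status <- rep("ok", nrow(configs))
    for (ci in seq_len(nrow(configs))) {
      params <- as.list(configs[ci, , drop = FALSE])
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
          status[ci] <- "failed"
          rlang::warn(paste0("configuration ", ci,
                             ": single-class fold, excluded"))
          break
        }
        fit <- fit_algorithm(spec$algorithm, X[tr, , drop = FALSE],
                             y[tr], params)
        s <- predict_scores(fit, X[!tr, , drop = FALSE])
        fold_scores[ci, f] <- score_predictions(spec$scoring, y[!tr], s)
      }
    }
    mean_score <- rowMeans(fold_scores)
    mean_score[status == "failed"] <- NA_real_
    if (all(is.na(mean_score))) {
      rlang::abort("all configurations failed cross-validation")
    }
    best <- which.max(mean_score)  # first index wins ties
    results <- tibble::as_tibble(configs)
    colnames(fold_scores) <- paste0("fold_", seq_len(k))
    results <- dplyr::bind_cols(results, tibble::as_tibble(fold_scores))
    results$mean_score <- mean_score
    results$status <- status
    list(best_params = as.list(configs[best, , drop = FALSE]),
         best_score = mean_score[best],
         results = results)
  })
}

#' Fit a tuned model and predict both phases
#'
#' Fits the spec's algorithm with `best_params` on the full training set
#' and emits per-phase predictions: show-up scores in `[0, 1]` and labels
#' obtained by thresholding the scores at 0.5. Seed-reproducible; an
#' unseen categorical level at predict time raises an `encoding_error`.
#'
#' @param spec A [model_spec()].
#' @param best_params Named list of hyperparameters (e.g. from
#'   [tune_model()]).
#' @param train,test Cohort tibbles.
#' @return List with `predictions` (tibble: `row_id`, `phase`, `actual`,
#'   `predicted`, `score`) and the fitted `model`.
#' @export
fit_predict <- function(spec, best_params, train, test) {
  encoder <- build_encoder(train)
  X_train <- encode_features(train, encoder)
  X_test <- encode_features(test, encoder)
  y_train <- outcome_to_binary(train$outcome)
  model <- withr::with_seed(spec$seed, {
    fit_algorithm(spec$algorithm, X_train, y_train, best_params)
  })
  phase_tbl <- function(phase, cohort, X) {
    s <- predict_scores(model, X)
    tibble::tibble(row_id = seq_len(nrow(cohort)), phase = phase,
                   actual = cohort$outcome,
                   predicted = ifelse(s >= 0.5, "show_up", "no_show"),
                   score = s)
  }
  preds <- dplyr::bind_rows(phase_tbl("train", train, X_train),
                            phase_tbl("test", test, X_test))
  list(predictions = preds, model = model, encoder = encoder)
}
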