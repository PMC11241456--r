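#' Confusion matrix counts
#'
#' Constructs the TP/TN/FP/FN counts with show-up as the positive class:
#' `tp` counts records that are actual show-up and predicted show-up.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) rlang::abort("confusion counts must be non-negative")
  if (sum(counts) < 1) rlang::abort("confusion matrix must contain at least one sample")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(actual = c("no_show", "show_up"),
                              predicted = c("no_show", "show_up")))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$tp + cm$tn + cm$fp + cm$fn

#' Tally a confusion matrix from label vectors
#'
#' @param actual,predicted Equal-length binary vectors (1 = show-up) or
#'   character vectors of `"show_up"` / `"no_show"`.
#' @return A [confusion_matrix()].
#' @export
#' @examples
#' confusion_from_labels(c(1, 1, 0, 0), c(1, 1, 0, 0))
confusion_from_labels <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    rlang::abort("actual and predicted must have equal length")
  }
  to01 <- function(x) {
    if (is.character(x) || is.factor(x)) outcome_to_binary(as.character(x))
    else as.integer(x)
  }
  a <- to01(actual); p <- to01(predicted)
  if (!all(c(a, p) %in% c(0L, 1L))) rlang::abort("labels must be binary")
  confusion_matrix(tp = sum(a == 1 & p == 1), tn = sum(a == 0 & p == 0),
                   fp = sum(a == 0 & p == 1), fn = sum(a == 1 & p == 0))
}

#' Classification accuracy
#'
#' Ratio of correctly classified samples to the total sample count.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
classification_accuracy <- function(cm) {
  (cm$tp + cm$tn) / cm_total(cm)
}

# Ratio with the zero-denominator policy: 0 plus a warning, so batch
# evaluation never aborts on a degenerate margin.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    rlang::warn(paste0(what, ": zero denominator, returning 0"))
    return(0)
  }
  num / den
}

per_class_weighted <- function(pos, neg, cm) {
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$tn + cm$fp
  list(show_up = pos, no_show = neg,
       weighted = (n_pos * pos + n_neg * neg) / cm_total(cm))
}

#' Precision (positive predictive value), per class and support-weighted
#'
#' Show-up precision is `tp / (tp + fp)`; the no-show class mirrors it as
#' `tn / (tn + fn)`. The weighted value averages the two with the actual
#' class sizes as weights, the convention under which a single printed
#' value per metric summarises both classes.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `show_up`, `no_show` and `weighted` components.
#' @export
precision <- function(cm) {
  per_class_weighted(safe_ratio(cm$tp, cm$tp + cm$fp, "precision(show_up)"),
                     safe_ratio(cm$tn, cm$tn + cm$fn, "precision(no_show)"),
                     cm)
}

#' Recall (sensitivity), per class and support-weighted
#'
#' Show-up recall is `tp / (tp + fn)`. The support-weighted recall always
#' equals the classification accuracy.
#'
#' @inheritParams precision
#' @return List with `show_up`, `no_show` and `weighted` components.
#' @export
recall <- function(cm) {
  per_class_weighted(safe_ratio(cm$tp, cm$tp + cm$fn, "recall(show_up)"),
                     safe_ratio(cm$tn, cm$tn + cm$fp, "recall(no_show)"),
                     cm)
}

#' F1 score, per class and support-weighted
#'
#' Harmonic mean of precision and recall per class; 0 when both are 0.
#'
#' @inheritParams precision
#' @return List with `show_up`, `no_show` and `weighted` components.
#' @export
f1_score <- function(cm) {
  p <- precision(cm); r <- recall(cm)
  h <- function(pp, rr) if (pp + rr == 0) 0 else 2 * pp * rr / (pp + rr)
  per_class_weighted(h(p$show_up, r$show_up), h(p$no_show, r$no_show), cm)
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in `[-1, 1]`.
#' A zero margin makes the denominator 0; the value is then reported as 0
#' with a warning.
#'
#' @inheritParams precision
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  # doubles: the four-margin product overflows 32-bit integers at n ~ 10^3
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) {
    rlang::warn("mcc: zero margin, returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Predicted-column rates of a confusion matrix
#'
#' Normalises each predicted-class column to 1: `alpha` is the fraction of
#' predicted no-shows that are actual no-shows, `beta` the fraction of
#' predicted show-ups that actually attend (the positive predictive value
#' of show-up predictions). `beta` is the show-up rate the pricing model
#' consumes.
#'
#' @inheritParams precision
#' @return List with `alpha`, `beta` and their complements.
#' @export
#' @examples
#' column_rates(confusion_matrix(tp = 116, tn = 90, fp = 3, fn = 5))$alpha
column_rates <- function(cm) {
  if (cm$tn + cm$fn == 0 || cm$tp + cm$fp == 0) {
    rlang::abort("column_rates: empty predicted column")
  }
  alpha <- cm$tn / (cm$tn + cm$fn)
  beta <- cm$tp / (cm$tp + cm$fp)
  list(alpha = alpha, beta = beta,
       one_minus_alpha = 1 - alpha, one_minus_beta = 1 - beta)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (grouping tied scores), producing the curve
#' of (1 - specificity, sensitivity) from (0, 0) to (1, 1); the AUC is the
#' trapezoidal area under it, which for tied-score grouping equals the
#' Mann-Whitney rank statistic `U / (n_pos * n_neg)`.
#'
#' @param scores Numeric show-up scores.
#' @param labels Binary labels (1 = show-up) or `"show_up"`/`"no_show"`.
#' @return List with `curve` (tibble of fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.character(labels) || is.factor(labels)) {
    outcome_to_binary(as.character(labels))
  } else as.integer(labels)
  if (length(scores) != length(y)) rlang::abort("length mismatch")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) rlang::abort("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  # group tied scores so the curve has one vertex per distinct threshold
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tpr <- c(0, cumsum(y == 1)[last_of_group] / n_pos, 1)
  fpr <- c(0, cumsum(y == 0)[last_of_group] / n_neg, 1)
  thr <- c(Inf, s[last_of_group], -Inf)
  keep <- !duplicated(cbind(fpr, tpr))
  curve <- tibble::tibble(threshold = thr[keep], fpr = fpr[keep],
                          tpr = tpr[keep])
  auc <- sum(diff(curve$fpr) *
               (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Calibration curve (reliability diagram)
#'
#' Bins scores into `n_bins` equal-width bins on `[0, 1]` and reports, per
#' non-empty bin, the mean score, the empirical show-up fraction and the
#' bin count.
#'
#' @inheritParams roc_auc
#' @param n_bins Number of equal-width bins (>= 2).
#' @return Tibble with columns `bin`, `mean_score`, `frac_positive`, `n`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  if (n_bins < 2) rlang::abort("n_bins must be >= 2")
  y <- if (is.character(labels) || is.factor(labels)) {
    outcome_to_binary(as.character(labels))
  } else as.integer(labels)
  if (any(scores < 0 | scores > 1)) rlang::abort("scores must lie in [0, 1]")
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, s = scores, y = y), .data$bin),
    mean_score = mean(.data$s), frac_positive = mean(.data$y),
    n = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$bin)
}

#' Full metric report for one prediction set
#'
#' AUC, classification accuracy and the support-weighted F1, precision,
#' recall and MCC for one model/phase — one row of the standard
#' performance table.
#'
#' @param actual,predicted Label vectors as in [confusion_from_labels()].
#' @param scores Show-up scores in `[0, 1]` (needed for AUC; omit to get
#'   `NA` there).
#' @return A one-row tibble with columns `auc`, `ca`, `f1`, `precision`,
#'   `recall`, `mcc`.
#' @export
metric_report <- function(actual, predicted, scores = NULL) {
  cm <- confusion_from_labels(actual, predicted)
  tibble::tibble(
    auc = if (is.null(scores)) NA_real_ else roc_auc(scores, actual)$auc,
    ca = classification_accuracy(cm),
    f1 = f1_score(cm)$weighted,
    precision = precision(cm)$weighted,
    recall = recall(cm)$weighted,
    mcc = mcc(cm))
}
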