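# Independent naive-loop oracles for the metric suite. Deliberately written
# as literal formula transcriptions with explicit loops, sharing no code
# with the implementation they check.

oracle_counts <- function(actual, predicted) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(actual)) {
    if (actual[i] == 1 && predicted[i] == 1) tp <- tp + 1L
    if (actual[i] == 0 && predicted[i] == 0) tn <- tn + 1L
    if (actual[i] == 0 && predicted[i] == 1) fp <- fp + 1L
    if (actual[i] == 1 && predicted[i] == 0) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  n <- tp + tn + fp + fn
  ca <- (tp + tn) / n
  prec_pos <- tp / (tp + fp)
  prec_neg <- tn / (tn + fn)
  rec_pos <- tp / (tp + fn)
  rec_neg <- tn / (tn + fp)
  f1_pos <- 2 * prec_pos * rec_pos / (prec_pos + rec_pos)
  f1_neg <- 2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  w_pos <- (tp + fn) / n
  w_neg <- (tn + fp) / n
  mcc <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(ca = ca,
       precision = w_pos * prec_pos + w_neg * prec_neg,
       recall = w_pos * rec_pos + w_neg * rec_neg,
       f1 = w_pos * f1_pos + w_neg * f1_neg,
       mcc = mcc,
       alpha = tn / (tn + fn),
       beta = tp / (tp + fp))
}

# Random confusion matrices with non-degenerate margins.
random_cm <- function() {
  repeat {
    counts <- stats::rpois(4, lambda = sample(c(5, 20, 80), 1)) + c(1, 1, 0, 0)
    cm <- list(tp = counts[1], tn = counts[2], fp = counts[3], fn = counts[4])
    if ((cm$tp + cm$fp) > 0 && (cm$tp + cm$fn) > 0 &&
        (cm$tn + cm$fp) > 0 && (cm$tn + cm$fn) > 0) {
      return(cm)
    }
  }
}

# Expand confusion counts into actual/predicted label vectors (show_up = 1).
labels_from_counts <- function(tp, tn, fp, fn) {
  list(actual = c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn)),
       predicted = c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn)))
}

# The printed test-phase confusion counts of the three classifiers.
table6_counts <- function() {
  list(RF = c(tp = 116, tn = 90, fp = 3, fn = 5),
       GB = c(tp = 117, tn = 90, fp = 3, fn = 4),
       AB = c(tp = 114, tn = 87, fp = 6, fn = 7))
}

# A small cohort whose outcome copies the SMS flag: trivially separable.
separable_cohort <- function(n = 120, seed = 11) {
  coh <- generate_cohort(cohort_config(n_patients = n, seed = seed,
                                       n_locations = 6))
  coh$outcome <- ifelse(coh$sms_received == 1, "show_up", "no_show")
  if (length(unique(coh$outcome)) < 2) stop("degenerate fixture")
  coh
}
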