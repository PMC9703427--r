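#' Confusion counts for one individual's test window
#'
#' Counts agreement between true and predicted binary states:
#' `TP = #\{s = 1, shat = 1\}`, `FP = #\{s = 0, shat = 1\}`,
#' `FN = #\{s = 1, shat = 0\}`, `TN = #\{s = 0, shat = 0\}`. The four counts
#' always sum to the number of evaluated time points.
#'
#' @param true_states,pred_states equal-length 0/1 vectors.
#' @return Named integer vector `c(tp, fp, fn, tn)` of class `sc_confusion`.
#' @export
confusion_counts <- function(true_states, pred_states) {
  s <- check_binary(true_states, "true_states")
  p <- check_binary(pred_states, "pred_states")
  if (length(s) != length(p)) {
    stop("`true_states` and `pred_states` must have the same length", call. = FALSE)
  }
  structure(c(tp = sum(s == 1L & p == 1L), fp = sum(s == 0L & p == 1L),
              fn = sum(s == 1L & p == 0L), tn = sum(s == 0L & p == 0L)),
            class = "sc_confusion")
}

#' Sensitivity, specificity, precision and F1 from confusion counts
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(fp+tn)`,
#' `precision = tp/(tp+fp)`, `f1 = 2*precision*sensitivity /
#' (precision+sensitivity)`. Any ratio with a zero denominator is undefined
#' and returned as `NA` (a value, not an error); `f1` is `NA` whenever
#' precision or sensitivity is undefined or their sum is zero. Undefined
#' metrics are excluded pairwise from cohort-level statistics downstream.
#'
#' @param counts an `sc_confusion` from [confusion_counts()], or any named
#'   vector/list with `tp`, `fp`, `fn`, `tn`.
#' @return Named numeric vector `c(sensitivity, specificity, precision, f1)`.
#' @export
basic_metrics <- function(counts) {
  counts <- as.list(counts)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- ratio(counts$tp, counts$tp + counts$fn)
  sp <- ratio(counts$tn, counts$fp + counts$tn)
  pre <- ratio(counts$tp, counts$tp + counts$fp)
  f1 <- if (is.na(se) || is.na(pre) || (pre + se) == 0) NA_real_ else
    2 * pre * se / (pre + se)
  c(sensitivity = se, specificity = sp, precision = pre, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) closed form with half credit for ties,
#' which equals the trapezoidal area under the empirical ROC curve
#' (sensitivity against 1 - specificity): the probability that a randomly
#' chosen positive outscores a randomly chosen negative, ties counting 1/2.
#'
#' @param scores numeric scores (higher means more state-1-like).
#' @param true_states equal-length 0/1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.8, 0.7, 0.6, 0.5), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, true_states) {
  s <- check_binary(true_states, "true_states")
  if (length(scores) != length(s)) {
    stop("`scores` and `true_states` must have the same length", call. = FALSE)
  }
  if (anyNA(scores)) stop("`scores` must not contain NA", call. = FALSE)
  n_pos <- sum(s == 1L)
  n_neg <- sum(s == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC is undefined when `true_states` contains a single class",
         call. = FALSE)
  }
  r <- rank(scores)  # average ranks give the tie half-credit
  (sum(r[s == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Per-individual metrics row from a prediction result; undefined metrics
# (single-class test truth, zero denominators) propagate as NA.
metrics_from_prediction <- function(pred) {
  bm <- basic_metrics(confusion_counts(pred$truth, pred$pred))
  auc <- if (length(unique(pred$truth)) < 2) NA_real_ else
    roc_auc(pred$score, pred$truth)
  data.frame(individual_id = pred$id, model = pred$model, gap = pred$gap,
             mode = pred$mode, auc = auc, f1 = bm[["f1"]],
             sensitivity = bm[["sensitivity"]],
             specificity = bm[["specificity"]],
             precision = bm[["precision"]],
             stringsAsFactors = FALSE)
}
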