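#' Area under the ROC curve
#'
#' Computed via the rank statistic: the probability that a uniformly drawn
#' positive outranks a uniformly drawn negative, counting ties as 1/2
#' (equivalent to the Mann-Whitney U normalisation).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 labels (or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_retinamil("single_class", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision with step interpolation: thresholds are placed at each
#' distinct score (descending) and precision is weighted by the recall
#' increment of that step. For constant scores this reduces to the positive
#' prevalence, the PR baseline.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) stop_retinamil("no_positives", "no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cut after each distinct score value
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  n <- seq_along(s)[last]
  prec <- tp / n
  dtp <- diff(c(0, tp))
  sum(dtp * prec) / npos
}

#' Operating point at high sensitivity or high specificity
#'
#' Sweeps all decision thresholds (predict positive when
#' `score >= threshold`) and, among the thresholds whose constrained metric
#' exceeds `level`, returns the one maximising the complementary metric;
#' ties resolve to the lowest threshold.
#'
#' @inheritParams roc_auc
#' @param constraint `"high_sens"` (sensitivity > `level`, maximise
#'   specificity) or `"high_spec"`.
#' @param level Constraint level (default 0.9).
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `constraint`.
#' @export
operating_point <- function(scores, labels,
                            constraint = c("high_sens", "high_spec"),
                            level = 0.9) {
  constraint <- match.arg(constraint)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_retinamil("single_class", "both classes must be present")
  }
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(th) sum(scores >= th & labels == 1) / n1,
                 numeric(1))
  spec <- vapply(thr, function(th) sum(scores < th & labels == 0) / n0,
                 numeric(1))
  ok <- if (constraint == "high_sens") sens > level else spec > level
  if (!any(ok)) {
    stop_retinamil("unattainable",
                   sprintf("no threshold attains %s > %g", constraint, level))
  }
  free <- if (constraint == "high_sens") spec else sens
  cand <- which(ok)
  best <- cand[free[cand] == max(free[cand])]
  pick <- best[which.min(thr[best])]
  tibble(threshold = thr[pick], sensitivity = sens[pick],
         specificity = spec[pick], constraint = constraint)
}

#' Classification report
#'
#' ROC AUC plus both high-sensitivity and high-specificity operating
#' points for a set of scored images.
#'
#' @param data Data frame with a score column and a 0/1 label column.
#' @param score,label Column names.
#' @return A one-row tibble with `auc` and the operating-point metrics.
#' @export
classification_report <- function(data, score = "score", label = "label") {
  s <- data[[score]]; y <- data[[label]]
  hs <- operating_point(s, y, "high_sens")
  hp <- operating_point(s, y, "high_spec")
  tibble(auc = roc_auc(s, y), n = length(s),
         sens_at_high_sens = hs$sensitivity, spec_at_high_sens = hs$specificity,
         sens_at_high_spec = hp$sensitivity, spec_at_high_spec = hp$specificity)
}

#' Aggregate image scores per subject
#'
#' Collapses the two eyes of a subject to one decision score (default: the
#' maximum, the conservative referral rule — refer the patient if either
#' eye looks referable) and the label to the subject-level maximum.
#'
#' @param data Data frame with score, label and subject columns.
#' @param score,label,subject Column names.
#' @param agg Aggregation function for the scores.
#' @return A tibble with one row per subject.
#' @export
aggregate_by_subject <- function(data, score = "score", label = "label",
                                 subject = "subject_id", agg = max) {
  data |>
    dplyr::group_by(.data[[subject]]) |>
    dplyr::summarise(score = agg(.data[[score]]),
                     label = max(.data[[label]]), .groups = "drop")
}
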