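# Evaluation metrics. AUC uses the Mann-Whitney rank form
#   AUC = (sum of positive-class mid-ranks - M(M+1)/2) / (M * N)
# with ascending mid-ranks for tied scores, equal to the probability that
# a random positive outscores a random negative with half credit for
# ties. Sensitivity, precision and F1 classify at a fixed threshold
# (default 0.5); average precision is the step-interpolated area under
# the precision-recall curve.

#' Rank-based AUC
#'
#' @param scores numeric prediction scores.
#' @param labels class labels; positives are `"positive"` or `TRUE`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == "positive" | labels == TRUE
  m <- sum(pos); n <- sum(!pos)
  if (!m || !n)
    stop("AUC undefined: one class is absent (", m, " positive / ", n,
         " negative)", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' Sensitivity (recall) at a classification threshold
#'
#' @inheritParams auc_score
#' @param threshold scores at or above it are classified positive.
#' @return TP / (number of positives).
#' @export
sensitivity_score <- function(scores, labels, threshold = 0.5) {
  pos <- labels == "positive" | labels == TRUE
  if (!sum(pos)) stop("no positive samples", call. = FALSE)
  sum(scores[pos] >= threshold) / sum(pos)
}

#' F1 score at a classification threshold
#'
#' Harmonic mean of precision and sensitivity; 0 by convention when
#' precision + sensitivity is 0 (e.g. nothing predicted positive and no
#' positive found).
#'
#' @inheritParams sensitivity_score
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pos <- labels == "positive" | labels == TRUE
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  p <- if (tp + fp) tp / (tp + fp) else 0
  s <- if (sum(pos)) tp / sum(pos) else 0
  if (p + s == 0) return(0)
  2 * p * s / (p + s)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step summation over descending-score thresholds:
#' `sum_k (R_k - R_{k-1}) * P_k` at each rank k, i.e. the mean precision
#' at the positions of the positives (no 11-point interpolation). Tied
#' scores are broken by original position for a deterministic ordering.
#'
#' @inheritParams auc_score
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  pos <- labels == "positive" | labels == TRUE
  if (!sum(pos)) stop("no positive samples", call. = FALSE)
  o <- order(-scores, seq_along(scores))
  hit <- pos[o]
  prec_at <- cumsum(hit) / seq_along(hit)
  sum(prec_at[hit]) / sum(hit)
}

#' All four evaluation metrics at once
#'
#' @inheritParams sensitivity_score
#' @return named numeric vector `auc`, `sensitivity`, `f1`, `ap`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  c(auc = auc_score(scores, labels),
    sensitivity = sensitivity_score(scores, labels, threshold),
    f1 = f1_score(scores, labels, threshold),
    ap = average_precision(scores, labels))
}

#' Paired two-sided t test between per-repeat metric series
#'
#' Operates on the per-repeat differences of two model variants evaluated
#' on shared splits. Degenerate inputs (zero-variance differences) cannot
#' produce a t statistic: identical series return p = 1, a constant
#' non-zero difference returns p = NA, both flagged via `degenerate`.
#'
#' @param a,b numeric metric series of equal length (one value per
#'   repeat).
#' @return list with `statistic`, `p_value`, `mean_difference`,
#'   `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  degenerate_result <- function()
    list(statistic = NA_real_,
         p_value = if (all(d == 0)) 1 else NA_real_,
         mean_difference = mean(d), degenerate = TRUE)
  if (sd(d) == 0) return(degenerate_result())
  tt <- tryCatch(t.test(a, b, paired = TRUE),
                 error = function(e) NULL)  # essentially-constant data
  if (is.null(tt)) return(degenerate_result())
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}

# mean +/- t-based 95% CI half-width over repeats
ci_summary <- function(x, level = 0.95) {
  n <- length(x)
  half <- if (n > 1 && sd(x) > 0)
    qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n) else 0
  c(mean = mean(x), ci = half)
}
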