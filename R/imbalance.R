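# Class-imbalance handling on the derivation set: random undersampling
# of the majority class, random oversampling of the minority class, or
# cost-sensitive boosting (positive-class weight = n_neg / n_pos).
# Resampling operates on sample indices, never on matrices, so one
# featurization serves every strategy; the validation set is never
# resampled.

#' Resampling specification
#'
#' @param strategy one of `"undersample"`, `"oversample"`,
#'   `"cost_sensitive"`, `"none"`.
#' @param ratio target positive:negative proportion as a pair of positive
#'   integers, e.g. `c(1, 2)` for 1:2. Ignored by `"cost_sensitive"` and
#'   `"none"`.
#' @param seed integer seed making the resampled index reproducible.
#' @return object of class `resample_spec`.
#' @export
resample_spec <- function(strategy = c("undersample", "oversample",
                                       "cost_sensitive", "none"),
                          ratio = c(1, 1), seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(length(ratio) == 2, all(ratio >= 1),
            all(ratio == as.integer(ratio)))
  structure(list(strategy = strategy, ratio = as.integer(ratio),
                 seed = as.integer(seed)),
            class = "resample_spec")
}

#' Randomly undersample the majority class
#'
#' Keeps every minority-class sample and reduces the majority class by
#' uniform sampling without replacement until the positive:negative
#' ratio is met (rounded down). If the ratio asks for more majority
#' samples than exist, all samples are kept and a warning is raised —
#' undersampling never drops minority samples to force a ratio.
#'
#' @param labels character/logical vector of class labels; positives are
#'   `"positive"` or `TRUE`.
#' @param spec a [resample_spec()].
#' @return integer vector of retained indices (original order preserved).
#' @export
undersample <- function(labels, spec) {
  stopifnot(inherits(spec, "resample_spec"))
  pos <- which(labels == "positive" | labels == TRUE)
  neg <- which(labels == "negative" | labels == FALSE)
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty", call. = FALSE)
  if (length(pos) <= length(neg)) {
    minority <- pos; majority <- neg
    target <- floor(length(pos) * spec$ratio[2] / spec$ratio[1])
  } else {
    minority <- neg; majority <- pos
    target <- floor(length(neg) * spec$ratio[1] / spec$ratio[2])
  }
  if (target > length(majority)) {
    warning("requested ratio needs more majority samples than exist; ",
            "keeping all", call. = FALSE)
    return(seq_along(labels))
  }
  set.seed(spec$seed)
  sort(c(minority, sample(majority, target)))
}

#' Randomly oversample the minority class
#'
#' Keeps every original sample and duplicates minority-class samples
#' uniformly with replacement until the ratio is met (rounded down).
#'
#' @inheritParams undersample
#' @return integer index vector: all original indices followed by the
#'   duplicated ones.
#' @export
oversample <- function(labels, spec) {
  stopifnot(inherits(spec, "resample_spec"))
  pos <- which(labels == "positive" | labels == TRUE)
  neg <- which(labels == "negative" | labels == FALSE)
  if (!length(pos) || !length(neg))
    stop("both classes must be non-empty", call. = FALSE)
  target_pos <- floor(length(neg) * spec$ratio[1] / spec$ratio[2])
  target_neg <- floor(length(pos) * spec$ratio[2] / spec$ratio[1])
  set.seed(spec$seed)
  extra <- integer(0)
  if (target_pos > length(pos))
    extra <- sample(pos, target_pos - length(pos), replace = TRUE)
  else if (target_neg > length(neg))
    extra <- sample(neg, target_neg - length(neg), replace = TRUE)
  c(seq_along(labels), extra)
}

#' Cost-sensitive positive-class weight
#'
#' Returns `n_negative / n_positive`, the weight handed to the classifier
#' as the positive-class (scale) weight instead of resampling.
#'
#' @param labels class labels as in [undersample()].
#' @return single positive number.
#' @export
cost_weight <- function(labels) {
  n_pos <- sum(labels == "positive" | labels == TRUE)
  n_neg <- sum(labels == "negative" | labels == FALSE)
  if (!n_pos || !n_neg)
    stop("both classes must be non-empty", call. = FALSE)
  n_neg / n_pos
}

#' The derivation-ratio grid from 10:1 to 1:10
#'
#' Positive:negative proportions 10:1, 9:1, ..., 1:1, ..., 1:9, 1:10 —
#' the 19 distinct points of that enumeration.
#'
#' @return integer matrix with columns `pos`, `neg`, one row per ratio.
#' @export
ratio_grid <- function() {
  rbind(cbind(pos = 10:1, neg = 1L), cbind(pos = 1L, neg = 2:10))
}
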