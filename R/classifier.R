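# Gradient-boosted tree backend (XGBoost), the default and only required
# classifier: 144 estimators, max depth 8, min child weight 5, binary
# logistic objective, single-threaded for bitwise reproducibility.

#' Classifier specification
#'
#' @param n_estimators number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum sum of instance weights per leaf.
#' @param positive_class_weight scale weight of the positive class
#'   (from [cost_weight()] for cost-sensitive boosting, 1 otherwise).
#' @param seed integer seed for the backend.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(n_estimators = 144, max_depth = 8,
                            min_child_weight = 5,
                            positive_class_weight = 1, seed = 1) {
  stopifnot(n_estimators >= 1, max_depth >= 1, min_child_weight > 0,
            positive_class_weight >= 0)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight,
                 positive_class_weight = positive_class_weight,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train the gradient-boosted classifier
#'
#' @param x numeric feature matrix (samples by features, named columns).
#' @param labels class labels; positives are `"positive"` or `TRUE`.
#' @param spec a [classifier_spec()].
#' @return object of class `etsm_model` wrapping the fitted booster and
#'   the feature names.
#' @export
train_classifier <- function(x, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(x))
  y <- as.integer(labels == "positive" | labels == TRUE)
  if (length(unique(y)) < 2)
    stop("single-class training data (", sum(y == 1), " positive / ",
         sum(y == 0), " negative); both classes are required",
         call. = FALSE)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = spec$max_depth,
                  min_child_weight = spec$min_child_weight,
                  scale_pos_weight = spec$positive_class_weight,
                  nthread = 1, seed = spec$seed),
    data = dtrain, nrounds = spec$n_estimators, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(x),
                 spec = spec),
            class = "etsm_model")
}

#' Predict positive-class scores
#'
#' @param object an `etsm_model`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.etsm_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (!identical(colnames(newdata), object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  as.numeric(predict(object$booster,
                     xgboost::xgb.DMatrix(newdata, nthread = 1)))
}

#' Per-feature importance scores
#'
#' Gain-based importance over every training feature; features never used
#' by a split have importance 0.
#'
#' @param model an `etsm_model`.
#' @param measure importance measure, `"Gain"`, `"Cover"` or
#'   `"Frequency"`.
#' @return named numeric vector over all training features.
#' @export
feature_importance <- function(model, measure = "Gain") {
  stopifnot(inherits(model, "etsm_model"),
            measure %in% c("Gain", "Cover", "Frequency"))
  imp <- setNames(numeric(length(model$feature_names)),
                  model$feature_names)
  tab <- xgboost::xgb.importance(model = model$booster)
  if (!is.null(tab) && nrow(tab))
    imp[tab$Feature] <- tab[[measure]]
  imp
}

#' Top-ranked features decoded to their clinical meaning
#'
#' Maps implicit columns back to their canonical drug-ID sets and
#' explicit columns to their variable and day slot, sorted by descending
#' importance with a deterministic tie-break (lower combination/column ID
#' first). `group = "implicit"` restricts the ranking to drug-combination
#' features, mirroring a top-k drug-combination importance table.
#'
#' @param model an `etsm_model`.
#' @param columns column metadata from [assemble_features()].
#' @param k number of rows to return.
#' @param group optional filter on the column group (e.g. `"implicit"`).
#' @param measure importance measure passed to [feature_importance()].
#' @return data frame `rank`, `name`, `group`, `source`, `drug_ids`
#'   (comma-joined for implicit columns, `NA` otherwise), `importance`.
#' @export
top_importances <- function(model, columns, k = 10, group = NULL,
                            measure = "Gain") {
  imp <- feature_importance(model, measure)
  meta <- columns[match(names(imp), columns$name), , drop = FALSE]
  df <- data.frame(name = names(imp), group = meta$group,
                   source = meta$source, importance = unname(imp),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  df <- df[order(-df$importance, df$name), , drop = FALSE]
  df <- utils::head(df, k)
  df$drug_ids <- ifelse(df$group == "implicit",
                        vapply(df$source, function(s)
                          paste(combo_drugs(s), collapse = ","), ""),
                        NA_character_)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("rank", "name", "group", "source", "drug_ids", "importance")]
}
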