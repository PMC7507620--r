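# Repeated stratified-split evaluation protocol: 60/40 derivation/
# validation split, stratified by class, repeated (default 10 times).
# Vocabulary, imputation medians and resampling are fitted on the
# derivation rows only; the validation set is scored untouched and
# imbalanced. Ablation variants run on identical split indices so
# comparisons are paired.

#' Stratified derivation/validation splits
#'
#' @param labels class labels of the samples.
#' @param n_repeats number of repeated splits.
#' @param fraction derivation fraction (default 0.6).
#' @param seed integer root seed.
#' @return list of `n_repeats` lists with integer `derivation` and
#'   `validation` index vectors; class fractions are preserved to within
#'   one sample per class.
#' @export
make_splits <- function(labels, n_repeats = 10, fraction = 0.6,
                        seed = 1) {
  pos <- which(labels == "positive" | labels == TRUE)
  neg <- which(labels == "negative" | labels == FALSE)
  if (length(pos) < 2 || length(neg) < 2)
    stop("protocol error: need at least 2 samples per class (",
         length(pos), " positive / ", length(neg), " negative)",
         call. = FALSE)
  lapply(seq_len(n_repeats), function(r) {
    set.seed(patient_seed(seed, r))
    d <- sort(c(sample(pos, round(fraction * length(pos))),
                sample(neg, round(fraction * length(neg)))))
    list(derivation = d,
         validation = setdiff(seq_along(labels), d))
  })
}

# one featurize/impute/resample/train/score pass on one split
run_fold <- function(cohort, samples, split, encoder, resample,
                     classifier, fold_seed, threshold = 0.5,
                     importance_k = 10) {
  D <- split$derivation; V <- split$validation
  vocab <- if (encoder == "ificf")
    build_vocabulary(cohort, samples[D, , drop = FALSE]) else NULL
  fm <- assemble_features(cohort, samples, encoder = encoder,
                          vocab = vocab)
  fm <- impute_features(fm, cohort, derivation = D)

  lab_d <- samples$label[D]
  spec <- classifier
  idx <- switch(resample$strategy,
    undersample = D[undersample(lab_d,
      resample_spec("undersample", resample$ratio, fold_seed))],
    oversample = D[oversample(lab_d,
      resample_spec("oversample", resample$ratio, fold_seed))],
    cost_sensitive = { spec$positive_class_weight <- cost_weight(lab_d); D },
    none = D)

  model <- train_classifier(fm$x[idx, , drop = FALSE],
                            samples$label[idx], spec)
  scores <- predict(model, fm$x[V, , drop = FALSE])
  metrics <- evaluate_predictions(scores, samples$label[V], threshold)
  top <- if (any(fm$columns$group == "implicit"))
    top_importances(model, fm$columns, k = importance_k,
                    group = "implicit") else NULL
  list(metrics = metrics, top_combinations = top,
       n_train = length(idx), n_validation = length(V))
}

#' Run the repeated stratified-split experiment
#'
#' Per repeat: stratified 60/40 split; combination vocabulary and
#' imputation medians fitted on the derivation rows; derivation resampled
#' per `resample`; classifier trained and scored on the untouched
#' validation rows; AUC, sensitivity, F1 and average precision recorded.
#' Aggregates mean and t-based 95% confidence half-widths across repeats.
#'
#' @param cohort a filtered [ehr_cohort].
#' @param labels output of [label_kdigo()] (filtered alongside the
#'   cohort).
#' @param lead_hours prediction lead, 24 or 48.
#' @param encoder implicit-block encoder (see [assemble_features()]).
#' @param resample a [resample_spec()].
#' @param classifier a [classifier_spec()].
#' @param n_repeats number of repeated splits (default 10).
#' @param fraction derivation fraction.
#' @param seed root seed; every split, resample and fit derives from it.
#' @param threshold classification threshold for sensitivity/F1.
#' @param splits optional precomputed [make_splits()] result, used to
#'   share split indices across ablation variants.
#' @param importance_k top-k drug combinations recorded per repeat.
#' @return object of class `metrics_report`: `per_repeat` (data frame of
#'   the four metrics per repeat), `summary` (mean and `ci` half-width
#'   per metric), `top_combinations` (per-repeat implicit importance
#'   tables, if any), `splits`, and the run settings.
#' @export
run_experiment <- function(cohort, labels, lead_hours = 24,
                           encoder = c("ificf", "bool", "times", "none"),
                           resample = resample_spec("undersample",
                                                    c(1, 1)),
                           classifier = classifier_spec(),
                           n_repeats = 10, fraction = 0.6, seed = 1,
                           threshold = 0.5, splits = NULL,
                           importance_k = 10) {
  encoder <- match.arg(encoder)
  samples <- assign_predictive_points(cohort, labels, lead_hours)
  if (is.null(splits))
    splits <- make_splits(samples$label, n_repeats, fraction, seed)
  n_repeats <- length(splits)

  folds <- lapply(seq_len(n_repeats), function(r) {
    cspec <- classifier
    cspec$seed <- patient_seed(seed, 30000 + r)
    run_fold(cohort, samples, splits[[r]], encoder, resample, cspec,
             fold_seed = patient_seed(seed, 10000 + r),
             threshold = threshold, importance_k = importance_k)
  })
  per_repeat <- data.frame(
    repeat_id = seq_len(n_repeats),
    do.call(rbind, lapply(folds, function(f) t(f$metrics))))
  names(per_repeat) <- c("repeat_id", "auc", "sensitivity", "f1", "ap")
  summ <- t(vapply(c("auc", "sensitivity", "f1", "ap"),
                   function(mt) ci_summary(per_repeat[[mt]]),
                   c(mean = 0, ci = 0)))
  structure(list(per_repeat = per_repeat,
                 summary = data.frame(metric = rownames(summ), summ,
                                      row.names = NULL),
                 top_combinations = lapply(folds,
                                           `[[`, "top_combinations"),
                 splits = splits, encoder = encoder,
                 lead_hours = lead_hours, resample = resample,
                 n_samples = nrow(samples), seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> encoder \"", x$encoder, "\", lead ",
      x$lead_hours, " h, ", nrow(x$per_repeat), " repeats on ",
      x$n_samples, " samples\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.3f ±%.3f\n", s$metric[i], s$mean[i],
                s$ci[i]))
  invisible(x)
}

#' Ablation over the implicit-indicator encoders
#'
#' Runs [run_experiment()] once per feature variant — `etsm` (IFICF),
#' `etsm_ex` (explicit only), `etsm_bool`, `etsm_times` — on identical
#' split indices (shared seeds), then compares each variant against
#' `etsm` with a paired two-sided t test per metric on the per-repeat
#' series.
#'
#' @inheritParams run_experiment
#' @param variants named character vector mapping variant name to
#'   encoder.
#' @return list with `reports` (named list of `metrics_report`) and
#'   `comparisons` (data frame: `variant`, `metric`, `mean_etsm`,
#'   `mean_variant`, `mean_difference`, `p_value`).
#' @export
run_ablation <- function(cohort, labels, lead_hours = 24,
                         resample = resample_spec("undersample",
                                                  c(1, 1)),
                         classifier = classifier_spec(),
                         n_repeats = 10, fraction = 0.6, seed = 1,
                         threshold = 0.5,
                         variants = c(etsm = "ificf", etsm_ex = "none",
                                      etsm_bool = "bool",
                                      etsm_times = "times")) {
  samples <- assign_predictive_points(cohort, labels, lead_hours)
  splits <- make_splits(samples$label, n_repeats, fraction, seed)
  reports <- lapply(variants, function(enc)
    run_experiment(cohort, labels, lead_hours, encoder = enc,
                   resample = resample, classifier = classifier,
                   seed = seed, threshold = threshold, splits = splits))
  names(reports) <- names(variants)

  base <- reports[["etsm"]]$per_repeat
  comp <- do.call(rbind, lapply(setdiff(names(variants), "etsm"),
    function(v) {
      do.call(rbind, lapply(c("auc", "sensitivity", "f1", "ap"),
        function(mt) {
          tt <- paired_ttest(base[[mt]], reports[[v]]$per_repeat[[mt]])
          data.frame(variant = v, metric = mt,
                     mean_etsm = mean(base[[mt]]),
                     mean_variant = mean(reports[[v]]$per_repeat[[mt]]),
                     mean_difference = tt$mean_difference,
                     p_value = tt$p_value, stringsAsFactors = FALSE)
        }))
    }))
  list(reports = reports, comparisons = comp)
}

#' Sweep the derivation-set class ratio
#'
#' For each repeat one stratified split is drawn; for every ratio of the
#' grid the derivation set is undersampled to that positive:negative
#' proportion, the classifier retrained, and the untouched validation set
#' scored — so within a repeat every ratio is evaluated on identical
#' validation rows.
#'
#' @inheritParams run_experiment
#' @param ratios integer matrix with columns `pos`, `neg`
#'   (default [ratio_grid()]).
#' @return data frame with one row per ratio and repeat: `ratio_pos`,
#'   `ratio_neg`, `ratio` (label like `"1:2"`), `repeat_id`, the four
#'   metrics, and `seed`.
#' @export
ratio_sweep <- function(cohort, labels, lead_hours = 24,
                        ratios = ratio_grid(),
                        encoder = c("ificf", "bool", "times", "none"),
                        classifier = classifier_spec(), n_repeats = 10,
                        fraction = 0.6, seed = 1, threshold = 0.5) {
  encoder <- match.arg(encoder)
  samples <- assign_predictive_points(cohort, labels, lead_hours)
  splits <- make_splits(samples$label, n_repeats, fraction, seed)

  out <- vector("list", length(splits) * nrow(ratios))
  k <- 0L
  for (r in seq_along(splits)) {
    D <- splits[[r]]$derivation; V <- splits[[r]]$validation
    vocab <- if (encoder == "ificf")
      build_vocabulary(cohort, samples[D, , drop = FALSE]) else NULL
    fm <- assemble_features(cohort, samples, encoder = encoder,
                            vocab = vocab)
    fm <- impute_features(fm, cohort, derivation = D)
    for (g in seq_len(nrow(ratios))) {
      ratio <- as.integer(ratios[g, ])
      idx <- D[suppressWarnings(undersample(samples$label[D],
        resample_spec("undersample", ratio,
                      patient_seed(seed, 20000 + 100 * r + g))))]
      cspec <- classifier
      cspec$seed <- patient_seed(seed, 30000 + 100 * r + g)
      model <- train_classifier(fm$x[idx, , drop = FALSE],
                                samples$label[idx], cspec)
      scores <- predict(model, fm$x[V, , drop = FALSE])
      m <- evaluate_predictions(scores, samples$label[V], threshold)
      k <- k + 1L
      out[[k]] <- data.frame(ratio_pos = ratio[1], ratio_neg = ratio[2],
                             ratio = paste0(ratio[1], ":", ratio[2]),
                             repeat_id = r, auc = m["auc"],
                             sensitivity = m["sensitivity"],
                             f1 = m["f1"], ap = m["ap"], seed = seed,
                             row.names = NULL,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
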