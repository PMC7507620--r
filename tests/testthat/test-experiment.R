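# small shared cohort for the harness tests
exp_cohort <- local({
  g <- generate_cohort(cohort_config(n_patients = 150, seed = 19))
  lab <- label_kdigo(g$cohort)
  filter_cohort(g$cohort, lab, 24)
})
fast_cls <- classifier_spec(n_estimators = 15, max_depth = 3)

test_that("classifier achieves perfect training sensitivity on a separable toy", {
  set.seed(1)
  x <- cbind(f1 = c(rnorm(10, -3), rnorm(10, 3)), f2 = rnorm(20))
  y <- rep(c("negative", "positive"), each = 10)
  model <- train_classifier(x, y, classifier_spec(n_estimators = 20,
                                                  max_depth = 2))
  expect_equal(sensitivity_score(predict(model, x), y), 1.0)
  # identical seed, identical predictions
  model2 <- train_classifier(x, y, classifier_spec(n_estimators = 20,
                                                   max_depth = 2))
  expect_identical(predict(model, x), predict(model2, x))
  # importance covers every feature
  expect_equal(names(feature_importance(model)), c("f1", "f2"))
  expect_true(all(feature_importance(model) >= 0))
})

test_that("single-class training data is rejected with class counts", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(train_classifier(x, rep("negative", 10)),
               "0 positive / 10 negative")
})

test_that("stratified splits preserve the class fraction within one sample", {
  labels <- c(rep("positive", 37), rep("negative", 113))
  splits <- make_splits(labels, n_repeats = 5, fraction = 0.6, seed = 2)
  for (sp in splits) {
    expect_equal(sum(labels[sp$derivation] == "positive"),
                 round(0.6 * 37))
    expect_equal(sum(labels[sp$validation] == "positive"),
                 37 - round(0.6 * 37))
    expect_length(intersect(sp$derivation, sp$validation), 0)
    expect_setequal(c(sp$derivation, sp$validation),
                    seq_along(labels))
  }
})

test_that("run_experiment is reproducible end to end and sized correctly", {
  r1 <- run_experiment(exp_cohort$cohort, exp_cohort$labels, 24,
                       encoder = "ificf", classifier = fast_cls,
                       n_repeats = 3, seed = 6)
  expect_equal(nrow(r1$per_repeat), 3)
  expect_equal(names(r1$per_repeat),
               c("repeat_id", "auc", "sensitivity", "f1", "ap"))
  expect_true(all(unlist(r1$per_repeat[, -1]) >= 0 &
                    unlist(r1$per_repeat[, -1]) <= 1))
  expect_true(all(r1$summary$ci >= 0))
  r2 <- run_experiment(exp_cohort$cohort, exp_cohort$labels, 24,
                       encoder = "ificf", classifier = fast_cls,
                       n_repeats = 3, seed = 6)
  expect_identical(r1$per_repeat, r2$per_repeat)
  r3 <- run_experiment(exp_cohort$cohort, exp_cohort$labels, 24,
                       encoder = "ificf", classifier = fast_cls,
                       n_repeats = 1, seed = 60)
  expect_equal(nrow(r3$per_repeat), 1)
})

test_that("ablation variants share split indices and report paired tests", {
  ab <- run_ablation(exp_cohort$cohort, exp_cohort$labels, 24,
                     classifier = fast_cls, n_repeats = 3, seed = 9)
  expect_named(ab$reports, c("etsm", "etsm_ex", "etsm_bool",
                             "etsm_times"))
  for (v in names(ab$reports))
    expect_identical(ab$reports[[v]]$splits, ab$reports$etsm$splits)
  expect_equal(nrow(ab$comparisons), 3 * 4)
  expect_true(all(c("p_value", "mean_difference") %in%
                    names(ab$comparisons)))
  # the explicit-only matrix is strictly narrower than the full one
  s <- assign_predictive_points(exp_cohort$cohort, exp_cohort$labels, 24)
  v <- build_vocabulary(exp_cohort$cohort, s)
  expect_gt(ncol(assemble_features(exp_cohort$cohort, s, "ificf",
                                   vocab = v)$x),
            ncol(assemble_features(exp_cohort$cohort, s, "none")$x))
})

test_that("top importances decode implicit columns to drug sets", {
  s <- assign_predictive_points(exp_cohort$cohort, exp_cohort$labels, 24)
  vocab <- build_vocabulary(exp_cohort$cohort, s)
  fm <- assemble_features(exp_cohort$cohort, s, "ificf", vocab = vocab)
  fm <- impute_features(fm, exp_cohort$cohort)
  model <- train_classifier(fm$x, s$label, fast_cls)
  top <- top_importances(model, fm$columns, k = 10, group = "implicit")
  expect_lte(nrow(top), 10)
  expect_true(all(top$group == "implicit"))
  expect_true(all(top$importance >= 0))
  expect_equal(top$rank, seq_len(nrow(top)))
  expect_false(is.unsorted(rev(top$importance)))
  # keys decode losslessly back to the drug inventory
  decoded <- unlist(strsplit(top$drug_ids, ","))
  expect_true(all(decoded %in% exp_cohort$cohort$drugs))
  expect_equal(combo_drugs(top$source[1]),
               strsplit(top$drug_ids[1], ",")[[1]])
})

test_that("validation rows pass through resampling untouched", {
  r <- run_experiment(exp_cohort$cohort, exp_cohort$labels, 24,
                      encoder = "none", classifier = fast_cls,
                      resample = resample_spec("undersample", c(1, 1)),
                      n_repeats = 2, seed = 12)
  s <- assign_predictive_points(exp_cohort$cohort, exp_cohort$labels, 24)
  for (sp in r$splits) {
    # every validation index is an original sample, none resampled away
    expect_setequal(sp$validation,
                    setdiff(seq_len(nrow(s)), sp$derivation))
  }
})
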