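test_that("explicit block extracts admission-day and predictive-point values", {
  vitals <- list(A = data.frame(day = c(0, 3), variable = "heart_rate",
                                value = c(80, 95)))
  creat <- list(A = data.frame(day = 0:3, value = rep(1, 4)))
  cohort <- toy_cohort(creat, vitals = vitals)
  samples <- data.frame(patient_id = "A", predictive_point = 3)
  ex <- explicit_features(cohort, samples, variables = "heart_rate")
  expect_equal(unname(ex[1, "ex_adm:heart_rate"]), 80)
  expect_equal(unname(ex[1, "ex_pp:heart_rate"]), 95)

  # variable never measured on either day: both slots missing
  ex2 <- explicit_features(cohort, samples, variables = "sbp")
  expect_true(all(is.na(ex2)))

  # predictive point on the admission day: the two columns coincide
  s0 <- data.frame(patient_id = "A", predictive_point = 0)
  ex3 <- explicit_features(cohort, s0, variables = "heart_rate")
  expect_equal(unname(ex3[1, 1]), unname(ex3[1, 2]))
})

test_that("several measurements on one day resolve to the last value", {
  cohort <- toy_cohort(
    list(A = data.frame(day = 0, value = 1)),
    vitals = list(A = data.frame(day = c(0, 0), variable = "heart_rate",
                                 value = c(80, 88))))
  ex <- explicit_features(cohort,
                          data.frame(patient_id = "A",
                                     predictive_point = 0),
                          variables = "heart_rate")
  expect_equal(unname(ex[1, "ex_adm:heart_rate"]), 88)
})

test_that("assembled matrices have the documented shape and are deterministic", {
  g <- generate_cohort(cohort_config(n_patients = 40, seed = 9))
  lab <- label_kdigo(g$cohort)
  flt <- filter_cohort(g$cohort, lab, 24)
  s <- assign_predictive_points(flt$cohort, flt$labels, 24)
  nv <- length(flt$cohort$variables) + 1   # + creatinine

  fm_none <- assemble_features(flt$cohort, s, "none")
  expect_equal(ncol(fm_none$x), 2 * nv)

  vocab <- build_vocabulary(flt$cohort, s)
  fm <- assemble_features(flt$cohort, s, "ificf", vocab = vocab)
  expect_equal(ncol(fm$x), 2 * nv + length(vocab$keys))
  expect_equal(fm$columns$group[1:nv], rep("explicit_admission", nv))
  expect_equal(sum(fm$columns$group == "implicit"), length(vocab$keys))

  fm_bool <- assemble_features(flt$cohort, s, "bool")
  expect_equal(ncol(fm_bool$x), 2 * nv + length(flt$cohort$drugs))

  fm2 <- assemble_features(flt$cohort, s, "ificf", vocab = vocab)
  expect_identical(fm$x, fm2$x)

  # implicit weights are the per-patient IFICF rows
  i <- which(s$label == "positive")[1]
  sq <- medication_sequence(flt$cohort, s$patient_id[i],
                            s$predictive_point[i])
  expect_equal(unname(fm$x[i, paste0("im:", vocab$keys)]),
               unname(ificf_weights(sq, vocab)))
})

test_that("imputation fills from the nearest visible day, earlier on ties", {
  vitals <- list(A = data.frame(day = c(0, 2), variable = "hr",
                                value = c(5, 7)))
  creat <- list(A = data.frame(day = 0:2, value = rep(1, 3)))
  cohort <- toy_cohort(creat, vitals = vitals)
  # predictive point day 1: no hr measured that day; day 0 and day 2 are
  # equidistant -> prefer the earlier observation
  samples <- data.frame(patient_id = "A", predictive_point = 1,
                        label = "negative")
  fm <- assemble_features(cohort, samples, "none", variables = "hr")
  expect_true(is.na(fm$x[1, "ex_pp:hr"]))
  imp <- impute_features(fm, cohort)
  expect_equal(unname(imp$x[1, "ex_pp:hr"]), 5)
})

test_that("imputation restricted to visible days; later values never leak", {
  # hr measured only after the predictive point: patient treated as
  # lacking the variable, so the derivation median fills both slots
  vitals <- list(A = data.frame(day = 4, variable = "hr", value = 99),
                 B = data.frame(day = 0, variable = "hr", value = 6.5))
  creat <- list(A = data.frame(day = 0:4, value = rep(1, 5)),
                B = data.frame(day = 0:4, value = rep(1, 5)))
  cohort <- toy_cohort(creat, vitals = vitals)
  samples <- data.frame(patient_id = c("A", "B"),
                        predictive_point = c(2, 2))
  fm <- assemble_features(cohort, samples, "none", variables = "hr")
  imp <- impute_features(fm, cohort)
  expect_equal(unname(imp$x[1, "ex_adm:hr"]), 6.5)
  expect_equal(unname(imp$x[1, "ex_pp:hr"]), 6.5)
})

test_that("derivation medians fill whole-stay gaps and freeze for validation", {
  vitals <- list(A = data.frame(day = 0, variable = "hr", value = 4),
                 B = data.frame(day = 0, variable = "hr", value = 8),
                 C = data.frame(day = 0, variable = "hr", value = 100))
  creat <- list(A = data.frame(day = 0:2, value = rep(1, 3)),
                B = data.frame(day = 0:2, value = rep(1, 3)),
                C = data.frame(day = 0:2, value = rep(1, 3)),
                D = data.frame(day = 0:2, value = rep(1, 3)))
  cohort <- toy_cohort(creat, vitals = vitals)
  samples <- data.frame(patient_id = c("A", "B", "C", "D"),
                        predictive_point = rep(2, 4))
  fm <- assemble_features(cohort, samples, "none", variables = "hr")
  # D has no hr at all; only A and B are derivation rows, so the
  # median is fitted on them (6) and C's value cannot shift it
  imp <- impute_features(fm, cohort, derivation = c(1, 2))
  expect_equal(unname(imp$x[4, "ex_adm:hr"]), 6)
  expect_false(anyNA(imp$x))
})

test_that("imputation never alters an observed value and warns on empty columns", {
  g <- generate_cohort(cohort_config(n_patients = 50, seed = 14,
                                     missing_rate = 0.4))
  lab <- label_kdigo(g$cohort)
  flt <- filter_cohort(g$cohort, lab, 24)
  s <- assign_predictive_points(flt$cohort, flt$labels, 24)
  fm <- assemble_features(flt$cohort, s, "none")
  imp <- impute_features(fm, flt$cohort)
  obs <- !is.na(fm$x)
  expect_equal(imp$x[obs], fm$x[obs])
  expect_false(anyNA(imp$x))

  # a variable absent everywhere falls back to 0 with a warning
  fm2 <- assemble_features(flt$cohort, s, "none",
                           variables = c("creatinine", "ghost"))
  # one warning per empty slot column (admission and predictive point)
  expect_warning(
    expect_warning(imp2 <- impute_features(fm2, flt$cohort),
                   "ex_adm:ghost"),
    "ex_pp:ghost")
  expect_equal(unname(imp2$x[, "ex_adm:ghost"]), rep(0, nrow(imp2$x)))

  # no missing values: matrix unchanged
  imp3 <- impute_features(imp, flt$cohort)
  expect_equal(imp3$x, imp$x)
})
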