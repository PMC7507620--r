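test_that("daily drug sets canonicalize and doc_freq counts patients", {
  # patient A uses {x,y} twice (listed in both orders) and B uses {y}
  drugs <- list(A = list(`0` = c("x", "y"), `1` = c("y", "x")),
                B = list(`0` = "y"))
  creat <- list(A = data.frame(day = 0:1, value = c(1, 1)),
                B = data.frame(day = 0, value = 1))
  cohort <- toy_cohort(creat, drugs)
  samples <- data.frame(patient_id = c("A", "B"),
                        predictive_point = c(1, 0))
  vocab <- build_vocabulary(cohort, samples)
  expect_equal(vocab$keys, c("x|y", "y"))
  expect_equal(unname(vocab$doc_freq[c("x|y", "y")]), c(1L, 1L))
  expect_equal(vocab$n_patients, 2L)
})

test_that("repeated use by one patient contributes once to doc_freq", {
  drugs <- list(A = setNames(rep(list(c("x", "y")), 5), 0:4))
  creat <- list(A = data.frame(day = 0:4, value = rep(1, 5)))
  cohort <- toy_cohort(creat, drugs)
  vocab <- build_vocabulary(cohort,
                            data.frame(patient_id = "A",
                                       predictive_point = 4))
  expect_equal(unname(vocab$doc_freq["x|y"]), 1L)
})

test_that("empty medication history yields an empty vocabulary", {
  creat <- list(A = data.frame(day = 0:1, value = c(1, 1)))
  cohort <- toy_cohort(creat)
  vocab <- build_vocabulary(cohort,
                            data.frame(patient_id = "A",
                                       predictive_point = 1))
  expect_length(vocab$keys, 0)
  expect_length(medication_sequence(cohort, "A", 1), 0)
})

test_that("indicator frequency counts and normalizes per Eq-style definition", {
  s <- c("c1", "c1", "c2")
  f <- indicator_frequency(s)
  expect_equal(unname(f["c1"]), 2 / 3)
  expect_equal(unname(f["c2"]), 1 / 3)
  expect_equal(unname(indicator_frequency("c1")["c1"]), 1)
  expect_equal(unname(indicator_frequency(s, "c9")["c9"]), 0)
  expect_equal(sum(indicator_frequency(character(0), c("a", "b"))), 0)
})

test_that("inverse cohort frequency follows log(N / (1 + n_c))", {
  vocab <- structure(list(keys = c("a", "b"),
                          doc_freq = c(a = 4L, b = 10L),
                          n_patients = 10L),
                     class = "combo_vocabulary")
  expect_equal(unname(inverse_cohort_frequency(vocab, "a")), log(2))
  # combination in every sequence: negative weight forced by formula
  expect_lt(unname(inverse_cohort_frequency(vocab, "b")), 0)
  # unseen: n_c = 0
  expect_equal(unname(inverse_cohort_frequency(vocab, "zz")), log(10))
  v1 <- structure(list(keys = character(0),
                       doc_freq = setNames(integer(0), character(0)),
                       n_patients = 1L), class = "combo_vocabulary")
  expect_equal(unname(inverse_cohort_frequency(v1, "a")), 0)
  # monotone non-increasing in doc_freq at fixed N
  icf <- vapply(0:9, function(n) log(10 / (1 + n)), 1.0)
  expect_true(all(diff(icf) < 0))
})

test_that("IFICF composes IF and ICF on the worked example", {
  vocab <- structure(list(keys = c("c1", "c2"),
                          doc_freq = c(c1 = 4L, c2 = 9L),
                          n_patients = 10L),
                     class = "combo_vocabulary")
  w <- ificf_weights(c("c1", "c1", "c2"), vocab)
  expect_equal(unname(w["c1"]), (2 / 3) * log(10 / 5))
  expect_equal(unname(w["c2"]), (1 / 3) * log(10 / 10))
  expect_equal(sum(ificf_weights(character(0), vocab)), 0)
})

test_that("IFICF matches the dictionary-counting oracle on random corpora", {
  set.seed(2024)
  for (rep in seq_len(60)) {
    corpus <- dedupe_corpus(random_corpus(sample(2:12, 1),
                                          sample(2:5, 1),
                                          sample(1:8, 1)))
    cc <- corpus_as_cohort(corpus)
    vocab <- build_vocabulary(cc$cohort, cc$samples)
    pick <- sample(length(corpus), 1)
    want <- oracle_ificf(corpus, pick)
    got <- ificf_weights(
      medication_sequence(cc$cohort, cc$ids[pick],
                          cc$samples$predictive_point[pick]), vocab)
    expect_equal(sort(names(got)), sort(names(want)))
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("IF sums to one over every non-empty generated sequence", {
  g <- generate_cohort(cohort_config(n_patients = 80, seed = 21))
  lab <- label_kdigo(g$cohort)
  flt <- filter_cohort(g$cohort, lab, 24)
  s <- assign_predictive_points(flt$cohort, flt$labels, 24)
  for (i in seq_len(nrow(s))) {
    sq <- medication_sequence(flt$cohort, s$patient_id[i],
                              s$predictive_point[i])
    if (length(sq))
      expect_equal(sum(indicator_frequency(sq)), 1)
  }
})

test_that("vocabulary building ignores patient and row order", {
  g <- generate_cohort(cohort_config(n_patients = 50, seed = 33))
  lab <- label_kdigo(g$cohort)
  flt <- filter_cohort(g$cohort, lab, 24)
  s <- assign_predictive_points(flt$cohort, flt$labels, 24)
  v1 <- build_vocabulary(flt$cohort, s)
  shuf <- flt$cohort
  set.seed(2)
  shuf$medications <- shuf$medications[sample(nrow(shuf$medications)), ]
  v2 <- build_vocabulary(shuf, s[sample(nrow(s)), ])
  expect_equal(v1$keys, v2$keys)
  expect_equal(v1$doc_freq, v2$doc_freq)
})

test_that("sequences stop at the predictive point", {
  drugs <- list(A = list(`0` = "x", `2` = "y", `4` = "z"))
  creat <- list(A = data.frame(day = 0:4, value = rep(1, 5)))
  cohort <- toy_cohort(creat, drugs)
  expect_equal(medication_sequence(cohort, "A", 2), c("x", "y"))
  expect_equal(medication_sequence(cohort, "A", 4), c("x", "y", "z"))
})

test_that("bool and times drug rows agree with their definitions", {
  drugs <- list(A = list(`0` = c("d1", "d2"), `1` = "d1", `3` = "d1"))
  creat <- list(A = data.frame(day = 0:3, value = rep(1, 4)))
  cohort <- toy_cohort(creat, drugs)
  inv <- c("d1", "d2", "d3")
  tr <- times_drug_features(cohort, "A", 3, inv)
  expect_equal(unname(tr), c(3, 1, 0))
  br <- bool_drug_features(cohort, "A", 3, inv)
  expect_equal(unname(br), c(1, 1, 0))
  # bool = indicator(times > 0), also across generated cohorts
  g <- generate_cohort(cohort_config(n_patients = 30, seed = 12))
  for (pid in g$cohort$stays$patient_id[1:10]) {
    pp <- g$cohort$stays$los_days[g$cohort$stays$patient_id == pid]
    expect_equal(bool_drug_features(g$cohort, pid, pp),
                 setNames(as.numeric(
                   times_drug_features(g$cohort, pid, pp) > 0),
                   g$cohort$drugs))
  }
})
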