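# Independent brute-force oracles and tiny fixture builders shared by
# the test files. Oracles deliberately re-derive each quantity from its
# definition (exhaustive scans, dictionary counting, pairwise
# comparison) and never call the package functions they check.

# exhaustive pair-scan KDIGO oracle: tests every ordered observation
# pair for the 48 h absolute rise and every value against the first
# recorded (baseline) for the 7-day 1.5-fold rise
oracle_kdigo <- function(days, values) {
  o <- order(days)
  days <- as.integer(days[o]); values <- as.numeric(values[o])
  keep <- !duplicated(days, fromLast = TRUE)
  days <- days[keep]; values <- values[keep]
  for (j in seq_along(days)) {
    trig <- days[j] - days[1] <= 7 && values[j] >= 1.5 * values[1]
    if (j > 1)
      for (i in seq_len(j - 1))
        if (days[j] - days[i] <= 2 && values[j] - values[i] >= 0.3)
          trig <- TRUE
    if (trig) return(list(is_aki = TRUE, onset_day = days[j]))
  }
  list(is_aki = FALSE, onset_day = NA_integer_)
}

# pairwise-comparison AUC oracle: fraction of (positive, negative)
# pairs where the positive outscores the negative, half credit for ties
oracle_auc <- function(scores, labels) {
  p <- scores[labels == "positive" | labels == TRUE]
  n <- scores[labels == "negative" | labels == FALSE]
  tot <- 0
  for (a in p) for (b in n)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# dictionary-counting IFICF oracle over a raw corpus:
# `corpus` is a list (one element per patient) of lists of per-day drug
# vectors; empty days contribute nothing to the sequence
oracle_ificf <- function(corpus, patient) {
  seqs <- lapply(corpus, function(dayset) {
    dayset <- dayset[lengths(dayset) > 0]
    vapply(dayset, function(d)
      paste(sort(unique(d)), collapse = "|"), "")
  })
  keys <- sort(unique(unlist(seqs, use.names = FALSE)))
  N <- length(corpus)
  out <- stats::setNames(numeric(length(keys)), keys)
  s <- seqs[[patient]]
  if (!length(s)) return(out)
  for (k in keys) {
    n_c <- sum(vapply(seqs, function(q) k %in% q, TRUE))
    out[k] <- (sum(s == k) / length(s)) * log(N / (1 + n_c))
  }
  out
}

# random raw corpus for the IFICF equivalence checks
random_corpus <- function(n_patients, n_drugs, n_days) {
  drugs <- sprintf("d%d", seq_len(n_drugs))
  lapply(seq_len(n_patients), function(i)
    lapply(seq_len(n_days), function(d) {
      k <- sample(0:min(3, n_drugs), 1)
      if (k == 0) character(0) else sample(drugs, k)
    }))
}

# wrap a raw corpus as an ehr_cohort (no measurements needed) plus the
# sample sheet exposing every day to feature generation
corpus_as_cohort <- function(corpus) {
  n <- length(corpus)
  ids <- sprintf("C%02d", seq_len(n))
  los <- vapply(corpus, length, 1L)
  meds <- do.call(rbind, lapply(seq_len(n), function(i) {
    dl <- corpus[[i]]
    nd <- lengths(dl)
    if (!sum(nd)) return(NULL)
    data.frame(patient_id = ids[i],
               day = rep(seq_along(dl) - 1L, nd),
               drug_id = unlist(dl, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(meds))
    meds <- data.frame(patient_id = character(0), day = integer(0),
                       drug_id = character(0), stringsAsFactors = FALSE)
  cohort <- ehr_cohort(
    data.frame(patient_id = ids, los_days = los,
               stringsAsFactors = FALSE),
    data.frame(patient_id = character(0), day = integer(0),
               variable = character(0), value = numeric(0),
               stringsAsFactors = FALSE),
    meds)
  samples <- data.frame(patient_id = ids,
                        predictive_point = los,
                        stringsAsFactors = FALSE)
  list(cohort = cohort, samples = samples, ids = ids)
}

# duplicate-free daily drug sets make oracle IF counts well defined:
# ehr_cohort dedupes (patient, day, drug) rows, so dedupe the raw corpus
# the same way before comparing
dedupe_corpus <- function(corpus) {
  lapply(corpus, function(dl) lapply(dl, function(d) sort(unique(d))))
}

# small labelled cohort used by several files: builds an ehr_cohort
# directly from per-patient creatinine series and drug day-lists
toy_cohort <- function(creatinine, drugs = NULL, vitals = NULL) {
  ids <- names(creatinine)
  los <- vapply(ids, function(p) {
    d <- max(creatinine[[p]]$day)
    if (!is.null(drugs[[p]]) && length(drugs[[p]]))
      d <- max(d, max(as.integer(names(drugs[[p]]))))
    d
  }, 1)
  meas <- do.call(rbind, c(
    lapply(ids, function(p)
      data.frame(patient_id = p, day = creatinine[[p]]$day,
                 variable = "creatinine", value = creatinine[[p]]$value,
                 stringsAsFactors = FALSE)),
    lapply(names(vitals), function(p)
      data.frame(patient_id = p, day = vitals[[p]]$day,
                 variable = vitals[[p]]$variable,
                 value = vitals[[p]]$value, stringsAsFactors = FALSE))))
  meds <- do.call(rbind, lapply(names(drugs), function(p) {
    dl <- drugs[[p]]
    if (!length(dl)) return(NULL)
    data.frame(patient_id = p,
               day = rep(as.integer(names(dl)), lengths(dl)),
               drug_id = unlist(dl, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(meds))
    meds <- data.frame(patient_id = character(0), day = integer(0),
                       drug_id = character(0), stringsAsFactors = FALSE)
  ehr_cohort(data.frame(patient_id = ids, los_days = los,
                        stringsAsFactors = FALSE),
             meas, meds)
}

fixture_path <- function(...) {
  system.file("extdata", "fivepatients", ..., package = "etsm")
}
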