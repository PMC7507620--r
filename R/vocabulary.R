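# Implicit medication indicators. A drug combination is the set of
# distinct drugs a patient received on one calendar day; the combination
# vocabulary C = {c_1..c_M} collects the distinct daily sets seen in the
# derivation corpus. Each combination is weighted per patient by
# IFICF = IF x ICF, a TF-IDF analogue over medication days:
#   IF(c, s)  = f_{c,s} / sum_c' f_{c',s}   (within-sequence frequency)
#   ICF(c, P) = log(N / (1 + n_c))          (log corpus rarity, natural log)
# where s is the patient's day-ordered sequence of combination IDs, N the
# number of patients in the corpus and n_c the number of patient
# sequences containing c.

#' Canonical key for a drug combination
#'
#' The canonical form of a daily drug set is the sorted vector of its
#' distinct drug IDs; keys join it with `"|"`. Combination IDs are
#' positions in the lexicographic order of keys, so they are reproducible
#' across runs and platforms.
#'
#' @param drugs character vector of drug IDs (any order, duplicates
#'   allowed).
#' @return single string key, e.g. `"D01|D03"`.
#' @export
combo_key <- function(drugs) {
  paste(sort(unique(as.character(drugs))), collapse = "|")
}

#' Split a combination key back into drug IDs
#' @param key key produced by [combo_key()].
#' @return character vector of drug IDs.
#' @export
combo_drugs <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

#' Day-ordered medication sequence of one patient
#'
#' One combination key per day on which at least one drug was given, up
#' to and including the predictive point; medication-free days contribute
#' nothing. Only medication at or before the predictive point is visible
#' to feature generation — later days would leak the future relative to
#' the prediction time.
#'
#' @param cohort an [ehr_cohort].
#' @param patient_id patient identifier.
#' @param predictive_point day offset at which features are frozen.
#' @return character vector of combination keys in day order (possibly
#'   empty).
#' @export
medication_sequence <- function(cohort, patient_id, predictive_point) {
  d <- cohort$medications
  d <- d[d$patient_id == patient_id & d$day <= predictive_point, ,
         drop = FALSE]
  if (!nrow(d)) return(character(0))
  sets <- split(d$drug_id, d$day)          # split() orders by day
  vapply(sets, combo_key, "", USE.NAMES = FALSE)
}

#' Build the drug-combination vocabulary from derivation patients
#'
#' Collects the distinct daily drug combinations over the derivation
#' samples' visible medication days and counts, for each combination, the
#' number of patient sequences containing it (`doc_freq`, i.e. n_c:
#' repeated use by one patient still counts once). The vocabulary is
#' fitted on derivation patients only and frozen for validation;
#' validation-only combinations are treated as unseen (n_c = 0).
#'
#' @param cohort an [ehr_cohort].
#' @param samples data frame with columns `patient_id` and
#'   `predictive_point` (one row per derivation sample).
#' @return object of class `combo_vocabulary`: `keys` (lexicographically
#'   sorted combination keys), `doc_freq` (named integer vector over
#'   `keys`), `n_patients` (N, the number of derivation samples).
#' @export
build_vocabulary <- function(cohort, samples) {
  stopifnot(inherits(cohort, "ehr_cohort"),
            all(c("patient_id", "predictive_point") %in% names(samples)))
  seqs <- lapply(seq_len(nrow(samples)), function(i)
    medication_sequence(cohort, samples$patient_id[i],
                        samples$predictive_point[i]))
  per_patient <- lapply(seqs, unique)
  keys <- sort(unique(unlist(per_patient, use.names = FALSE)))
  doc_freq <- if (length(keys)) {
    tab <- table(factor(unlist(per_patient, use.names = FALSE),
                        levels = keys))
    setNames(as.integer(tab), keys)
  } else setNames(integer(0), character(0))
  structure(list(keys = keys, doc_freq = doc_freq,
                 n_patients = nrow(samples)),
            class = "combo_vocabulary")
}

#' @export
print.combo_vocabulary <- function(x, ...) {
  cat("<combo_vocabulary> ", length(x$keys),
      " distinct drug combinations over ", x$n_patients, " patients\n",
      sep = "")
  invisible(x)
}

#' Indicator frequency of combinations within one sequence
#'
#' `IF(c, s) = f_{c,s} / sum_c' f_{c',s}`: the fraction of the patient's
#' medicated days on which the daily combination was exactly `c`. Over
#' the distinct combinations of a non-empty sequence the values sum to 1.
#' An empty sequence yields an all-zero row by convention (no division by
#' zero).
#'
#' @param sequence character vector of combination keys
#'   ([medication_sequence()]).
#' @param combos keys to evaluate; defaults to the distinct combinations
#'   of the sequence.
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
indicator_frequency <- function(sequence, combos = NULL) {
  if (is.null(combos)) combos <- sort(unique(sequence))
  if (!length(sequence)) return(setNames(numeric(length(combos)), combos))
  counts <- table(factor(sequence, levels = combos))
  setNames(as.numeric(counts) / length(sequence), combos)
}

#' Inverse cohort frequency of combinations
#'
#' `ICF(c, P) = log(N / (1 + n_c))` with the natural logarithm; strictly
#' decreasing in n_c. Combinations unseen in the vocabulary take n_c = 0,
#' i.e. `log(N)`. The log base only rescales every implicit feature by a
#' shared constant, which tree-based classifiers ignore.
#'
#' @param vocab a [build_vocabulary()] result.
#' @param combos character vector of combination keys.
#' @return named numeric vector of ICF values.
#' @export
inverse_cohort_frequency <- function(vocab, combos) {
  stopifnot(inherits(vocab, "combo_vocabulary"), vocab$n_patients >= 1)
  n_c <- ifelse(combos %in% vocab$keys,
                vocab$doc_freq[combos], 0L)
  setNames(log(vocab$n_patients / (1 + as.numeric(n_c))), combos)
}

#' IFICF weight row for one patient sequence
#'
#' Entry for combination c is `IF(c, s) * ICF(c, P)` over the vocabulary
#' columns; zero wherever IF is zero, so the row support is contained in
#' the sequence's distinct combinations. Sequence combinations absent
#' from the vocabulary still enter the IF denominator but produce no
#' column.
#'
#' @param sequence character vector of combination keys.
#' @param vocab a [build_vocabulary()] result.
#' @return named numeric vector over `vocab$keys`.
#' @export
ificf_weights <- function(sequence, vocab) {
  stopifnot(inherits(vocab, "combo_vocabulary"))
  out <- setNames(numeric(length(vocab$keys)), vocab$keys)
  if (!length(sequence) || !length(vocab$keys)) return(out)
  present <- intersect(unique(sequence), vocab$keys)
  if (!length(present)) return(out)
  f <- table(factor(sequence, levels = present))
  if_part <- as.numeric(f) / length(sequence)
  icf_part <- inverse_cohort_frequency(vocab, present)
  out[present] <- if_part * icf_part
  out
}

#' Boolean per-drug indicator row
#'
#' One dimension per drug in the inventory; 1 iff the patient ever took
#' the drug on any day at or before the predictive point.
#'
#' @inheritParams medication_sequence
#' @param inventory character vector of drug IDs defining the columns.
#' @return named numeric 0/1 vector over `inventory`.
#' @export
bool_drug_features <- function(cohort, patient_id, predictive_point,
                               inventory = cohort$drugs) {
  t_row <- times_drug_features(cohort, patient_id, predictive_point,
                               inventory)
  setNames(as.numeric(t_row > 0), names(t_row))
}

#' Per-drug administration-day count row
#'
#' One dimension per drug; the value is the number of days at or before
#' the predictive point on which the drug appears (a drug given on three
#' days has weight 3).
#'
#' @inheritParams bool_drug_features
#' @return named numeric count vector over `inventory`.
#' @export
times_drug_features <- function(cohort, patient_id, predictive_point,
                                inventory = cohort$drugs) {
  d <- cohort$medications
  d <- d[d$patient_id == patient_id & d$day <= predictive_point, ,
         drop = FALSE]
  counts <- table(factor(d$drug_id, levels = inventory))
  setNames(as.numeric(counts), inventory)
}
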