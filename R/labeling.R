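# KDIGO creatinine criteria, binary (no staging, no urine output):
# AKI if serum creatinine rises by >= 0.3 mg/dl within 48 h, or reaches
# >= 1.5x the stay baseline within 7 days. Baseline = first recorded
# creatinine of the stay; the absolute-rise rule compares each value to
# the minimum observed value in the preceding 2 days.

#' KDIGO onset scan for a single creatinine series
#'
#' @param days integer day offsets (day 0 = admission), not necessarily
#'   sorted; at most one value per day is used (the last supplied).
#' @param values serum creatinine in mg/dl, parallel to `days`.
#' @return list with `is_aki` (logical) and `onset_day` (integer or `NA`):
#'   the earliest day on which either criterion is satisfied.
#' @export
kdigo_onset <- function(days, values) {
  stopifnot(length(days) == length(values))
  if (!length(days)) return(list(is_aki = FALSE, onset_day = NA_integer_))
  o <- order(days)
  days <- as.integer(days[o]); values <- as.numeric(values[o])
  keep <- !duplicated(days, fromLast = TRUE)
  days <- days[keep]; values <- values[keep]
  baseline <- values[1L]; day0 <- days[1L]
  for (j in seq_along(days)) {
    prev <- which(days < days[j] & days[j] - days <= 2L)
    rise <- length(prev) > 0 && values[j] - min(values[prev]) >= 0.3
    fold <- days[j] - day0 <= 7L && values[j] >= 1.5 * baseline
    if (rise || fold)
      return(list(is_aki = TRUE, onset_day = days[j]))
  }
  list(is_aki = FALSE, onset_day = NA_integer_)
}

#' Label a cohort for AKI with the KDIGO creatinine criteria
#'
#' Applies [kdigo_onset()] to every stay's creatinine series. Stays with an
#' empty creatinine series cannot be labelled; they are flagged
#' `labelable = FALSE` and are later removed by [filter_cohort()] under the
#' insufficient-information rule.
#'
#' @param cohort an [ehr_cohort].
#' @return data frame with one row per stay: `patient_id`, `labelable`,
#'   `is_aki`, `onset_day` (`NA` for non-AKI), `timing_days` (days from
#'   admission to onset, equal to `onset_day` under the day-offset
#'   convention).
#' @export
label_kdigo <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  cr_all <- cohort$measurements[
    cohort$measurements$variable == cohort$creatinine_variable, ,
    drop = FALSE]
  by_pat <- split(cr_all[, c("day", "value")], cr_all$patient_id)
  res <- lapply(cohort$stays$patient_id, function(pid) {
    cr <- by_pat[[pid]]
    if (is.null(cr) || !nrow(cr))
      return(data.frame(patient_id = pid, labelable = FALSE,
                        is_aki = FALSE, onset_day = NA_integer_,
                        timing_days = NA_integer_,
                        stringsAsFactors = FALSE))
    k <- kdigo_onset(cr$day, cr$value)
    data.frame(patient_id = pid, labelable = TRUE, is_aki = k$is_aki,
               onset_day = k$onset_day, timing_days = k$onset_day,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Filter a labelled cohort for a given prediction lead
#'
#' Removes (1) stays with no measurements and no medications, or with no
#' creatinine series (unlabelable) — the insufficient-information rule —
#' and (2) stays shorter than the prediction lead, including AKI stays
#' whose onset falls within the lead of admission so no valid predictive
#' point exists. Filtering is total and idempotent.
#'
#' @param cohort an [ehr_cohort].
#' @param labels output of [label_kdigo()] for `cohort`.
#' @param lead_hours prediction lead, 24 or 48.
#' @return list with `cohort` (filtered [ehr_cohort]), `labels` (filtered)
#'   and `report`, a `cohort_filter_report` reconciling
#'   `n_original = n_removed_no_data + n_removed_short_stay + n_retained`
#'   and carrying the per-rule patient ID lists.
#' @export
filter_cohort <- function(cohort, labels, lead_hours = 24) {
  stopifnot(inherits(cohort, "ehr_cohort"), lead_hours %in% c(24, 48))
  lead_days <- lead_hours / 24L
  ids <- cohort$stays$patient_id
  has_meas <- ids %in% cohort$measurements$patient_id
  has_meds <- ids %in% cohort$medications$patient_id
  lab <- labels[match(ids, labels$patient_id), , drop = FALSE]

  no_data <- (!has_meas & !has_meds) | !lab$labelable
  short <- !no_data &
    (cohort$stays$los_days < lead_days |
       (lab$is_aki & lab$onset_day < lead_days))
  keep <- !no_data & !short

  report <- structure(list(
    lead_hours = lead_hours,
    n_original = length(ids),
    n_removed_no_data = sum(no_data),
    n_removed_short_stay = sum(short),
    n_retained = sum(keep),
    removed_no_data_ids = ids[no_data],
    removed_short_stay_ids = ids[short]
  ), class = "cohort_filter_report")

  keep_ids <- ids[keep]
  sub <- function(df) df[df$patient_id %in% keep_ids, , drop = FALSE]
  out <- cohort
  out$stays <- sub(cohort$stays)
  out$measurements <- sub(cohort$measurements)
  out$medications <- sub(cohort$medications)
  out$drugs <- sort(unique(out$medications$drug_id))
  out$variables <- setdiff(sort(unique(out$measurements$variable)),
                           cohort$creatinine_variable)
  list(cohort = out, labels = lab[keep, , drop = FALSE], report = report)
}

#' @export
print.cohort_filter_report <- function(x, ...) {
  cat("<cohort_filter_report> lead ", x$lead_hours, " h: ",
      x$n_original, " stays; removed ", x$n_removed_no_data,
      " (insufficient information) + ", x$n_removed_short_stay,
      " (stay shorter than lead / no valid predictive point); retained ",
      x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Assign the predictive point for each retained stay
#'
#' The predictive point is the day at which features are frozen. For AKI
#' stays it precedes onset by the lead (24 h = 1 day, 48 h = 2 days). The
#' KDIGO cohorts this package targets do not define a predictive point for
#' non-AKI stays; here it is anchored at discharge minus the lead, which
#' gives every negative the maximal observation window and mirrors the
#' positive construction.
#'
#' @inheritParams filter_cohort
#' @return data frame of prediction samples: `patient_id`, `label`
#'   (`"positive"`/`"negative"`), `predictive_point` (day offset),
#'   `lead_hours`. Samples whose predictive point would fall before
#'   admission are excluded and listed in the `"excluded"` attribute.
#' @export
assign_predictive_points <- function(cohort, labels, lead_hours = 24) {
  stopifnot(inherits(cohort, "ehr_cohort"), lead_hours %in% c(24, 48))
  lead_days <- lead_hours / 24L
  lab <- labels[match(cohort$stays$patient_id, labels$patient_id), ,
                drop = FALSE]
  pp <- ifelse(lab$is_aki, lab$onset_day - lead_days,
               cohort$stays$los_days - lead_days)
  out <- data.frame(patient_id = cohort$stays$patient_id,
                    label = ifelse(lab$is_aki, "positive", "negative"),
                    predictive_point = as.integer(pp),
                    lead_hours = lead_hours, stringsAsFactors = FALSE)
  bad <- out$predictive_point < 0
  if (any(bad))
    message(sum(bad), " sample(s) excluded: predictive point before ",
            "admission (", paste(out$patient_id[bad], collapse = ", "), ")")
  excluded <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
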