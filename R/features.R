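# Feature matrix assembly. The explicit indicator group holds each
# measurement variable at two day slots -- ICU admission day and the
# predictive point. The implicit indicator group holds the medication
# encoding: IFICF over the combination vocabulary (default), per-drug
# boolean or administration-day counts (ablation alternates), or nothing.

#' Explicit indicator block: admission-day and predictive-point values
#'
#' For each variable two columns are produced: its value on the admission
#' day (day 0) and on the predictive-point day. When several measurements
#' fall on one day the last value of the day is used. Absent observations
#' are `NA` and are filled downstream by [impute_features()].
#'
#' @param cohort an [ehr_cohort].
#' @param samples data frame with `patient_id` and `predictive_point`.
#' @param variables measurement variables to extract; defaults to every
#'   non-creatinine variable plus creatinine.
#' @return numeric matrix, one row per sample, columns
#'   `ex_adm:<var>` / `ex_pp:<var>`.
#' @export
explicit_features <- function(cohort, samples,
                              variables = c(cohort$variables,
                                            cohort$creatinine_variable)) {
  m <- cohort$measurements[cohort$measurements$variable %in% variables, ,
                           drop = FALSE]
  # last value of each (patient, variable, day)
  key <- paste(m$patient_id, m$variable, m$day, sep = "\r")
  last <- !duplicated(key, fromLast = TRUE)
  lookup <- setNames(m$value[last], key[last])
  n <- nrow(samples)
  adm <- matrix(NA_real_, n, length(variables),
                dimnames = list(samples$patient_id,
                                paste0("ex_adm:", variables)))
  pp <- matrix(NA_real_, n, length(variables),
               dimnames = list(samples$patient_id,
                               paste0("ex_pp:", variables)))
  for (j in seq_along(variables)) {
    adm[, j] <- lookup[paste(samples$patient_id, variables[j], 0L,
                             sep = "\r")]
    pp[, j] <- lookup[paste(samples$patient_id, variables[j],
                            samples$predictive_point, sep = "\r")]
  }
  cbind(adm, pp)
}

#' Assemble the full feature matrix for a set of prediction samples
#'
#' Concatenates the explicit block with the selected implicit block in a
#' deterministic column order. Encoders: `"ificf"` (combination IFICF
#' weights over the vocabulary), `"bool"` / `"times"` (per-drug
#' indicators/counts), `"none"` (explicit indicators only — the
#' explicit-only ablation variant).
#'
#' @param cohort an [ehr_cohort].
#' @param samples data frame with `patient_id`, `predictive_point` and
#'   optionally `label`.
#' @param encoder implicit-block encoder.
#' @param vocab [build_vocabulary()] result; required for
#'   `encoder = "ificf"`.
#' @param inventory drug inventory for `"bool"`/`"times"`; defaults to
#'   the cohort's drugs.
#' @param variables explicit variables; see [explicit_features()].
#' @return object of class `feature_matrix`: list with `x` (numeric
#'   matrix, samples by features), `samples` (the input data frame) and
#'   `columns` (per-column metadata: `name`, `group` in
#'   `explicit_admission` / `explicit_predpoint` / `implicit`, `source` —
#'   the variable name, combination key or drug ID).
#' @export
assemble_features <- function(cohort, samples,
                              encoder = c("ificf", "bool", "times",
                                          "none"),
                              vocab = NULL,
                              inventory = cohort$drugs,
                              variables = c(cohort$variables,
                                            cohort$creatinine_variable)) {
  encoder <- match.arg(encoder)
  ex <- explicit_features(cohort, samples, variables)
  med_split <- split(cohort$medications[c("day", "drug_id")],
                     cohort$medications$patient_id)
  visible <- function(pid, pp) {
    d <- med_split[[pid]]
    if (is.null(d)) return(NULL)
    d <- d[d$day <= pp, , drop = FALSE]
    if (nrow(d)) d else NULL
  }
  imp <- switch(encoder,
    ificf = {
      if (is.null(vocab))
        stop("encoder \"ificf\" requires a vocabulary", call. = FALSE)
      rows <- lapply(seq_len(nrow(samples)), function(i) {
        d <- visible(samples$patient_id[i], samples$predictive_point[i])
        s <- if (is.null(d)) character(0) else
          vapply(split(d$drug_id, d$day), combo_key, "",
                 USE.NAMES = FALSE)
        ificf_weights(s, vocab)
      })
      m <- do.call(rbind, rows)
      if (is.null(m)) m <- matrix(0, 0, length(vocab$keys))
      colnames(m) <- paste0("im:", vocab$keys)
      m
    },
    bool = ,
    times = {
      rows <- lapply(seq_len(nrow(samples)), function(i) {
        d <- visible(samples$patient_id[i], samples$predictive_point[i])
        counts <- if (is.null(d)) numeric(length(inventory)) else
          as.numeric(table(factor(d$drug_id, levels = inventory)))
        if (encoder == "bool") as.numeric(counts > 0) else counts
      })
      m <- do.call(rbind, rows)
      if (is.null(m)) m <- matrix(0, 0, length(inventory))
      colnames(m) <- paste0("im:", inventory)
      m
    },
    none = matrix(0, nrow(samples), 0))
  x <- cbind(ex, imp)
  rownames(x) <- samples$patient_id
  nv <- length(variables)
  columns <- data.frame(
    name = colnames(x),
    group = c(rep("explicit_admission", nv),
              rep("explicit_predpoint", nv),
              rep("implicit", ncol(imp))),
    source = c(variables, variables,
               sub("^im:", "", colnames(imp))),
    stringsAsFactors = FALSE)
  structure(list(x = x, samples = samples, columns = columns,
                 encoder = encoder),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " samples x ", ncol(x$x),
      " features (", sum(x$columns$group != "implicit"), " explicit + ",
      sum(x$columns$group == "implicit"), " implicit, encoder \"",
      x$encoder, "\")\n", sep = "")
  invisible(x)
}

#' Impute missing explicit values
#'
#' A missing explicit value is replaced by the same patient's
#' nearest-in-time observation of the same variable on the visible days
#' (at or before the predictive point), preferring the earlier day on
#' distance ties. A patient with no observation of the variable at all
#' receives the derivation-set median of the column; medians are computed
#' on derivation samples only and reused for validation so no validation
#' information leaks into training. Implicit columns are untouched;
#' observed values are never altered.
#'
#' @param fm a [assemble_features()] result.
#' @param cohort the [ehr_cohort] the matrix was built from.
#' @param derivation logical vector (or integer indices) marking the
#'   derivation rows of `fm`; defaults to all rows.
#' @return a `feature_matrix` with no missing entries and an attribute
#'   `"medians"` holding the derivation medians used.
#' @export
impute_features <- function(fm, cohort, derivation = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  if (is.null(derivation)) derivation <- rep(TRUE, nrow(x))
  if (is.numeric(derivation))
    derivation <- seq_len(nrow(x)) %in% derivation
  explicit <- fm$columns$group != "implicit"

  # nearest-in-time fill from the patient's own series
  slot_day <- function(j) {
    if (fm$columns$group[j] == "explicit_admission") rep(0L, nrow(x))
    else fm$samples$predictive_point
  }
  m <- cohort$measurements
  series <- split(seq_len(nrow(m)),
                  paste(m$patient_id, m$variable, sep = "\r"))
  for (j in which(explicit)) {
    miss <- which(is.na(x[, j]))
    if (!length(miss)) next
    v <- fm$columns$source[j]
    days <- slot_day(j)
    for (i in miss) {
      rows <- series[[paste(fm$samples$patient_id[i], v, sep = "\r")]]
      if (is.null(rows)) next
      vis <- m$day[rows] <= fm$samples$predictive_point[i]
      if (!any(vis)) next
      obs_day <- m$day[rows][vis]
      obs_val <- m$value[rows][vis]
      dist <- abs(obs_day - days[i])
      sel <- which(dist == min(dist))
      day_pick <- min(obs_day[sel])            # earlier day on ties
      at_day <- which(obs_day == day_pick)
      x[i, j] <- obs_val[at_day[length(at_day)]]  # last value of the day
    }
  }

  # derivation medians for patients lacking the variable entirely
  medians <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  for (j in which(explicit)) {
    med <- median(x[derivation, j], na.rm = TRUE)
    if (is.na(med)) {
      med <- 0
      warning("explicit column ", colnames(x)[j],
              " entirely missing in the derivation set; filled with 0",
              call. = FALSE)
    }
    medians[j] <- med
    x[is.na(x[, j]), j] <- med
  }
  out <- fm
  out$x <- x
  attr(out, "medians") <- medians
  out
}
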