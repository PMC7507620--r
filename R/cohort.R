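# Internal time convention: calendar days as integer offsets from ICU
# admission (day 0 = admission day). 24 h = 1 day, 48 h = 2 days.

#' Construct an ICU cohort object from in-memory tables
#'
#' An `ehr_cohort` bundles the three long-format tables the pipeline
#' consumes: per-stay metadata, timestamped vital-sign/laboratory
#' measurements, and daily medication administrations. Days are integer
#' offsets from each patient's admission (day 0 = admission day).
#'
#' @param stays data frame with columns `patient_id`, `los_days`
#'   (length of stay in whole days, i.e. discharge day offset) and
#'   optionally `admit_date` (a `Date`).
#' @param measurements data frame with columns `patient_id`, `day`,
#'   `variable`, `value`.
#' @param medications data frame with columns `patient_id`, `day`,
#'   `drug_id`. Duplicate (patient, day, drug) rows are collapsed: a daily
#'   drug set contains each drug at most once.
#' @param creatinine_variable name of the measurement variable holding
#'   serum creatinine in mg/dl. Values in umol/l must be divided by 26.5
#'   before ingestion; the package never mixes units.
#'
#' @return An object of class `ehr_cohort`: a list with elements `stays`,
#'   `measurements`, `medications`, `variables` (sorted measurement
#'   variable names excluding creatinine), `drugs` (sorted drug inventory)
#'   and `creatinine_variable`.
#' @export
ehr_cohort <- function(stays, measurements, medications,
                       creatinine_variable = "creatinine") {
  stopifnot(is.data.frame(stays), is.data.frame(measurements),
            is.data.frame(medications))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("schema error: ", what, " table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(stays, c("patient_id", "los_days"), "stays")
  need(measurements, c("patient_id", "day", "variable", "value"),
       "measurements")
  need(medications, c("patient_id", "day", "drug_id"), "medications")

  stays$patient_id <- as.character(stays$patient_id)
  stays$los_days <- as.integer(stays$los_days)
  if (anyDuplicated(stays$patient_id))
    stop("integrity error: duplicated patient_id in stays table",
         call. = FALSE)
  if (any(stays$los_days < 0))
    stop("integrity error: discharge precedes admission for patient(s): ",
         paste(stays$patient_id[stays$los_days < 0], collapse = ", "),
         call. = FALSE)

  measurements$patient_id <- as.character(measurements$patient_id)
  measurements$day <- as.integer(measurements$day)
  measurements$variable <- as.character(measurements$variable)
  measurements$value <- as.numeric(measurements$value)
  medications$patient_id <- as.character(medications$patient_id)
  medications$day <- as.integer(medications$day)
  medications$drug_id <- as.character(medications$drug_id)
  medications <- unique(medications[, c("patient_id", "day", "drug_id")])

  check_window <- function(df, what) {
    unknown <- setdiff(df$patient_id, stays$patient_id)
    if (length(unknown))
      stop("integrity error: ", what,
           " reference stays absent from stays table: ",
           paste(sort(unique(unknown)), collapse = ", "), call. = FALSE)
    los <- stays$los_days[match(df$patient_id, stays$patient_id)]
    bad <- df$day < 0 | df$day > los
    if (any(bad))
      stop("integrity error: ", what,
           " outside the stay window for patient(s): ",
           paste(sort(unique(df$patient_id[bad])), collapse = ", "),
           call. = FALSE)
  }
  check_window(measurements, "measurement days")
  check_window(medications, "medication days")

  cr <- measurements$variable == creatinine_variable
  if (any(measurements$value[cr] <= 0, na.rm = TRUE))
    stop("integrity error: non-positive creatinine value(s) for patient(s): ",
         paste(sort(unique(measurements$patient_id[cr &
           measurements$value <= 0])), collapse = ", "), call. = FALSE)

  structure(list(
    stays = stays[, intersect(c("patient_id", "admit_date", "los_days"),
                              names(stays)), drop = FALSE],
    measurements = measurements,
    medications = medications,
    variables = setdiff(sort(unique(measurements$variable)),
                        creatinine_variable),
    drugs = sort(unique(medications$drug_id)),
    creatinine_variable = creatinine_variable
  ), class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", nrow(x$stays), " stays, ",
      nrow(x$measurements), " measurements (",
      length(x$variables), " variables + creatinine), ",
      nrow(x$medications), " medication rows (",
      length(x$drugs), " distinct drugs)\n", sep = "")
  invisible(x)
}

#' Read an ICU cohort from three delimited tables
#'
#' Ingests the long-format tables
#' `measurements(patient_id, date, variable, value)`,
#' `medications(patient_id, date, drug_id)` and
#' `stays(patient_id, admit_date, discharge_date)` with ISO-8601 dates,
#' converts dates to day offsets from admission and validates integrity
#' (every referenced stay exists; all event days fall inside the stay
#' window). Rows whose value or date fails to parse are reported via the
#' `"bad_rows"` attribute and a warning, never silently dropped.
#'
#' @param measurements_path,medications_path,stays_path file paths.
#' @param delim field delimiter; `","` (default) and `"\t"` are accepted.
#' @inheritParams ehr_cohort
#' @return An [ehr_cohort] object, with attribute `"bad_rows"` describing
#'   unparseable rows (possibly zero-row).
#' @export
read_cohort <- function(measurements_path, medications_path, stays_path,
                        delim = ",", creatinine_variable = "creatinine") {
  if (!delim %in% c(",", "\t"))
    stop("delim must be \",\" or \"\\t\"", call. = FALSE)
  rd <- function(path) {
    utils::read.table(path, header = TRUE, sep = delim,
                      colClasses = "character", stringsAsFactors = FALSE,
                      quote = "\"", comment.char = "", fill = FALSE,
                      fileEncoding = "UTF-8")
  }
  stays_raw <- rd(stays_path)
  meas_raw <- rd(measurements_path)
  meds_raw <- rd(medications_path)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("schema error: ", what, " table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(stays_raw, c("patient_id", "admit_date", "discharge_date"), "stays")
  need(meas_raw, c("patient_id", "date", "variable", "value"),
       "measurements")
  need(meds_raw, c("patient_id", "date", "drug_id"), "medications")

  iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

  admit <- iso_date(stays_raw$admit_date)
  disch <- iso_date(stays_raw$discharge_date)
  if (anyNA(admit) || anyNA(disch))
    stop("schema error: unparseable ISO-8601 date in stays table",
         call. = FALSE)
  stays <- data.frame(patient_id = stays_raw$patient_id,
                      admit_date = admit,
                      los_days = as.integer(disch - admit),
                      stringsAsFactors = FALSE)
  adm_of <- function(pid) stays$admit_date[match(pid, stays$patient_id)]

  bad <- list()
  mday <- iso_date(meas_raw$date)
  mval <- suppressWarnings(as.numeric(meas_raw$value))
  bad_m <- is.na(mday) | is.na(mval)
  if (any(bad_m))
    bad$measurements <- cbind(meas_raw[bad_m, , drop = FALSE],
                              row = which(bad_m))
  measurements <- data.frame(
    patient_id = meas_raw$patient_id[!bad_m],
    day = as.integer(mday[!bad_m] - adm_of(meas_raw$patient_id[!bad_m])),
    variable = meas_raw$variable[!bad_m],
    value = mval[!bad_m], stringsAsFactors = FALSE)

  dday <- iso_date(meds_raw$date)
  bad_d <- is.na(dday)
  if (any(bad_d))
    bad$medications <- cbind(meds_raw[bad_d, , drop = FALSE],
                             row = which(bad_d))
  medications <- data.frame(
    patient_id = meds_raw$patient_id[!bad_d],
    day = as.integer(dday[!bad_d] - adm_of(meds_raw$patient_id[!bad_d])),
    drug_id = meds_raw$drug_id[!bad_d], stringsAsFactors = FALSE)

  if (length(bad))
    warning(sum(vapply(bad, nrow, 1L)),
            " row(s) with unparseable values were excluded; ",
            "see attr(x, \"bad_rows\")", call. = FALSE)

  out <- ehr_cohort(stays, measurements, medications,
                    creatinine_variable = creatinine_variable)
  attr(out, "bad_rows") <- bad
  out
}

# Per-patient views used throughout the package ------------------------

#' Extract one patient's record from a cohort
#'
#' @param cohort an [ehr_cohort].
#' @param patient_id patient identifier.
#' @return list with `patient_id`, `los_days`, `measurements` (data frame),
#'   `daily_drugs` (list of character vectors keyed by day as name),
#'   `creatinine` (data frame `day`, `value` sorted by day, last value of
#'   each day kept).
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  i <- match(patient_id, cohort$stays$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  m <- cohort$measurements[cohort$measurements$patient_id == patient_id, ,
                           drop = FALSE]
  d <- cohort$medications[cohort$medications$patient_id == patient_id, ,
                          drop = FALSE]
  cr <- m[m$variable == cohort$creatinine_variable, c("day", "value")]
  cr <- cr[order(cr$day), , drop = FALSE]
  if (nrow(cr)) cr <- cr[!duplicated(cr$day, fromLast = TRUE), ,
                         drop = FALSE]
  dd <- if (nrow(d)) lapply(split(d$drug_id, d$day), function(x) sort(unique(x)))
        else list()
  list(patient_id = patient_id,
       los_days = cohort$stays$los_days[i],
       measurements = m,
       daily_drugs = dd,
       creatinine = cr)
}
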