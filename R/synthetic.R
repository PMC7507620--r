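# Seeded synthetic ICU cohort generator. The generator emulates the
# structure the pipeline assumes -- daily vitals/labs with missingness,
# skew-popularity daily drug sets, and creatinine trajectories built to
# satisfy (or avoid) the KDIGO criteria by construction -- plus a
# plantable drug-combination risk effect used for signal-recovery tests.

#' Configuration for the synthetic ICU cohort generator
#'
#' @param n_patients number of ICU stays to generate.
#' @param n_drugs size of the drug inventory; drug IDs are `D01`, `D02`,
#'   ... in decreasing order of popularity.
#' @param n_vitals number of non-creatinine daily measurement variables
#'   (`vital01`, `vital02`, ...).
#' @param stay_length integer `c(min, max)` length of stay in days
#'   (discharge day offset); minimum 1.
#' @param target_prevalence desired AKI fraction in (0, 1). The baseline
#'   daily hazard is calibrated so the expected prevalence over the
#'   realized covariates equals this value.
#' @param missing_rate probability in `[0, 1)` that a non-creatinine
#'   daily measurement cell is absent. Creatinine is recorded daily.
#' @param planted_combinations list of planted risk effects, each a list
#'   with `drugs` (character vector of drug IDs), `effect` (added to the
#'   daily log-odds of AKI once cumulative exposure reaches `min_days`)
#'   and `min_days` (exposure days before the effect activates).
#' @param exposure_rate fraction of patients given a forced exposure run:
#'   a contiguous block of days on which the daily drug set is exactly the
#'   planted combination. Exposure assignment is independent of outcome,
#'   so a zero effect implies no exposed/unexposed risk difference.
#' @param drug_popularity geometric decay ratio in (0, 1) of drug
#'   popularity; values near 1 flatten the distribution, small values
#'   concentrate prescribing on the head drugs so that the most widely
#'   used drug covers most patients.
#' @param vital_effect log-odds coefficient of the first vital's
#'   patient-level offset in the daily AKI hazard; gives the explicit
#'   indicators a genuine (but bounded) signal.
#' @param seed integer root seed; every draw descends from it via
#'   per-patient substreams, so per-patient output is invariant to
#'   cohort ordering.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          n_drugs = 25,
                          n_vitals = 8,
                          stay_length = c(3, 14),
                          target_prevalence = 0.15,
                          missing_rate = 0.2,
                          planted_combinations = list(
                            list(drugs = c("D04", "D06"), effect = 2.0,
                                 min_days = 2)),
                          exposure_rate = 0.35,
                          drug_popularity = 0.65,
                          vital_effect = 0.8,
                          seed = 1) {
  stopifnot(n_patients >= 0, n_drugs >= 1, n_vitals >= 1,
            length(stay_length) == 2, stay_length[1] >= 1,
            stay_length[1] <= stay_length[2],
            target_prevalence > 0, target_prevalence < 1,
            missing_rate >= 0, missing_rate < 1,
            exposure_rate >= 0, exposure_rate <= 1,
            drug_popularity > 0, drug_popularity < 1)
  inventory <- sprintf("D%02d", seq_len(n_drugs))
  for (pc in planted_combinations) {
    stopifnot(is.character(pc$drugs), length(pc$drugs) >= 1,
              is.numeric(pc$effect), pc$min_days >= 1)
    if (!all(pc$drugs %in% inventory))
      stop("planted combination drugs must lie in the drug inventory ",
           "(D01..", sprintf("D%02d", n_drugs), ")", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_drugs = as.integer(n_drugs),
                 n_vitals = as.integer(n_vitals),
                 stay_length = as.integer(stay_length),
                 target_prevalence = target_prevalence,
                 missing_rate = missing_rate,
                 planted_combinations = planted_combinations,
                 exposure_rate = exposure_rate,
                 drug_popularity = drug_popularity,
                 vital_effect = vital_effect,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Derive a per-patient substream seed (< 2^31) from the root seed.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %%
               2147483647)
}

#' Generate a synthetic ICU cohort
#'
#' Per patient: stay length uniform on the configured range; daily drug
#' sets drawn without replacement from a geometric popularity law (plus
#' forced-exposure runs of any planted combination); daily vitals are
#' AR(1) series around a patient-level offset; the daily AKI hazard is
#' `plogis(base + vital_effect * offset1 + sum of active planted effects)`
#' with `base` calibrated so the expected prevalence equals the target;
#' finally the creatinine series is built so that [kdigo_onset()] fires
#' exactly on the sampled event day (a 0.35 mg/dl rise over the preceding
#' 2-day minimum) and never fires for event-free patients (noise bounded
#' inside both KDIGO criteria).
#'
#' @param config a [cohort_config].
#' @return list with `cohort` (an [ehr_cohort]), `labels` (the generator's
#'   intended labels, same shape as [label_kdigo()] output), `truth`
#'   (per-patient truth sheet: exposure days, event cause) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  inventory <- sprintf("D%02d", seq_len(config$n_drugs))
  pop <- config$drug_popularity ^ (seq_len(config$n_drugs) - 1)
  pop <- pop / sum(pop)
  vitals <- sprintf("vital%02d", seq_len(config$n_vitals))
  plants <- config$planted_combinations

  pats <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    L <- sample(config$stay_length[1]:config$stay_length[2], 1L)
    off <- rnorm(config$n_vitals, 0, 1)
    # AR(1) daily deviations per vital, days 0..L
    ar <- matrix(0, nrow = L + 1L, ncol = config$n_vitals)
    for (k in seq_len(config$n_vitals)) {
      e <- rnorm(L + 1L, 0, 0.5)
      for (d in seq_len(L + 1L))
        ar[d, k] <- if (d == 1L) e[d] else 0.7 * ar[d - 1L, k] + e[d]
    }
    # daily drug sets
    day_has_meds <- runif(L + 1L) > 0.15
    nd <- pmin(1L + rpois(L + 1L, 1.2), 5L)
    drug_sets <- lapply(seq_len(L + 1L), function(d) {
      if (!day_has_meds[d]) return(character(0))
      sort(sample(inventory, nd[d], prob = pop))
    })
    # forced exposure runs (daily set becomes exactly the planted combo)
    exposed_flag <- logical(length(plants))
    for (j in seq_along(plants)) {
      exposed_flag[j] <- runif(1) < config$exposure_rate
      if (exposed_flag[j] && L >= 1L) {
        run <- min(plants[[j]]$min_days + rpois(1, 1), L)
        start <- sample(seq_len(max(1L, L - run + 1L)), 1L)
        for (d in start:(start + run - 1L))
          drug_sets[[d + 1L]] <- sort(plants[[j]]$drugs)
      }
    }
    u <- runif(L)                       # event-day uniforms, days 1..L
    cr_base <- runif(1, 0.6, 1.1)
    cr_noise <- runif(L, -0.08, 0.14)   # days 1..L
    miss <- matrix(runif((L + 1L) * config$n_vitals) < config$missing_rate,
                   nrow = L + 1L)
    # planted-effect activation per day (cumulative exposure >= min_days)
    active <- matrix(FALSE, nrow = L + 1L, ncol = max(1L, length(plants)))
    expo_days <- integer(length(plants))
    for (j in seq_along(plants)) {
      hit <- vapply(drug_sets,
                    function(s) all(plants[[j]]$drugs %in% s), TRUE)
      expo_days[j] <- sum(hit)
      active[, j] <- cumsum(hit) >= plants[[j]]$min_days
    }
    effects <- vapply(plants, function(p) p$effect, 1.0)
    xlin <- config$vital_effect * off[1] +
      if (length(plants)) as.numeric(active[-1L, seq_along(plants),
                                            drop = FALSE] %*% effects)
      else 0
    pats[[i]] <- list(L = L, off = off, ar = ar, drug_sets = drug_sets,
                      u = u, cr_base = cr_base, cr_noise = cr_noise,
                      miss = miss, xlin = xlin,
                      active = active, expo_days = expo_days,
                      exposed = expo_days >=
                        vapply(plants, function(p) p$min_days, 1.0))
  }

  # calibrate the baseline log-odds so expected prevalence == target
  base <- 0
  if (n > 0) {
    expected_prev <- function(b) {
      mean(vapply(pats, function(p)
        1 - prod(1 - plogis(b + p$xlin)), 1.0))
    }
    f <- function(b) expected_prev(b) - config$target_prevalence
    if (f(-30) > 0 || f(10) < 0)
      stop("configuration error: target prevalence ",
           config$target_prevalence,
           " is unattainable under the configured stay lengths and ",
           "effects", call. = FALSE)
    base <- uniroot(f, c(-30, 10), tol = 1e-10)$root
  }

  stays <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    admit_date = as.Date("2023-01-01") + (seq_len(n) - 1L) %% 60L,
    los_days = vapply(pats, function(p) p$L, 1L)[seq_len(n)],
    stringsAsFactors = FALSE)
  if (n == 0)
    stays <- data.frame(patient_id = character(0),
                        admit_date = as.Date(character(0)),
                        los_days = integer(0), stringsAsFactors = FALSE)

  meas_list <- vector("list", n)
  meds_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pats[[i]]
    pid <- stays$patient_id[i]
    haz <- plogis(base + p$xlin)
    hit <- which(p$u < haz)
    event_day <- if (length(hit)) hit[1] else NA_integer_

    # creatinine: first value = baseline; bounded noise keeps both KDIGO
    # criteria silent; on the event day force a 0.35 rise over the
    # preceding 2-day minimum, then stay elevated.
    cr <- numeric(p$L + 1L)
    cr[1L] <- p$cr_base
    shift <- 0
    for (d in seq_len(p$L)) {
      if (!is.na(event_day) && d == event_day) {
        lo <- max(1L, d - 1L)           # days d-2..d-1 as indices lo..d
        shift <- min(cr[lo:d]) + 0.35 - (p$cr_base + p$cr_noise[d])
      }
      cr[d + 1L] <- p$cr_base + p$cr_noise[d] + shift
    }

    grid <- expand.grid(day = 0:p$L, variable = vitals,
                        stringsAsFactors = FALSE)
    vals <- vapply(seq_len(nrow(grid)), function(r) {
      k <- match(grid$variable[r], vitals)
      10 * k + p$off[k] + p$ar[grid$day[r] + 1L, k]
    }, 1.0)
    keep <- !p$miss[cbind(grid$day + 1L, match(grid$variable, vitals))]
    meas <- data.frame(patient_id = pid,
                       day = c(grid$day[keep], 0:p$L),
                       variable = c(grid$variable[keep],
                                    rep("creatinine", p$L + 1L)),
                       value = c(vals[keep], round(cr, 4)),
                       stringsAsFactors = FALSE)
    meas_list[[i]] <- meas

    nd <- vapply(p$drug_sets, length, 1L)
    meds_list[[i]] <- data.frame(
      patient_id = rep(pid, sum(nd)),
      day = rep(0:p$L, nd),
      drug_id = unlist(p$drug_sets, use.names = FALSE),
      stringsAsFactors = FALSE)

    cause <- if (is.na(event_day)) NA_character_
      else if (length(plants) && any(p$active[event_day + 1L,
                                              seq_along(plants)]))
        "planted" else "background"
    truth_list[[i]] <- data.frame(
      patient_id = pid, is_aki = !is.na(event_day),
      onset_day = event_day,
      exposed = if (length(plants)) any(p$exposed) else FALSE,
      exposure_days = if (length(plants)) sum(p$expo_days) else 0L,
      cause = cause, stringsAsFactors = FALSE)
  }

  empty_meas <- data.frame(patient_id = character(0), day = integer(0),
                           variable = character(0), value = numeric(0),
                           stringsAsFactors = FALSE)
  empty_meds <- data.frame(patient_id = character(0), day = integer(0),
                           drug_id = character(0), stringsAsFactors = FALSE)
  cohort <- ehr_cohort(
    stays,
    if (n) do.call(rbind, meas_list) else empty_meas,
    if (n) do.call(rbind, meds_list) else empty_meds)

  truth <- if (n) do.call(rbind, truth_list) else
    data.frame(patient_id = character(0), is_aki = logical(0),
               onset_day = integer(0), exposed = logical(0),
               exposure_days = integer(0), cause = character(0),
               stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = truth$patient_id,
                       labelable = rep(TRUE, nrow(truth)),
                       is_aki = truth$is_aki, onset_day = truth$onset_day,
                       timing_days = truth$onset_day,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, labels = labels, truth = truth, config = config)
}

#' Write a cohort as the three delimited fixture tables
#'
#' Emits `stays.csv`, `measurements.csv` and `medications.csv` in the
#' layout [read_cohort()] consumes (ISO-8601 dates reconstructed from the
#' stay admission dates). Numeric values are printed with 17 significant
#' digits so a round trip reproduces the cohort exactly.
#'
#' @param cohort an [ehr_cohort].
#' @param dir output directory (created if needed).
#' @param delim field delimiter, `","` or `"\t"`.
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir, delim = ",") {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", dir, call. = FALSE)
  admit <- if ("admit_date" %in% names(cohort$stays))
    cohort$stays$admit_date else
      rep(as.Date("2023-01-01"), nrow(cohort$stays))
  adm_of <- function(pid) admit[match(pid, cohort$stays$patient_id)]

  stays_out <- data.frame(
    patient_id = cohort$stays$patient_id,
    admit_date = format(admit, "%Y-%m-%d"),
    discharge_date = format(admit + cohort$stays$los_days, "%Y-%m-%d"),
    stringsAsFactors = FALSE)
  meas_out <- data.frame(
    patient_id = cohort$measurements$patient_id,
    date = format(adm_of(cohort$measurements$patient_id) +
                    cohort$measurements$day, "%Y-%m-%d"),
    variable = cohort$measurements$variable,
    value = sprintf("%.17g", cohort$measurements$value),
    stringsAsFactors = FALSE)
  meds_out <- data.frame(
    patient_id = cohort$medications$patient_id,
    date = format(adm_of(cohort$medications$patient_id) +
                    cohort$medications$day, "%Y-%m-%d"),
    drug_id = cohort$medications$drug_id,
    stringsAsFactors = FALSE)

  paths <- c(stays = file.path(dir, "stays.csv"),
             measurements = file.path(dir, "measurements.csv"),
             medications = file.path(dir, "medications.csv"))
  wr <- function(df, path) utils::write.table(
    df, path, sep = delim, row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8")
  wr(stays_out, paths["stays"])
  wr(meas_out, paths["measurements"])
  wr(meds_out, paths["medications"])
  invisible(paths)
}
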