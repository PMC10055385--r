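# Case/control construction: apply the study's PsA case definition, the
# psoriasis-first requirement, eligibility filters (age, record span, fully
# observed window), index-date rules, and seeded 1:4 control sampling.

#' Cohort construction criteria
#'
#' Defaults encode the study definitions: a case has at least two outpatient
#' 696.0 (psoriatic arthropathy) diagnoses on distinct dates or at least one
#' admission claim, plus a psoriasis code (696.1/696.8) strictly before the
#' first 696.0; controls have psoriasis and no qualifying PsA pattern.
#' Eligibility requires age 5-99 at index, at least 156 weeks between first
#' and last record, an index date inside the 2002-2013 enrollment interval,
#' and the full observation + prediction window observed before the index.
#'
#' @param psa_code PsA diagnosis code.
#' @param pso_codes Psoriasis inclusion codes.
#' @param min_outpatient_psa,min_inpatient_psa Claim-count thresholds for the
#'   qualifying pattern (outpatient claims counted on distinct dates).
#' @param age_range Inclusive age bounds (completed years) at the index date.
#' @param min_record_span_weeks Minimum first-to-last record span.
#' @param enrollment_start,enrollment_end Index dates must fall inside this
#'   interval.
#' @param control_ratio Controls sampled per case.
#' @param sampling_seed Seed for control sampling.
#' @return A `cohort_criteria` object.
#' @export
cohort_criteria <- function(psa_code = "696.0",
                            pso_codes = c("696.1", "696.8"),
                            min_outpatient_psa = 2L,
                            min_inpatient_psa = 1L,
                            age_range = c(5L, 99L),
                            min_record_span_weeks = 156L,
                            enrollment_start = "2002-01-01",
                            enrollment_end = "2013-12-31",
                            control_ratio = 4L,
                            sampling_seed = 1L) {
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stop_cfg("age_range", "must be an ordered pair of years")
  structure(list(
    psa_code = psa_code, pso_codes = pso_codes,
    min_outpatient_psa = as.integer(min_outpatient_psa),
    min_inpatient_psa = as.integer(min_inpatient_psa),
    age_range = as.numeric(age_range),
    min_record_span_weeks = as.integer(min_record_span_weeks),
    enrollment_start = as_date(enrollment_start),
    enrollment_end = as_date(enrollment_end),
    control_ratio = as.integer(control_ratio),
    sampling_seed = as.integer(sampling_seed)
  ), class = "cohort_criteria")
}

# Parse-level validation shared by the identify operations: every diagnosis
# claim must carry an ICD-9-CM-shaped code (E-codes are tolerated here -- the
# cohort rules never match them -- but empty/garbled strings are an error,
# reported with their row number).
validate_claims <- function(claims) {
  claims <- as.data.table(claims)
  need <- c("patient_id", "event_date", "kind", "code")
  miss <- setdiff(need, names(claims))
  if (length(miss))
    stop(sprintf("claims table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  bad <- which(is.na(claims$code) | !grepl("^[A-Za-z0-9]", claims$code) |
                 grepl("\\s", claims$code))
  if (length(bad))
    stop(sprintf("malformed code string in claims row %d: '%s'",
                 bad[1], claims$code[bad[1]]), call. = FALSE)
  bad_kind <- which(!claims$kind %in% c("diagnosis", "prescription"))
  if (length(bad_kind))
    stop(sprintf("unknown record kind in claims row %d: '%s'",
                 bad_kind[1], claims$kind[bad_kind[1]]), call. = FALSE)
  claims
}

# Per-patient summary of the PsA pattern: distinct outpatient claim dates,
# inpatient claim count, and the first PsA diagnosis date of any setting.
psa_pattern <- function(claims, criteria) {
  psa <- claims[kind == "diagnosis" & code == criteria$psa_code]
  if (!nrow(psa)) {
    return(data.table(patient_id = character(), n_outpatient_dates = integer(),
                      n_inpatient = integer(), first_psa = as.Date(character()),
                      qualifies = logical()))
  }
  pat <- psa[, .(
    n_outpatient_dates = uniqueN(event_date[setting == "outpatient"]),
    n_inpatient = sum(setting == "inpatient"),
    first_psa = min(event_date)
  ), by = patient_id]
  pat[, qualifies := n_outpatient_dates >= criteria$min_outpatient_psa |
        n_inpatient >= criteria$min_inpatient_psa]
  pat
}

#' Identify PsA cases
#'
#' Returns exactly the patients meeting the qualifying PsA pattern whose first
#' psoriasis code predates their first PsA diagnosis strictly; patients
#' without psoriasis, or whose psoriasis first appears on/after the first PsA
#' date, are excluded. The index date is the first PsA diagnosis date (ties on
#' the same day are irrelevant: the earliest date wins).
#'
#' @param claims Claims table, date-sorted per patient.
#' @param criteria A [cohort_criteria()].
#' @return data.table with `patient_id`, `label = "case"`, `index_date`.
#' @export
identify_cases <- function(claims, criteria = cohort_criteria()) {
  claims <- validate_claims(claims)
  pat <- psa_pattern(claims, criteria)
  pso_claims <- claims[kind == "diagnosis" & code %in% criteria$pso_codes]
  if (!nrow(pso_claims)) {
    return(data.table(patient_id = character(), label = character(),
                      index_date = as.Date(character())))
  }
  pso <- pso_claims[, .(first_pso = min(event_date)), by = patient_id]
  cases <- merge(pat[qualifies == TRUE], pso, by = "patient_id")
  cases <- cases[first_pso < first_psa]
  out <- cases[, .(patient_id, label = "case", index_date = first_psa)]
  setorder(out, patient_id)
  out[]
}

#' Identify the control pool
#'
#' Patients with at least one psoriasis code and no qualifying PsA pattern
#' (sub-threshold 696.0 claims are allowed). The index date is the last record
#' date of any kind.
#'
#' @inheritParams identify_cases
#' @return data.table with `patient_id`, `label = "control"`, `index_date`.
#' @export
identify_control_pool <- function(claims, criteria = cohort_criteria()) {
  claims <- validate_claims(claims)
  pat <- psa_pattern(claims, criteria)
  excluded <- pat[qualifies == TRUE, patient_id]
  pso_pat <- unique(claims[kind == "diagnosis" & code %in% criteria$pso_codes,
                           patient_id])
  pool_ids <- setdiff(pso_pat, excluded)
  if (!length(pool_ids)) {
    return(data.table(patient_id = character(), label = character(),
                      index_date = as.Date(character())))
  }
  last_rec <- claims[patient_id %in% pool_ids,
                     .(index_date = max(event_date)), by = patient_id]
  out <- last_rec[, .(patient_id, label = "control", index_date)]
  setorder(out, patient_id)
  out[]
}

#' Apply eligibility filters
#'
#' Retains members aged within the criteria range (completed years) at index,
#' with a first-to-last record span of at least `min_record_span_weeks`, an
#' index date inside the enrollment interval, and the full observation +
#' prediction window fitting on/after the first record. Attaches
#' `age_at_index` (fractional years) and `sex` from demographics.
#'
#' @param members Output of [identify_cases()] / [identify_control_pool()].
#' @param claims Claims table for record spans.
#' @param demographics Table with `patient_id`, `birth_date`, `sex`; a missing
#'   row for any member is a data error naming the patient.
#' @param criteria A [cohort_criteria()].
#' @param windows A [window_spec()] giving the observation/prediction window
#'   that must be fully observed before the index date.
#' @return Filtered members with `age_at_index` and `sex` columns.
#' @export
apply_eligibility <- function(members, claims, demographics,
                              criteria = cohort_criteria(),
                              windows = window_spec()) {
  members <- as.data.table(members)
  if (!nrow(members)) {
    return(cbind(members, data.table(age_at_index = numeric(), sex = character())))
  }
  claims <- as.data.table(claims)
  demographics <- as.data.table(demographics)
  miss <- setdiff(members$patient_id, demographics$patient_id)
  if (length(miss))
    stop(sprintf("no demographics row for patient %s", miss[1]), call. = FALSE)
  spans <- claims[, .(first_rec = min(event_date), last_rec = max(event_date)),
                  by = patient_id]
  m <- merge(members, spans, by = "patient_id", all.x = TRUE)
  m <- merge(m, demographics[, .(patient_id, birth_date, sex)], by = "patient_id")
  m[, age_at_index := as.numeric(index_date - birth_date) / 365.25]
  window_days <- 7L * (windows$observation_weeks + windows$prediction_weeks)
  keep <- !is.na(m$first_rec) &
    floor(m$age_at_index) >= criteria$age_range[1] &
    floor(m$age_at_index) <= criteria$age_range[2] &
    as.numeric(m$last_rec - m$first_rec) >= 7L * criteria$min_record_span_weeks &
    m$index_date >= criteria$enrollment_start &
    m$index_date <= criteria$enrollment_end &
    as.numeric(m$index_date - m$first_rec) >= window_days
  out <- m[keep, .(patient_id, label, index_date, age_at_index, sex)]
  setorder(out, patient_id)
  out[]
}

#' Sample controls from the eligible pool
#'
#' Uniform sampling without replacement of exactly `control_ratio * n_cases`
#' controls, seeded by `criteria$sampling_seed`.
#'
#' @param pool Eligible control members.
#' @param n_cases Number of cases to match.
#' @param criteria A [cohort_criteria()].
#' @return data.table of sampled controls.
#' @export
sample_controls <- function(pool, n_cases, criteria = cohort_criteria()) {
  pool <- as.data.table(pool)
  n_want <- criteria$control_ratio * n_cases
  if (nrow(pool) < n_want)
    stop(sprintf("control pool too small: need %d controls, have %d (deficit %d)",
                 n_want, nrow(pool), n_want - nrow(pool)), call. = FALSE)
  idx <- with_seed(criteria$sampling_seed, sample(nrow(pool), n_want))
  out <- pool[sort(idx)]
  setorder(out, patient_id)
  out[]
}

#' Build the full case-control cohort
#'
#' Runs case identification, control-pool identification, eligibility, and
#' seeded 1:`control_ratio` control sampling, returning the combined cohort.
#'
#' @inheritParams apply_eligibility
#' @return data.table with `patient_id`, `label` (case/control), `index_date`,
#'   `age_at_index`, `sex`.
#' @export
build_cohort <- function(claims, demographics, criteria = cohort_criteria(),
                         windows = window_spec()) {
  cases <- apply_eligibility(identify_cases(claims, criteria),
                             claims, demographics, criteria, windows)
  pool <- apply_eligibility(identify_control_pool(claims, criteria),
                            claims, demographics, criteria, windows)
  controls <- sample_controls(pool, nrow(cases), criteria)
  out <- rbind(cases, controls)
  setorder(out, patient_id)
  out[]
}
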