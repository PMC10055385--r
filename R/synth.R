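# Seeded synthetic-claims generator. Emulates the statistical structure the
# downstream analysis assumes -- psoriasis patients with >= 156 weeks of
# outpatient/inpatient claims, a case subpopulation whose first psoriatic-
# arthritis (PsA) diagnosis defines the index date and whose designated risk
# codes occur at elevated rates inside the observation window -- so that every
# stage of the pipeline is testable with known ground truth.

#' Default per-visit code frequencies
#'
#' A single mapping covering both diagnosis (ICD-9-CM) and prescription (ATC)
#' codes; the record kind is inferred from the lexical form of the code. The
#' values are calibrated to the aggregate order of magnitude reported for this
#' population (roughly 30-50 diagnosis code-units and 40-50 drug-days per
#' person-year at the default visit rate), not to any real per-code
#' distribution.
#'
#' @return Named numeric vector, code -> per-visit probability.
#' @export
default_code_freqs <- function() {
  c(
    # common chronic / ambulatory diagnoses (3-digit ICD-9-CM)
    "401" = 0.10, "272" = 0.07, "250" = 0.05, "460" = 0.09, "465" = 0.07,
    "466" = 0.03, "486" = 0.02, "530" = 0.07, "558" = 0.03, "535" = 0.04,
    "715" = 0.05, "714" = 0.04, "719" = 0.05, "724" = 0.07, "729" = 0.04,
    "780" = 0.03, "786" = 0.03, "079" = 0.02, "691" = 0.03, "692" = 0.05,
    "110" = 0.03, "V04" = 0.01, "V70" = 0.02,
    # prescriptions (ATC categories; days supplied drawn separately)
    "N02BE" = 0.05, "M01AE" = 0.04, "M01AB" = 0.03, "A02BA" = 0.02,
    "R06AX" = 0.02, "D07AC" = 0.03, "D05AX02" = 0.01, "H02AB" = 0.01,
    "N05BA" = 0.01, "L04AX03" = 0.005, "D05AA" = 0.005
  )
}

#' Default days-supplied distribution
#'
#' Short ambulatory prescriptions dominate (3-7 days), with a tail of chronic
#' 28/60/90-day refills; support is restricted to 1..90 days.
#'
#' @return Named numeric vector, days -> probability (sums to 1).
#' @export
default_drug_days <- function() {
  c("3" = 0.33, "5" = 0.20, "7" = 0.30, "14" = 0.08, "28" = 0.06,
    "60" = 0.02, "90" = 0.01)
}

#' Configuration for the synthetic-claims generator
#'
#' Defaults state the emulated study conditions: claims from 1999-01-01 to
#' 2013-12-31, a 1:4 case-control ratio, a 131-week observation window
#' separated from the index date by a 25-week prediction window, and
#' demographic distributions matching the sampled population (cases mean age
#' 42.7 years, 61.4% male; controls 46.9 years, 57.1% male).
#'
#' @param n_cases Number of case patients to generate.
#' @param control_ratio Controls generated per case (study value 4).
#' @param n_controls Override for the control-pool size (default
#'   `control_ratio * n_cases`).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param calendar_start,calendar_end Calendar span of the claims database.
#' @param visit_rate Mean outpatient visits per patient-week (homogeneous
#'   Poisson process).
#' @param background_code_freqs Named vector, code -> per-visit probability;
#'   may mix ICD-9-CM and ATC codes. Must not contain 696.x, which the
#'   generator manages itself.
#' @param risk_codes Named vector, code -> rate multiplier (>= 0) applied to
#'   case visits inside the observation window; names must be a subset of
#'   `names(background_code_freqs)`.
#' @param drug_days_dist Named probability vector over days supplied
#'   (support 1..90).
#' @param age_dist List with `mean`/`sd` (each named `case`,`control`) and
#'   `range`, the truncation bounds for age at index.
#' @param sex_male Named vector of male fractions for cases and controls.
#' @param inpatient_fraction Probability a diagnosis event is an admission
#'   claim; also the probability that a case's qualifying PsA pattern is a
#'   single admission claim rather than two outpatient claims.
#' @param pso_visit_prob Per-visit probability of a psoriasis (696.1/696.8)
#'   diagnosis being recorded.
#' @param observation_weeks,prediction_weeks Window geometry the planted risk
#'   signal is aligned to.
#' @param risk_ramp If `TRUE` the risk-code multiplier ramps linearly from 1
#'   at the start of the observation window to its full value at the end, so
#'   the temporal convolution has a trend to find; if `FALSE` (default) the
#'   elevation is flat across the window.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_cases = 100L,
                       control_ratio = 4L,
                       n_controls = NULL,
                       seed = 1L,
                       calendar_start = "1999-01-01",
                       calendar_end = "2013-12-31",
                       visit_rate = 0.5,
                       background_code_freqs = default_code_freqs(),
                       risk_codes = c("714" = 3),
                       drug_days_dist = default_drug_days(),
                       age_dist = list(mean = c(case = 42.7, control = 46.9),
                                       sd = c(case = 17.2, control = 20.2),
                                       range = c(5, 95)),
                       sex_male = c(case = 0.614, control = 0.571),
                       inpatient_fraction = 0.05,
                       pso_visit_prob = 0.25,
                       observation_weeks = 131L,
                       prediction_weeks = 25L,
                       risk_ramp = FALSE) {
  if (!is_count(n_cases)) stop_cfg("n_cases", "must be a non-negative integer")
  if (!is_count(control_ratio) || control_ratio < 1)
    stop_cfg("control_ratio", "must be a positive integer")
  if (is.null(n_controls)) n_controls <- control_ratio * n_cases
  if (!is_count(n_controls)) stop_cfg("n_controls", "must be a non-negative integer")
  if (!is_count(abs(seed))) stop_cfg("seed", "must be an integer")
  calendar_start <- as_date(calendar_start)
  calendar_end <- as_date(calendar_end)
  if (is.na(calendar_start) || is.na(calendar_end) || calendar_start >= calendar_end)
    stop_cfg("calendar_span", "must be an ordered date interval")
  if (!is.numeric(visit_rate) || visit_rate <= 0)
    stop_cfg("visit_rate", "must be a positive rate per patient-week")
  p <- background_code_freqs
  if (is.null(names(p)) || any(names(p) == "") || any(p < 0) || any(p > 1))
    stop_cfg("background_code_freqs", "must be a named vector of probabilities in [0,1]")
  if (any(startsWith(names(p), "696")))
    stop_cfg("background_code_freqs",
             "must not contain 696.x codes; the generator plants those itself")
  if (length(risk_codes)) {
    if (is.null(names(risk_codes)) || any(risk_codes < 0))
      stop_cfg("risk_codes", "must be a named vector of multipliers >= 0")
    if (!all(names(risk_codes) %in% names(p)))
      stop_cfg("risk_codes", "must be a subset of names(background_code_freqs)")
  }
  dd <- drug_days_dist
  days <- suppressWarnings(as.integer(names(dd)))
  if (is.null(names(dd)) || anyNA(days) || any(days < 1) || any(days > 90) ||
      any(dd < 0) || abs(sum(dd) - 1) > 1e-8)
    stop_cfg("drug_days_dist", "must be a probability vector over days 1..90")
  for (f in c("mean", "sd")) {
    if (!all(c("case", "control") %in% names(age_dist[[f]])))
      stop_cfg("age_dist", sprintf("`%s` needs `case` and `control` entries", f))
  }
  if (length(age_dist$range) != 2L || diff(age_dist$range) <= 0)
    stop_cfg("age_dist", "`range` must be an ordered pair")
  if (!all(c("case", "control") %in% names(sex_male)) ||
      any(sex_male < 0) || any(sex_male > 1))
    stop_cfg("sex_male", "needs `case`/`control` fractions in [0,1]")
  if (inpatient_fraction < 0 || inpatient_fraction > 1)
    stop_cfg("inpatient_fraction", "must be a probability")
  if (pso_visit_prob < 0 || pso_visit_prob > 1)
    stop_cfg("pso_visit_prob", "must be a probability")
  if (!is_count(observation_weeks) || observation_weeks < 1)
    stop_cfg("observation_weeks", "must be a positive integer")
  if (!is_count(prediction_weeks) || prediction_weeks < 1)
    stop_cfg("prediction_weeks", "must be a positive integer")

  structure(list(
    n_cases = as.integer(n_cases), control_ratio = as.integer(control_ratio),
    n_controls = as.integer(n_controls), seed = as.integer(seed),
    calendar_start = calendar_start, calendar_end = calendar_end,
    visit_rate = visit_rate, background_code_freqs = p,
    risk_codes = risk_codes, drug_days_dist = dd, age_dist = age_dist,
    sex_male = sex_male, inpatient_fraction = inpatient_fraction,
    pso_visit_prob = pso_visit_prob,
    observation_weeks = as.integer(observation_weeks),
    prediction_weeks = as.integer(prediction_weeks),
    risk_ramp = isTRUE(risk_ramp)
  ), class = "sim_config")
}

code_is_drug <- function(code) {
  grepl("^[A-Z][0-9]{2}[A-Z]", code)
}

#' Simulate a synthetic claims population
#'
#' Generates patients as homogeneous Poisson visit processes over individual
#' record spans of at least 156 weeks (so the full observation + prediction
#' window fits before every index date). Cases receive a qualifying PsA
#' pattern anchored at their true index date (two outpatient 696.0 claims on
#' distinct dates, or one admission claim), a psoriasis code strictly before
#' it, and multiplicatively elevated risk-code rates inside the observation
#' window. Controls carry psoriasis codes, never a qualifying PsA pattern,
#' and their index date is their last record.
#'
#' @param config A [sim_config()].
#' @return List with `claims` (patient_id, event_date, kind, code, setting,
#'   days_supplied), `demographics` (patient_id, birth_date, sex) and `truth`
#'   (patient_id, true_label, true_index_date, plus the planted risk codes as
#'   an attribute `planted_risk_codes`), all keyed data.tables sorted
#'   deterministically.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  n_cases <- cfg$n_cases
  n_ctrl <- cfg$n_controls
  n <- n_cases + n_ctrl
  window_days <- 7L * (cfg$observation_weeks + cfg$prediction_weeks)
  pred_days <- 7L * cfg$prediction_weeks

  label <- rep(c("case", "control"), c(n_cases, n_ctrl))
  id <- sprintf("P%06d", seq_len(n))

  # Index dates: leave a full window + 1 week of history before the index and,
  # for cases, room for the second qualifying claim and some follow-up after.
  lo <- as.integer(cfg$calendar_start) + window_days + 7L
  hi <- as.integer(cfg$calendar_end)
  hi_case <- hi - 130L
  if (lo >= hi_case) stop_cfg("calendar_span", "too short for the window geometry")
  index <- integer(n)
  index[label == "case"] <- lo + floor(runif(n_cases) * (hi_case - lo + 1L))
  index[label == "control"] <- lo + floor(runif(n_ctrl) * (hi - lo + 1L))

  extra <- floor(runif(n) * 105) * 7L            # 0..104 extra weeks of history
  start <- pmax(as.integer(cfg$calendar_start), index - window_days - extra)

  # Demographics; age measured at the index date.
  grp <- ifelse(label == "case", "case", "control")
  age <- rtnorm(n, cfg$age_dist$mean[grp], cfg$age_dist$sd[grp],
                cfg$age_dist$range[1], cfg$age_dist$range[2])
  sex <- ifelse(runif(n) < cfg$sex_male[grp], "M", "F")
  birth <- index - as.integer(round(age * 365.25))

  # Case PsA pattern and record end.
  pat_inpt <- runif(n) < cfg$inpatient_fraction   # per-patient pattern draw
  delta2 <- 14L + floor(runif(n) * 107)           # second outpatient claim lag
  last <- integer(n)
  is_case <- label == "case"
  follow <- 28L + floor(runif(n) * 337)
  last[is_case] <- pmin(hi, pmax(index[is_case] + follow[is_case],
                                 index[is_case] + delta2[is_case]))
  last[!is_case] <- index[!is_case]               # control index = last record

  patients <- data.table(
    patient_id = id, label = label, index = index, start = start, last = last,
    birth = birth, age = age, sex = sex,
    pattern_inpatient = pat_inpt, delta2 = delta2
  )

  # Poisson visit process over each record span.
  span_weeks <- (patients$last - patients$start) / 7
  nv <- rpois(n, cfg$visit_rate * span_weeks)
  vis <- patients[rep(seq_len(n), nv),
                  .(patient_id, label, index, start, last)]
  vis[, date := start + floor(runif(.N) * (last - start + 1L))]
  # Anchor visits guarantee the record span and the prior-psoriasis claim.
  anchors <- rbind(
    patients[, .(patient_id, label, index, start, last, date = start, anchor = TRUE)],
    patients[, .(patient_id, label, index, start, last, date = last, anchor = TRUE)]
  )
  vis[, anchor := FALSE]
  vis <- rbind(vis, anchors)

  nvis <- nrow(vis)
  freqs <- cfg$background_code_freqs
  codes <- names(freqs)
  mult <- setNames(rep(1, length(codes)), codes)
  mult[names(cfg$risk_codes)] <- cfg$risk_codes

  # In-window flag (cases only) for the planted elevation; optional linear
  # ramp toward the index date.
  delta <- vis$index - vis$date
  inwin <- vis$label == "case" & delta >= pred_days + 1L & delta <= window_days
  ramp <- if (cfg$risk_ramp) {
    pmin(1, pmax(0, (window_days - delta) / (window_days - pred_days)))
  } else rep(1, nvis)

  ev <- vector("list", length(codes) + 2L)
  for (i in seq_along(codes)) {
    code <- codes[i]
    p <- freqs[[code]]
    m <- mult[[code]]
    peff <- rep(p, nvis)
    if (m != 1) {
      me <- 1 + (m - 1) * ramp[inwin]
      peff[inwin] <- pmin(1, p * me)
    }
    keep <- runif(nvis) < peff
    if (!any(keep)) next
    ev[[i]] <- data.table(patient_id = vis$patient_id[keep],
                          event_date = vis$date[keep], code = code)
  }

  # Psoriasis process: recurring 696.1/696.8 plus guaranteed claims at the
  # anchor visits (start of record for everyone, last record for controls).
  pso_keep <- runif(nvis) < cfg$pso_visit_prob | vis$anchor
  pso <- data.table(patient_id = vis$patient_id[pso_keep],
                    event_date = vis$date[pso_keep], code = "696.1")
  pso[runif(.N) < 0.15, code := "696.8"]
  ev[[length(codes) + 1L]] <- pso

  # Qualifying PsA pattern for cases, anchored at the true index date.
  if (n_cases) {
    pc <- patients[label == "case"]
    psa <- rbind(
      data.table(patient_id = pc$patient_id, event_date = pc$index,
                 code = "696.0", inpt = pc$pattern_inpatient),
      data.table(patient_id = pc$patient_id[!pc$pattern_inpatient],
                 event_date = pmin(pc$index[!pc$pattern_inpatient] +
                                     pc$delta2[!pc$pattern_inpatient], hi),
                 code = "696.0", inpt = FALSE)
    )
  } else {
    psa <- data.table(patient_id = character(), event_date = integer(),
                      code = character(), inpt = logical())
  }

  events <- rbindlist(ev, use.names = TRUE)
  is_drug <- code_is_drug(events$code)

  dx <- events[!is_drug]
  dx[, setting := ifelse(runif(.N) < cfg$inpatient_fraction, "inpatient", "outpatient")]
  dx <- rbind(dx, psa[, .(patient_id, event_date, code,
                          setting = ifelse(inpt, "inpatient", "outpatient"))])
  dx[, `:=`(kind = "diagnosis", days_supplied = NA_integer_)]

  rx <- events[is_drug]
  days_supp <- as.integer(names(cfg$drug_days_dist))
  rx[, days_supplied := days_supp[
    findInterval(runif(.N), cumsum(cfg$drug_days_dist), left.open = TRUE) + 1L]]
  rx[, `:=`(kind = "prescription", setting = NA_character_)]

  claims <- rbind(dx, rx, use.names = TRUE)
  claims[, event_date := as.Date(event_date, origin = "1970-01-01")]
  claims <- claims[, .(patient_id, event_date, kind, code, setting, days_supplied)]
  setorder(claims, patient_id, event_date, kind, code, setting, days_supplied,
           na.last = TRUE)
  # Deduplicate identical same-day claims so the two qualifying outpatient
  # claims are guaranteed to sit on distinct dates.
  claims <- unique(claims)

  demographics <- patients[, .(patient_id,
                               birth_date = as.Date(birth, origin = "1970-01-01"),
                               sex)]
  setorder(demographics, patient_id)

  truth <- patients[, .(patient_id, true_label = label,
                        true_index_date = as.Date(index, origin = "1970-01-01"))]
  setorder(truth, patient_id)
  setattr(truth, "planted_risk_codes", names(cfg$risk_codes))

  list(claims = claims[], demographics = demographics[], truth = truth[])
}

#' Write / read a simulated population as CSV
#'
#' Plain-CSV dialect: `claims.csv` with columns
#' `patient_id,event_date,kind,code,setting,days_supplied` (ISO-8601 dates,
#' empty fields where a column does not apply to the record kind),
#' `demographics.csv` with `patient_id,birth_date,sex`, and (when ground truth
#' is supplied) `truth.csv` with `patient_id,true_label,true_index_date`.
#'
#' @param claims,demographics,truth Tables as returned by
#'   [simulate_population()]; `truth` may be `NULL`.
#' @param path Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_claims <- function(claims, demographics, path, truth = NULL) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", path), call. = FALSE)
  }
  files <- file.path(path, c("claims.csv", "demographics.csv"))
  fwrite(as.data.table(claims), files[1], dateTimeAs = "ISO")
  fwrite(as.data.table(demographics), files[2], dateTimeAs = "ISO")
  if (!is.null(truth)) {
    files <- c(files, file.path(path, "truth.csv"))
    fwrite(as.data.table(truth)[, .(patient_id, true_label, true_index_date)],
           files[3], dateTimeAs = "ISO")
  }
  invisible(files)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "claims.csv") else path
  dt <- fread(f, colClasses = list(character = c("patient_id", "kind", "code",
                                                 "setting"),
                                   Date = "event_date",
                                   integer = "days_supplied"))
  dt[setting == "", setting := NA_character_]
  setorder(dt, patient_id, event_date, kind, code, setting, days_supplied,
           na.last = TRUE)
  dt[]
}

#' @rdname write_claims
#' @export
read_demographics <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "demographics.csv") else path
  fread(f, colClasses = list(character = c("patient_id", "sex"),
                             Date = "birth_date"))[]
}
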