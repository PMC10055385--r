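library(data.table)

# Shared fixtures. Everything is generated in code; the "scaled world" keeps
# the study's structure (visit process, planted signal geometry, eligibility
# rules tied to the window) while shrinking windows/cohorts so the suite fits
# a single-CPU budget. Scale-downs are documented in the methods vignette.

# A coherent scaled-down study world: windows shrink together with the
# eligibility span (so every simulated patient stays eligible) and the visit
# rate scales up by 131/obs so the number of in-window events -- and hence
# the statistical content of each map -- matches the full 131-week world.
scaled_world <- function(n_cases, seed, risk_codes = c("714" = 5),
                         obs = 52L, pred = 10L,
                         visit_rate = 0.5 * 131 / obs, ...) {
  cfg <- sim_config(n_cases = n_cases, seed = seed, risk_codes = risk_codes,
                    visit_rate = visit_rate,
                    observation_weeks = obs, prediction_weeks = pred, ...)
  list(
    cfg = cfg,
    windows = window_spec(obs, pred),
    criteria = cohort_criteria(min_record_span_weeks = obs + pred,
                               enrollment_start = "1999-01-01",
                               sampling_seed = seed)
  )
}

# Simulate -> cohort -> raw tpm_set in one go (compact vocabulary).
scaled_tpm_set <- function(n_cases, seed, extra_diag = character(), ...) {
  w <- scaled_world(n_cases, seed, ...)
  pop <- simulate_population(w$cfg)
  coh <- build_cohort(pop$claims, pop$demographics, w$criteria, w$windows)
  vocab <- vocabulary_from_claims(pop$claims, extra_diagnosis = extra_diag)
  list(ts = build_tpm_set(pop$claims, coh, vocab, w$windows),
       pop = pop, cohort = coh, world = w, vocab = vocab)
}

# Hand-built claim rows for cohort-rule tests.
claim_row <- function(id, date, code, kind = "diagnosis",
                      setting = if (kind == "diagnosis") "outpatient" else NA,
                      days = NA_integer_) {
  data.table::data.table(patient_id = id, event_date = as.Date(date),
                         kind = kind, code = code,
                         setting = as.character(setting),
                         days_supplied = as.integer(days))
}

claims_table <- function(...) data.table::rbindlist(list(...))

# Independent O(n^2) pairwise AUROC oracle (ties count 1/2).
auc_bruteforce <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Independent exhaustive-enumeration oracle for the threshold rule:
# candidates are the observed scores; maximize sens+spec, ties to higher
# sensitivity, then higher threshold.
threshold_bruteforce <- function(scores, labels) {
  y <- as.integer(labels)
  cand <- sort(unique(scores))
  best <- NULL
  for (thr in cand) {
    sens <- mean(scores[y == 1] >= thr)
    spec <- mean(scores[y == 0] < thr)
    key <- c(sens + spec, sens, thr)
    if (is.null(best) || key[1] > best[1] + 1e-12 ||
        (abs(key[1] - best[1]) <= 1e-12 &&
         (key[2] > best[2] + 1e-12 ||
          (abs(key[2] - best[2]) <= 1e-12 && key[3] > best[3])))) {
      best <- key
    }
  }
  best[3]
}
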