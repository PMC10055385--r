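# Cohort construction rules: the qualifying PsA pattern, psoriasis-first
# exclusion, index dates, eligibility filters, and seeded control sampling.

pso_before <- function(id) claim_row(id, "2003-01-01", "696.1")

test_that("the qualifying pattern covers all outpatient x inpatient combinations", {
  # enumerate {0,1,2} outpatient dates x {0,1} inpatient claims against the
  # rule: case iff outpatient >= 2 or inpatient >= 1 (with prior psoriasis)
  combos <- expand.grid(n_out = 0:2, n_in = 0:1)
  for (i in seq_len(nrow(combos))) {
    n_out <- combos$n_out[i]; n_in <- combos$n_in[i]
    rows <- list(pso_before("P1"))
    if (n_out >= 1) rows <- c(rows, list(claim_row("P1", "2006-01-10", "696.0")))
    if (n_out >= 2) rows <- c(rows, list(claim_row("P1", "2006-03-10", "696.0")))
    if (n_in >= 1) rows <- c(rows, list(
      claim_row("P1", "2006-02-01", "696.0", setting = "inpatient")))
    cases <- identify_cases(do.call(claims_table, rows))
    expected <- n_out >= 2 || n_in >= 1
    expect_identical(nrow(cases) == 1L, expected,
                     label = sprintf("n_out=%d n_in=%d", n_out, n_in))
    if (expected) {
      first <- if (n_out >= 1) as.Date("2006-01-10") else as.Date("2006-02-01")
      expect_identical(cases$index_date, first)
    }
  }
})

test_that("two same-day outpatient claims count as one date", {
  cl <- claims_table(pso_before("P1"),
                     claim_row("P1", "2006-01-10", "696.0"),
                     claim_row("P1", "2006-01-10", "696.0"))
  expect_identical(nrow(identify_cases(cl)), 0L)
})

test_that("psoriasis must exist and strictly precede the first PsA diagnosis", {
  psa2 <- function(id) claims_table(claim_row(id, "2006-01-10", "696.0"),
                                    claim_row(id, "2006-03-10", "696.0"))
  # no psoriasis at all
  expect_identical(nrow(identify_cases(psa2("P1"))), 0L)
  # psoriasis after PsA
  cl <- rbind(psa2("P1"), claim_row("P1", "2007-01-01", "696.1"))
  expect_identical(nrow(identify_cases(cl)), 0L)
  # psoriasis on the same day as the first PsA: not strictly before
  cl <- rbind(psa2("P1"), claim_row("P1", "2006-01-10", "696.8"))
  expect_identical(nrow(identify_cases(cl)), 0L)
  # 696.8 also counts as psoriasis when prior
  cl <- rbind(psa2("P1"), claim_row("P1", "2004-01-01", "696.8"))
  expect_identical(nrow(identify_cases(cl)), 1L)
})

test_that("control pool: psoriasis without a qualifying pattern, index = last record", {
  cl <- claims_table(
    pso_before("C1"), claim_row("C1", "2008-06-01", "401"),
    claim_row("C1", "2009-09-09", "696.1"),
    # C2 has a single sub-threshold outpatient PsA claim: still in the pool
    pso_before("C2"), claim_row("C2", "2007-01-01", "696.0"),
    claim_row("C2", "2010-02-02", "N02BA01", kind = "prescription", days = 7),
    # C3 is a case: excluded from the pool
    pso_before("C3"), claim_row("C3", "2006-01-10", "696.0"),
    claim_row("C3", "2006-05-10", "696.0"),
    # C4 has no psoriasis: not in the pool
    claim_row("C4", "2005-01-01", "250"))
  pool <- identify_control_pool(cl)
  expect_setequal(pool$patient_id, c("C1", "C2"))
  expect_identical(pool[patient_id == "C1", index_date], as.Date("2009-09-09"))
  expect_identical(pool[patient_id == "C2", index_date], as.Date("2010-02-02"))
  expect_identical(nrow(identify_control_pool(cl[0])), 0L)
  # disjointness with the case set
  expect_length(intersect(pool$patient_id, identify_cases(cl)$patient_id), 0L)
})

test_that("malformed codes are a parse error with a row reference", {
  cl <- claims_table(pso_before("P1"), claim_row("P1", "2006-01-10", "bad code"))
  expect_error(identify_cases(cl), "row 2")
})

test_that("eligibility retains exactly the hand-evaluated subset", {
  # ten members engineered around each boundary; window = 131 + 25 weeks
  mk <- function(id, index, first, last, birth) {
    list(member = data.table(patient_id = id, label = "control",
                             index_date = as.Date(index)),
         span = claims_table(claim_row(id, first, "696.1"),
                             claim_row(id, last, "696.1")),
         demo = data.table(patient_id = id, birth_date = as.Date(birth),
                           sex = "F"))
  }
  specs <- list(
    mk("E01", "2008-01-01", "2004-01-01", "2008-06-01", "1970-01-01"), # keep
    mk("E02", "2008-01-01", "2004-01-01", "2008-06-01", "2003-06-15"), # age 4
    mk("E03", "2008-01-01", "2004-01-01", "2008-06-01", "2002-06-15"), # age 5: keep
    mk("E04", "2008-01-01", "2004-01-01", "2008-06-01", "1907-06-15"), # age 100
    mk("E05", "2008-01-01", "2005-02-01", "2008-01-01", "1970-01-01"), # 152w span
    # 155-weeks span (just under 156): drop
    mk("E06", "2008-01-01", as.character(as.Date("2008-01-01") - 155 * 7),
       "2008-01-01", "1970-01-01"),
    # exactly 156 weeks, window fits exactly: keep
    mk("E07", "2008-01-01", as.character(as.Date("2008-01-01") - 156 * 7),
       "2008-01-01", "1970-01-01"),
    # long span but window does not fit before index: drop
    mk("E08", "2005-01-01", "2003-01-01", "2008-06-01", "1970-01-01"),
    mk("E09", "2001-06-01", "1999-01-01", "2005-06-01", "1970-01-01"), # index pre-2002
    mk("E10", "2013-06-01", "2009-01-01", "2013-06-01", "1970-01-01")  # keep
  )
  members <- data.table::rbindlist(lapply(specs, `[[`, "member"))
  claims <- data.table::rbindlist(lapply(specs, `[[`, "span"))
  demo <- data.table::rbindlist(lapply(specs, `[[`, "demo"))
  kept <- apply_eligibility(members, claims, demo)
  expect_setequal(kept$patient_id, c("E01", "E03", "E07", "E10"))
  expect_true(all(c("age_at_index", "sex") %in% names(kept)))

  # missing demographics names the patient
  expect_error(apply_eligibility(members, claims, demo[patient_id != "E05"]),
               "E05")
})

test_that("control sampling is exact, seeded, and errors on deficit", {
  pool <- data.table(patient_id = sprintf("C%03d", 1:100), label = "control",
                     index_date = as.Date("2010-01-01"))
  s1 <- sample_controls(pool, 20, cohort_criteria(sampling_seed = 5))
  s2 <- sample_controls(pool, 20, cohort_criteria(sampling_seed = 5))
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 80L)
  expect_false(identical(
    s1, sample_controls(pool, 20, cohort_criteria(sampling_seed = 6))))
  expect_identical(nrow(sample_controls(pool, 0, cohort_criteria())), 0L)
  expect_error(sample_controls(pool, 30, cohort_criteria()), "deficit 20")
})

test_that("built cohorts are disjoint, eligible, and hold the 1:4 ratio", {
  pop <- simulate_population(sim_config(n_cases = 30, seed = 77))
  coh <- build_cohort(pop$claims, pop$demographics)
  expect_identical(sum(coh$label == "case"), 30L)
  expect_identical(sum(coh$label == "control"), 120L)
  expect_identical(anyDuplicated(coh$patient_id), 0L)
  expect_true(all(floor(coh$age_at_index) >= 5 & floor(coh$age_at_index) <= 99))
})
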