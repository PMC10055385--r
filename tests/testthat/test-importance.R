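# Occlusion-sensitivity importance and logistic-regression odds ratios.

test_that("occlusion blanks exactly the requested rows and never mutates inputs", {
  fx <- scaled_tpm_set(6, seed = 23, obs = 13L, pred = 3L,
                       extra_diag = "V98")
  ts <- apply_normalization(fx$ts, fit_normalization(fx$ts))
  before <- ts$maps
  r <- which(apply(ts$maps, 1, sum) > 0)[1]
  occ <- occlude(ts, feature_group("one", rows = r))
  expect_identical(ts$maps, before)                 # input untouched
  expect_true(all(occ$maps[r, , ] == 0))
  diff_rows <- which(apply(occ$maps != ts$maps, 1, any))
  expect_identical(diff_rows, r)                    # only that row differs
  # occluding an all-zero row is a no-op
  zr <- which(apply(ts$maps, 1, sum) == 0)[1]
  expect_false(is.na(zr))
  expect_identical(occlude(ts, feature_group("zero", rows = zr))$maps, ts$maps)
  # occluding every row zeroes the array
  all_rows <- seq_len(dim(ts$maps)[1])
  expect_true(all(occlude(ts, feature_group("all", rows = all_rows))$maps == 0))
  # bounds are checked; empty groups are rejected
  expect_error(occlude(ts, feature_group("oob", rows = 10000L)), "row indices")
  expect_error(feature_group("empty"), "at least one")
  # auxiliary occlusion replaces age by the supplied fill
  occ_age <- occlude(ts, feature_group("age", include_age = TRUE),
                     aux_fill = c(age = 47))
  expect_true(all(occ_age$age == 47))
  expect_error(occlude(ts, feature_group("age", include_age = TRUE)), "aux_fill")
})

test_that("auroc_loss: zero for absent features, matches its definition otherwise", {
  fx <- scaled_tpm_set(10, seed = 29, obs = 13L, pred = 3L,
                       extra_diag = "V99")
  ts <- apply_normalization(fx$ts, fit_normalization(fx$ts))
  mod <- train_cnn(build_model(model_spec(epochs = 2L, seed = 1),
                               dim(ts$maps)[1:2]), ts)
  # a code absent from every map: loss exactly 0
  vr <- fx$vocab$row_index[["V99"]]
  expect_true(all(ts$maps[vr, , ] == 0))
  e <- auroc_loss(mod, ts, feature_group("V99", rows = vr))
  expect_identical(e$loss_percent, 0)
  expect_identical(e$auroc_full, e$auroc_occluded)
  # the loss invariant holds for a non-trivial feature
  r <- fx$vocab$row_index[["714"]]
  e2 <- auroc_loss(mod, ts, feature_group("714", rows = r))
  expect_equal(e2$loss_percent,
               (e2$auroc_occluded - e2$auroc_full) / e2$auroc_full * 100)
})

test_that("rank_features sorts ascending by loss with name tie-breaks, baseline intact", {
  fx <- scaled_tpm_set(10, seed = 37, obs = 13L, pred = 3L)
  ts <- apply_normalization(fx$ts, fit_normalization(fx$ts))
  mod <- train_cnn(build_model(model_spec(epochs = 2L, seed = 2),
                               dim(ts$maps)[1:2]), ts)
  base_before <- roc_auc(predict(mod, ts), ts$y)$auc
  r <- unname(fx$vocab$row_index[["714"]])
  feats <- list(feature_group("b_copy", rows = r),
                feature_group("a_copy", rows = r),
                feature_group("other", rows = unname(fx$vocab$row_index[["401"]])))
  ranked <- rank_features(mod, ts, feats)
  expect_identical(nrow(ranked), 3L)
  expect_true(!is.unsorted(ranked$loss_percent))
  # identical features: identical losses, name order
  dup <- ranked[ranked$feature %in% c("a_copy", "b_copy"), ]
  expect_identical(dup$loss_percent[1], dup$loss_percent[2])
  expect_identical(dup$feature, sort(dup$feature))
  # baseline AUROC identical before/after the importance run
  expect_identical(roc_auc(predict(mod, ts), ts$y)$auc, base_before)
})

test_that("two planted codes rank by their multipliers (5 before 2)", {
  # scaled ordering-recovery: 5 seeds, small world, adequate training
  wins <- 0L
  for (seed in 1:5) {
    fx <- scaled_tpm_set(50, seed = 600 + seed,
                         risk_codes = c("714" = 5, "719" = 2),
                         obs = 13L, pred = 3L)
    ts <- apply_normalization(fx$ts, fit_normalization(fx$ts))
    mod <- train_cnn(build_model(model_spec(epochs = 12L, batch_size = 16L,
                                            seed = seed),
                                 dim(ts$maps)[1:2]), ts)
    ranked <- rank_features(mod, ts, feature_groups_from_codes(
      fx$vocab, groups = list("714" = "714", "719" = "719")))
    if (identical(ranked$feature, c("714", "719"))) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("univariable logistic OR matches the closed-form cross-product", {
  # 2x2 table a=30 b=70 c=10 d=90 -> OR = (30*90)/(70*10) = 3.857...
  n <- 200
  cohort <- data.table(patient_id = sprintf("P%03d", 1:n),
                       label = rep(c("case", "control"), each = 100),
                       index_date = as.Date("2010-01-01"),
                       age_at_index = 50, sex = "F")
  exposed <- c(rep(TRUE, 30), rep(FALSE, 70), rep(TRUE, 10), rep(FALSE, 90))
  claims <- data.table(patient_id = cohort$patient_id[exposed],
                       event_date = as.Date("2010-01-01") - 200,
                       kind = "diagnosis", code = "714.0",
                       setting = "outpatient", days_supplied = NA_integer_)
  res <- logistic_ors(cohort, claims, "714", univariable = TRUE)
  expect_equal(res$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_true(res$estimable)
  expect_true(res$significant)
  expect_lt(res$ci_low, res$odds_ratio)
  expect_gt(res$ci_high, res$odds_ratio)
})

test_that("perfect separation is flagged non-estimable and the run continues", {
  n <- 60
  cohort <- data.table(patient_id = sprintf("S%03d", 1:n),
                       label = rep(c("case", "control"), each = 30),
                       index_date = as.Date("2010-01-01"),
                       age_at_index = 50, sex = "F")
  claims <- rbind(
    # "714" present in every case and no control: separated
    data.table(patient_id = cohort$patient_id[1:30],
               event_date = as.Date("2010-01-01") - 200, kind = "diagnosis",
               code = "714.0", setting = "outpatient",
               days_supplied = NA_integer_),
    # "401" present in a mixed subset: estimable
    data.table(patient_id = cohort$patient_id[c(5:20, 35:50)],
               event_date = as.Date("2010-01-01") - 300, kind = "diagnosis",
               code = "401.9", setting = "outpatient",
               days_supplied = NA_integer_))
  res <- logistic_ors(cohort, claims, c("714", "401"), univariable = TRUE)
  expect_false(res$estimable[res$predictor == "714"])
  expect_true(res$estimable[res$predictor == "401"])
})

test_that("OR confidence intervals cover the null at ~95% under independence", {
  # scaled coverage simulation: predictor independent of outcome
  set.seed(71)
  n <- 800
  cover <- vapply(1:120, function(i) {
    y <- rbinom(n, 1, 0.2)
    x <- rbinom(n, 1, 0.3)
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    sm <- summary(fit)$coefficients["x", ]
    lo <- exp(sm[1] - 1.96 * sm[2]); hi <- exp(sm[1] + 1.96 * sm[2])
    lo <= 1 && 1 <= hi
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("presence predictors only see the observation window", {
  cohort <- data.table(patient_id = "W1", label = "case",
                       index_date = as.Date("2010-01-01"),
                       age_at_index = 40, sex = "M")
  claims <- claims_table(
    claim_row("W1", as.Date("2010-01-01") - 10, "714"),   # prediction window
    claim_row("W1", as.Date("2010-01-01") - 400, "401"))  # observation window
  X <- tpmrisk:::presence_matrix(cohort, claims, c("714", "401"), window_spec())
  expect_identical(as.vector(X), c(0L, 1L))
})
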