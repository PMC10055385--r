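# Occlusion-sensitivity feature importance: zero a feature's map rows (or
# replace an auxiliary input by its training mean), rescore with the SAME
# trained model, and report the relative AUROC loss; plus logistic-regression
# odds ratios for identified predictors.

#' Define a feature group for occlusion
#'
#' A feature is one vocabulary code or a clinical group of codes (a set of map
#' rows), and/or one of the auxiliary inputs (age, sex).
#'
#' @param name Feature label (used for deterministic tie-breaking).
#' @param rows Integer map-row indices (may be empty if an auxiliary flag is
#'   set).
#' @param include_age,include_sex Occlude the auxiliary input as part of this
#'   feature.
#' @return A `feature_group` object.
#' @export
feature_group <- function(name, rows = integer(), include_age = FALSE,
                          include_sex = FALSE) {
  rows <- as.integer(rows)
  if (!length(rows) && !include_age && !include_sex)
    stop("feature group must name at least one row or auxiliary input",
         call. = FALSE)
  structure(list(name = as.character(name), rows = rows,
                 include_age = isTRUE(include_age),
                 include_sex = isTRUE(include_sex)),
            class = "feature_group")
}

#' Feature groups from vocabulary codes
#'
#' @param vocab A [vocabulary()].
#' @param groups Named list, group name -> character vector of vocabulary
#'   codes; or `NULL` to build one single-code group per vocabulary code in
#'   `codes`.
#' @param codes Codes for single-code groups when `groups` is `NULL`.
#' @return List of [feature_group()] objects.
#' @export
feature_groups_from_codes <- function(vocab, groups = NULL, codes = NULL) {
  stopifnot(inherits(vocab, "tpm_vocab"))
  if (is.null(groups)) {
    codes <- codes %||% names(vocab$row_index)
    groups <- setNames(as.list(codes), codes)
  }
  lapply(names(groups), function(nm) {
    rows <- vocab$row_index[groups[[nm]]]
    if (anyNA(rows))
      stop(sprintf("feature group '%s' references code(s) outside the vocabulary: %s",
                   nm, paste(groups[[nm]][is.na(rows)], collapse = ", ")),
           call. = FALSE)
    feature_group(nm, unname(rows))
  })
}

#' Occlude a feature in a set of maps
#'
#' Returns copies with the feature's rows set to 0 across all weeks; auxiliary
#' age/sex are replaced by the supplied fill values (training-set means) when
#' flagged. Inputs are never mutated.
#'
#' @param tpm_set A (normalized) `tpm_set`.
#' @param feature A [feature_group()].
#' @param aux_fill Named vector with `age` and/or `sex` fill values, required
#'   when the corresponding flag is set.
#' @return A new `tpm_set` with the feature blanked.
#' @export
occlude <- function(tpm_set, feature, aux_fill = NULL) {
  stopifnot(inherits(tpm_set, "tpm_set"), inherits(feature, "feature_group"))
  n_rows <- dim(tpm_set$maps)[1]
  if (length(feature$rows) &&
      (min(feature$rows) < 1L || max(feature$rows) > n_rows))
    stop(sprintf("feature '%s' has row indices outside 1..%d",
                 feature$name, n_rows), call. = FALSE)
  out <- tpm_set
  if (length(feature$rows)) out$maps[feature$rows, , ] <- 0
  if (feature$include_age) {
    if (is.null(aux_fill) || !"age" %in% names(aux_fill))
      stop("occluding age requires aux_fill[\"age\"]", call. = FALSE)
    out$age <- rep(as.numeric(aux_fill[["age"]]), length(out$age))
  }
  if (feature$include_sex) {
    if (is.null(aux_fill) || !"sex" %in% names(aux_fill))
      stop("occluding sex requires aux_fill[\"sex\"]", call. = FALSE)
    out$sex <- rep(as.numeric(aux_fill[["sex"]]), length(out$age))
  }
  out
}

#' AUROC loss under occlusion of one feature
#'
#' Scores the intact and occluded maps with the *same* trained model (no
#' refit) and reports the relative loss
#' `loss_percent = (auroc_occluded - auroc_full) / auroc_full * 100`
#' (negative = degradation).
#'
#' @param model A trained `tpm_cnn`.
#' @param tpm_set Normalized evaluation maps with labels.
#' @param feature A [feature_group()].
#' @param aux_fill See [occlude()].
#' @param baseline Optional precomputed intact AUROC (to avoid rescoring the
#'   baseline for every feature).
#' @return One-row data.frame: `feature`, `auroc_full`, `auroc_occluded`,
#'   `loss_percent`.
#' @export
auroc_loss <- function(model, tpm_set, feature, aux_fill = NULL,
                       baseline = NULL) {
  y <- tpm_set$y
  if (is.null(baseline))
    baseline <- roc_auc(predict(model, tpm_set), y, ci = "none")$auc
  occ <- occlude(tpm_set, feature, aux_fill)
  auc_occ <- roc_auc(predict(model, occ), y, ci = "none")$auc
  data.frame(feature = feature$name, auroc_full = baseline,
             auroc_occluded = auc_occ,
             loss_percent = (auc_occ - baseline) / baseline * 100,
             stringsAsFactors = FALSE)
}

#' Rank features by occlusion AUROC loss
#'
#' One occlusion per feature, each evaluated against the intact baseline
#' (leave-one-out, not cumulative removal), sorted ascending by
#' `loss_percent` -- the most damaging occlusion first -- with ties broken by
#' feature name for determinism.
#'
#' @inheritParams auroc_loss
#' @param features List of [feature_group()] objects.
#' @return data.frame of importance entries, most important first.
#' @export
rank_features <- function(model, tpm_set, features, aux_fill = NULL) {
  if (!length(features)) stop("no features supplied", call. = FALSE)
  baseline <- roc_auc(predict(model, tpm_set), tpm_set$y, ci = "none")$auc
  rows <- lapply(features, function(f)
    auroc_loss(model, tpm_set, f, aux_fill, baseline = baseline))
  out <- do.call(rbind, rows)
  out <- out[order(out$loss_percent, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Logistic-regression odds ratios for predictors
#'
#' Codes each predictor as presence/absence of the (truncated) code during the
#' member's observation window and fits a logistic regression of case status
#' on the predictors -- multivariable by default, to mitigate confounding, or
#' one univariable fit per predictor. Returns odds ratios with Wald confidence
#' intervals and p-values; perfectly separated predictors are flagged
#' non-estimable and the run continues.
#'
#' @param cohort Cohort members (with `index_date`, `label`).
#' @param claims Claims table.
#' @param predictors Character vector of vocabulary category codes.
#' @param windows A [window_spec()].
#' @param univariable Fit each predictor alone instead of jointly.
#' @param conf_level Wald CI coverage.
#' @return data.frame: `predictor`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `significant` (p < .05), `estimable`.
#' @export
logistic_ors <- function(cohort, claims, predictors, windows = window_spec(),
                         univariable = FALSE, conf_level = 0.95) {
  cohort <- as.data.table(cohort)
  claims <- as.data.table(claims)
  y <- as.integer(cohort$label == "case")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  X <- presence_matrix(cohort, claims, predictors, windows)
  fit_one <- function(Xsub) {
    df <- data.frame(y = y, Xsub, check.names = FALSE)
    suppressWarnings(glm(y ~ ., data = df, family = binomial(),
                         control = list(epsilon = 1e-12, maxit = 100)))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  extract <- function(fit, nm) {
    sm <- summary(fit)$coefficients
    row <- sm[rownames(sm) == paste0("`", nm, "`") | rownames(sm) == nm, ,
              drop = FALSE]
    if (!nrow(row) || abs(row[1, 1]) > 15 || row[1, 2] > 100) {
      return(data.frame(predictor = nm, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, significant = NA,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    est <- row[1, 1]; se <- row[1, 2]; p <- row[1, 4]
    data.frame(predictor = nm, odds_ratio = exp(est),
               ci_low = exp(est - z * se), ci_high = exp(est + z * se),
               p_value = p, significant = p < 0.05, estimable = TRUE,
               stringsAsFactors = FALSE)
  }
  if (univariable) {
    out <- do.call(rbind, lapply(predictors, function(nm)
      extract(fit_one(X[, nm, drop = FALSE]), nm)))
  } else {
    fit <- fit_one(X)
    out <- do.call(rbind, lapply(predictors, function(nm) extract(fit, nm)))
  }
  rownames(out) <- NULL
  out
}

# 0/1 matrix: member x predictor, presence of the truncated code inside the
# observation window.
presence_matrix <- function(cohort, claims, predictors, windows) {
  cl <- merge(claims, cohort[, .(patient_id, index_date)], by = "patient_id")
  cl[, cat := NA_character_]
  cl[kind == "diagnosis", cat := truncate_diagnosis_safe(code)]
  cl[kind == "prescription", cat := truncate_drug_safe(code)]
  cl[, col := lag_to_column(as.numeric(index_date - event_date), windows)]
  cl <- cl[!is.na(col) & cat %in% predictors]
  X <- matrix(0L, nrow(cohort), length(predictors),
              dimnames = list(NULL, predictors))
  if (nrow(cl)) {
    hit <- unique(cl[, .(patient_id, cat)])
    pid <- match(hit$patient_id, cohort$patient_id)
    X[cbind(pid, match(hit$cat, predictors))] <- 1L
  }
  X
}
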