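# Temporal phenomic maps: encode each cohort member's observation window as a
# codes-by-weeks matrix (weekly diagnosis counts; prescription days spread
# day-by-day), then normalize per row into [0,1] with statistics fitted on the
# training set only.

#' Observation / prediction window geometry
#'
#' Weeks are exact 7-day blocks counted backward from the index date: the
#' observation window ends `prediction_weeks * 7` days before the index, and
#' column `w` (1-based, 1 = oldest) of the map covers days
#' `[index - (P + W - w + 1) * 7, index - (P + W - w) * 7)` for
#' `W = observation_weeks`, `P = prediction_weeks`. Defaults are the study
#' geometry: 131 observation weeks, 25 prediction weeks.
#'
#' @param observation_weeks,prediction_weeks Positive integers.
#' @return A `window_spec` object.
#' @export
window_spec <- function(observation_weeks = 131L, prediction_weeks = 25L) {
  if (!is_count(observation_weeks) || observation_weeks < 1)
    stop_cfg("observation_weeks", "must be a positive integer")
  if (!is_count(prediction_weeks) || prediction_weeks < 1)
    stop_cfg("prediction_weeks", "must be a positive integer")
  structure(list(observation_weeks = as.integer(observation_weeks),
                 prediction_weeks = as.integer(prediction_weeks)),
            class = "window_spec")
}

# Map day lags (index_date - event day, in days) to 1-based map columns;
# NA outside the observation window.
lag_to_column <- function(delta, windows) {
  W <- windows$observation_weeks
  P <- windows$prediction_weeks
  col <- W + P + 1L - as.integer(ceiling(delta / 7))
  col[delta < P * 7L + 1L | delta > (W + P) * 7L] <- NA_integer_
  col
}

#' Build raw temporal phenomic maps for a cohort
#'
#' For every cohort member, diagnosis cells count that code's claims in each
#' observation-window week and drug cells count the prescription days falling
#' in each week (a prescription's supply is spread day-by-day from its start
#' date, so multi-week scripts populate adjacent columns and only in-window
#' days contribute). Claims dated in the prediction window or after the index
#' date contribute nothing. Codes that cannot be mapped to the vocabulary are
#' skipped and counted in `n_skipped`.
#'
#' @param claims Claims table.
#' @param cohort Cohort members with `patient_id`, `label`, `index_date`,
#'   `age_at_index`, `sex` (see [build_cohort()]).
#' @param vocab A [vocabulary()].
#' @param windows A [window_spec()].
#' @return A `tpm_set`: list with `maps` (array `n_rows x W x n_patients` of
#'   raw counts), `patient_id`, `label` (factor), `y` (0/1), `age`, `sex`,
#'   `vocab`, `windows`, `n_skipped`.
#' @export
build_tpm_set <- function(claims, cohort, vocab, windows = window_spec()) {
  stopifnot(inherits(vocab, "tpm_vocab"), inherits(windows, "window_spec"))
  claims <- as.data.table(claims)
  cohort <- as.data.table(cohort)
  if (anyDuplicated(cohort$patient_id))
    stop("cohort has duplicated patient ids", call. = FALSE)
  n <- nrow(cohort)
  W <- windows$observation_weeks
  maps <- array(0, dim = c(vocab$n_rows, W, n))

  cl <- merge(claims,
              cohort[, .(patient_id, index_date, pt = seq_len(.N))],
              by = "patient_id")
  n_skipped <- 0L
  if (nrow(cl)) {
    cl[, cat := NA_character_]
    cl[kind == "diagnosis", cat := truncate_diagnosis_safe(code)]
    cl[kind == "prescription", cat := truncate_drug_safe(code)]
    cl[, row := vocab$row_index[cat]]
    n_skipped <- sum(is.na(cl$row))
    cl <- cl[!is.na(row)]

    dx <- cl[kind == "diagnosis"]
    if (nrow(dx)) {
      dx[, col := lag_to_column(as.numeric(index_date - event_date), windows)]
      dx <- dx[!is.na(col), .(v = .N), by = .(row, col, pt)]
      if (nrow(dx)) maps[cbind(dx$row, dx$col, dx$pt)] <-
          maps[cbind(dx$row, dx$col, dx$pt)] + dx$v
    }
    rx <- cl[kind == "prescription" & !is.na(days_supplied) & days_supplied > 0]
    if (nrow(rx)) {
      # expand each prescription into its covered days
      days <- rx[rep(seq_len(.N), days_supplied)]
      days[, offset := sequence(rx$days_supplied) - 1L]
      days[, col := lag_to_column(as.numeric(index_date - event_date) - offset,
                                  windows)]
      days <- days[!is.na(col), .(v = .N), by = .(row, col, pt)]
      if (nrow(days)) maps[cbind(days$row, days$col, days$pt)] <-
          maps[cbind(days$row, days$col, days$pt)] + days$v
    }
  }

  age <- if ("age_at_index" %in% names(cohort)) cohort$age_at_index else
    rep(NA_real_, n)
  sex <- if ("sex" %in% names(cohort)) cohort$sex else rep(NA_character_, n)
  structure(list(
    maps = maps,
    patient_id = cohort$patient_id,
    label = factor(cohort$label, levels = c("control", "case")),
    y = as.integer(cohort$label == "case"),
    age = age,
    sex = sex,
    vocab = vocab,
    windows = windows,
    n_skipped = n_skipped
  ), class = "tpm_set")
}

#' Build one member's temporal phenomic map
#'
#' Convenience wrapper around [build_tpm_set()] for a single cohort member.
#'
#' @param member One-row cohort table (or list) with `patient_id`, `label`,
#'   `index_date` and optionally `age_at_index`, `sex`.
#' @inheritParams build_tpm_set
#' @return Numeric matrix `n_rows x observation_weeks` with attributes
#'   `patient_id`, `label`, `age`, `sex`.
#' @export
build_tpm <- function(member, claims, vocab, windows = window_spec()) {
  member <- as.data.table(as.list(unclass(member))[
    intersect(c("patient_id", "label", "index_date", "age_at_index", "sex"),
              names(member))])
  stopifnot(nrow(member) == 1L)
  ts <- build_tpm_set(claims, member, vocab, windows)
  m <- ts$maps[, , 1L]
  dim(m) <- dim(ts$maps)[1:2]
  structure(m, patient_id = ts$patient_id, label = as.character(ts$label[1]),
            age = ts$age, sex = ts$sex, n_skipped = ts$n_skipped)
}

#' @export
print.tpm_set <- function(x, ...) {
  cat(sprintf("<tpm_set> %d maps of %d rows x %d weeks (%d case / %d control)%s\n",
              length(x$patient_id), dim(x$maps)[1], dim(x$maps)[2],
              sum(x$y == 1), sum(x$y == 0),
              if (x$n_skipped) sprintf("; %d unmappable claims skipped", x$n_skipped)
              else ""))
  invisible(x)
}

#' Fit row-wise normalization statistics
#'
#' Per-row maxima over the training maps only; the transform divides each row
#' by its training maximum (rows with maximum 0 stay 0) and clips to [0,1], so
#' holdout cells exceeding the training maximum saturate at 1.
#'
#' @param tpm_set A raw [build_tpm_set()] result.
#' @param idx Indices of the training maps the statistics may see (default:
#'   all maps).
#' @return A `tpm_norm` object holding the per-row maxima.
#' @export
fit_normalization <- function(tpm_set, idx = NULL) {
  stopifnot(inherits(tpm_set, "tpm_set"))
  idx <- idx %||% seq_along(tpm_set$patient_id)
  if (!length(idx)) stop("need at least one training map", call. = FALSE)
  m <- tpm_set$maps[, , idx, drop = FALSE]
  dim(m) <- c(dim(m)[1], dim(m)[2] * dim(m)[3])
  structure(list(row_max = apply(m, 1L, max), n_fit = length(idx)),
            class = "tpm_norm")
}

#' Apply normalization to a tpm_set (or subset of it)
#'
#' @param tpm_set A raw `tpm_set`.
#' @param stats A [fit_normalization()] result.
#' @param idx Optional subset of maps to keep.
#' @return A `tpm_set` whose `maps` lie in [0,1].
#' @export
apply_normalization <- function(tpm_set, stats, idx = NULL) {
  stopifnot(inherits(tpm_set, "tpm_set"), inherits(stats, "tpm_norm"))
  out <- tpm_set
  if (!is.null(idx)) {
    out$maps <- tpm_set$maps[, , idx, drop = FALSE]
    out$patient_id <- tpm_set$patient_id[idx]
    out$label <- tpm_set$label[idx]
    out$y <- tpm_set$y[idx]
    out$age <- tpm_set$age[idx]
    out$sex <- tpm_set$sex[idx]
  }
  scale <- ifelse(stats$row_max > 0, stats$row_max, 1)
  out$maps <- pmin(out$maps / scale, 1)   # scale recycles along rows (dim 1)
  out$normalized <- TRUE
  out
}
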