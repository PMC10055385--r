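# Evaluation: 80:20 holdout split, stratified 5-fold cross-validation, ROC
# analysis (AUROC = tie-corrected Mann-Whitney statistic), optimal-threshold
# selection by maximum sensitivity + specificity, and confusion-matrix
# metrics.

#' Split plan
#'
#' @param holdout_fraction Fraction reserved for the final holdout (study
#'   value 0.2); 0 disables the holdout.
#' @param n_folds Cross-validation folds on the remaining training set.
#' @param seed Seed for the assignment.
#' @param stratified Stratify both the holdout and the folds by label
#'   (default), keeping the 1:4 case-control ratio in every part.
#' @return A `split_plan` object.
#' @export
split_plan <- function(holdout_fraction = 0.2, n_folds = 5L, seed = 1L,
                       stratified = TRUE) {
  if (holdout_fraction < 0 || holdout_fraction >= 1)
    stop_cfg("holdout_fraction", "must lie in [0, 1)")
  if (!is_count(n_folds) || n_folds < 2L)
    stop_cfg("n_folds", "must be an integer >= 2")
  structure(list(holdout_fraction = holdout_fraction,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "split_plan")
}

#' Deterministic holdout + cross-validation assignment
#'
#' @param labels 0/1 (or factor) label per sample.
#' @param plan A [split_plan()].
#' @return List with `holdout` (indices) and `folds` (list of validation-index
#'   vectors partitioning the non-holdout samples).
#' @export
make_split <- function(labels, plan = split_plan()) {
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2]) else
    as.integer(labels)
  n <- length(y)
  if (n < plan$n_folds)
    stop(sprintf("cannot split %d samples into %d folds", n, plan$n_folds),
         call. = FALSE)
  with_seed(plan$seed, {
    strata <- if (plan$stratified) split(seq_len(n), y) else list(seq_len(n))
    holdout <- integer()
    folds <- vector("list", plan$n_folds)
    offset <- 0L   # rotate fold assignment across strata so sizes balance
    for (s in strata) {
      s <- s[sample(length(s))]
      nh <- round(plan$holdout_fraction * length(s))
      holdout <- c(holdout, s[seq_len(nh)])
      rest <- s[-seq_len(nh)]
      if (nh == 0L) rest <- s
      fold_of <- ((seq_along(rest) - 1L + offset) %% plan$n_folds) + 1L
      offset <- (offset + length(rest)) %% plan$n_folds
      for (f in seq_len(plan$n_folds)) {
        folds[[f]] <- c(folds[[f]], rest[fold_of == f])
      }
    }
    list(holdout = sort(holdout), folds = lapply(folds, sort))
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by `n1 * n0`, counting
#' ties as 1/2 (rank formulation). Confidence intervals by stratified
#' bootstrap (default 2000 replicates) or the Hanley-McNeil normal
#' approximation.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels (1 = case).
#' @param ci `"bootstrap"`, `"normal"` or `"none"`.
#' @param conf_level CI coverage.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return List with `auc` and (unless `ci = "none"`) `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, ci = c("none", "bootstrap", "normal"),
                    conf_level = 0.95, n_boot = 2000L, seed = 1L) {
  ci <- match.arg(ci)
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  auc <- auc_rank(scores, y, n1, n0)
  out <- list(auc = auc)
  if (ci == "bootstrap") {
    i1 <- which(y == 1); i0 <- which(y == 0)
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      b1 <- i1[sample.int(n1, n1, replace = TRUE)]
      b0 <- i0[sample.int(n0, n0, replace = TRUE)]
      sb <- c(scores[b1], scores[b0])
      auc_rank(sb, rep(1:0, c(n1, n0)), n1, n0)
    }, numeric(1)))
    qs <- quantile(reps, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                   names = FALSE)
    out$ci_low <- qs[1]; out$ci_high <- qs[2]
  } else if (ci == "normal") {
    # Hanley & McNeil (1982) standard error
    q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
    z <- qnorm(1 - (1 - conf_level) / 2)
    out$ci_low <- max(0, auc - z * se); out$ci_high <- min(1, auc + z * se)
  }
  out
}

auc_rank <- function(scores, y, n1, n0) {
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal discrimination threshold
#'
#' The observed score maximizing sensitivity + specificity (Youden-style rule
#' with `score >= threshold` classed positive). Ties on the sum are broken
#' toward the higher sensitivity; residual ties toward the higher threshold.
#'
#' @inheritParams roc_auc
#' @return The selected threshold.
#' @export
optimal_threshold <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("threshold undefined: both classes must be present", call. = FALSE)
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(thr) sum(scores >= thr & y == 1) / n1, 0)
  spec <- vapply(cand, function(thr) sum(scores < thr & y == 0) / n0, 0)
  s <- sens + spec
  keep <- which(s > max(s) - 1e-12)
  keep <- keep[sens[keep] > max(sens[keep]) - 1e-12]
  cand[max(keep)]
}

#' Confusion-matrix metrics at a threshold
#'
#' Standard 2x2 definitions with `score >= threshold` classed positive;
#' ratios with a zero denominator are reported as `NA`, not 0.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, and the
#'   underlying counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  y <- as.integer(labels)
  pos <- scores >= threshold
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  fn <- sum(!pos & y == 1); tn <- sum(!pos & y == 0)
  ratio <- function(a, b) if (b == 0L) NA_real_ else a / b
  list(sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Cross-validated training and holdout evaluation
#'
#' For each fold: normalization statistics are fitted on that fold's training
#' maps only, a fresh model is trained, and the withheld fold is scored --
#' holdout samples never enter any normalization fit or training batch.
#' Finally the model is retrained on the full training set and scored once on
#' the holdout.
#'
#' @param tpm_set A *raw* (unnormalized) [build_tpm_set()] result.
#' @param plan A [split_plan()].
#' @param spec A [model_spec()].
#' @param ci_boot Bootstrap replicates for the holdout AUROC CI.
#' @param verbose Print fold progress.
#' @return An `eval_result`: per-fold metrics with mean/SD, the holdout
#'   metrics with AUROC CI and selected threshold, and per-fold bookkeeping
#'   (normalization checksums, indices) for leakage auditing.
#' @export
crossvalidate <- function(tpm_set, plan = split_plan(), spec = model_spec(),
                          ci_boot = 2000L, verbose = FALSE) {
  stopifnot(inherits(tpm_set, "tpm_set"))
  y <- tpm_set$y
  sp <- make_split(y, plan)
  train_all <- sort(unlist(sp$folds))
  input_shape <- dim(tpm_set$maps)[1:2]
  fold_rows <- list()
  fold_norm_sum <- numeric(length(sp$folds))
  for (f in seq_along(sp$folds)) {
    val <- sp$folds[[f]]
    tr <- setdiff(train_all, val)
    norm <- fit_normalization(tpm_set, tr)
    fold_norm_sum[f] <- sum(norm$row_max)
    spec_f <- spec
    spec_f$seed <- spec$seed + f
    mod <- build_model(spec_f, input_shape)
    mod <- train_cnn(mod, apply_normalization(tpm_set, norm, tr))
    scores <- predict(mod, apply_normalization(tpm_set, norm, val))
    yv <- y[val]
    auc <- roc_auc(scores, yv, ci = "none")$auc
    thr <- optimal_threshold(scores, yv)
    cm <- confusion_metrics(scores, yv, thr)
    fold_rows[[f]] <- data.frame(fold = f, n_val = length(val), auroc = auc,
                                 threshold = thr,
                                 sensitivity = cm$sensitivity,
                                 specificity = cm$specificity,
                                 ppv = cm$ppv, npv = cm$npv)
    if (verbose) message(sprintf("fold %d/%d: AUROC %.3f", f,
                                 length(sp$folds), auc))
  }
  folds_df <- do.call(rbind, fold_rows)
  mets <- c("auroc", "sensitivity", "specificity", "ppv", "npv")
  summary_df <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(folds_df[[m]], na.rm = TRUE), 0),
    sd = vapply(mets, function(m) sd(folds_df[[m]], na.rm = TRUE), 0)
  )
  holdout <- NULL
  final_model <- NULL
  if (length(sp$holdout)) {
    norm <- fit_normalization(tpm_set, train_all)
    final_model <- train_cnn(build_model(spec, input_shape),
                             apply_normalization(tpm_set, norm, train_all))
    scores <- predict(final_model, apply_normalization(tpm_set, norm, sp$holdout))
    yh <- y[sp$holdout]
    auc <- roc_auc(scores, yh, ci = if (ci_boot > 0) "bootstrap" else "none",
                   n_boot = ci_boot, seed = plan$seed)
    thr <- optimal_threshold(scores, yh)
    holdout <- c(list(n = length(sp$holdout), threshold = thr, scores = scores),
                 auc, confusion_metrics(scores, yh, thr))
  }
  structure(list(folds = folds_df, summary = summary_df, holdout = holdout,
                 split = sp, fold_norm_sum = fold_norm_sum,
                 final_model = final_model, plan = plan),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> cross-validation folds:\n")
  print(x$folds, row.names = FALSE, digits = 3)
  cat("summary (mean, SD over folds):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$holdout)) {
    cat(sprintf("holdout (n=%d): AUROC %.3f", x$holdout$n, x$holdout$auc))
    if (!is.null(x$holdout$ci_low))
      cat(sprintf(" (95%% CI %.3f-%.3f)", x$holdout$ci_low, x$holdout$ci_high))
    cat(sprintf(", threshold %.3f, sens %.2f, spec %.2f\n",
                x$holdout$threshold, x$holdout$sensitivity,
                x$holdout$specificity))
  }
  invisible(x)
}
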