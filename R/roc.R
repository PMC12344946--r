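# ROC / Youden diagnostics for one parameter x genotype question, plus the
# confusion-matrix arithmetic that reconstructs published accuracies and the
# stratified re-evaluation at fixed cut-offs.

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC of a continuous VOI-mean parameter against a binary
#' molecular label. The AUC is the rank-sum (Mann-Whitney) estimator, which
#' equals the trapezoidal area under the empirical curve (ties contribute
#' 1/2); the 95% CI uses the DeLong variance estimator (via
#' \pkg{pROC}). The decision direction is auto-oriented so AUC >= 0.5 and
#' recorded. The operating threshold maximizes the Youden index J =
#' sensitivity + specificity - 1 over all observed values, ties broken
#' toward the smaller threshold; the decision rule is inclusive ("predict
#' positive if the value is on the positive side of the threshold, the
#' threshold itself included").
#'
#' @param values Numeric vector of per-subject parameter means.
#' @param labels Vector of class labels (two classes, n >= 3 each).
#' @param positive The positive-class label (IDH-mutant for the IDH
#'   question, non-codeleted for 1p/19q).
#' @return List of class `roc_result`: `auc`, `ci_lo`, `ci_hi`, `direction`
#'   (`"higher"` or `"lower"` = which side of the threshold is called
#'   positive), `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, labels, positive) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  if (n_pos < 3 || n_neg < 3) stop("need n >= 3 per class")

  auc_hi <- rank_sum_auc(values[is_pos], values[!is_pos])
  direction <- if (auc_hi >= 0.5) "higher" else "lower"
  auc <- max(auc_hi, 1 - auc_hi)

  sweep <- threshold_sweep(values, is_pos, direction)
  best <- which(sweep$j == max(sweep$j))
  best <- best[which.min(sweep$threshold[best])]  # ties -> smaller threshold

  ci <- tryCatch({
    r <- pROC::roc(response = factor(is_pos, levels = c(FALSE, TRUE)),
                   predictor = values,
                   direction = if (direction == "higher") "<" else ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
  }, error = function(e) c(NA_real_, NA_real_))

  structure(list(auc = auc, ci_lo = ci[1], ci_hi = ci[2],
                 direction = direction,
                 threshold = sweep$threshold[best],
                 sensitivity = sweep$sens[best],
                 specificity = sweep$spec[best],
                 accuracy = sweep$acc[best],
                 youden_j = sweep$j[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

# Mann-Whitney AUC of "positive values higher", ties counted 1/2.
rank_sum_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Confusion metrics at every observed threshold under the inclusive rule.
threshold_sweep <- function(values, is_pos, direction) {
  thr <- sort(unique(values))
  sens <- spec <- acc <- numeric(length(thr))
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  for (i in seq_along(thr)) {
    pred <- if (direction == "higher") values >= thr[i] else values <= thr[i]
    tp <- sum(pred & is_pos); tn <- sum(!pred & !is_pos)
    sens[i] <- tp / n_pos
    spec[i] <- tn / n_neg
    acc[i] <- (tp + tn) / (n_pos + n_neg)
  }
  list(threshold = thr, sens = sens, spec = spec, acc = acc,
       j = sens + spec - 1)
}

#' Accuracy reconstructed from printed sensitivity and specificity
#'
#' Given a published (sensitivity, specificity) pair and the class sizes,
#' reconstructs the integer confusion matrix (TP = round(sens * n_pos),
#' TN = round(spec * n_neg)) and the implied accuracy. Errors if a rate is
#' inconsistent with any integer count beyond rounding tolerance (0.005),
#' i.e. could not have been produced by those group sizes.
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @param n_pos,n_neg Class sizes (>= 1).
#' @return List with `accuracy`, `tp`, `fn`, `tn`, `fp`.
#' @export
accuracy_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  if (abs(sensitivity - tp / n_pos) > 0.005) {
    stop("sensitivity inconsistent with any integer count at n_pos = ", n_pos)
  }
  if (abs(specificity - tn / n_neg) > 0.005) {
    stop("specificity inconsistent with any integer count at n_neg = ", n_neg)
  }
  list(accuracy = (tp + tn) / (n_pos + n_neg),
       tp = tp, fn = n_pos - tp, tn = tn, fp = n_neg - tn)
}

#' Per-parameter ROC table for one genotype question
#'
#' Runs [roc_analysis()] for each of the nine parameters against one
#' genotype question with the cohort's positive-class conventions
#' (IDH-mutant; 1p/19q non-codeleted).
#'
#' @param cohort A `cohort_table`.
#' @param question `"IDH"` or `"1p19q"`.
#' @return Tibble mirroring the published ROC table layout.
#' @export
genotype_roc_table <- function(cohort, question = c("IDH", "1p19q")) {
  question <- match.arg(question)
  rows <- lapply(parameter_registry(), function(p) {
    gr <- question_groups(cohort, question, p)
    # a = wild-type / non-codeleted, b = mutant / codeleted
    if (question == "IDH") {
      values <- c(gr$a, gr$b)
      labels <- rep(c("neg", "pos"), c(length(gr$a), length(gr$b)))
    } else {
      values <- c(gr$a, gr$b)
      labels <- rep(c("pos", "neg"), c(length(gr$a), length(gr$b)))
    }
    r <- roc_analysis(values, labels, positive = "pos")
    tibble::tibble(question = question, parameter = p, auc = r$auc,
                   ci_lo = r$ci_lo, ci_hi = r$ci_hi,
                   direction = r$direction, threshold = r$threshold,
                   sensitivity = r$sensitivity, specificity = r$specificity,
                   accuracy = r$accuracy, youden_j = r$youden_j)
  })
  do.call(rbind, rows)
}

#' Diagnostic performance within morphology strata at a fixed cut-off
#'
#' Applies an externally provided decision threshold (not re-optimized per
#' stratum) to one parameter within the strata defined by a logical
#' morphology column (e.g. `enhancement`), reporting sensitivity,
#' specificity and accuracy per stratum. A stratum missing one class
#' reports accuracy only (the class-conditional rate is `NA`); an empty
#' stratum is skipped.
#'
#' @param cohort A `cohort_table`.
#' @param stratum_flag Name of a logical column of `cohort`.
#' @param parameter Name of the parameter column.
#' @param threshold Fixed decision threshold.
#' @param direction `"higher"` or `"lower"`: the positive side of the
#'   threshold (inclusive).
#' @param question `"IDH"` or `"1p19q"` (sets the positive class:
#'   IDH-mutant / non-codeleted).
#' @return Tibble with one row per stratum level.
#' @export
stratified_performance <- function(cohort, stratum_flag, parameter,
                                   threshold,
                                   direction = c("higher", "lower"),
                                   question = c("IDH", "1p19q")) {
  direction <- match.arg(direction)
  question <- match.arg(question)
  if (!stratum_flag %in% names(cohort)) stop("unknown stratum flag")
  rows <- list()
  for (lev in c(TRUE, FALSE)) {
    sub <- cohort[!is.na(cohort[[stratum_flag]]) &
                    cohort[[stratum_flag]] == lev, ]
    if (question == "1p19q") {
      sub <- sub[sub$codeletion_status != "not-applicable", ]
    }
    v <- sub[[parameter]]
    keep <- is.finite(v)
    sub <- sub[keep, ]; v <- v[keep]
    if (nrow(sub) == 0) {
      message("stratum ", stratum_flag, " = ", lev, " is empty; skipped")
      next
    }
    is_pos <- if (question == "IDH") sub$idh_status == "mutant"
              else sub$codeletion_status == "non-codeleted"
    pred <- if (direction == "higher") v >= threshold else v <= threshold
    tp <- sum(pred & is_pos); fn <- sum(!pred & is_pos)
    tn <- sum(!pred & !is_pos); fp <- sum(pred & !is_pos)
    rows[[length(rows) + 1]] <- tibble::tibble(
      stratum = stratum_flag, level = lev, n = nrow(sub),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (tp + tn) / nrow(sub))
  }
  do.call(rbind, rows)
}
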