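# Inferential machinery: normality-gated two-group tests, BH correction over
# the 18 parameter-by-gene hypotheses, effect sizes, categorical tests and
# inter-rater agreement.

#' Normality-gated two-group comparison
#'
#' Reproduces the test-selection gate used for the cohort comparisons: each
#' group is tested for normality (Shapiro-Wilk at alpha = 0.05, both groups
#' must pass); normal data are then gated by Levene's test of variance
#' homogeneity (alpha = 0.05) into a pooled or Welch t-test; anything else
#' goes to the two-sided Mann-Whitney U test. Group summaries are formatted
#' "mean +/- SD" on the t path and "median (Q1, Q3)" on the U path. Cohen's d
#' (pooled SD, `mean(a) - mean(b)`) is attached regardless of path.
#'
#' @param a,b Numeric vectors (first and second group; for the cohort
#'   questions the convention is a = wild-type vs b = mutant, and
#'   a = non-codeleted vs b = codeleted).
#' @param alpha Gate level for the Shapiro-Wilk and Levene tests.
#' @return List of class `group_comparison`: `test` (`"t"`, `"welch_t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `cohens_d`, `normal_gate`,
#'   `equal_var_gate`, and per-group `summary_a` / `summary_b` strings.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both groups")
  }
  sw_p <- function(x) {
    if (stats::var(x) == 0) return(0)  # constant group: not normal
    stats::shapiro.test(x)$p.value
  }
  normal <- sw_p(a) > alpha && sw_p(b) > alpha
  equal_var <- NA
  if (normal) {
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(c(a, b) ~ g, center = mean)
    equal_var <- lev[["Pr(>F)"]][1] > alpha
    tt <- stats::t.test(a, b, var.equal = equal_var)
    test <- if (equal_var) "t" else "welch_t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    test <- "mann_whitney"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  fmt <- function(x) {
    if (normal) sprintf("%.3f ± %.3f", mean(x), stats::sd(x))
    else sprintf("%.3f (%.3f, %.3f)",
                 stats::median(x), stats::quantile(x, 0.25),
                 stats::quantile(x, 0.75))
  }
  structure(list(test = test, statistic = statistic, p_value = p,
                 cohens_d = cohens_d(a, b), normal_gate = normal,
                 equal_var_gate = equal_var,
                 summary_a = fmt(a), summary_b = fmt(b),
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' order-preserving with the input indexing, monotone and capped at 1. In
#' the cohort analysis it is applied jointly to the 18 p-values of the
#' 9 parameters x 2 genotype questions.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
adjust_bh <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Cohen's d with pooled SD
#'
#' `d = (mean(a) - mean(b)) / s_pooled`. The cohort sign convention fixes the
#' group order as (wild-type, mutant) for IDH and (non-codeleted, codeleted)
#' for 1p/19q, so a negative d means the second (mutant / codeleted) group is
#' higher. |d| > 0.8 is read as a strong effect.
#'
#' @param a,b Numeric vectors, n >= 2 each.
#' @return The effect size d.
#' @export
cohens_d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Chi-square test for categorical tables
#'
#' Pearson chi-square on a 2 x k contingency table. Continuity correction
#' policy: none for 2 x k with k > 2; Yates correction for 2 x 2 tables
#' where any expected count is below 10, plain Pearson otherwise.
#'
#' @param tab Matrix of non-negative integer counts.
#' @return List with `statistic`, `p_value`, `expected` and `correction`
#'   (logical, whether Yates was applied).
#' @export
chi_square_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in the contingency table")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  correct <- all(dim(tab) == 2) && any(expected < 10)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       expected = expected, correction = correct)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-rater absolute-agreement ICC from the two-way random-effects ANOVA
#' decomposition, the form used to assess inter-observer agreement of the
#' VOI-mean parameters, with the 95% CI from the standard F-distribution
#' bounds (McGraw & Wong).
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 5 subjects, >= 2 raters, no missing cells).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci_lo`, `ci_hi`, `model`.
#' @export
icc_two_way_random <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("need >= 5 subjects and >= 2 raters")
  if (anyNA(ratings)) stop("no missing cells allowed")
  if (stats::var(as.vector(ratings)) == 0) {
    stop("constant ratings matrix: ICC undefined")
  }
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + bb * mse)^2 /
    ((a * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_lo = lo, ci_hi = hi,
                 model = "two-way random, absolute agreement, single rater"),
            class = "icc_result")
}

#' The 18 parameter-by-genotype group comparisons
#'
#' Runs [compare_groups()] for each of the nine diffusion parameters against
#' both genotype questions (IDH: wild-type vs mutant over the whole cohort;
#' 1p/19q: non-codeleted vs codeleted within IDH-mutant subjects) and
#' adjusts the 18 raw p-values jointly by Benjamini-Hochberg. Both raw and
#' adjusted p-values are reported. Subjects with a missing value for a
#' parameter are dropped from that comparison only.
#'
#' @param cohort A `cohort_table` (see [build_cohort_table()]).
#' @return Tibble with one row per parameter x question.
#' @export
genotype_comparison_table <- function(cohort) {
  pars <- parameter_registry()
  rows <- list()
  for (question in c("IDH", "1p19q")) {
    for (p in pars) {
      gr <- question_groups(cohort, question, p)
      cmp <- compare_groups(gr$a, gr$b)
      lab <- if (question == "IDH") c("wild-type", "mutant")
             else c("non-codeleted", "codeleted")
      rows[[length(rows) + 1]] <- tibble::tibble(
        question = question, parameter = p, test = cmp$test,
        statistic = cmp$statistic, p_raw = cmp$p_value,
        cohens_d = cmp$cohens_d,
        group_a = lab[1], summary_a = cmp$summary_a, n_a = cmp$n_a,
        group_b = lab[2], summary_b = cmp$summary_b, n_b = cmp$n_b)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- adjust_bh(out$p_raw)
  out
}

# Split cohort values for one question; a = reference group (wild-type /
# non-codeleted), b = the other (mutant / codeleted).
question_groups <- function(cohort, question, parameter) {
  v <- cohort[[parameter]]
  if (question == "IDH") {
    a <- v[cohort$idh_status == "wild-type"]
    b <- v[cohort$idh_status == "mutant"]
  } else {
    a <- v[cohort$codeletion_status == "non-codeleted"]
    b <- v[cohort$codeletion_status == "codeleted"]
  }
  list(a = a[is.finite(a)], b = b[is.finite(b)])
}
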