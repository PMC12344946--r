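# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation paths.

# Truncated power series sum_k (-x)^k / Gamma(alpha k + 1) with an explicit
# numerical certificate: trustworthy iff the truncation tail and the
# cancellation round-off are both far below 1e-8.
ml_series_oracle <- function(x, alpha, nterms = 80L) {
  k <- 0:nterms
  terms <- (-1)^k * exp(k * log(x) - lgamma(alpha * k + 1))
  if (x == 0) terms <- c(1, rep(0, nterms))
  nxt <- exp((nterms + 1) * log(max(x, .Machine$double.xmin)) -
               lgamma(alpha * (nterms + 1) + 1))
  certified <- is.finite(nxt) && nxt < 1e-10 &&
    max(abs(terms)) * .Machine$double.eps * (nterms + 1) < 1e-9
  list(value = sum(terms), certified = certified)
}

# Complete-monotonicity spectral representation (log-substituted so the
# quadrature behaves for small alpha): independent of both package paths.
ml_spectral_oracle <- function(x, alpha) {
  if (x == 0) return(1)
  if (alpha == 1) return(exp(-x))
  f <- function(u) {
    r <- exp(u); t <- r^alpha
    v <- exp(-r * x^(1 / alpha)) * (1 / pi) * t * sin(alpha * pi) /
      (t^2 + 2 * t * cos(alpha * pi) + 1)
    v[!is.finite(v)] <- 0
    v
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
}

ml_oracle <- function(x, alpha) {
  s <- ml_series_oracle(x, alpha)
  if (s$certified) s$value else ml_spectral_oracle(x, alpha)
}

erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
# scaled complementary error function exp(z^2) erfc(z), stable for large z
erfcx <- function(z) {
  if (z < 25) return(exp(z^2) * erfc(z))
  # asymptotic expansion 1/(z sqrt(pi)) * sum (-1)^k (2k-1)!! / (2 z^2)^k
  k <- 0:8
  terms <- (-1)^k * cumprod(c(1, seq(1, 15, by = 2))) / (2 * z^2)^k
  sum(terms) / (z * sqrt(pi))
}

# Mean of a Rice(nu, sigma) variable via the scaled Bessel closed form.
rician_mean <- function(nu, sigma) {
  t <- nu^2 / (2 * sigma^2)
  # L_{1/2}(-t) = e^{-t/2}[(1+t) I0(t/2) + t I1(t/2)]; the e^{-t/2} cancels
  # against the rescaling of the exponentially scaled Bessel values.
  l_half <- (1 + t) * besselI(t / 2, 0, expon.scaled = TRUE) +
    t * besselI(t / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l_half
}

# Pairwise (Mann-Whitney) AUC, ties counted 1/2.
pairwise_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC curve traced over all thresholds.
trapezoid_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, -Inf)))
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o], 1); tpr <- c(0, tpr[o], 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive Youden search over every observed cut-point (inclusive rule,
# positive class on the "higher" side), ties toward the smaller threshold.
enumerate_youden <- function(values, is_pos) {
  thr <- sort(unique(values))
  best_j <- -Inf; best_t <- NA
  for (t in thr) {
    sens <- mean(values[is_pos] >= t)
    spec <- mean(values[!is_pos] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(threshold = best_t, j = best_j)
}

# Tiny fitted-cohort builder used by VOI/statistics/diagnostics tests: one
# constant-valued parameter map per subject.
constant_map <- function(value, dims = c(2, 2, 1)) {
  structure(list(model = "mono", parameter = "Mono_ADC",
                 values = array(value, dims), rss = array(0, dims),
                 valid = array(TRUE, dims)),
            class = "parameter_map")
}

# A cohort table straight from per-subject parameter values (no fitting).
values_cohort <- function(idh_values, q_values = NULL) {
  pars <- parameter_registry()
  n_w <- length(idh_values$wild); n_nc <- length(idh_values$noncodel)
  n_c <- length(idh_values$codel)
  tbl <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n_w + n_nc + n_c)),
    idh_status = rep(c("wild-type", "mutant", "mutant"), c(n_w, n_nc, n_c)),
    codeletion_status = rep(c("not-applicable", "non-codeleted", "codeleted"),
                            c(n_w, n_nc, n_c)))
  for (p in pars) {
    tbl[[p]] <- c(idh_values$wild, idh_values$noncodel, idh_values$codel)
  }
  class(tbl) <- c("cohort_table", class(tbl))
  tbl
}
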