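# Forward signal equations of the four diffusion models.
#
# All diffusivities (ADC, D, D*, DDC, Dm) are stored and reported in units of
# 1e-3 mm^2/s -- the scale on which clinical tables print them -- and are
# rescaled internally before forming b * D with b in s/mm^2.

DIFF_SCALE <- 1e-3

#' Mono-exponential model parameters
#' @param adc Apparent diffusion coefficient, 1e-3 mm^2/s, in (0, 4].
#' @return Object of class `mono_params`.
#' @export
mono_params <- function(adc) {
  check_scalar(adc, "adc", lower = 0, upper = 4, lower_open = TRUE)
  structure(list(adc = adc), class = c("mono_params", "dwi_params"))
}

#' IVIM (bi-exponential) model parameters
#' @param d Slow (tissue) diffusion coefficient, 1e-3 mm^2/s.
#' @param d_star Fast (pseudo-)diffusion coefficient, 1e-3 mm^2/s; must
#'   exceed `d`.
#' @param f Perfusion fraction in \[0, 1\].
#' @return Object of class `ivim_params`.
#' @export
ivim_params <- function(d, d_star, f) {
  check_scalar(d, "d", lower = 0, lower_open = TRUE)
  check_scalar(d_star, "d_star", lower = 0, lower_open = TRUE)
  check_scalar(f, "f", lower = 0, upper = 1)
  if (d >= d_star) stop("ivim_params: d must be smaller than d_star")
  structure(list(d = d, d_star = d_star, f = f),
            class = c("ivim_params", "dwi_params"))
}

#' Stretched-exponential model parameters
#' @param ddc Distributed diffusion coefficient, 1e-3 mm^2/s, > 0.
#' @param alpha Heterogeneity index in (0, 1].
#' @return Object of class `sem_params`.
#' @export
sem_params <- function(ddc, alpha) {
  check_scalar(ddc, "ddc", lower = 0, lower_open = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, lower_open = TRUE)
  structure(list(ddc = ddc, alpha = alpha),
            class = c("sem_params", "dwi_params"))
}

#' Continuous-time random walk model parameters
#' @param dm Anomalous diffusion coefficient, 1e-3 mm^2/s, > 0.
#' @param alpha Temporal diffusion heterogeneity index in (0, 1].
#' @param beta Spatial diffusion heterogeneity index in (0, 1]; values above
#'   1 (superdiffusion) are excluded by normalization.
#' @return Object of class `ctrw_params`.
#' @export
ctrw_params <- function(dm, alpha, beta) {
  check_scalar(dm, "dm", lower = 0, lower_open = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, lower_open = TRUE)
  check_scalar(beta, "beta", lower = 0, upper = 1, lower_open = TRUE)
  structure(list(dm = dm, alpha = alpha, beta = beta),
            class = c("ctrw_params", "dwi_params"))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE) {
  if (length(x) != 1 || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", name))
  }
  if (x < lower || (lower_open && x == lower) || x > upper) {
    stop(sprintf("%s = %g outside the admissible range", name, x))
  }
  invisible(TRUE)
}

check_b <- function(b) {
  b <- as.numeric(b)
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be finite and >= 0")
  b
}

#' Mono-exponential signal attenuation
#'
#' `S(b)/S(0) = exp(-b * ADC)`.
#'
#' @param b Numeric vector of b-values, s/mm^2.
#' @param params A [mono_params()] object.
#' @return Attenuation ratio in (0, 1], same length as `b`.
#' @export
mono_signal <- function(b, params) {
  stopifnot(inherits(params, "mono_params"))
  b <- check_b(b)
  exp(-b * params$adc * DIFF_SCALE)
}

#' IVIM signal attenuation
#'
#' `S(b)/S(0) = f * exp(-b * D*) + (1 - f) * exp(-b * D)`. With `f = 0` the
#' curve reduces to the mono-exponential model with ADC = D.
#'
#' @inheritParams mono_signal
#' @param params An [ivim_params()] object.
#' @return Attenuation ratio in (0, 1].
#' @export
ivim_signal <- function(b, params) {
  stopifnot(inherits(params, "ivim_params"))
  b <- check_b(b)
  params$f * exp(-b * params$d_star * DIFF_SCALE) +
    (1 - params$f) * exp(-b * params$d * DIFF_SCALE)
}

#' Stretched-exponential signal attenuation
#'
#' `S(b)/S(0) = exp(-(b * DDC)^alpha)`. With `alpha = 1` the curve reduces
#' to the mono-exponential model with ADC = DDC.
#'
#' @inheritParams mono_signal
#' @param params A [sem_params()] object.
#' @return Attenuation ratio in (0, 1].
#' @export
sem_signal <- function(b, params) {
  stopifnot(inherits(params, "sem_params"))
  b <- check_b(b)
  exp(-(b * params$ddc * DIFF_SCALE)^params$alpha)
}

#' CTRW signal attenuation
#'
#' `S(b)/S(0) = E_alpha(-(b * Dm)^beta)` where `E_alpha` is the one-parameter
#' Mittag-Leffler function (see [mittag_leffler_neg()]). With
#' `alpha = beta = 1` the curve reduces to the mono-exponential model with
#' ADC = Dm.
#'
#' @inheritParams mono_signal
#' @param params A [ctrw_params()] object.
#' @return Attenuation ratio in (0, 1].
#' @export
ctrw_signal <- function(b, params) {
  stopifnot(inherits(params, "ctrw_params"))
  b <- check_b(b)
  mittag_leffler_neg((b * params$dm * DIFF_SCALE)^params$beta, params$alpha)
}
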