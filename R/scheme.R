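# Acquisition scheme and per-voxel signal containers.

#' Diffusion-weighting scheme
#'
#' Defines the ordered b-values (s/mm^2) and the number of diffusion-encoding
#' directions of a multi-b-value DWI acquisition. The default scheme is the
#' 13-b-value, 30-direction spin-echo EPI protocol used throughout the
#' package: b = 0, 10, 20, 30, 50, 70, 100, 150, 200, 400, 800, 1500,
#' 2000 s/mm^2.
#'
#' @param b_values Numeric vector of b-values in s/mm^2. Must start at 0 and
#'   be strictly increasing.
#' @param n_directions Positive integer count of diffusion-encoding
#'   directions applied to every b > 0 shell.
#' @return An object of class `bvalue_scheme`.
#' @export
bvalue_scheme <- function(b_values = c(0, 10, 20, 30, 50, 70, 100, 150, 200,
                                       400, 800, 1500, 2000),
                          n_directions = 30L) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2 || anyNA(b_values)) {
    stop("b_values must be a numeric vector of length >= 2 without NA")
  }
  if (b_values[1] != 0) stop("the first b-value must be 0")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly increasing")
  n_directions <- as.integer(n_directions)
  if (is.na(n_directions) || n_directions < 1) {
    stop("n_directions must be a positive integer")
  }
  structure(list(b_values = b_values, n_directions = n_directions),
            class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("DWI b-value scheme:", length(x$b_values), "b-values,",
      x$n_directions, "directions\n")
  cat("  b =", paste(x$b_values, collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' Per-voxel (or per-VOI) diffusion signal curve
#'
#' Couples measured intensities to a [bvalue_scheme()]. Intensities are kept
#' in arbitrary units together with the b = 0 reference `s0`; model fitting
#' operates on the normalized ratio `signal / s0`.
#'
#' @param scheme A [bvalue_scheme()].
#' @param signal Numeric vector of intensities aligned to `scheme$b_values`.
#' @param s0 Signal at b = 0 (defaults to `signal[1]`). Must be positive.
#' @return An object of class `dwi_signal`.
#' @export
dwi_signal <- function(scheme, signal, s0 = signal[1]) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  signal <- as.numeric(signal)
  if (length(signal) != length(scheme$b_values)) {
    stop("signal length must match the number of b-values")
  }
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive and finite")
  structure(list(scheme = scheme, signal = signal, s0 = s0),
            class = "dwi_signal")
}

# Normalized attenuation curve of a dwi_signal.
normalized_signal <- function(sig) {
  stopifnot(inherits(sig, "dwi_signal"))
  sig$signal / sig$s0
}
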