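# Direction averaging and bounded voxelwise nonlinear fitting.
#
# All fits minimize the sum of squared residuals on the normalized signal
# S(b)/S(0), with S(0) fixed to the (direction-handled) b = 0 intensity.
# Optimization is deterministic box-constrained Levenberg-Marquardt; the only
# randomness in any replicate study lives in the noise generator.

#' Fitting configuration
#'
#' Parameter bounds, the IVIM segmentation split, and optimizer controls
#' shared by all four model fitters. Diffusivity bounds are on the
#' 1e-3 mm^2/s reporting scale.
#'
#' @param adc_bounds,ddc_bounds,dm_bounds Bounds for the mono/SEM/CTRW
#'   diffusivities (default (0, 4]).
#' @param d_bounds Bounds for the IVIM slow coefficient (default (0, 3]).
#' @param d_star_max Upper bound for the IVIM fast coefficient (default 500);
#'   its lower bound is the fitted `d` (enforced by parametrizing
#'   `d_star = d + delta`, `delta > 0`).
#' @param f_bounds Bounds for the perfusion fraction (default \[0, 0.5\]).
#' @param alpha_bounds,beta_bounds Bounds for the heterogeneity indices
#'   (default (0, 1]).
#' @param ivim_split_b Split b-value of the segmented IVIM fit, s/mm^2;
#'   b >= split is treated as perfusion-free (default 200, the largest
#'   perfusion-dominated boundary in the default scheme). Must be a member
#'   of the scheme being fitted.
#' @param max_iterations,reltol Optimizer controls.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(adc_bounds = c(1e-4, 4),
                       d_bounds = c(1e-4, 3),
                       d_star_max = 500,
                       f_bounds = c(0, 0.5),
                       ddc_bounds = c(1e-4, 4),
                       dm_bounds = c(1e-4, 4),
                       alpha_bounds = c(1e-3, 1),
                       beta_bounds = c(1e-3, 1),
                       ivim_split_b = 200,
                       max_iterations = 200L,
                       reltol = 1e-10) {
  for (bn in list(adc_bounds, d_bounds, f_bounds, ddc_bounds, dm_bounds,
                  alpha_bounds, beta_bounds)) {
    if (length(bn) != 2 || bn[1] >= bn[2]) stop("bounds must satisfy lower < upper")
  }
  structure(list(adc_bounds = adc_bounds, d_bounds = d_bounds,
                 d_star_max = d_star_max, f_bounds = f_bounds,
                 ddc_bounds = ddc_bounds, dm_bounds = dm_bounds,
                 alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                 ivim_split_b = ivim_split_b,
                 max_iterations = as.integer(max_iterations),
                 reltol = reltol),
            class = "fit_config")
}

# Bounded least squares (Levenberg-Marquardt with box constraints).
# `fn` returns the residual vector; `value` is its sum of squares.
bounded_fit <- function(par, fn, lower, upper, cfg) {
  res <- tryCatch(
    minpack.lm::nls.lm(par, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = cfg$max_iterations,
                         ftol = cfg$reltol, ptol = cfg$reltol)),
    error = function(e) NULL)
  if (is.null(res)) return(list(par = par, value = sum(fn(par)^2), ok = FALSE))
  list(par = res$par, value = res$deviance, ok = res$info %in% 1:4)
}

check_sig <- function(sig) {
  stopifnot(inherits(sig, "dwi_signal"))
  y <- normalized_signal(sig)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("fitting requires finite, positive signals")
  }
  if (length(unique(sig$scheme$b_values)) < 2) stop("need >= 2 distinct b-values")
  y
}

fit_result <- function(model, params, rss, flag = "ok") {
  structure(list(model = model, params = params, rss = rss, flag = flag),
            class = "gliodwi_fit")
}

#' Fit the mono-exponential model
#'
#' Nonlinear least squares of `exp(-b * ADC)` over all b-values, initialized
#' from the log-linear regression slope. A degenerate (flat) signal is
#' returned at the lower ADC bound with flag `"degenerate"`.
#'
#' @param sig A [dwi_signal()].
#' @param cfg A [fit_config()].
#' @return A `gliodwi_fit` with `params = c(adc = ...)`, the residual sum of
#'   squares `rss`, and a status `flag`.
#' @export
fit_mono <- function(sig, cfg = fit_config()) {
  y <- check_sig(sig)
  b <- sig$scheme$b_values
  lo <- cfg$adc_bounds[1]; hi <- cfg$adc_bounds[2]
  slope <- -stats::coef(stats::lm(log(y) ~ b))[["b"]] / DIFF_SCALE
  init <- min(max(slope, lo), hi)
  obj <- function(p) exp(-b * p[1] * DIFF_SCALE) - y
  ft <- bounded_fit(init, obj, lo, hi, cfg)
  flag <- if (!ft$ok) "no_convergence" else if (ft$par[1] <= lo * (1 + 1e-6)) "degenerate" else "ok"
  fit_result("mono", c(adc = unname(ft$par[1])), ft$value, flag)
}

#' Fit the IVIM model (segmented, then joint refinement)
#'
#' Stage 1 estimates the slow coefficient `D` by log-linear fit over
#' b >= `ivim_split_b` (where the perfusion compartment has decayed). Stage 2
#' fixes `D` and fits `(f, D*)` over all b-values. Stage 3 refines
#' `(D, D*, f)` jointly under bounds, with `D < D*` enforced by fitting
#' `delta = D* - D > 0`. If the refinement fails, the stage-1 `D` is returned
#' with `f = 0` and flag `"segmented_only"`.
#'
#' @inheritParams fit_mono
#' @return A `gliodwi_fit` with `params = c(d, d_star, f)`.
#' @export
fit_ivim_segmented <- function(sig, cfg = fit_config()) {
  y <- check_sig(sig)
  b <- sig$scheme$b_values
  if (!(cfg$ivim_split_b %in% b)) {
    stop("ivim_split_b must be a member of the b-value scheme")
  }
  hi_idx <- b >= cfg$ivim_split_b
  if (sum(hi_idx) < 2 || sum(!hi_idx) < 1) {
    stop("scheme must include b-values on both sides of ivim_split_b")
  }
  # stage 1: log-linear tissue fit on the high-b tail
  co <- stats::coef(stats::lm(log(y[hi_idx]) ~ b[hi_idx]))
  d1 <- min(max(-co[[2]] / DIFF_SCALE, cfg$d_bounds[1]), cfg$d_bounds[2])
  f1 <- min(max(1 - exp(co[[1]]), cfg$f_bounds[1]), cfg$f_bounds[2])

  curve <- function(d, dstar, f) {
    f * exp(-b * dstar * DIFF_SCALE) + (1 - f) * exp(-b * d * DIFF_SCALE)
  }
  # stage 2: fix d, fit (f, delta) with d_star = d + delta
  obj2 <- function(p) curve(d1, d1 + p[2], p[1]) - y
  st2 <- bounded_fit(c(f1, max(10, 5 * d1)), obj2,
                     lower = c(cfg$f_bounds[1], 1e-6),
                     upper = c(cfg$f_bounds[2], cfg$d_star_max), cfg)
  # stage 3: joint bounded refinement of (d, delta, f)
  obj3 <- function(p) curve(p[1], p[1] + p[2], p[3]) - y
  st3 <- bounded_fit(c(d1, st2$par[2], st2$par[1]), obj3,
                     lower = c(cfg$d_bounds[1], 1e-6, cfg$f_bounds[1]),
                     upper = c(cfg$d_bounds[2], cfg$d_star_max, cfg$f_bounds[2]),
                     cfg)
  if (!st2$ok && !st3$ok) {
    return(fit_result("ivim",
                      c(d = d1, d_star = d1 + max(10, 5 * d1), f = 0),
                      sum((curve(d1, d1 + 10, 0) - y)^2), "segmented_only"))
  }
  p <- st3$par
  fit_result("ivim",
             c(d = unname(p[1]), d_star = unname(p[1] + p[2]), f = unname(p[3])),
             st3$value, "ok")
}

#' Fit the stretched-exponential model
#'
#' Bounded least squares of `exp(-(b * DDC)^alpha)`, initialized from the
#' mono-exponential fit (`DDC <- ADC`, `alpha <- 0.9`).
#'
#' @inheritParams fit_mono
#' @return A `gliodwi_fit` with `params = c(ddc, alpha)`.
#' @export
fit_sem <- function(sig, cfg = fit_config()) {
  y <- check_sig(sig)
  b <- sig$scheme$b_values
  adc0 <- fit_mono(sig, cfg)$params[["adc"]]
  init <- c(min(max(adc0, cfg$ddc_bounds[1]), cfg$ddc_bounds[2]), 0.9)
  obj <- function(p) exp(-(b * p[1] * DIFF_SCALE)^p[2]) - y
  ft <- bounded_fit(init, obj,
                    lower = c(cfg$ddc_bounds[1], cfg$alpha_bounds[1]),
                    upper = c(cfg$ddc_bounds[2], cfg$alpha_bounds[2]), cfg)
  fit_result("sem", c(ddc = unname(ft$par[1]), alpha = unname(ft$par[2])),
             ft$value, if (ft$ok) "ok" else "no_convergence")
}

# Multi-start (alpha, beta) initializations for the CTRW fit; dm always
# starts from the mono ADC. Chosen to straddle the alpha/beta exchange
# degeneracy's basins.
CTRW_STARTS <- list(c(0.9, 0.95), c(0.7, 0.9), c(0.95, 0.8))

#' Fit the continuous-time random walk model
#'
#' Bounded least squares of `E_alpha(-(b * Dm)^beta)` over `(Dm, alpha,
#' beta)`, alpha and beta in (0, 1]. Three deterministic starts are used and
#' the smallest residual wins; residual ties are broken toward the larger
#' alpha. Flag is `"invalid"` if every start fails.
#'
#' @inheritParams fit_mono
#' @return A `gliodwi_fit` with `params = c(dm, alpha, beta)`.
#' @export
fit_ctrw <- function(sig, cfg = fit_config()) {
  y <- check_sig(sig)
  b <- sig$scheme$b_values
  adc0 <- fit_mono(sig, cfg)$params[["adc"]]
  dm0 <- min(max(adc0, cfg$dm_bounds[1]), cfg$dm_bounds[2])
  obj <- function(p) {
    mittag_leffler_neg((b * p[1] * DIFF_SCALE)^p[3], p[2]) - y
  }
  lower <- c(cfg$dm_bounds[1], cfg$alpha_bounds[1], cfg$beta_bounds[1])
  upper <- c(cfg$dm_bounds[2], cfg$alpha_bounds[2], cfg$beta_bounds[2])
  best <- NULL
  for (st in CTRW_STARTS) {
    ft <- bounded_fit(c(dm0, st[1], st[2]), obj, lower, upper, cfg)
    if (!ft$ok) next
    if (is.null(best) ||
        ft$value < best$value - 1e-14 ||
        (abs(ft$value - best$value) <= 1e-14 && ft$par[2] > best$par[2])) {
      best <- ft
    }
  }
  if (is.null(best)) {
    return(fit_result("ctrw", c(dm = NA_real_, alpha = NA_real_, beta = NA_real_),
                      NA_real_, "invalid"))
  }
  fit_result("ctrw",
             c(dm = unname(best$par[1]), alpha = unname(best$par[2]),
               beta = unname(best$par[3])),
             best$value, "ok")
}

#' Geometric direction averaging
#'
#' Collapses the diffusion-direction axis of a multi-direction acquisition by
#' the per-b geometric mean (arithmetic mean of log-signals), the
#' orientation-averaging step applied before voxelwise fitting. The b = 0
#' entry is passed through unchanged (stored in direction 1; replicated
#' copies, if present, average to the same value). Non-positive intensities
#' are excluded from the log-mean and counted; `NA` entries are treated as
#' absent measurements.
#'
#' @param x Either a matrix `[n_b x n_directions]` for one voxel, or a 5-D
#'   array `[x, y, z, n_b, n_directions]`.
#' @param scheme The [bvalue_scheme()]; the direction axis must have length
#'   `scheme$n_directions`.
#' @return For matrix input, a list with `signal` (length `n_b`), `valid`
#'   (logical), and `n_excluded`. For 5-D input, a list with `data` (4-D
#'   array), `valid` (3-D logical: every b-shell had at least one usable
#'   direction), and `n_excluded` (total non-positive intensities dropped).
#' @export
average_directions <- function(x, scheme) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  if (is.matrix(x)) {
    return(avg_dir_matrix(x, scheme))
  }
  if (!(is.array(x) && length(dim(x)) == 5)) {
    stop("x must be a [n_b x n_dir] matrix or a 5-D array")
  }
  dm <- dim(x)
  if (dm[4] != length(scheme$b_values) || dm[5] != scheme$n_directions) {
    stop("array b/direction axes do not match the scheme")
  }
  out <- array(NA_real_, dm[1:4])
  valid <- array(TRUE, dm[1:3])
  nexcl <- 0L
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    r <- avg_dir_matrix(matrix(x[i, j, k, , ], nrow = dm[4]), scheme)
    out[i, j, k, ] <- r$signal
    valid[i, j, k] <- all(r$valid)
    nexcl <- nexcl + r$n_excluded
  }
  list(data = out, valid = valid, n_excluded = nexcl)
}

avg_dir_matrix <- function(m, scheme) {
  nb <- length(scheme$b_values)
  if (nrow(m) != nb) stop("matrix rows must match the number of b-values")
  b0 <- scheme$b_values == 0
  sig <- rep(NA_real_, nb)
  valid <- rep(FALSE, nb)
  nexcl <- 0L
  for (i in seq_len(nb)) {
    v <- m[i, ]
    if (b0[i]) {
      sig[i] <- v[1]
      valid[i] <- is.finite(v[1]) && v[1] > 0
      next
    }
    v <- v[!is.na(v)]
    bad <- !is.finite(v) | v <= 0
    nexcl <- nexcl + sum(bad)
    v <- v[!bad]
    if (length(v) > 0) {
      sig[i] <- exp(mean(log(v)))
      valid[i] <- TRUE
    }
  }
  list(signal = sig, valid = valid, n_excluded = nexcl)
}

# Canonical parameter registry: the 9 reported map names, in table order.
#' Names of the nine reported diffusion parameters
#' @return Character vector in standard table order.
#' @export
parameter_registry <- function() {
  c("Mono_ADC", "IVIM_D", "IVIM_Dstar", "IVIM_f",
    "SEM_alpha", "SEM_DDC", "CTRW_alpha", "CTRW_beta", "CTRW_Dm")
}

model_of_parameter <- function(p) {
  c(Mono_ADC = "mono", IVIM_D = "ivim", IVIM_Dstar = "ivim", IVIM_f = "ivim",
    SEM_alpha = "sem", SEM_DDC = "sem",
    CTRW_alpha = "ctrw", CTRW_beta = "ctrw", CTRW_Dm = "ctrw")[p]
}

#' Voxelwise parametric map fitting
#'
#' Fits the requested models to every voxel inside `mask` of a
#' direction-averaged 4-D volume and assembles one parametric map per model
#' parameter (nine in total across the four models), each with a residual
#' sum-of-squares volume and a validity mask. Voxel-level failures are
#' recorded in the validity mask and never abort the volume.
#'
#' @param volume_4d Numeric 4-D array `[x, y, z, n_b]` of direction-averaged
#'   intensities.
#' @param scheme The [bvalue_scheme()].
#' @param mask Logical (or 0/1) 3-D array aligned to the volume grid.
#' @param models Character subset of `c("mono", "ivim", "sem", "ctrw")`.
#' @param cfg A [fit_config()].
#' @return A named list of `parameter_map` objects (one per parameter), each
#'   holding `model`, `parameter`, `values`, `rss` and `valid` arrays.
#' @export
fit_parameter_maps <- function(volume_4d, scheme, mask,
                               models = c("mono", "ivim", "sem", "ctrw"),
                               cfg = fit_config()) {
  stopifnot(length(dim(volume_4d)) == 4)
  models <- match.arg(models, several.ok = TRUE)
  dm <- dim(volume_4d)
  if (dm[4] != length(scheme$b_values)) stop("4th axis must match b-values")
  mask <- array(as.logical(mask), dm[1:3])
  if (!any(mask)) {
    warning("empty mask: returning empty maps")
  }
  fitters <- list(mono = fit_mono, ivim = fit_ivim_segmented,
                  sem = fit_sem, ctrw = fit_ctrw)
  pars <- parameter_registry()
  pars <- pars[model_of_parameter(pars) %in% models]
  maps <- lapply(pars, function(p) {
    structure(list(model = unname(model_of_parameter(p)), parameter = p,
                   values = array(NA_real_, dm[1:3]),
                   rss = array(NA_real_, dm[1:3]),
                   valid = array(FALSE, dm[1:3])),
              class = "parameter_map")
  })
  names(maps) <- pars
  par_key <- list(Mono_ADC = c("mono", "adc"), IVIM_D = c("ivim", "d"),
                  IVIM_Dstar = c("ivim", "d_star"), IVIM_f = c("ivim", "f"),
                  SEM_alpha = c("sem", "alpha"), SEM_DDC = c("sem", "ddc"),
                  CTRW_alpha = c("ctrw", "alpha"), CTRW_beta = c("ctrw", "beta"),
                  CTRW_Dm = c("ctrw", "dm"))
  idx <- which(mask, arr.ind = TRUE)
  n_failed <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    yv <- volume_4d[i, j, k, ]
    fits <- list()
    if (all(is.finite(yv)) && all(yv > 0)) {
      sig <- dwi_signal(scheme, yv)
      for (mset in models) {
        fits[[mset]] <- tryCatch(fitters[[mset]](sig, cfg), error = function(e) NULL)
      }
    }
    voxel_ok <- length(fits) > 0
    for (p in pars) {
      key <- par_key[[p]]
      ft <- fits[[key[1]]]
      if (is.null(ft) || ft$flag == "invalid" || !is.finite(ft$params[[key[2]]])) next
      maps[[p]]$values[i, j, k] <- ft$params[[key[2]]]
      maps[[p]]$rss[i, j, k] <- ft$rss
      maps[[p]]$valid[i, j, k] <- TRUE
    }
    if (!voxel_ok) n_failed <- n_failed + 1L
  }
  attr(maps, "n_voxels") <- nrow(idx)
  attr(maps, "n_failed") <- n_failed
  maps
}
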