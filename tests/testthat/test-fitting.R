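# Direction averaging and bounded voxelwise fitting.

scheme13 <- bvalue_scheme()
b13 <- scheme13$b_values

test_that("direction averaging is the per-b geometric mean", {
  sc <- bvalue_scheme(c(0, 500, 1000), n_directions = 2L)
  m <- rbind(c(100, NA), c(exp(1), exp(3)), c(5, 5))
  r <- average_directions(m, sc)
  expect_equal(r$signal, c(100, exp(2), 5))
  expect_identical(r$n_excluded, 0L)
  # randomized 30-direction shell vs independent log-domain average
  sc30 <- bvalue_scheme(c(0, 1000), n_directions = 30L)
  set.seed(11)
  v <- exp(rnorm(30, -1, 0.3))
  m <- rbind(c(200, rep(NA, 29)), v)
  r <- average_directions(m, sc30)
  expect_equal(r$signal[2], exp(mean(log(v))), tolerance = 1e-12)
})

test_that("non-positive intensities are excluded with a count", {
  sc <- bvalue_scheme(c(0, 1000), n_directions = 3L)
  m <- rbind(c(10, NA, NA), c(2, -1, 8))
  r <- average_directions(m, sc)
  expect_identical(r$n_excluded, 1L)
  expect_equal(r$signal[2], exp(mean(log(c(2, 8)))))
  # all-invalid shell is flagged
  m2 <- rbind(c(10, NA, NA), c(-1, 0, -3))
  r2 <- average_directions(m2, sc)
  expect_false(r2$valid[2])
  expect_identical(r2$n_excluded, 3L)
})

test_that("noiseless curves on the 13-b scheme are recovered exactly", {
  # mono
  f <- fit_mono(dwi_signal(scheme13, mono_signal(b13, mono_params(1.2))))
  expect_equal(f$params[["adc"]], 1.2, tolerance = 1e-4)
  expect_identical(f$flag, "ok")
  # SEM (table-scale values)
  f <- fit_sem(dwi_signal(scheme13, sem_signal(b13, sem_params(1.117, 0.867))))
  expect_equal(f$params[["ddc"]], 1.117, tolerance = 1e-3)
  expect_equal(f$params[["alpha"]], 0.867, tolerance = 1e-3)
  # IVIM, generic and table-scale
  f <- fit_ivim_segmented(
    dwi_signal(scheme13, ivim_signal(b13, ivim_params(1.0, 10, 0.1))))
  expect_equal(unname(f$params[c("d", "d_star", "f")]), c(1.0, 10, 0.1),
               tolerance = 1e-3)
  f <- fit_ivim_segmented(
    dwi_signal(scheme13, ivim_signal(b13, ivim_params(0.983, 7.298, 0.089))))
  expect_equal(f$params[["d"]], 0.983, tolerance = 1e-2)
  expect_equal(f$params[["d_star"]], 7.298, tolerance = 7.298 * 1e-2)
  expect_equal(f$params[["f"]], 0.089, tolerance = 1e-2)
  # CTRW (table-scale)
  f <- fit_ctrw(
    dwi_signal(scheme13, ctrw_signal(b13, ctrw_params(1.218, 0.825, 0.938))))
  expect_equal(f$params[["dm"]], 1.218, tolerance = 1.218 * 1e-2)
  expect_equal(f$params[["alpha"]], 0.825, tolerance = 0.825 * 1e-2)
  expect_equal(f$params[["beta"]], 0.938, tolerance = 0.938 * 1e-2)
})

test_that("boundary reductions are recovered at the boundary", {
  y <- mono_signal(b13, mono_params(1.1))
  f <- fit_sem(dwi_signal(scheme13, y))
  expect_gte(f$params[["alpha"]], 0.999)
  f <- fit_ctrw(dwi_signal(scheme13, y))
  expect_gte(f$params[["alpha"]], 0.99)
  expect_gte(f$params[["beta"]], 0.99)
  f <- fit_ivim_segmented(dwi_signal(scheme13, y))
  expect_lt(f$params[["f"]], 1e-3)
  expect_equal(f$params[["d"]], 1.1, tolerance = 1e-3)
})

test_that("degenerate and invalid inputs are flagged, not fatal", {
  f <- fit_mono(dwi_signal(scheme13, rep(1, 13)))
  expect_identical(f$flag, "degenerate")
  expect_equal(f$params[["adc"]], fit_config()$adc_bounds[1])
  expect_error(fit_mono(dwi_signal(scheme13, c(rep(1, 12), -1))), "positive")
  bad_cfg <- fit_config(ivim_split_b = 333)
  expect_error(fit_ivim_segmented(
    dwi_signal(scheme13, mono_signal(b13, mono_params(1))), bad_cfg),
    "member")
})

test_that("fit residual is optimal at least to the generating parameters", {
  set.seed(5)
  for (i in 1:5) {
    tr <- c(dm = runif(1, 0.8, 1.6), alpha = runif(1, 0.7, 0.95),
            beta = runif(1, 0.85, 1))
    y <- ctrw_signal(b13, ctrw_params(tr[1], tr[2], tr[3])) *
      exp(rnorm(13, 0, 0.01))
    f <- fit_ctrw(dwi_signal(scheme13, y))
    yn <- y / y[1]
    rss_truth <- sum((ctrw_signal(b13, ctrw_params(tr[1], tr[2], tr[3])) - yn)^2)
    expect_lte(f$rss, rss_truth + 1e-10)
  }
})

test_that("fitted values respect the configured bounds under heavy noise", {
  set.seed(9)
  cfg <- fit_config()
  for (i in 1:10) {
    y <- ctrw_signal(b13, ctrw_params(1.2, 0.85, 0.94)) * exp(rnorm(13, 0, 0.2))
    s <- dwi_signal(scheme13, y)
    fm <- fit_mono(s); fs <- fit_sem(s); fi <- fit_ivim_segmented(s)
    fc <- fit_ctrw(s)
    expect_true(fm$params[["adc"]] >= cfg$adc_bounds[1] &&
                  fm$params[["adc"]] <= cfg$adc_bounds[2])
    expect_true(fs$params[["alpha"]] <= 1 && fs$params[["alpha"]] > 0)
    expect_true(fc$params[["alpha"]] <= 1 && fc$params[["beta"]] <= 1)
    expect_true(fi$params[["f"]] >= 0 && fi$params[["f"]] <= 0.5)
    expect_true(fi$params[["d_star"]] > fi$params[["d"]])
  }
})

test_that("recovery error grows monotonically as SNR falls", {
  set.seed(21)
  snrs <- c(200, 100, 50, 25)
  rmse <- vapply(snrs, function(snr) {
    errs <- replicate(40, {
      clean <- mono_signal(b13, mono_params(1.088))
      noisy <- sqrt((clean + rnorm(13, 0, 1 / snr))^2 + rnorm(13, 0, 1 / snr)^2)
      fit_mono(dwi_signal(scheme13, noisy, s0 = 1))$params[["adc"]] - 1.088
    })
    sqrt(mean(errs^2))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})

test_that("parametric maps reproduce a two-region phantom and isolate faults", {
  sc <- scheme13
  dims <- c(5, 5, 1)
  vol <- array(NA_real_, c(dims, 13))
  truth <- array(NA_real_, dims)
  for (i in 1:5) for (j in 1:5) {
    adc <- if (i <= 2) 0.9 else 1.4
    truth[i, j, 1] <- adc
    vol[i, j, 1, ] <- 1000 * mono_signal(b13, mono_params(adc))
  }
  vol[3, 3, 1, ] <- 0  # corrupted voxel
  mask <- array(TRUE, dims)
  maps <- fit_parameter_maps(vol, sc, mask, models = "mono")
  adc_map <- maps$Mono_ADC
  expect_false(adc_map$valid[3, 3, 1])
  ok <- adc_map$valid
  expect_equal(adc_map$values[ok], truth[ok], tolerance = 1e-6)
  expect_identical(sum(ok), 24L)
  # empty mask warns and fits nothing
  expect_warning(m0 <- fit_parameter_maps(vol, sc, array(FALSE, dims),
                                          models = "mono"), "empty mask")
  expect_false(any(m0$Mono_ADC$valid))
})
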