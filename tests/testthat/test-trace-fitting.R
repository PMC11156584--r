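test_that("baseline correction is distortion-free on a constant baseline", {
  tt <- seq(0, 7200)
  tr <- tibble::tibble(time_s = tt, intensity_au = rep(5, length(tt)))
  out <- baseline_correct(tr)
  expect_equal(out$intensity_au, rep(1, length(tt)), tolerance = 1e-9)
  out_sub <- baseline_correct(tr, mode = "subtract")
  expect_equal(out_sub$intensity_au, rep(0, length(tt)), tolerance = 1e-9)
  # a transient on a constant baseline is preserved up to the scale factor
  tr2 <- tr
  bump <- 3600:4500
  tr2$intensity_au[bump] <- tr2$intensity_au[bump] - 2
  out2 <- baseline_correct(tr2, exclude = list(c(3598, 4501)))
  expect_equal(out2$intensity_au * 5, tr2$intensity_au, tolerance = 1e-9)
})

test_that("a planted recovery survives 6%-per-hour drift correction", {
  tr <- sim_frap_trace(d = 136, sigma = 150, bleach_times = 7200,
                       duration = 14400, drift_rate = 0.06, noise_cv = 0)
  out <- baseline_correct(tr, exclude = list(c(7200, 7230 + 3600)))
  # recovered relative transient amplitude vs planted (i_inf - i0)/i_inf
  i0_hat <- out$intensity_au[out$time_s == 7230]
  late <- out$intensity_au[out$time_s > 13000]
  amp_hat <- mean(late) - i0_hat
  expect_equal(amp_hat, 0.8, tolerance = 0.02)
})

test_that("excluded samples cannot influence the fitted baseline", {
  tr <- sim_frap_trace(bleach_times = 3600, duration = 10800, seed = 4)
  excl <- list(c(3600, 3630 + 3600))
  out1 <- baseline_correct(tr, exclude = excl)
  tr2 <- tr
  inside <- tr2$time_s >= 3700 & tr2$time_s <= 6000
  tr2$intensity_au[inside] <- tr2$intensity_au[inside] * 50 + 7
  out2 <- baseline_correct(tr2, exclude = excl)
  expect_identical(out1$baseline_au, out2$baseline_au)
})

test_that("baseline correction refuses insufficient coverage", {
  tr <- sim_frap_trace(bleach_times = 600, duration = 4000, seed = 1)
  expect_error(baseline_correct(tr, exclude = list(c(0, 4000))),
               "insufficient baseline coverage")
})

test_that("FRAP fitting recovers the generating coefficient without noise", {
  tr <- sim_frap_trace(d = 136, sigma = 150, bleach_times = 600,
                       duration = 4230, noise_cv = 0, drift_rate = 0)
  fit <- fit_frap(tr, sigma = 150, bleach_event = c(600, 30))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["d_um2_s"]], 136, tolerance = 0.005)
  # free-intensity variant agrees on clean data
  fit2 <- fit_frap(tr, sigma = 150, bleach_event = c(600, 30),
                   free_intensities = TRUE)
  expect_equal(fit2$estimates[["d_um2_s"]], 136, tolerance = 0.005)
})

test_that("FRAP fitting is unbiased at 1% multiplicative noise", {
  errs <- conv <- numeric(20)
  for (s in 1:20) {
    tr <- sim_frap_trace(d = 136, sigma = 150, bleach_times = 600,
                         duration = 4230, noise_cv = 0.01, drift_rate = 0,
                         seed = 100 + s)
    fit <- fit_frap(tr, sigma = 150, bleach_event = c(600, 30))
    errs[s] <- abs(fit$estimates[["d_um2_s"]] / 136 - 1)
    conv[s] <- fit$converged
  }
  expect_lt(median(errs), 0.03)
  expect_true(all(conv == 1))
})

test_that("FRAP estimate is invariant to affine intensity transforms", {
  tr <- sim_frap_trace(d = 136, sigma = 150, bleach_times = 600,
                       duration = 4230, noise_cv = 0.01, drift_rate = 0,
                       seed = 7)
  fit <- fit_frap(tr, sigma = 150, bleach_event = c(600, 30))
  tr_aff <- dplyr::mutate(tr, intensity_au = 3.7 * intensity_au - 11)
  fit_aff <- fit_frap(tr_aff, sigma = 150, bleach_event = c(600, 30))
  expect_equal(fit_aff$estimates[["d_um2_s"]], fit$estimates[["d_um2_s"]],
               tolerance = 1e-6)
})

test_that("rescaling time rescales the fitted coefficient inversely", {
  tr <- sim_frap_trace(d = 136, sigma = 150, bleach_times = 0,
                       duration = 3630, noise_cv = 0, drift_rate = 0)
  rec <- dplyr::filter(tr, time_s >= 30)
  rec$time_s <- rec$time_s - 30
  fit1 <- fit_frap(rec, sigma = 150, i_inf = 1)
  k <- 4
  rec2 <- dplyr::mutate(rec, time_s = time_s * k)
  fit2 <- fit_frap(rec2, sigma = 150, i_inf = 1)
  expect_equal(fit2$estimates[["d_um2_s"]],
               fit1$estimates[["d_um2_s"]] / k, tolerance = 1e-6)
})

test_that("clearance-free fitting recovers the gel coefficient with ~0% clearance", {
  tr <- sim_clearance_trace(d = 295, tau = Inf, sigma = 250,
                            distance = 3335, duration = 6 * 3600,
                            noise_cv = 0)
  fit <- fit_clearance(tr, tau = Inf)
  expect_equal(fit$estimates[["d_um2_s"]], 295, tolerance = 0.005)
  expect_lt(fit$clearance_at_peak_pct, 1e-6)
})

test_that("joint (D, tau) recovery stays within 10% at 2% noise", {
  d_true <- 230.7; tau_true <- 2600
  err_d <- err_tau <- numeric(20)
  for (s in 1:20) {
    tr <- sim_clearance_trace(d = d_true, tau = tau_true, noise_cv = 0.02,
                              seed = 200 + s)
    fit <- fit_clearance(tr)
    err_d[s] <- abs(fit$estimates[["d_um2_s"]] / d_true - 1)
    err_tau[s] <- abs(fit$estimates[["tau_s"]] / tau_true - 1)
  }
  expect_lt(median(err_d), 0.10)
  expect_lt(median(err_tau), 0.10)
})

test_that("clearance-at-peak is evaluated at the fitted curve's maximum", {
  tr <- sim_clearance_trace(noise_cv = 0.02, seed = 31)
  fit <- fit_clearance(tr)
  tt <- seq(1, 2 * max(tr$time_s), length.out = 2e5)
  t_grid <- tt[which.max(fit$fitted_fn(tt))]
  expect_equal(fit$peak_time_s, t_grid, tolerance = 1e-3)
  expect_equal(fit$clearance_at_peak_pct,
               clearance_percent(fit$peak_time_s, fit$estimates[["tau_s"]]),
               tolerance = 1e-6)
})

test_that("Gaussian profile fitting recovers exact and planted parameters", {
  x <- seq(-4000, 4000, by = 250)
  pars <- c(a = 2.5, x0 = 300, w = 900, b = 0.2)
  y <- pars["b"] + pars["a"] * exp(-(x - pars["x0"])^2 / (2 * pars["w"]^2))
  fit <- fit_gaussian_profile(
    tibble::tibble(ap_distance_um = x, mean_intensity_au = y))
  expect_equal(unname(fit$estimates),
               unname(pars[c("a", "x0", "w", "b")]), tolerance = 1e-6,
               ignore_attr = TRUE)
  # symmetric profile centres at the symmetry point
  ysym <- 1 + exp(-x^2 / (2 * 700^2))
  fsym <- fit_gaussian_profile(
    tibble::tibble(ap_distance_um = x, mean_intensity_au = ysym))
  expect_equal(fit_gaussian_profile(
    tibble::tibble(ap_distance_um = x, mean_intensity_au = ysym)
  )$estimates[["center_um"]], 0, tolerance = 1e-6)
  expect_error(fit_gaussian_profile(
    tibble::tibble(ap_distance_um = x[1:5], mean_intensity_au = y[1:5])),
    "at least 8")
})

test_that("histology width reflects the clearance-model spread at 3 h", {
  d <- 230.7; t_kill <- 3 * 3600; sigma <- 250
  w_true <- sqrt(sigma^2 + 2 * d * t_kill)
  errs <- vapply(1:5, function(s) {
    pr <- sim_histology_profile(d = d, t_kill = t_kill, sigma = sigma,
                                noise_cv = 0.05, seed = 300 + s)
    fit <- fit_gaussian_profile(pr)
    abs(fit$estimates[["width_um"]] / w_true - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("intensity calibration is exact on a line and inverts cleanly", {
  cal <- calibrate_intensity(
    data.frame(concentration = c(0, 1, 2), intensity_au = c(0, 2, 4)))
  expect_equal(cal$estimates[["slope"]], 2)
  expect_equal(cal$estimates[["intercept_au"]], 0)
  expect_equal(cal$r_squared, 1)
  tr <- tibble::tibble(time_s = 1:5, intensity_au = c(1, 3, 5, 2, 8))
  out <- apply_calibration(tr, cal)
  expect_equal(out$concentration * cal$estimates[["slope"]] +
                 cal$estimates[["intercept_au"]],
               tr$intensity_au, tolerance = 1e-12)
  expect_error(calibrate_intensity(
    data.frame(concentration = 0:4, intensity_au = c(5, 4, 3, 2, 1))),
    "slope")
})

test_that("calibration OLS matches the closed-form estimator", {
  set.seed(21)
  conc <- 0:5
  y <- 1.5 + 3.2 * conc + rnorm(6, sd = 0.3)
  cal <- calibrate_intensity(
    data.frame(concentration = conc, intensity_au = y))
  o <- oracle_ols(conc, y)
  expect_equal(cal$estimates[["slope"]], o$slope, tolerance = 1e-12)
  expect_equal(cal$estimates[["intercept_au"]], o$intercept,
               tolerance = 1e-12)
  expect_equal(cal$std_error[["slope"]], o$se_slope, tolerance = 1e-12)
})

test_that("fit objects expose tidy, glance and autoplot views", {
  tr <- sim_clearance_trace(noise_cv = 0.02, seed = 5)
  fit <- fit_clearance(tr)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low",
                     "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_true(gl$rss >= 0 && gl$n == fit$n)
  expect_s3_class(autoplot(fit), "ggplot")
})
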