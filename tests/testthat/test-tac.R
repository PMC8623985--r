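lam_phys <- lu177_decay_data()$lambda_phys_per_h

test_that("noiseless mono-exponential parameters are recovered exactly", {
  fit <- fit_monoexponential(expo_points(10, 0.01))
  expect_equal(fit$A0_pct_ia, 10, tolerance = 1e-9)
  expect_equal(fit$lambda_bio_per_h, 0.01, tolerance = 1e-7)
  expect_equal(fit$lambda_eff_per_h, 0.01 + lam_phys, tolerance = 1e-7)
  expect_equal(fit$rms_log_residual, 0, tolerance = 1e-12)

  # without decay correction the fitted slope is the effective constant
  fit2 <- fit_monoexponential(expo_points(10, 0.01), decay_corrected = FALSE)
  expect_equal(fit2$lambda_bio_per_h, 0.01 - lam_phys, tolerance = 1e-7)
  expect_equal(fit2$lambda_eff_per_h, 0.01, tolerance = 1e-7)
})

test_that("rising uptake clamps biological clearance at zero", {
  # bone-like accretion pattern
  pts <- data.frame(time_h = c(4, 24, 48, 72),
                    pct_ia = c(0.65, 0.88, 1.74, 2.20))
  fit <- fit_monoexponential(pts, organ = "bone")
  expect_equal(fit$lambda_bio_per_h, 0)
  expect_equal(fit$lambda_eff_per_h, lam_phys)
  expect_equal(fit$lambda_eff_per_h, 4.3430e-3, tolerance = 1e-4)
  # constrained zero-slope fit level: geometric mean of the window
  expect_equal(fit$A0_pct_ia, exp(mean(log(pts$pct_ia))))
  expect_true(fit$lambda_eff_per_h >= lam_phys)
})

test_that("fit window starts at the observed peak", {
  # liver-like pattern peaking at the second timepoint
  pts <- data.frame(time_h = c(4, 24, 48, 72),
                    pct_ia = c(5.83, 11.56, 6.82, 5.13))
  fit <- fit_monoexponential(pts)
  expect_equal(min(fit$fit_window), 24)
  expect_false(4 %in% fit$fit_window)

  # terminal zero drops out of the log-space window
  pts2 <- data.frame(time_h = c(4, 24, 48, 72),
                     pct_ia = c(2.12, 0.55, 2.15, 0))
  fit2 <- fit_monoexponential(pts2)
  expect_false(72 %in% fit2$fit_window)
  expect_true(fit2$lambda_eff_per_h >= lam_phys)
})

test_that("degenerate series: all-zero integrates to zero, too-sparse errors", {
  z <- fit_monoexponential(data.frame(time_h = c(4, 24), pct_ia = c(0, 0)))
  expect_true(z$zero_activity)
  expect_equal(integrate_tac(z)$a_tilde_mbq_s_per_mbq, 0)

  expect_error(
    fit_monoexponential(data.frame(time_h = c(4, 24, 48), pct_ia = c(0, 5, 0))),
    "2 positive points")
  expect_error(
    fit_monoexponential(data.frame(time_h = 4, pct_ia = 7)),
    "2 distinct timepoints")
})

test_that("closed-form integral matches its definition and the decay bound", {
  # lambda_eff = 0.01 overall: choose lambda_bio to complement physical decay
  fit <- fit_monoexponential(expo_points(10, 0.01 - lam_phys))
  tia <- integrate_tac(fit)
  expect_equal(tia$a_tilde_mbq_s_per_mbq, 3600 * (10 / 100) / 0.01,
               tolerance = 1e-6)
  expect_equal(tia$a_tilde_mbq_s_per_mbq, 36000, tolerance = 1e-4)
})

test_that("integration matches numerical quadrature within 0.1% on random fits", {
  set.seed(42)
  for (i in 1:200) {
    A0 <- runif(1, 0.1, 80)
    lam <- runif(1, 0, 0.05)
    times <- sort(sample(c(2, 4, 8, 24, 48, 72, 96), 4))
    pts <- data.frame(time_h = times, pct_ia = A0 * exp(-lam * times))
    fit <- fit_monoexponential(pts)
    for (ph in c("ignore_pre_peak", "trapezoid_pre_peak")) {
      got <- integrate_tac(fit, peak_handling = ph)$a_tilde_mbq_s_per_mbq
      want <- tia_quadrature(fit, peak_handling = ph)
      expect_equal(got, want, tolerance = 1e-3)
    }
  }
})

test_that("pre-peak trapezoid never exceeds the back-extrapolated integral", {
  # peaked series: the fitted exponential back-extrapolated to t = 0 bounds
  # the linear ramp from zero
  pts <- data.frame(time_h = c(4, 24, 48, 72),
                    pct_ia = c(5.8, 11.6, 6.8, 5.1))
  fit <- fit_monoexponential(pts)
  a_ig <- integrate_tac(fit, peak_handling = "ignore_pre_peak")$a_tilde_mbq_s_per_mbq
  a_tr <- integrate_tac(fit, peak_handling = "trapezoid_pre_peak")$a_tilde_mbq_s_per_mbq
  expect_gt(a_ig, a_tr)
  # same exponential tail: the difference is only the pre-peak segment
  lam <- fit$lambda_eff_per_h
  pre_analytic <- (fit$A0_pct_ia / 100) * (1 - exp(-lam * 24)) / lam
  expect_lt(a_ig - a_tr, 3600 * pre_analytic)
})

test_that("whole-table fitting is linear and records per-organ provenance", {
  up <- rbind(
    data.frame(organ = "liver", time_h = c(4, 24, 48, 72),
               pct_ia = 10 * exp(-0.01 * c(4, 24, 48, 72))),
    data.frame(organ = "bone", time_h = c(4, 24, 48, 72),
               pct_ia = c(0.65, 0.88, 1.74, 2.20)))
  attr(up, "decay_corrected") <- TRUE
  tia <- build_all_tia(up)
  expect_equal(nrow(tia), 2)
  expect_true(all(tia$method == "monoexp_from_peak"))

  up2 <- up; up2$pct_ia <- 2 * up2$pct_ia
  attr(up2, "decay_corrected") <- TRUE
  tia2 <- build_all_tia(up2)
  expect_equal(tia2$a_tilde_mbq_s_per_mbq, 2 * tia$a_tilde_mbq_s_per_mbq)

  empty <- up[0, ]; attr(empty, "decay_corrected") <- TRUE
  expect_equal(nrow(build_all_tia(empty)), 0)

  # single-positive-point organ: error by default, physical-decay fallback on request
  bad <- data.frame(organ = "bone marrow", time_h = c(4, 24),
                    pct_ia = c(0, 3))
  attr(bad, "decay_corrected") <- TRUE
  expect_error(build_all_tia(bad), "positive points")
  fb <- build_all_tia(bad, on_insufficient = "fallback_physical")
  expect_equal(fb$method, "single_point_physical_fallback")
  expect_equal(fb$lambda_eff_per_h, lam_phys)
  expect_equal(fb$a_tilde_mbq_s_per_mbq, 3600 * (3 / 100) / lam_phys)
})

test_that("time-integrated activity never exceeds the physical-decay bound", {
  set.seed(7)
  bound <- 3600 / lam_phys  # 100 %IA decaying with no biological clearance
  for (i in 1:100) {
    A0 <- runif(1, 0, 100)
    lam <- runif(1, 0, 0.1)
    noise <- exp(rnorm(4, 0, 0.1))
    pts <- data.frame(time_h = c(4, 24, 48, 72),
                      pct_ia = pmin(A0 * exp(-lam * c(4, 24, 48, 72)) * noise,
                                    100))
    fit <- fit_monoexponential(pts)
    a <- integrate_tac(fit)$a_tilde_mbq_s_per_mbq
    if (fit$A0_pct_ia <= 100) expect_lte(a, bound)
  }
  expect_equal(bound, 8.29e5, tolerance = 5e-3)
})
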