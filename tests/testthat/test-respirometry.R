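test_that("ppm readings convert to air fractions by definition", {
  expect_equal(ppm_to_fraction(0), 0)
  expect_equal(ppm_to_fraction(100), 1e-4)
  expect_equal(ppm_to_fraction(1e6), 1)
  expect_error(ppm_to_fraction(NA_real_), "finite")
})

test_that("baseline fits recover constant and drifting references", {
  t <- 0:300
  flat <- make_session(t, rep(10, length(t)))
  bl <- fit_baseline(flat, c(0, 95))
  expect_equal(unname(predict(bl, c(0, 150, 300))), c(10, 10, 10), tolerance = 1e-10)

  drifting <- make_session(t, 5 + 0.01 * t)
  bl2 <- fit_baseline(drifting, c(0, 95))
  expect_equal(unname(bl2$coefficients[["slope"]]), 0.01, tolerance = 1e-10)

  # noisy drift: recovered slope within 3 SE of the configured drift
  set.seed(41)
  noisy <- make_session(t, 5 + 0.01 * t + rnorm(length(t), 0, 1))
  ref <- t <= 95
  ls <- lm(co2_ppm ~ time_s, data = noisy$trace[ref, ])
  se <- summary(ls)$coefficients["time_s", "Std. Error"]
  bl3 <- fit_baseline(noisy, c(0, 95))
  expect_lt(abs(bl3$coefficients[["slope"]] - 0.01), 3 * se)

  # constant method ignores slope
  bl4 <- fit_baseline(drifting, c(0, 95), method = "constant")
  expect_equal(unname(bl4$coefficients[["slope"]]), 0)

  expect_error(fit_baseline(flat, c(120, 150)), "before the injection")
  expect_error(fit_baseline(flat, c(0, 2)), "5 samples")
})

test_that("bolus integration matches closed forms", {
  t <- 0:600
  # null bolus
  flat <- make_session(t, rep(3, length(t)), flow = 100)
  bl <- fit_baseline(flat, c(0, 95))
  expect_equal(integrate_bolus(flat, bl, c(100, 500)), 0, tolerance = 1e-12)

  # rectangular excess: 100 ppm for 60 s at 100 mL/min -> 0.01 mL
  ppm <- rep(0, length(t))
  ppm[t >= 200 & t < 260] <- 100
  rect <- make_session(t, ppm, flow = 100)
  bl0 <- fit_baseline(rect, c(0, 95))
  expect_equal(integrate_bolus(rect, bl0, c(150, 350)),
               1e-4 * 100 * 1, tolerance = 1e-9)

  # Gaussian bolus against its analytic area
  area_ppm_s <- 5000; sd_s <- 10; centre <- 300
  gauss <- make_session(t, area_ppm_s / (sd_s * sqrt(2 * pi)) *
                          exp(-0.5 * ((t - centre) / sd_s)^2), flow = 150)
  blg <- fit_baseline(gauss, c(0, 95))
  analytic <- area_ppm_s * 1e-6 * 150 / 60
  got <- integrate_bolus(gauss, blg, c(200, 400))
  expect_lt(abs(got - analytic) / analytic, 1e-3)

  # trapezoid agrees with high-resolution quadrature on the same bolus
  fine <- stats::integrate(function(x) area_ppm_s / (sd_s * sqrt(2 * pi)) *
                             exp(-0.5 * ((x - centre) / sd_s)^2) * 1e-6 * 150 / 60,
                           200, 400, rel.tol = 1e-10)$value
  expect_lt(abs(got - fine) / fine, 1e-3)

  expect_error(integrate_bolus(rect, bl0, c(900, 1000)), "outside the trace")
})

test_that("integration is additive over disjoint sub-windows", {
  t <- 0:600
  set.seed(9)
  ppm <- 4 + rnorm(length(t), 0, 2) +
    800 * exp(-0.5 * ((t - 300) / 12)^2)
  s <- make_session(t, ppm, flow = 120)
  bl <- fit_baseline(s, c(0, 95))
  whole <- integrate_bolus(s, bl, c(200, 400))
  left <- integrate_bolus(s, bl, c(200, 300))
  right <- integrate_bolus(s, bl, c(300, 400))
  expect_equal(left + right, whole, tolerance = 1e-12)
})

test_that("the stop-flow correction chain computes VCO2 as specified", {
  # direct substitution: (0.06 - 0.01) * (20/10) / 60
  expect_equal(compute_vco2(0.06, 0.01, 20, 10, 60), 0.1 / 60, tolerance = 1e-12)
  expect_equal(compute_vco2(0.02, 0.02, 20, 10, 60), 0)
  expect_error(compute_vco2(0.06, 0.01, 20, 0, 60), "injected")
  expect_error(compute_vco2(0.06, 0.01, 20, 10, 0), "incubation")
})

test_that("a noiseless generated pair round-trips through processing", {
  p <- trace_params(noise_sd_ppm = 0)
  rate <- 0.0031
  animal <- sim_trace(rate, p, seed = 1, stage = "instar4", session_id = "a")
  ctrl <- sim_trace(0, p, seed = 2, stage = "instar4", session_id = "c",
                    is_control = TRUE)
  got <- process_session(animal, ctrl)
  expect_lt(abs(got$vco2_ml_min - rate), 1e-6)
  expect_identical(got$qc_flags, "")

  # a control processed against itself gives exactly zero
  self <- process_session(ctrl, ctrl)
  expect_equal(self$vco2_ml_min, 0)
})

test_that("the processed rate is invariant to flow rescaling of the trace", {
  t <- 0:600
  excess <- 600 * exp(-0.5 * ((t - 300) / 10)^2)
  base <- 5
  s1 <- make_session(t, base + excess, flow = 100, injection_time = 150)
  s2 <- make_session(t, base + excess / 2, flow = 200, injection_time = 150)
  c1 <- make_session(t, rep(base, length(t)), flow = 100, injection_time = 150,
                     is_control = TRUE)
  c2 <- make_session(t, rep(base, length(t)), flow = 200, injection_time = 150,
                     is_control = TRUE)
  r1 <- process_session(s1, c1, windows = list(integration = c(200, 400)))
  r2 <- process_session(s2, c2, windows = list(integration = c(200, 400)))
  expect_equal(r1$vco2_ml_min, r2$vco2_ml_min, tolerance = 1e-12)
})

test_that("undetectable boluses are flagged, not dropped, and negatives kept", {
  t <- 0:600
  set.seed(31)
  quiet <- make_session(t, 5 + rnorm(length(t), 0, 2), injection_time = 150)
  ctrl <- make_session(t, 5 + rnorm(length(t), 0, 2), injection_time = 150,
                       is_control = TRUE)
  out <- process_session(quiet, ctrl)
  expect_match(out$qc_flags, "no_bolus")
  expect_true(is.finite(out$vco2_ml_min))
  if (out$integrated_volume_ml - out$control_volume_ml < 0) {
    expect_match(out$qc_flags, "negative_volume")
    expect_lt(out$vco2_ml_min, 0)  # retained, not truncated at zero
  }
})

test_that("session IO round-trips through CSV + JSON sidecars", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(replicates = tibble::tibble(
    stage = "instar4", host = c("Urtica", "Salix", "Ribes"), n = 3L
  ), batch_size = 5L)
  study <- sim_study(cfg, seed = 21)
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  back <- read_study(dir)
  expect_equal(length(back$sessions), length(study$sessions))
  sid <- names(study$sessions)[[2]]
  expect_equal(back$sessions[[sid]]$trace$co2_ppm,
               study$sessions[[sid]]$trace$co2_ppm, tolerance = 1e-12)
  expect_equal(back$sessions[[sid]]$injected_volume_ml,
               study$sessions[[sid]]$injected_volume_ml)
  # processing the re-read study matches processing the in-memory one
  v1 <- process_study(study)
  v2 <- process_study(back)
  expect_equal(dplyr::arrange(v2, session_id)$vco2_ml_min,
               dplyr::arrange(v1, session_id)$vco2_ml_min, tolerance = 1e-10)
})
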