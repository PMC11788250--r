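test_that("noiseless bolus samples are recovered almost exactly", {
  sch <- frame_schedule()
  truth <- bolus_input(0.18, 25000, 5, A = c(350, 160), l = c(0.7, 0.015))
  y <- frame_average(truth, sch$start_min, sch$duration_min)
  fit <- fit_idif(y, sch, n_terms = 3)
  tt <- seq(0.05, 59, by = 0.05)
  rms <- sqrt(mean((es_eval(fit$model, tt) - es_eval(truth, tt))^2))
  expect_lt(rms / max(es_eval(truth, tt)), 0.005)
  expect_true(fit$converged)
})

test_that("flat or non-positive samples are rejected (no peak)", {
  sch <- frame_schedule()
  expect_error(fit_idif(rep(0, nrow(sch)), sch), "peak")
  expect_error(fit_idif(rep(-3, nrow(sch)), sch), "peak")
})

test_that("fit residual RMS reflects the injected noise level", {
  gt <- default_ground_truth(21)
  ds <- simulate_dataset(gt)
  sch <- ds$schedule
  sig_true <- ds$sigma[, "idif"]
  fit <- fit_idif(ds$idif, sch, sigma = pmax(sig_true, 1))
  # residual RMS should sit within +/-50% of the injected noise RMS
  expect_gt(fit$residual_rms, 0.5 * sqrt(mean(sig_true^2)))
  expect_lt(fit$residual_rms, 1.5 * sqrt(mean(sig_true^2)))
})

test_that("identity corrections return the IDIF unchanged", {
  f <- make_test_expsum(8)
  corr <- aif_corrections(gamma = 1, tau = 0,
                          delays = c(heart = 0, lungs = 0, liver = 0,
                                     kidneys = 0, femur = 0))
  g <- corrected_input(f, corr, "liver")
  t <- seq(0.1, 50, length.out = 60)
  expect_equal(es_eval(g, t), es_eval(f, t), tolerance = 1e-12)
})

test_that("dispersion of a single exponential has the known closed form", {
  a <- 0.9; tau <- 0.25
  f <- expsum(1, a)
  g <- es_disperse(f, tau)
  t <- seq(0.05, 10, length.out = 50)
  expect_equal(es_eval(g, t),
               (exp(-a * t) - exp(-t / tau)) / (1 - a * tau),
               tolerance = 1e-10)
})

test_that("gamma is applied exactly in the chosen direction", {
  f <- make_test_expsum(10)
  corr <- aif_corrections(gamma = 2, tau = 0,
                          delays = c(heart = 0, lungs = 0, liver = 0,
                                     kidneys = 0, femur = 0))
  t <- seq(0.2, 20, length.out = 30)
  expect_equal(es_eval(corrected_input(f, corr, "heart"), t),
               es_eval(f, t) / 2)         # default: IDIF divided by gamma
  expect_equal(es_eval(corrected_input(f, corr, "heart",
                                       gamma_direction = "multiply"), t),
               es_eval(f, t) * 2)
})

test_that("delay moves the peak by exactly delta-t", {
  f <- bolus_input(0.2, 1000, 4, A = 50, l = 0.05)
  corr <- aif_corrections(gamma = 1, tau = 0.1,
                          delays = c(heart = 0.3, lungs = 0, liver = 0,
                                     kidneys = -0.15, femur = 0))
  tg <- seq(0, 10, by = 1e-3)
  ref <- corrected_input(f, corr, "lungs")
  t_ref <- tg[which.max(es_eval(ref, tg))]
  t_heart <- tg[which.max(es_eval(corrected_input(f, corr, "heart"), tg))]
  t_kid <- tg[which.max(es_eval(corrected_input(f, corr, "kidneys"), tg))]
  expect_equal(t_heart - t_ref, 0.3, tolerance = 2e-3)
  expect_equal(t_kid - t_ref, -0.15, tolerance = 2e-3)
})

test_that("correction parameters are validated", {
  expect_error(aif_corrections(gamma = 0), "gamma")
  expect_error(aif_corrections(tau = -1), "tau")
  expect_error(aif_corrections(delays = c(brain = 0.1)), "organ")
})
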