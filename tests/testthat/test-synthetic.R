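test_that("the default schedule reproduces the acquisition protocol", {
  sch <- frame_schedule()
  expect_identical(nrow(sch), 33L)
  expect_equal(sum(sch$duration_s), 3540)
  expect_equal(sch$start_s[1], 0)
  # contiguous, non-overlapping
  expect_equal(sch$start_s[-1], (sch$start_s + sch$duration_s)[-33])
  expect_identical(nrow(schedule_frames(sch, "short")), 18L)
  expect_identical(nrow(schedule_frames(sch, "long")), 33L)
})

test_that("ground truth draws are reproducible and physical", {
  g1 <- default_ground_truth(7)
  g2 <- default_ground_truth(7)
  expect_identical(g1$par, g2$par)
  expect_identical(g1$idif_true, g2$idif_true)
  expect_false(identical(g1$par, default_ground_truth(8)$par))
  b <- joint_bounds()
  for (s in 1:50) {
    p <- default_ground_truth(s)$par
    expect_true(all(p >= b$lower[names(p)] - 1e-12))
    expect_true(all(p <= b$upper[names(p)] + 1e-12))
    expect_true(all(p[grepl("^vb_", names(p))] >= 0 &
                      p[grepl("^vb_", names(p))] <= 1))
  }
})

test_that("population draws centre on the stated kidney uptake", {
  k1 <- vapply(1:1000, function(s)
    default_ground_truth(s)$par[["K1_kidneys"]], numeric(1))
  se <- 0.45 / sqrt(1000)
  expect_lt(abs(mean(k1) - 2.21), 3 * se)
})

test_that("zero noise scale reproduces the forward model exactly", {
  sc0 <- c(heart = 0, lungs = 0, liver = 0, kidneys = 0, femur = 0,
           idif = 0)
  gt <- default_ground_truth(3, noise = noise_spec(sc = sc0))
  ds <- simulate_dataset(gt)
  expect_equal(unname(ds$tacs),
               unname(ds$noiseless[, colnames(ds$tacs)]), tolerance = 1e-12)
})

test_that("noise scales as the counting-statistics formula demands", {
  ns <- noise_spec()
  # 10 s vs 300 s frame at equal CT and t: sigma ratio sqrt(30)
  s10 <- noise_sigma(ns, "liver", 100, 5, 10 / 60)
  s300 <- noise_sigma(ns, "liver", 100, 5, 300 / 60)
  expect_equal(s10 / s300, sqrt(30), tolerance = 1e-12)
  # decay-correction inflation over the hour: e^{lambda * 59} ~ 1.45
  r <- noise_sigma(ns, "liver", 100, 59, 1) / noise_sigma(ns, "liver", 100, 0, 1)
  expect_equal(r, exp(log(2) / 109.77 * 59), tolerance = 1e-12)
  expect_equal(unname(r), 1.45, tolerance = 0.01)
})

test_that("simulated frame noise matches its formula empirically", {
  gt <- default_ground_truth(5)
  clean <- forward_model(gt$par, gt$idif_true, gt$schedule)
  frame <- 21L; organ <- "kidneys"
  sig_theory <- noise_sigma(gt$noise, organ, clean[frame, organ],
                            gt$schedule$mid_min[frame],
                            gt$schedule$duration_min[frame])
  draws <- vapply(1:500, function(i)
    simulate_dataset(gt, seed = 1000 + i)$tacs[frame, organ], numeric(1))
  expect_lt(abs(stats::sd(draws) - sig_theory) / sig_theory, 0.10)
  expect_lt(abs(mean(draws) - clean[frame, organ]) / sig_theory, 0.2)
})

test_that("negative activities are kept, not clipped", {
  # a high-noise region of near-zero activity must produce negatives
  gt <- default_ground_truth(2)
  vals <- vapply(1:50, function(i)
    min(simulate_dataset(gt, seed = i)$tacs[1:2, ]), numeric(1))
  expect_true(any(vals < 0))
})
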