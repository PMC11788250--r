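# build a synthetic ensemble object without running any fits
fake_ensemble <- function(chi2, pm) {
  best_i <- which.min(chi2)
  structure(list(results = NULL,
                 best = structure(list(chi2_nu = chi2[best_i]),
                                  class = "fit_result"),
                 chi2_nu = chi2, converged = rep(TRUE, length(chi2)),
                 par_matrix = pm, n_starts = length(chi2)),
            class = "multistart_ensemble")
}

test_that("near-optimal set applies the +1 threshold", {
  pm <- matrix(seq_len(8), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  e <- fake_ensemble(c(1.0, 1.5, 2.0, 2.5), pm)
  s <- near_optimal_set(e)
  expect_identical(s$indices, 1:3)
  expect_identical(s$n_points, 3L)
  # identical chi2 everywhere keeps the full ensemble
  e2 <- fake_ensemble(rep(2, 4), pm)
  expect_identical(near_optimal_set(e2)$n_points, 4L)
  # subsets below 3 points are flagged
  e3 <- fake_ensemble(c(1, 9, 9, 9), pm)
  expect_true(isTRUE(attr(near_optimal_set(e3), "too_small")))
})

test_that("correlation matrix matches the two-pass textbook formula", {
  set.seed(31)
  pm <- cbind(K1_kidneys = rnorm(20), k2_kidneys = rnorm(20),
              vb_kidneys = rnorm(20))
  rep <- correlation_matrix(pm)
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(rep$r["K1_kidneys", "k2_kidneys"],
               two_pass(pm[, 1], pm[, 2]), tolerance = 1e-12)
  expect_true(isSymmetric(rep$r))
  expect_true(all(diag(rep$r) == 1))
  expect_true(all(abs(rep$r) <= 1 + 1e-12))
})

test_that("degenerate inputs are handled explicitly", {
  pm <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  rep <- correlation_matrix(pm)
  expect_true(is.na(rep$r["a", "b"])) # zero variance: missing, not 0
  # exactly collinear pair
  pm2 <- cbind(K1 = c(1, 2, 3, 4), k2 = 2 * c(1, 2, 3, 4))
  expect_equal(correlation_matrix(pm2)$r["K1", "k2"], 1)
  expect_error(correlation_matrix(pm[1:2, ]), "fewer than 3")
})

test_that("organ scoping keeps the organ block plus shared corrections", {
  pm <- matrix(rnorm(60), nrow = 10)
  colnames(pm) <- c("gamma", "tau", "K1_femur", "k2_femur", "vb_femur",
                    "K1_liver")
  rep <- correlation_matrix(pm, organ = "femur")
  expect_setequal(colnames(rep$r),
                  c("K1_femur", "k2_femur", "vb_femur", "gamma", "tau"))
})

test_that("exact Wilcoxon significance matches brute-force enumeration", {
  r_all_pos <- c(0.9, 0.8, 0.95, 0.85, 0.9, 0.92)
  out <- significance_across_subjects(r_all_pos)
  expect_equal(out$p_value, 2 / 64, tolerance = 1e-12)   # = 0.03125
  expect_true(out$significant)
  expect_equal(out$p_value, wilcoxon_enum_p(r_all_pos), tolerance = 1e-12)

  r_balanced <- c(0.9, -0.9, 0.9, -0.9, 0.9, -0.9)
  out2 <- significance_across_subjects(r_balanced)
  expect_false(out2$significant)

  set.seed(17)
  for (i in 1:10) {
    r <- round(stats::runif(6, -1, 1), 3)
    r <- r[r != 0]
    if (anyDuplicated(abs(r))) next
    expect_equal(significance_across_subjects(r)$p_value,
                 wilcoxon_enum_p(r), tolerance = 1e-12)
  }
  # five positive, one smallest-magnitude negative: p = 4/64
  r5 <- c(0.9, 0.8, 0.7, 0.6, 0.5, -0.1)
  expect_equal(significance_across_subjects(r5)$p_value,
               wilcoxon_enum_p(r5), tolerance = 1e-12)
  expect_error(significance_across_subjects(c(0.5, NA)), "undefined")
})

test_that("2-D kernel density integrates to one over its grid", {
  set.seed(23)
  pm <- cbind(K1_kidneys = rnorm(300, 2, 0.3),
              k2_kidneys = rnorm(300, 2.4, 0.5))
  sub <- list(par_matrix = pm)
  kd <- kde2d_pair(sub, "K1_kidneys", "k2_kidneys", n = 151)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  expect_equal(sum(kd$z) * dx * dy, 1, tolerance = 0.01)
})
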