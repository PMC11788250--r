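test_that("joint parameter vector round-trips losslessly", {
  gt <- default_ground_truth(13)
  up <- joint_unpack(gt$par)
  expect_identical(joint_pack(up$corr, up$organs), gt$par)
  expect_identical(length(joint_param_names()), 22L)
  expect_error(joint_unpack(gt$par[-3]), "missing")
})

test_that("degrees of freedom follow the frame counts and 22 parameters", {
  fx <- make_noiseless_dataset(1)
  ps <- fit_problem(fx$ds, fx$gt$idif_true, scale = "short",
                    sigma = fx$sigma1)
  pl <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  expect_identical(ps$n_obs, 5L * 18L)
  expect_identical(pl$n_obs, 5L * 33L)
  expect_identical(score_fit(fx$gt$par, ps)$nu, 90L - 22L)  # 68
  expect_identical(score_fit(fx$gt$par, pl)$nu, 165L - 22L) # 143
})

test_that("residuals vanish on data generated at the parameters", {
  fx <- make_noiseless_dataset(2)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  r <- joint_objective(fx$gt$par, pr)
  expect_lt(max(abs(r)), 1e-9)
  expect_identical(length(r), 165L)
})

test_that("a single organ's K1 only perturbs that organ's residuals", {
  fx <- make_noiseless_dataset(3)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  r0 <- matrix(joint_objective(fx$gt$par, pr), ncol = 5)
  p2 <- fx$gt$par; p2[["K1_liver"]] <- p2[["K1_liver"]] * 1.3
  r1 <- matrix(joint_objective(p2, pr), ncol = 5)
  changed <- colSums(abs(r1 - r0)) > 1e-10
  expect_identical(unname(changed),
                   colnames(pr$obs) == "liver")
})

test_that("score_fit equals the stacked weighted sum of squares", {
  gt <- default_ground_truth(4)
  ds <- simulate_dataset(gt)
  pr <- fit_problem(ds, gt$idif_true, scale = "long", sigma = ds$sigma_fit)
  r <- joint_objective(gt$par, pr)
  sc <- score_fit(gt$par, pr)
  expect_equal(sc$chi2_nu, sum(r^2) / sc$nu, tolerance = 1e-12)
  expect_equal(sum(sc$per_organ), sc$chi2_nu * sc$nu, tolerance = 1e-10)
})

test_that("sigma of zero is a configuration error", {
  fx <- make_noiseless_dataset(5)
  s0 <- fx$sigma1; s0[3, "liver"] <- 0
  expect_error(fit_problem(fx$ds, fx$gt$idif_true, sigma = s0),
               "sigma")
})

test_that("noiseless fit started at the truth stays at the truth", {
  fx <- make_noiseless_dataset(6)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  f <- fit_once(fx$gt$par, pr)
  expect_true(f$converged)
  expect_lt(max(abs(f$par - fx$gt$par) / pmax(abs(fx$gt$par), 1e-9)), 1e-6)
})

test_that("noiseless recovery from a perturbed start is near exact", {
  fx <- make_noiseless_dataset(7)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  set.seed(1)
  start <- fx$gt$par * runif(22, 0.8, 1.2)
  f <- fit_once(start, pr, maxiter = 400)
  expect_lt(abs(f$par[["K1_kidneys"]] - fx$gt$par[["K1_kidneys"]]) /
              fx$gt$par[["K1_kidneys"]], 0.01)
})

test_that("a pathological start at the box corner never crashes", {
  fx <- make_noiseless_dataset(8)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1)
  f <- fit_once(joint_bounds()$upper, pr, maxiter = 30)
  expect_s3_class(f, "fit_result")
  expect_true(is.finite(f$chi2_nu) || !f$converged)
})

test_that("centred Latin hypercube stratifies every dimension", {
  set.seed(2)
  u <- lhs_centered(16, 3)
  for (j in 1:3)
    expect_identical(sort(u[, j]), (seq_len(16) - 0.5) / 16)
})

test_that("multistart is deterministic and degenerates gracefully", {
  fx <- make_noiseless_dataset(9)
  pr <- fit_problem(fx$ds, fx$gt$idif_true, scale = "long",
                    sigma = fx$sigma1,
                    free = c("K1_liver", "vb_liver"),
                    fixed = fx$gt$par)
  e1 <- multistart(pr, n_starts = 1, seed = 5)
  expect_identical(e1$best$par, e1$mode$par) # single start: mode == best
  e2 <- multistart(pr, n_starts = 12, seed = 6)
  e3 <- multistart(pr, n_starts = 12, seed = 6)
  expect_identical(e2$par_matrix, e3$par_matrix)
  expect_identical(e2$chi2_nu, e3$chi2_nu)
})

test_that("a well-identified single-organ problem has one basin", {
  gt <- default_ground_truth(10)
  ds <- simulate_dataset(gt)
  pr <- fit_problem(ds, gt$idif_true, scale = "long", organs = "liver",
                    sigma = ds$sigma_fit,
                    free = c("K1_liver", "vb_liver"),
                    fixed = gt$par)
  e <- multistart(pr, n_starts = 30, seed = 3, polish_n = 30)
  # the dominant basin collects (nearly) all starts, and every
  # statistically equivalent fit pinpoints the same parameters
  in_basin <- e$chi2_nu <= e$best$chi2_nu + 1
  expect_gte(mean(in_basin[e$converged]), 0.9)
  pm <- e$par_matrix[in_basin, , drop = FALSE]
  spread <- apply(pm, 2, function(x) diff(range(x)) / stats::median(x))
  expect_true(all(spread < 0.01))
  expect_lt(abs(e$best$par[["K1_liver"]] - gt$par[["K1_liver"]]) /
              gt$par[["K1_liver"]], 0.15)
})

test_that("chi-square excursion solves the quadratic toy exactly", {
  nu <- 50; s <- 0.2; hat <- 1.3
  chi2_fun <- function(x) (x - hat)^2 / (nu * s^2)
  ex <- chi2_excursion(chi2_fun, hat, lower = -10, upper = 10)
  expect_equal(ex$upper - hat, s * sqrt(nu), tolerance = 1e-6)
  expect_equal(hat - ex$lower, s * sqrt(nu), tolerance = 1e-6)
  expect_false(ex$censored_lower || ex$censored_upper)
  # flat direction: never crosses, censored at both bounds
  ex2 <- chi2_excursion(function(x) 0, 0.5, lower = 0, upper = 1)
  expect_true(ex2$censored_lower && ex2$censored_upper)
  expect_identical(c(ex2$lower, ex2$upper), c(0, 1))
})

test_that("error bars cover a known noiseless optimum tightly", {
  fx <- make_noiseless_dataset(11)
  ds <- simulate_dataset(fx$gt)
  pr <- fit_problem(ds, fx$gt$idif_true, scale = "long", organs = "liver",
                    sigma = ds$sigma_fit,
                    free = c("K1_liver", "vb_liver"), fixed = fx$gt$par)
  f <- fit_once(fx$gt$par, pr)
  eb <- error_bars(f, pr)
  expect_identical(eb$param, c("K1_liver", "vb_liver"))
  expect_true(all(is.finite(eb$err)))
  expect_true(all(eb$upper > eb$estimate & eb$lower < eb$estimate))
})

test_that("compiled and building-block model paths agree", {
  gt <- default_ground_truth(19)
  ds <- simulate_dataset(gt)
  for (scale in c("short", "long")) {
    pr <- fit_problem(ds, gt$idif_true, scale = scale, sigma = ds$sigma_fit)
    set.seed(3)
    for (i in 1:5) {
      full <- nafkin:::.full_par(pr, nafkin:::.u_to_par(pr, runif(22)))
      a <- nafkin:::.model_frames(pr, full)
      b <- nafkin:::.model_frames_reference(pr, full)
      expect_lt(max(abs(a - b) / pmax(abs(b), 1e-9)), 1e-7)
    }
  }
})
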