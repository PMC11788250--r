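test_that("organ topologies carry the right structure", {
  expect_equal(organ_model("heart")$vd_constraint, 0.665)
  expect_equal(organ_model("lungs")$vd_constraint, 0.763)
  expect_equal(organ_model("liver")$vd_constraint, 0.751)
  expect_identical(organ_model("femur")$n_tissue_compartments, 2L)
  expect_false(organ_model("femur")$has_clearance)
  expect_true(organ_model("kidneys")$has_clearance)
  expect_error(kinetic_params(organ_model("liver"), K1 = 1, k3 = 0.1),
               "trapping")
  expect_error(kinetic_params(organ_model("femur"), K1 = 1, k4 = 0.1),
               "clearance")
  expect_error(kinetic_params(organ_model("femur"), K1 = -1), ">= 0")
  expect_error(kinetic_params(organ_model("femur"), K1 = 1, vb = 1.2),
               "vb")
})

test_that("Vd constraint pins k2 = K1/Vd exactly", {
  for (o in c("heart", "lungs", "liver")) {
    m <- organ_model(o)
    p <- kinetic_params(m, K1 = 0.37, k2 = 99) # supplied k2 ignored
    expect_identical(p$k2, 0.37 / m$vd_constraint)
  }
})

test_that("no uptake means no tissue signal", {
  ca <- make_test_expsum(2)
  p <- kinetic_params(organ_model("kidneys"), K1 = 0, k2 = 1, k3 = 0.5,
                      k4 = 0.2, vb = 0)
  sol <- solve_tissue(organ_model("kidneys"), p, ca,
                      times = seq(0, 50, by = 1))
  expect_true(all(sol$eval$CT == 0))
})

test_that("pure integration limit: 1TC with k2 = 0", {
  # femur with k2 = k3 = 0 collapses to dC1/dt = K1 Ca; for Ca = A e^{-at},
  # C1(t) = K1 A (1 - e^{-at})/a
  A <- 7; a <- 0.9; K1 <- 0.4
  p <- kinetic_params(organ_model("femur"), K1 = K1, k2 = 0, k3 = 0, vb = 0)
  sol <- solve_tissue(organ_model("femur"), p, expsum(A, a))
  t <- c(0.5, 2, 10)
  expect_equal(es_eval(sol$C1, t), K1 * A * (1 - exp(-a * t)) / a,
               tolerance = 1e-10)
})

test_that("closed-form solutions match numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  tt <- seq(0, 59, by = 1)
  for (rep in 1:8) {
    ca <- make_test_expsum(rep + 100)
    for (o in c("heart", "lungs", "liver", "kidneys", "femur")) {
      m <- organ_model(o)
      two <- m$n_tissue_compartments == 2L
      p <- kinetic_params(m, K1 = runif(1, 0.05, 3),
                          k2 = if (two) runif(1, 0.05, 3) else 0,
                          k3 = if (m$has_trapping) runif(1, 0.02, 3) else 0,
                          k4 = if (m$has_clearance) runif(1, 0.02, 2) else 0,
                          vb = runif(1, 0, 0.5))
      sol <- solve_tissue(m, p, ca)
      rhs <- function(t, y, parms) {
        cat_ <- es_eval(ca, t)
        list(c(p$K1 * cat_ - (p$k2 + p$k3) * y[1],
               p$k3 * y[1] - p$k4 * y[2]))
      }
      num <- deSolve::ode(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-12)
      cf <- es_eval(sol$C1, tt) + if (two) es_eval(sol$C2, tt) else 0
      ref <- num[, 2] + if (two) num[, 3] else 0
      expect_lt(max(abs(cf - ref) / pmax(abs(ref), 1e-6 * max(abs(ref)))), 1e-6)
    }
  }
})

test_that("conservation: with all efflux off, C1 integrates the input", {
  ca <- make_test_expsum(4)
  p <- kinetic_params(organ_model("femur"), K1 = 0.8, k2 = 0, k3 = 0, vb = 0)
  sol <- solve_tissue(organ_model("femur"), p, ca)
  for (T in c(2, 15, 50))
    expect_equal(es_eval(sol$C1, T), 0.8 * quad_mean(ca, 0, T) * T,
                 tolerance = 1e-8)
})

test_that("irreversibly trapped compartment is non-decreasing", {
  ca <- make_test_expsum(6)
  p <- kinetic_params(organ_model("femur"), K1 = 0.3, k2 = 0.2, k3 = 0.15,
                      vb = 0.05)
  sol <- solve_tissue(organ_model("femur"), p, ca)
  c2 <- es_eval(sol$C2, seq(0, 59, by = 0.25))
  expect_true(all(diff(c2) >= -1e-10))
})

test_that("influx rate follows Ki = K1 k3/(k2+k3)", {
  p <- list(K1 = 0.26, k2 = 0.20, k3 = 0.14) # femur long-scale means
  expect_equal(influx_rate(p), 0.26 * 0.14 / 0.34, tolerance = 1e-12)
  expect_equal(influx_rate(list(K1 = 0.5, k2 = 1, k3 = 0)), 0)
  expect_equal(influx_rate(list(K1 = 0.5, k2 = 0, k3 = 2)), 0.5)
  expect_error(influx_rate(list(K1 = 1, k2 = 0, k3 = 0)), "undefined")
})
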