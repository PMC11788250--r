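# shared fixtures, all generated in code

# a modest multi-exponential test curve with a ramp term
make_test_expsum <- function(seed = 1) {
  set.seed(seed)
  expsum(coef = c(runif(1, 500, 2000), runif(2, 10, 300)),
         rate = c(runif(1, 2, 8), runif(1, 0.2, 1), runif(1, 0.005, 0.05)),
         power = c(1L, 0L, 0L),
         onset = runif(1, 0.05, 0.3))
}

# numerical quadrature oracle for frame averages / integrals
quad_mean <- function(f, a, b) {
  # piecewise to keep adaptive quadrature happy on long windows
  cuts <- unique(c(a, pmin(pmax(c(0.5, 2, 10), a), b), b))
  tot <- 0
  for (i in seq_len(length(cuts) - 1L))
    tot <- tot + stats::integrate(function(t) es_eval(f, t),
                                  cuts[i], cuts[i + 1], rel.tol = 1e-11,
                                  subdivisions = 2000L)$value
  tot / (b - a)
}

# discrete-grid convolution oracle: (f (x) e^{-a t}) on a fine grid
conv_oracle <- function(f, a, t, dt = 1e-4) {
  tg <- seq(0, max(t) + dt, by = dt)
  fg <- es_eval(f, tg)
  kg <- exp(-a * tg)
  full <- stats::convolve(fg, rev(kg), type = "open")[seq_along(tg)] * dt
  stats::approx(tg, full, xout = t)$y
}

# one small noiseless dataset built from a fixed ground truth
make_noiseless_dataset <- function(seed = 1) {
  gt <- default_ground_truth(seed)
  clean <- forward_model(gt$par, gt$idif_true, gt$schedule)
  sig <- matrix(1, nrow(clean), ncol(clean), dimnames = dimnames(clean))
  ds <- structure(list(tacs = clean[, setdiff(colnames(clean), "idif")],
                       idif = clean[, "idif"], noiseless = clean,
                       sigma = sig, sigma_fit = sig,
                       schedule = gt$schedule, noise = gt$noise, gt = gt),
                  class = "tac_dataset")
  list(gt = gt, ds = ds, sigma1 = sig)
}

femur_ki <- function(p)
  p[["K1_femur"]] * p[["k3_femur"]] / (p[["k2_femur"]] + p[["k3_femur"]])

# brute-force exact Wilcoxon signed-rank p (two-sided, no ties/zeros):
# enumerate all 2^n sign assignments of the ranked |x|
wilcoxon_enum_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- grid %*% r
  d <- abs(Wall - n * (n + 1) / 4)
  mean(d >= abs(W - n * (n + 1) / 4))
}
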