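#' Counting-statistics noise model
#'
#' Frame noise is modelled as zero-mean Gaussian with standard deviation
#' \deqn{\sigma(t) = S_c \, e^{\lambda t} \sqrt{C_T(t) / \Delta t},}
#' where `Sc` is a per-organ scale chosen qualitatively to match the noise
#' seen in that organ's VOI, the exponential undoes the decay correction
#' applied to the data (18F decay constant `lambda = ln 2 / 109.77` per
#' min), `CT` is the (noiseless) frame activity and `dt` the frame length.
#' Short early frames and decay-corrected late frames are therefore the
#' noisiest, as in real reconstructions.
#'
#' @param sc named per-organ scale factors, plus an `idif` entry for the
#'   vena-cava curve (image derived, hence noisier).
#' @param lambda_decay 1/min; fixed to the 18F value by default.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sc = c(heart = 0.7, lungs = 0.6, liver = 0.4,
                              kidneys = 0.5, femur = 0.4, idif = 1.2),
                       lambda_decay = log(2) / 109.77) {
  if (any(sc < 0) || any(!is.finite(sc))) stop("Sc factors must be >= 0")
  if (!all(c(ORGANS, "idif") %in% names(sc)))
    stop("sc needs entries for every organ and for 'idif'")
  structure(list(sc = sc, lambda_decay = lambda_decay), class = "noise_spec")
}

#' Noise standard deviation per frame
#'
#' @param noise a [noise_spec].
#' @param region organ id or `"idif"`.
#' @param ct noiseless frame activity values (negatives are floored at 0).
#' @param mid_min frame mid-times, min.
#' @param dur_min frame durations, min.
#' @return numeric vector of per-frame SDs.
#' @export
noise_sigma <- function(noise, region, ct, mid_min, dur_min) {
  stopifnot(inherits(noise, "noise_spec"))
  noise$sc[[region]] * exp(noise$lambda_decay * mid_min) *
    sqrt(pmax(ct, 0) / dur_min)
}

# per-subject sampling distributions: mean, sd, lower truncation.
# Kinetic centres are the long-scale population values for this tracer;
# blood volumes, the heart uptake and the input-function shape are set to
# physiologically plausible values (see the methods vignette).
.GT_DRAWS <- list(
  K1_heart   = c(0.50, 0.15, 0.05),
  K1_lungs   = c(0.06, 0.08, 0.01),
  K1_liver   = c(0.49, 0.43, 0.05),
  K1_kidneys = c(2.21, 0.45, 0.30),
  k2_kidneys = c(2.43, 2.05, 0.30),
  k3_kidneys = c(2.40, 0.90, 0.30),
  k4_kidneys = c(1.40, 0.56, 0.05),
  K1_femur   = c(0.26, 0.08, 0.03),
  k2_femur   = c(0.20, 0.24, 0.02),
  k3_femur   = c(0.14, 0.15, 0.02),
  vb_heart   = c(0.35, 0.10, 0.02),
  vb_lungs   = c(0.15, 0.05, 0.02),
  vb_liver   = c(0.20, 0.05, 0.02),
  vb_kidneys = c(0.20, 0.05, 0.02),
  vb_femur   = c(0.06, 0.02, 0.01),
  gamma      = c(0.80, 0.20, 0.30),
  tau        = c(0.20, 0.08, 0.02),
  delay_heart   = c(0.25, 0.10, -0.40),
  delay_lungs   = c(0.25, 0.10, -0.40),
  delay_liver   = c(0.30, 0.10, -0.40),
  delay_kidneys = c(0.30, 0.10, -0.40),
  delay_femur   = c(0.25, 0.10, -0.40)
)

.rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

#' Draw a ground-truth multi-organ subject
#'
#' Samples one subject's joint parameters from truncated normal
#' distributions centred on the long-scale population kinetics (kidney
#' `K1 = 2.21 +/- 0.45` mL/mL/min, femur `K1 = 0.26 +/- 0.08`, etc.), plus
#' a bolus-shaped true IDIF scaled to a ~12 MBq-class injection in a
#' mouse, the default frame schedule and the default noise model.
#'
#' @param subject_seed integer seed; identical seeds give identical
#'   subjects.
#' @param schedule a [frame_schedule].
#' @param noise a [noise_spec].
#' @param at_means logical: if `TRUE`, skip the random draw and place the
#'   subject exactly at the distribution centres.
#' @return a `ground_truth`: list with `par` (named 22-vector), `corr`,
#'   `organs`, `idif_true` ([expsum]), `schedule`, `noise`,
#'   `subject_seed`.
#' @export
default_ground_truth <- function(subject_seed = 1L,
                                 schedule = frame_schedule(),
                                 noise = noise_spec(),
                                 at_means = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"), inherits(noise, "noise_spec"))
  bounds <- joint_bounds()
  par <- stats::setNames(numeric(length(.GT_DRAWS)), names(.GT_DRAWS))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(subject_seed)
    expr
  }
  draw_all <- function() {
    for (nm in names(.GT_DRAWS)) {
      d <- .GT_DRAWS[[nm]]
      par[nm] <<- if (at_means) d[1]
        else .rtrunc_norm(1, d[1], d[2], max(d[3], bounds$lower[[nm]]),
                          bounds$upper[[nm]])
    }
    # bolus IDIF: fast washout peak plus intermediate and slow clearance
    A1 <- if (at_means) 30000 else .rtrunc_norm(1, 30000, 6000, 10000)
    l1 <- if (at_means) 6 else .rtrunc_norm(1, 6, 1, 3)
    A2 <- if (at_means) 400 else .rtrunc_norm(1, 400, 80, 100)
    A3 <- if (at_means) 180 else .rtrunc_norm(1, 180, 40, 50)
    t0 <- if (at_means) 0.15 else .rtrunc_norm(1, 0.15, 0.05, 0.02, 0.5)
    bolus_input(t0, A1, l1, A = c(A2, A3), l = c(0.6, 0.012))
  }
  idif_true <- withr_seed(draw_all())
  up <- joint_unpack(par[joint_param_names()])
  structure(list(par = joint_pack(up$corr, up$organs), corr = up$corr,
                 organs = up$organs, idif_true = idif_true,
                 schedule = schedule, noise = noise,
                 subject_seed = subject_seed),
            class = "ground_truth")
}

#' Noiseless forward model of a subject
#'
#' Frame-averaged model TACs for every organ plus the (uncorrected) IDIF,
#' given joint parameters and a true input curve.
#'
#' @param par named joint-parameter vector (see [joint_param_names()]).
#' @param idif_true true IDIF, an [expsum].
#' @param schedule a [frame_schedule].
#' @param gamma_direction passed to [corrected_input()].
#' @return matrix frames x (organs + idif) of frame-averaged activities.
#' @export
forward_model <- function(par, idif_true, schedule,
                          gamma_direction = "divide") {
  up <- joint_unpack(par)
  st <- schedule$start_min; du <- schedule$duration_min
  out <- matrix(0, nrow(schedule), length(ORGANS) + 1L,
                dimnames = list(NULL, c(ORGANS, "idif")))
  for (o in ORGANS) {
    ca <- corrected_input(idif_true, up$corr, o, gamma_direction)
    ct <- solve_tissue(organ_model(o), up$organs[[o]], ca)$CT
    out[, o] <- frame_average(ct, st, du)
  }
  out[, "idif"] <- frame_average(idif_true, st, du)
  out
}

#' Simulate a framed noisy dataset from a ground truth
#'
#' Applies the counting-statistics noise model to the noiseless
#' frame-averaged TACs: independent Gaussian noise per frame and region
#' with `sigma = Sc exp(lambda t) sqrt(CT/dt)`. Negative simulated
#' activities are kept (decay-corrected PET data can go negative); keeping
#' them preserves the symmetry the weighted fit assumes.
#'
#' @param gt a [default_ground_truth()] result.
#' @param seed optional seed for the noise draw; defaults to
#'   `gt$subject_seed + 1`.
#' @return a `tac_dataset`: list with `tacs` (frames x organs matrix,
#'   noisy), `idif` (noisy vector), `noiseless` (matrix incl. idif),
#'   `sigma` (matrix of true SDs incl. idif), `schedule`, `noise`, `gt`.
#' @export
simulate_dataset <- function(gt, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(seed)) seed <- gt$subject_seed + 1L
  sch <- gt$schedule
  clean <- forward_model(gt$par, gt$idif_true, sch)
  sigma <- clean
  for (reg in colnames(clean))
    sigma[, reg] <- noise_sigma(gt$noise, reg, clean[, reg],
                                sch$mid_min, sch$duration_min)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noisy <- clean + matrix(stats::rnorm(length(clean)), nrow(clean)) * sigma
  # weighting variant: frames before bolus arrival have sigma = 0 (no
  # counts), which cannot weight residuals; floor at 1% of the per-region
  # maximum for use as fit weights
  sigma_fit <- sigma
  for (j in seq_len(ncol(sigma_fit)))
    sigma_fit[, j] <- pmax(sigma_fit[, j], 0.01 * max(sigma_fit[, j]))
  structure(list(tacs = noisy[, ORGANS, drop = FALSE],
                 idif = noisy[, "idif"],
                 noiseless = clean, sigma = sigma, sigma_fit = sigma_fit,
                 schedule = sch, noise = gt$noise, gt = gt),
            class = "tac_dataset")
}
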