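#' Build a bolus-type analytic input function
#'
#' Linear-rise bolus model: from onset `t0` the curve rises linearly and
#' relaxes through a sum of decaying exponentials,
#' \deqn{C(t) = \Big(A_1 (t - t_0) - \sum_j A_j\Big) e^{-\lambda_1 (t-t_0)}
#'       + \sum_j A_j e^{-\lambda_j (t-t_0)}, \quad t \ge t_0,}
#' which is continuous with `C(t0) = 0` and lives entirely inside the
#' [expsum] algebra.
#'
#' @param t0 bolus arrival time, min.
#' @param A1 ramp slope amplitude (kBq/mL/min).
#' @param l1 fast washout rate, 1/min.
#' @param A amplitudes of the slower exponentials (kBq/mL), length >= 0.
#' @param l rates of the slower exponentials, 1/min, same length as `A`.
#' @return an [expsum].
#' @export
bolus_input <- function(t0, A1, l1, A = numeric(0), l = numeric(0)) {
  stopifnot(length(A) == length(l))
  expsum(coef = c(A1, -sum(A), A),
         rate = c(l1, l1, l),
         power = c(1L, 0L, rep(0L, length(A))),
         onset = t0)
}

.bolus_unpack <- function(par, n_terms) {
  # par = (t0, A1, l1, A_2.., l_2..); n_terms = total number of rates
  list(t0 = par[1], A1 = par[2], l1 = par[3],
       A = if (n_terms > 1) par[3 + seq_len(n_terms - 1)] else numeric(0),
       l = if (n_terms > 1) par[3 + n_terms - 1 + seq_len(n_terms - 1)]
           else numeric(0))
}

#' Fit an analytic model to a noisy image-derived input function
#'
#' The vena-cava IDIF is image derived and especially noisy, so it is
#' smoothed by fitting the framed samples with the [bolus_input()] model
#' (linear rise plus `n_terms` decaying exponentials) by least squares,
#' yielding an analytical expression used everywhere downstream. The fit is
#' restarted from a deterministic grid of washout/clearance rate
#' combinations (including a plain single-exponential candidate) and the
#' best refined solution is kept.
#'
#' @param samples framed IDIF activity values, kBq/mL, one per frame.
#' @param schedule a [frame_schedule] matching `samples`.
#' @param n_terms number of exponential rates (2-4; default 3).
#' @param sigma optional per-frame noise SDs; if supplied the fit is
#'   weighted by `1/sigma`, otherwise unweighted.
#' @return an `idif_fit`: list with `model` ([expsum]), `residual_rms`,
#'   `n_terms`, `par`, `converged`.
#' @export
fit_idif <- function(samples, schedule, n_terms = 3, sigma = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  y <- as.numeric(samples)
  if (length(y) != nrow(schedule))
    stop("samples length does not match the frame schedule")
  if (n_terms < 1 || n_terms > 4) stop("n_terms must be in 1..4")
  if (max(y) <= 0 || stats::sd(y) == 0)
    stop("no bolus peak present in the IDIF samples")
  w <- if (is.null(sigma)) rep(1, length(y)) else 1 / as.numeric(sigma)
  if (any(!is.finite(w)) || any(w <= 0)) stop("sigma must be positive/finite")

  st <- schedule$start_min; du <- schedule$duration_min
  i_pk <- which.max(y)
  t_pk <- schedule$mid_min[i_pk]
  peak <- y[i_pk]
  tail_lvl <- max(mean(y[st > max(st) / 2]), peak * 1e-3)

  resid_fn <- function(par) {
    u <- .bolus_unpack(par, n_terms)
    f <- bolus_input(u$t0, u$A1, u$l1, u$A, u$l)
    (frame_average(f, st, du) - y) * w
  }

  # deterministic multistart over rate combinations
  n_slow <- n_terms - 1
  l1_grid <- c(2, 5, 12) / max(t_pk, 0.05) * 0.25
  slow_base <- c(0.8, 0.05, 0.005)[seq_len(n_slow)]
  starts <- list()
  for (l1 in l1_grid) for (mult in c(0.5, 1, 2)) {
    starts[[length(starts) + 1L]] <- c(
      max(t_pk - 1 / l1, 0.01), peak * l1 * exp(1), l1,
      rep(tail_lvl, n_slow), slow_base * mult)
  }
  # single-exponential-like candidate: tiny ramp, one dominant slow term
  if (n_slow >= 1)
    starts[[length(starts) + 1L]] <- c(0.01, peak * 0.01, 5,
                                       c(peak, rep(tail_lvl, n_slow - 1)),
                                       slow_base)
  lower <- c(0, 0, 0.1, rep(0, n_slow), rep(1e-4, n_slow))
  upper <- c(max(t_pk, 0.02), Inf, 200, rep(Inf, n_slow), rep(10, n_slow))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("IDIF fit failed from every start")

  u <- .bolus_unpack(best$par, n_terms)
  model <- bolus_input(u$t0, u$A1, u$l1, u$A, u$l)
  res <- frame_average(model, st, du) - y
  rms <- sqrt(mean(res^2))

  # sanity: a single decaying exponential must not beat the bolus model
  se_fit <- tryCatch(minpack.lm::nls.lm(
    par = c(peak, 0.5), lower = c(0, 1e-4), upper = c(Inf, 50),
    fn = function(p) (frame_average(expsum(p[1], p[2]), st, du) - y) * w),
    error = function(e) NULL)
  if (!is.null(se_fit) && se_fit$deviance < best$deviance * (1 - 1e-6))
    warning("bolus IDIF model fits worse than a single exponential; ",
            "check the input data")

  structure(list(model = model, residual_rms = rms, n_terms = n_terms,
                 par = best$par, converged = best$info %in% 1:4),
            class = "idif_fit")
}

#' @export
print.idif_fit <- function(x, ...) {
  cat(sprintf("<idif_fit: %d exponential rate(s), residual RMS %.4g>\n",
              x$n_terms, x$residual_rms))
  invisible(x)
}

#' Shared cardiovascular corrections for the input function
#'
#' Three corrections map the vena-cava IDIF to the arterial input seen by
#' each organ: a partial-volume magnitude factor `gamma`, a dispersion time
#' constant `tau` (bolus smearing along the vasculature, shared by all
#' organs), and a per-organ arrival delay.
#'
#' @param gamma partial-volume scale factor, dimensionless, `> 0`.
#' @param tau dispersion time constant, min, `>= 0`.
#' @param delays named numeric vector of per-organ delays, min (names from
#'   `heart, lungs, liver, kidneys, femur`; may be negative).
#' @return an `aif_corrections` list.
#' @export
aif_corrections <- function(gamma = 1, tau = 0,
                            delays = c(heart = 0, lungs = 0, liver = 0,
                                       kidneys = 0, femur = 0)) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (is.null(names(delays)) || !all(names(delays) %in% ORGANS))
    stop("delays must be named with organ ids")
  structure(list(gamma = gamma, tau = tau, delays = delays),
            class = "aif_corrections")
}

#' Corrected per-organ input function
#'
#' Builds the arterial input seen by one organ from the fitted IDIF:
#' \deqn{C_a^{organ}(t) = \frac{1}{\gamma}\,
#'   \Big[\tfrac{1}{\tau} e^{-t/\tau} \otimes C_{IDIF}\Big](t - \Delta t).}
#' By default the IDIF magnitude is divided by `gamma` (the partial-volume
#' reading under which the measured vena-cava curve is a gamma-scaled
#' version of the true input); `gamma_direction = "multiply"` applies the
#' opposite convention.
#'
#' @param idif an `idif_fit` or a bare [expsum] for the IDIF.
#' @param corr an [aif_corrections].
#' @param organ organ id (selects the delay).
#' @param gamma_direction `"divide"` (default, output = IDIF / gamma) or
#'   `"multiply"`.
#' @return an [expsum]: the organ's input function.
#' @export
corrected_input <- function(idif, corr, organ,
                            gamma_direction = c("divide", "multiply")) {
  gamma_direction <- match.arg(gamma_direction)
  f <- if (inherits(idif, "idif_fit")) idif$model else idif
  stopifnot(inherits(f, "expsum"), inherits(corr, "aif_corrections"))
  organ <- match.arg(organ, ORGANS)
  g <- if (gamma_direction == "divide") 1 / corr$gamma else corr$gamma
  dt <- if (organ %in% names(corr$delays)) corr$delays[[organ]] else 0
  es_shift(es_disperse(es_scale(f, g), corr$tau), dt)
}
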