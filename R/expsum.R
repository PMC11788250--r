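#' Exponential-sum curves
#'
#' An `expsum` represents a continuous curve as a finite sum of causal
#' polynomial-exponential terms
#' \deqn{f(t) = \sum_i c_i (t - t_{0i})^{p_i} e^{-r_i (t - t_{0i})}, \quad t \ge t_{0i},}
#' and 0 before each term's onset. The family is closed under scaling, time
#' shift, convolution with a one-sided exponential kernel, and definite
#' integration, which is exactly the algebra needed to carry a
#' sum-of-exponentials arterial input function through dispersion correction
#' and serial compartment models without any numerical ODE solving.
#'
#' @param coef term amplitudes (activity units, e.g. kBq/mL).
#' @param rate decay rates, 1/min, all `>= 0`.
#' @param power integer polynomial powers, all `>= 0` (a power of 1 with a
#'   positive coefficient gives the linear bolus rise).
#' @param onset common or per-term onset time t0, min.
#' @return an object of class `expsum`.
#' @examples
#' f <- expsum(coef = c(2, -2), rate = c(0.1, 1))   # 2 e^{-0.1 t} - 2 e^{-t}
#' es_eval(f, c(0, 1, 5))
#' @export
expsum <- function(coef, rate, power = 0L, onset = 0) {
  n <- max(length(coef), length(rate), length(power), length(onset))
  x <- list(
    coef = rep_len(as.numeric(coef), n),
    rate = rep_len(as.numeric(rate), n),
    power = rep_len(as.integer(power), n),
    onset = rep_len(as.numeric(onset), n)
  )
  if (any(!is.finite(x$coef)) || any(!is.finite(x$rate)))
    stop("expsum terms must be finite")
  if (any(x$rate < 0)) stop("expsum rates must be >= 0 (decaying terms only)")
  if (any(x$power < 0)) stop("expsum powers must be non-negative integers")
  structure(x, class = "expsum")
}

.as_expsum <- function(x) {
  structure(list(coef = as.numeric(x$coef), rate = as.numeric(x$rate),
                 power = as.integer(x$power), onset = as.numeric(x$onset)),
            class = "expsum")
}

#' @export
print.expsum <- function(x, ...) {
  cat(sprintf("<expsum: %d term(s)>\n", length(x$coef)))
  df <- data.frame(coef = signif(x$coef, 6), rate = signif(x$rate, 6),
                   power = x$power, onset = signif(x$onset, 6))
  print(utils::head(df, 12L), row.names = FALSE)
  if (length(x$coef) > 12L) cat("...\n")
  invisible(x)
}

#' Evaluate an exponential-sum curve
#'
#' @param f an [expsum].
#' @param t times, min.
#' @return numeric vector `f(t)`; 0 for `t` before every onset.
#' @export
es_eval <- function(f, t) {
  stopifnot(inherits(f, "expsum"))
  .es_eval_cpp(f$coef, f$rate, f$power, f$onset, as.numeric(t))
}

#' Scale an exponential-sum curve by a constant
#' @param f an [expsum].
#' @param k scalar multiplier.
#' @export
es_scale <- function(f, k) {
  stopifnot(inherits(f, "expsum"), is.finite(k))
  f$coef <- f$coef * k
  f
}

#' Shift an exponential-sum curve in time
#'
#' `es_shift(f, dt)(t) == f(t - dt)`: a positive `dt` delays the curve.
#' @param f an [expsum].
#' @param dt shift, min (may be negative).
#' @export
es_shift <- function(f, dt) {
  stopifnot(inherits(f, "expsum"), is.finite(dt))
  f$onset <- f$onset + dt
  f
}

#' Add two exponential-sum curves
#' @param f,g [expsum] objects.
#' @export
es_add <- function(f, g) {
  stopifnot(inherits(f, "expsum"), inherits(g, "expsum"))
  .as_expsum(list(coef = c(f$coef, g$coef), rate = c(f$rate, g$rate),
                  power = c(f$power, g$power), onset = c(f$onset, g$onset)))
}

#' Convolve with a causal exponential kernel
#'
#' Returns the exact closed form of \eqn{(f \otimes e^{-a t})(t)} for the
#' one-sided (causal) kernel. Terms whose rate lies within `tol` of the
#' kernel rate are expanded as a short series in the rate gap (the leading
#' term is the limiting \eqn{t^{p+1} e^{-a t}} form), keeping the result
#' accurate to near machine precision when compartment rates (nearly)
#' coincide with input rates — the regime where the two-rate closed form
#' cancels catastrophically.
#'
#' @param f an [expsum].
#' @param a kernel rate, 1/min, `>= 0` (`a = 0` gives the running integral).
#' @param tol rate-coincidence switchover, 1/min.
#' @export
es_conv_exp <- function(f, a, tol = 1e-3) {
  stopifnot(inherits(f, "expsum"), is.finite(a), a >= 0)
  .as_expsum(.es_conv_exp_cpp(f$coef, f$rate, f$power, f$onset, a, tol))
}

#' Convolve with a normalised dispersion kernel
#'
#' Applies the unit-area smearing kernel \eqn{(1/\tau) e^{-t/\tau}} used to
#' model bolus dispersion along the vasculature. `tau = 0` is the identity.
#'
#' @param f an [expsum].
#' @param tau dispersion time constant, min, `>= 0`.
#' @export
es_disperse <- function(f, tau) {
  stopifnot(inherits(f, "expsum"), is.finite(tau), tau >= 0)
  if (tau < 1e-8) return(f)
  es_scale(es_conv_exp(f, 1 / tau), 1 / tau)
}

#' Definite integral of an exponential-sum curve
#' @param f an [expsum].
#' @param lower,upper integration limits, min.
#' @export
es_integrate <- function(f, lower, upper) {
  stopifnot(inherits(f, "expsum"))
  m <- .es_frame_avg_cpp(f$coef, f$rate, f$power, f$onset,
                         as.numeric(lower), as.numeric(upper))
  m * (upper - lower)
}

#' Frame averages of a continuous curve
#'
#' Mean concentration over each PET frame, computed by closed-form
#' integration of the exponential-sum terms. Frame averaging (rather than
#' midpoint sampling) is how model curves are compared with framed data:
#' with frames up to 300 s, midpoint evaluation is biased wherever the
#' kinetics are fast.
#'
#' @param curve an [expsum].
#' @param start frame start times, min.
#' @param duration frame durations, min, all `> 0`.
#' @return numeric vector of frame means.
#' @export
frame_average <- function(curve, start, duration) {
  stopifnot(inherits(curve, "expsum"))
  start <- as.numeric(start); duration <- as.numeric(duration)
  if (length(start) != length(duration) || any(duration <= 0))
    stop("invalid frames: need equal-length start/duration with duration > 0")
  .es_frame_avg_cpp(curve$coef, curve$rate, curve$power, curve$onset,
                    start, start + duration)
}
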