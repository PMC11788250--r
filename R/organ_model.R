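#' @keywords internal
ORGANS <- c("heart", "lungs", "liver", "kidneys", "femur")

# tissue water fractions used as fixed volumes of distribution (mL/cm^3)
# for the one-tissue-compartment organs
VD_CONSTRAINT <- c(heart = 0.665, lungs = 0.763, liver = 0.751)

#' Compartment topology of an organ
#'
#' Three configurations are used. Heart, lungs and liver are one-tissue
#' compartment models (no trapping, no clearance) with the volume of
#' distribution Vd = K1/k2 fixed at the tissue water fraction, so k2 is
#' derived from K1 and is not a free parameter. The femur adds a second
#' compartment that irreversibly traps fluoride in bone mineral (k3 > 0,
#' k4 = 0). The kidneys add clearance to the bladder from the second
#' compartment (k3, k4 both free).
#'
#' @param organ one of `"heart"`, `"lungs"`, `"liver"`, `"kidneys"`,
#'   `"femur"`.
#' @return an `organ_model` list: `organ_id`, `n_tissue_compartments`,
#'   `has_trapping`, `has_clearance`, `vd_constraint` (`NA` if none).
#' @export
organ_model <- function(organ) {
  organ <- match.arg(organ, ORGANS)
  two <- organ %in% c("kidneys", "femur")
  structure(list(
    organ_id = organ,
    n_tissue_compartments = if (two) 2L else 1L,
    has_trapping = two,
    has_clearance = organ == "kidneys",
    vd_constraint = if (two) NA_real_ else unname(VD_CONSTRAINT[organ])
  ), class = "organ_model")
}

#' @export
print.organ_model <- function(x, ...) {
  cat(sprintf("<organ_model %s: %dTC%s%s%s>\n", x$organ_id,
              x$n_tissue_compartments,
              if (x$has_trapping) " +k3" else "",
              if (x$has_clearance) " +k4" else "",
              if (!is.na(x$vd_constraint))
                sprintf(", Vd = %.3f" , x$vd_constraint) else ""))
  invisible(x)
}

#' Kinetic parameters of one organ
#'
#' Rate constants, fractional blood volume and input delay for one organ.
#' For organs with a volume-of-distribution constraint, `k2` is derived as
#' `K1 / Vd` and any supplied `k2` is ignored.
#'
#' @param model an [organ_model].
#' @param K1 uptake rate blood -> tissue, mL/mL/min.
#' @param k2 efflux rate tissue -> blood, 1/min (ignored for Vd-constrained
#'   organs).
#' @param k3 trapping rate, 1/min (must be 0 unless the model traps).
#' @param k4 clearance-to-bladder rate, 1/min (must be 0 unless the model
#'   clears).
#' @param vb fractional blood volume of the VOI signal, in \[0, 1\].
#' @param delay input-function arrival delay for this organ, min.
#' @return a `kinetic_params` list.
#' @export
kinetic_params <- function(model, K1, k2 = 0, k3 = 0, k4 = 0, vb = 0,
                           delay = 0) {
  stopifnot(inherits(model, "organ_model"))
  if (!is.na(model$vd_constraint)) k2 <- K1 / model$vd_constraint
  if (!model$has_trapping && k3 != 0)
    stop(sprintf("%s has no trapping compartment; k3 must be 0",
                 model$organ_id))
  if (!model$has_clearance && k4 != 0)
    stop(sprintf("%s has no bladder clearance; k4 must be 0",
                 model$organ_id))
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("rate constants must be finite and >= 0")
  if (!is.finite(vb) || vb < 0 || vb > 1) stop("vb must lie in [0, 1]")
  structure(list(organ_id = model$organ_id, K1 = K1, k2 = k2, k3 = k3,
                 k4 = k4, vb = vb, delay = delay),
            class = "kinetic_params")
}

#' Solve the tissue compartments in closed form
#'
#' Given an analytic input function Ca (an [expsum]), solves
#' \deqn{dC_1/dt = K_1 C_a - (k_2 + k_3) C_1, \qquad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' exactly within the exponential-sum algebra (no numerical ODE
#' integration). The modelled VOI signal is
#' \deqn{C_T(t) = (1 - v_b)(C_1 + C_2) + v_b C_a(t),}
#' with the organ's own corrected input as the vascular contamination term.
#'
#' @param model an [organ_model].
#' @param params a [kinetic_params] for that organ.
#' @param input the organ's corrected input function, an [expsum]
#'   (already delayed — `params$delay` is applied upstream when the input
#'   is built with [corrected_input()]).
#' @param times optional time grid, min: if supplied, the returned list
#'   gains matrices of evaluated curves.
#' @return list with [expsum] components `C1`, `C2` (`NULL` for 1TC
#'   organs) and `CT`, plus `eval` (data frame on `times`) when `times` is
#'   given.
#' @export
solve_tissue <- function(model, params, input, times = NULL) {
  stopifnot(inherits(model, "organ_model"), inherits(params, "kinetic_params"),
            inherits(input, "expsum"))
  if (!identical(model$organ_id, params$organ_id))
    stop("params were built for a different organ")
  C1 <- es_scale(es_conv_exp(input, params$k2 + params$k3), params$K1)
  C2 <- NULL
  tissue <- C1
  if (model$n_tissue_compartments == 2L) {
    C2 <- es_scale(es_conv_exp(C1, params$k4), params$k3)
    tissue <- es_add(C1, C2)
  }
  CT <- es_add(es_scale(tissue, 1 - params$vb), es_scale(input, params$vb))
  out <- list(C1 = C1, C2 = C2, CT = CT)
  if (!is.null(times)) {
    out$eval <- data.frame(
      time_min = times,
      C1 = es_eval(C1, times),
      C2 = if (is.null(C2)) 0 else es_eval(C2, times),
      CT = es_eval(CT, times)
    )
  }
  out
}

#' Net influx rate Ki
#'
#' The macro-parameter \eqn{K_i = K_1 k_3 / (k_2 + k_3)} of an
#' irreversible two-tissue model: the steady-state rate at which tracer is
#' committed to the trapped compartment. Unlike K1 and k2 individually, Ki
#' is robust to the K1-k2 ridge degeneracy.
#'
#' @param params a [kinetic_params] (or anything with `K1`, `k2`, `k3`).
#' @return Ki in mL/mL/min.
#' @export
influx_rate <- function(params) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3
  if (!is.finite(K1) || !is.finite(k2) || !is.finite(k3))
    stop("K1, k2, k3 must be finite")
  if (k2 + k3 <= 0)
    stop("influx rate undefined: k2 + k3 must be > 0")
  K1 * k3 / (k2 + k3)
}
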