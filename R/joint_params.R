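#' Names of the free parameters of the joint model
#'
#' The joint five-organ model has 22 free scalars: the shared corrections
#' `gamma` and `tau`; one delay and one fractional blood volume per organ;
#' `K1` for the three Vd-constrained organs (their `k2` is derived as
#' `K1/Vd` and is never free); `K1, k2, k3, k4` for the kidneys; and
#' `K1, k2, k3` for the femur.
#'
#' @return character vector of length 22, in canonical order.
#' @export
joint_param_names <- function() {
  c("gamma", "tau",
    paste0("delay_", ORGANS),
    paste0("vb_", ORGANS),
    "K1_heart", "K1_lungs", "K1_liver",
    "K1_kidneys", "k2_kidneys", "k3_kidneys", "k4_kidneys",
    "K1_femur", "k2_femur", "k3_femur")
}

#' Default box bounds for the joint fit
#'
#' Bounds reflect the fitted ranges seen in practice plus physiology:
#' rates in \[0, 10\] (1/min or mL/mL/min), blood volumes in \[0, 1\],
#' `gamma` in \[0.1, 3\], `tau` in \[0.001, 2\] min and delays in
#' \[-0.5, 1\] min (small negative delays occur).
#'
#' @return list with named numeric vectors `lower` and `upper`.
#' @export
joint_bounds <- function() {
  nm <- joint_param_names()
  lower <- stats::setNames(rep(0, length(nm)), nm)
  upper <- stats::setNames(rep(10, length(nm)), nm)
  lower["gamma"] <- 0.1; upper["gamma"] <- 3
  lower["tau"] <- 1e-3;  upper["tau"] <- 2
  lower[grepl("^delay_", nm)] <- -0.5
  upper[grepl("^delay_", nm)] <- 1
  upper[grepl("^vb_", nm)] <- 1
  list(lower = lower, upper = upper)
}

#' Assemble the flat joint-parameter vector
#'
#' @param corr an [aif_corrections] carrying `gamma`, `tau` and the five
#'   organ delays.
#' @param organs named list of [kinetic_params], one per organ.
#' @return named numeric vector of length 22 in [joint_param_names()]
#'   order.
#' @seealso [joint_unpack()] for the inverse.
#' @export
joint_pack <- function(corr, organs) {
  stopifnot(inherits(corr, "aif_corrections"),
            setequal(names(organs), ORGANS))
  v <- c(gamma = corr$gamma, tau = corr$tau)
  for (o in ORGANS) v[paste0("delay_", o)] <- corr$delays[[o]]
  for (o in ORGANS) v[paste0("vb_", o)] <- organs[[o]]$vb
  for (o in c("heart", "lungs", "liver")) v[paste0("K1_", o)] <- organs[[o]]$K1
  for (f in c("K1", "k2", "k3", "k4")) v[paste0(f, "_kidneys")] <- organs$kidneys[[f]]
  for (f in c("K1", "k2", "k3")) v[paste0(f, "_femur")] <- organs$femur[[f]]
  v[joint_param_names()]
}

#' Unpack a flat joint-parameter vector
#'
#' Inverse of [joint_pack()]: rebuilds the correction object and the five
#' [kinetic_params], deriving `k2 = K1/Vd` for the constrained organs.
#'
#' @param par named numeric vector over (a subset of)
#'   [joint_param_names()]; missing names are an error.
#' @return list with `corr` ([aif_corrections]) and `organs` (named list
#'   of [kinetic_params]).
#' @export
joint_unpack <- function(par) {
  nm <- joint_param_names()
  if (!all(nm %in% names(par)))
    stop("missing joint parameters: ", paste(setdiff(nm, names(par)),
                                             collapse = ", "))
  delays <- stats::setNames(as.numeric(par[paste0("delay_", ORGANS)]), ORGANS)
  corr <- aif_corrections(gamma = par[["gamma"]], tau = par[["tau"]],
                          delays = delays)
  organs <- list()
  for (o in ORGANS) {
    m <- organ_model(o)
    organs[[o]] <- kinetic_params(
      m,
      K1 = par[[paste0("K1_", o)]],
      k2 = if (o %in% c("kidneys", "femur")) par[[paste0("k2_", o)]] else 0,
      k3 = if (o %in% c("kidneys", "femur")) par[[paste0("k3_", o)]] else 0,
      k4 = if (o == "kidneys") par[["k4_kidneys"]] else 0,
      vb = par[[paste0("vb_", o)]],
      delay = delays[[o]])
  }
  list(corr = corr, organs = organs)
}
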