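#' Define a joint fitting problem
#'
#' Packages observed framed TACs, the analytic IDIF, the frame selection
#' (short or long scale), the noise weights and the free/fixed parameter
#' split into one object consumed by [joint_objective()], [fit_once()] and
#' [multistart()].
#'
#' Noise weights: residuals are scaled by per-frame SDs from the
#' counting-statistics model. Either pass `sigma` directly (e.g. the true
#' SDs of a simulation, for calibration work) or pass a [noise_spec] and
#' the SDs are computed from the observed activities, floored at 1% of
#' each organ's maximum so that near-zero early frames cannot get infinite
#' weight.
#'
#' @param data a `tac_dataset` from [simulate_dataset()], or a frames x
#'   organs matrix of observed activities.
#' @param idif an `idif_fit` or [expsum] for the (uncorrected) IDIF.
#' @param schedule a [frame_schedule]; defaults to the dataset's.
#' @param scale `"long"` or `"short"`.
#' @param organs organs to include (default all five).
#' @param noise a [noise_spec] used to compute weights from the data.
#' @param sigma optional frames x organs matrix of noise SDs (full
#'   schedule; rows are subset to the scale internally).
#' @param free names of free parameters; default: all parameters relevant
#'   to `organs` (the full 22-vector when all organs are used).
#' @param fixed named values for non-free parameters that matter to the
#'   model (required when they differ from box midpoints).
#' @param gamma_direction passed to [corrected_input()].
#' @return a `fit_problem` list.
#' @export
fit_problem <- function(data, idif, schedule = NULL,
                        scale = c("long", "short"), organs = ORGANS,
                        noise = NULL, sigma = NULL, free = NULL,
                        fixed = NULL,
                        gamma_direction = c("divide", "multiply")) {
  scale <- match.arg(scale)
  gamma_direction <- match.arg(gamma_direction)
  organs <- match.arg(organs, ORGANS, several.ok = TRUE)
  if (inherits(data, "tac_dataset")) {
    if (is.null(schedule)) schedule <- data$schedule
    if (is.null(noise) && is.null(sigma)) noise <- data$noise
    obs_full <- data$tacs
  } else {
    obs_full <- as.matrix(data)
    if (is.null(schedule)) stop("schedule is required with matrix data")
  }
  stopifnot(inherits(schedule, "frame_schedule"),
            nrow(obs_full) == nrow(schedule))
  if (!all(organs %in% colnames(obs_full)))
    stop("data lacks columns for: ",
         paste(setdiff(organs, colnames(obs_full)), collapse = ", "))
  sel <- schedule_frames(schedule, scale)
  idx <- as.integer(rownames(sel))
  if (is.null(idx) || any(is.na(idx))) idx <- seq_len(nrow(sel))
  obs <- obs_full[idx, organs, drop = FALSE]

  if (is.null(sigma)) {
    if (is.null(noise)) stop("either sigma or a noise_spec must be given")
    sigma_sel <- obs
    for (o in organs) {
      floor_ct <- 0.01 * max(obs_full[, o])
      sigma_sel[, o] <- noise_sigma(noise, o, pmax(obs[, o], floor_ct),
                                    sel$mid_min, sel$duration_min)
    }
  } else {
    sigma_sel <- as.matrix(sigma)[idx, organs, drop = FALSE]
  }
  if (any(!is.finite(sigma_sel)) || any(sigma_sel <= 0))
    stop("noise model yields non-positive sigma; cannot weight residuals")

  nm <- joint_param_names()
  relevant <- c("gamma", "tau",
                paste0("delay_", organs), paste0("vb_", organs),
                paste0("K1_", organs),
                if ("kidneys" %in% organs) c("k2_kidneys", "k3_kidneys", "k4_kidneys"),
                if ("femur" %in% organs) c("k2_femur", "k3_femur"))
  relevant <- intersect(nm, relevant)
  if (is.null(free)) free <- relevant
  if (!all(free %in% nm)) stop("unknown parameter names in 'free'")
  bounds <- joint_bounds()
  template <- (bounds$lower + bounds$upper) / 2
  template["tau"] <- 0.2
  if (!is.null(fixed)) template[names(fixed)] <- fixed

  structure(list(obs = obs, sigma = sigma_sel, organs = organs,
                 organ_codes = match(organs, ORGANS) - 1L,
                 free_idx = match(free, nm),
                 frames = sel, idx = idx, scale = scale,
                 idif = if (inherits(idif, "idif_fit")) idif$model else idif,
                 free = free, template = template,
                 lower = bounds$lower[free], upper = bounds$upper[free],
                 ratelike = grepl("^K1_|^k[234]_|^tau$", free),
                 n_obs = length(obs), n_free = length(free),
                 gamma_direction = gamma_direction),
            class = "fit_problem")
}

# Bounded parameters are fitted through a smooth monotone map from an
# unbounded internal coordinate z: u = logistic(z) in (0,1), then either a
# linear stretch over [lo, hi] or, for rate-like parameters (K1, k2, k3,
# k4, tau), a log-scale stretch over [max(lo, 1e-3), hi]. This avoids the
# hard clipping at box bounds that strands Levenberg-Marquardt steps, and
# makes steps in rate constants multiplicative, which matches their
# dynamic range.
.RATE_FLOOR <- 1e-3

.u_to_par <- function(problem, u) {
  lo <- problem$lower; hi <- problem$upper
  lo2 <- pmax(lo, .RATE_FLOOR)
  ifelse(problem$ratelike, lo2 * (hi / lo2)^u, lo + (hi - lo) * u)
}

.par_to_u <- function(problem, par) {
  lo <- problem$lower; hi <- problem$upper
  lo2 <- pmax(lo, .RATE_FLOOR)
  rl <- problem$ratelike
  u <- numeric(length(par))
  pr <- pmin(pmax(par[rl], lo2[rl]), hi[rl])
  u[rl] <- log(pr / lo2[rl]) / log(hi[rl] / lo2[rl])
  pl <- pmin(pmax(par[!rl], lo[!rl]), hi[!rl])
  u[!rl] <- (pl - lo[!rl]) / (hi[!rl] - lo[!rl])
  pmin(pmax(u, 1e-7), 1 - 1e-7)
}

.full_par <- function(problem, par_free) {
  full <- problem$template
  full[problem$free_idx] <- par_free
  full
}

# fast path: one compiled call per evaluation (the gamma-scaled dispersed
# IDIF is shared across organs inside it). Mathematically identical to the
# reference path below, which the test suite checks it against.
.model_frames <- function(problem, full) {
  st <- problem$frames$start_min
  en <- st + problem$frames$duration_min
  idif <- problem$idif
  out <- .joint_model_frames_cpp(unname(full[joint_param_names()]),
                                 idif$coef, idif$rate, idif$power,
                                 idif$onset, problem$organ_codes,
                                 st, en,
                                 problem$gamma_direction == "divide",
                                 unname(VD_CONSTRAINT))
  colnames(out) <- problem$organs
  out
}

# reference path through the public building blocks
.model_frames_reference <- function(problem, full) {
  up <- joint_unpack(full)
  st <- problem$frames$start_min; du <- problem$frames$duration_min
  out <- matrix(0, nrow(problem$frames), length(problem$organs),
                dimnames = list(NULL, problem$organs))
  for (o in problem$organs) {
    ca <- corrected_input(problem$idif, up$corr, o, problem$gamma_direction)
    ct <- solve_tissue(organ_model(o), up$organs[[o]], ca)$CT
    out[, o] <- frame_average(ct, st, du)
  }
  out
}

#' Weighted residual vector of the joint model
#'
#' Residuals `(O_i - C_i)/sigma_i` stacked over the problem's organs and
#' selected frames; the quantity the Levenberg-Marquardt minimiser drives
#' to zero.
#'
#' @param par values of the free parameters (named or in `problem$free`
#'   order).
#' @param problem a [fit_problem].
#' @return numeric vector of length `n_frames * n_organs`.
#' @export
joint_objective <- function(par, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  pv <- as.numeric(par)
  if (!is.null(names(par))) pv <- as.numeric(par[problem$free])
  mod <- .model_frames(problem, .full_par(problem, pv))
  as.numeric((problem$obs - mod) / problem$sigma)
}

#' Reduced chi-square of a parameter vector
#'
#' \eqn{\chi^2_\nu = \nu^{-1} \sum_i (O_i - C_i)^2 / \sigma_i^2} with
#' \eqn{\nu} = number of observations minus number of free parameters.
#' Per-organ contributions are the unreduced weighted sums of squares and
#' add up to \eqn{\chi^2_\nu \cdot \nu}.
#'
#' @param par free-parameter values.
#' @param problem a [fit_problem].
#' @return list with `chi2_nu`, `per_organ` (named raw SS), `nu`,
#'   `n_obs`, `n_free`.
#' @export
score_fit <- function(par, problem) {
  nu <- problem$n_obs - problem$n_free
  if (nu <= 0)
    stop("non-positive degrees of freedom: more free parameters than ",
         "observations on this scale")
  r <- matrix(joint_objective(par, problem), ncol = length(problem$organs))
  per <- stats::setNames(colSums(r^2), problem$organs)
  list(chi2_nu = sum(per) / nu, per_organ = per, nu = nu,
       n_obs = problem$n_obs, n_free = problem$n_free)
}

#' One bounded Levenberg-Marquardt fit
#'
#' Minimizes the weighted residuals of [joint_objective()] by
#' Levenberg-Marquardt. The box bounds are enforced through a smooth
#' logistic reparameterization (log-scaled for rate constants), so the
#' optimizer never has to clip steps at a bound; a parameter escaping
#' towards a bound simply saturates.
#'
#' @param start named (or `problem$free`-ordered) start values, inside the
#'   bounds.
#' @param problem a [fit_problem].
#' @param maxiter iteration cap.
#' @return a `fit_result`: `par` (free, named), `full_par` (all 22),
#'   `chi2_nu`, `per_organ_chi2`, `converged`, `n_obs`, `n_free`, `nu`,
#'   `info`, `niter`. Non-convergence is recorded, never dropped.
#' @export
fit_once <- function(start, problem, maxiter = 150, ftol = 1e-10,
                     ptol = 1e-10) {
  stopifnot(inherits(problem, "fit_problem"))
  sv <- if (!is.null(names(start))) as.numeric(start[problem$free])
        else as.numeric(start)
  z0 <- stats::qlogis(.par_to_u(problem, sv))
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = z0,
                         fn = function(z)
                           joint_objective(
                             .u_to_par(problem, stats::plogis(z)), problem),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = ptol, ftol = ftol))),
    error = function(e) NULL)
  if (is.null(fit)) {
    par <- stats::setNames(.u_to_par(problem, .par_to_u(problem, sv)),
                           problem$free)
    sc <- score_fit(par, problem)
    return(structure(list(par = par,
                          full_par = .full_par(problem, unname(par)),
                          chi2_nu = sc$chi2_nu, per_organ_chi2 = sc$per_organ,
                          converged = FALSE, n_obs = sc$n_obs,
                          n_free = sc$n_free, nu = sc$nu,
                          info = NA_integer_, niter = 0L),
                     class = "fit_result"))
  }
  par <- stats::setNames(.u_to_par(problem, stats::plogis(fit$par)),
                         problem$free)
  sc <- score_fit(par, problem)
  structure(list(par = par, full_par = .full_par(problem, unname(par)),
                 chi2_nu = sc$chi2_nu, per_organ_chi2 = sc$per_organ,
                 converged = fit$info %in% 1:4, n_obs = sc$n_obs,
                 n_free = sc$n_free, nu = sc$nu,
                 info = fit$info, niter = fit$niter),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: chi2_nu = %.4g (nu = %d), %s>\n", x$chi2_nu,
              x$nu, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Centered Latin hypercube sample
#'
#' Stratified start points over the unit hypercube: each dimension is an
#' independent random permutation of cell centres `(i - 0.5)/n`, giving
#' one point per row stratum in every dimension.
#'
#' @param n number of points.
#' @param d number of dimensions.
#' @return `n x d` matrix in (0, 1).
#' @export
lhs_centered <- function(n, d) {
  stopifnot(n >= 1, d >= 1)
  m <- matrix(0, n, d)
  for (j in seq_len(d)) m[, j] <- (sample.int(n) - 0.5) / n
  m
}

#' Multistart joint fitting
#'
#' Repeats the bounded Levenberg-Marquardt fit from `n_starts` centred
#' Latin-hypercube start points spread over the parameter box. All fits
#' are retained (including non-converged ones); `best` is the
#' minimum-chi2 result and `mode` is the converged ensemble member with
#' the highest kernel density estimate in standardized parameter space
#' (Gaussian product kernel, Scott bandwidth) — the highest-probability
#' parameter set rather than the single deepest minimum.
#'
#' @param problem a [fit_problem].
#' @param n_starts number of restarts (default 5000; smaller
#'   ensembles are appropriate for testing).
#' @param seed integer seed making the ensemble reproducible.
#' @param maxiter per-fit iteration cap during exploration.
#' @param polish_n the best `polish_n` exploration fits are re-run to
#'   tight tolerance (`polish_maxiter` iterations); exploration itself
#'   uses a looser stopping rule, which changes nothing about which basin
#'   a start descends into but stops grinding inside it.
#' @param polish_maxiter iteration cap for the polish stage.
#' @return a `multistart_ensemble`: `results` (list of `fit_result`),
#'   `best`, `mode`, `chi2_nu` (vector), `converged` (logical vector),
#'   `par_matrix` (n_starts x n_free).
#' @export
multistart <- function(problem, n_starts = 5000, seed = 1L, maxiter = 60,
                       polish_n = 10L, polish_maxiter = 400L) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- problem$n_free
  u <- lhs_centered(n_starts, d)
  # strata live in the same transformed coordinates the optimizer uses:
  # log-scale for rate-like parameters, linear for the rest
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts))
    results[[i]] <- fit_once(.u_to_par(problem, u[i, ]), problem,
                             maxiter = maxiter, ftol = 1e-8, ptol = 1e-8)
  chi2 <- vapply(results, `[[`, numeric(1), "chi2_nu")
  topk <- order(ifelse(is.finite(chi2), chi2, Inf))[
    seq_len(min(polish_n, n_starts))]
  for (i in topk)
    results[[i]] <- fit_once(results[[i]]$par, problem,
                             maxiter = polish_maxiter)
  .assemble_ensemble(results, problem, n_starts, seed)
}

.assemble_ensemble <- function(results, problem, n_starts, seed) {
  d <- problem$n_free
  chi2 <- vapply(results, `[[`, numeric(1), "chi2_nu")
  conv <- vapply(results, `[[`, logical(1), "converged")
  if (!any(conv & is.finite(chi2)))
    stop("no converged fit in the multistart ensemble")
  pm <- t(vapply(results, `[[`, numeric(d), "par"))
  colnames(pm) <- problem$free
  best <- results[[which.min(ifelse(is.finite(chi2), chi2, Inf))]]
  # the density mode is taken within the statistically equivalent set
  # (chi2_nu within +1 of the best); over the full ensemble it would be
  # dominated by whichever distant local minimum collects the most starts
  ic <- which(conv & is.finite(chi2) & chi2 <= best$chi2_nu + 1)
  if (length(ic) == 0L)
    ic <- which(is.finite(chi2) & chi2 <= best$chi2_nu + 1)
  if (length(ic) == 0L) ic <- which(is.finite(chi2))
  mode_idx <- ic[kde_mode_index(pm[ic, , drop = FALSE])]
  structure(list(results = results, best = best,
                 mode = results[[mode_idx]], mode_index = mode_idx,
                 chi2_nu = chi2, converged = conv, par_matrix = pm,
                 problem = problem, n_starts = n_starts, seed = seed),
            class = "multistart_ensemble")
}

#' Densify the near-optimal region of an ensemble
#'
#' A few hundred global restarts typically leave only a handful of fits
#' inside the near-optimal window, too few for stable correlation
#' estimates. `refine_ensemble` adds fits started from a Latin hypercube
#' in a neighbourhood of the current best fit (in the optimizer's
#' transformed coordinates) and merges them into the ensemble; membership
#' of the near-optimal set is still decided purely by the chi-square
#' criterion. At the study's full restart count this densification happens
#' by itself.
#'
#' @param ensemble a `multistart_ensemble`.
#' @param n_extra extra fits to add.
#' @param seed integer seed.
#' @param radius half-width of the sampling box around the best fit, in
#'   transformed (0, 1) coordinates.
#' @param maxiter iteration cap for the extra fits.
#' @return the enlarged `multistart_ensemble`.
#' @export
refine_ensemble <- function(ensemble, n_extra = 150, seed = 1L,
                            radius = 0.08, maxiter = 150) {
  stopifnot(inherits(ensemble, "multistart_ensemble"))
  problem <- ensemble$problem
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u0 <- .par_to_u(problem, ensemble$best$par)
  u <- lhs_centered(n_extra, problem$n_free)
  u <- sweep(u * 2 * radius, 2, u0 - radius, "+")
  u <- pmin(pmax(u, 1e-7), 1 - 1e-7)
  extra <- vector("list", n_extra)
  for (i in seq_len(n_extra))
    extra[[i]] <- fit_once(.u_to_par(problem, u[i, ]), problem,
                           maxiter = maxiter)
  .assemble_ensemble(c(ensemble$results, extra), problem,
                     ensemble$n_starts + n_extra, ensemble$seed)
}

#' @export
print.multistart_ensemble <- function(x, ...) {
  cat(sprintf("<multistart_ensemble: %d starts, %d converged, best chi2_nu = %.4g>\n",
              x$n_starts, sum(x$converged), x$best$chi2_nu))
  invisible(x)
}

#' Index of the kernel-density mode of a parameter ensemble
#'
#' Standardizes the columns, applies a Gaussian product kernel with Scott
#' bandwidth `n^(-1/(d+4))`, and returns the row with the highest density
#' estimate. Returning an ensemble member (not an off-grid argmax) keeps
#' the selection reproducible.
#'
#' @param x numeric matrix (rows = ensemble members).
#' @return integer row index.
#' @export
kde_mode_index <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1L) return(1L)
  keep <- apply(x, 2, stats::sd) > 0
  if (!any(keep)) return(1L)
  z <- scale(x[, keep, drop = FALSE])
  d <- ncol(z)
  h <- n^(-1 / (d + 4))
  dens <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    ii <- s:min(s + chunk - 1L, n)
    cross <- tcrossprod(z[ii, , drop = FALSE], z) # (len ii) x n
    d2 <- outer(rowSums(z[ii, , drop = FALSE]^2), rowSums(z^2), "+") - 2 * cross
    dens[ii] <- rowSums(exp(-0.5 * pmax(d2, 0) / h^2))
  }
  which.max(dens)
}

#' Parameter excursion at a chi-square increase of +1
#'
#' Scans a 1-D function of one parameter away from its optimum until the
#' reduced chi-square has risen by `delta`, by root finding. Used for the
#' error bars: the amount a parameter can move before the fit quality
#' degrades by one unit of reduced chi-square.
#'
#' @param chi2_fun function of a scalar returning the reduced chi-square.
#' @param estimate the optimum.
#' @param lower,upper box bounds for the parameter.
#' @param delta chi-square increase defining the interval (default 1).
#' @return list `lower`, `upper` (crossing points), `censored_lower`,
#'   `censored_upper` (TRUE when the bound was hit first).
#' @export
chi2_excursion <- function(chi2_fun, estimate, lower, upper, delta = 1) {
  target <- chi2_fun(estimate) + delta
  g <- function(x) chi2_fun(x) - target
  scan <- function(bound) {
    if (abs(bound - estimate) < 1e-12) return(list(x = estimate, cens = TRUE))
    gb <- g(bound)
    if (!is.finite(gb) || gb < 0) return(list(x = bound, cens = TRUE))
    r <- stats::uniroot(g, lower = min(estimate, bound),
                        upper = max(estimate, bound), tol = 1e-8)
    list(x = r$root, cens = FALSE)
  }
  lo <- scan(lower); hi <- scan(upper)
  list(lower = lo$x, upper = hi$x,
       censored_lower = lo$cens, censored_upper = hi$cens)
}

#' Delta-chi-square error bars for a fitted result
#'
#' For each requested parameter, the other parameters are held at the
#' optimum (or re-optimized when `profile = TRUE`) while the parameter is
#' scanned until the reduced chi-square increases by 1; the excursion is
#' the reported uncertainty. Parameters that hit a box bound before the
#' crossing are flagged bound-censored.
#'
#' @param fit a `fit_result` (e.g. `ensemble$best`).
#' @param problem the [fit_problem] it was fitted on.
#' @param params parameter names to scan (default: all free).
#' @param profile re-optimize the remaining parameters at each scan point
#'   (slower; default FALSE holds them fixed).
#' @return data frame: `param`, `estimate`, `lower`, `upper`, `err`
#'   (mean uncensored excursion), `censored_lower`, `censored_upper`.
#' @export
error_bars <- function(fit, problem, params = NULL, profile = FALSE) {
  stopifnot(inherits(fit, "fit_result"), inherits(problem, "fit_problem"))
  if (is.null(params)) params <- problem$free
  stopifnot(all(params %in% problem$free))
  base <- fit$par
  rows <- lapply(params, function(nm) {
    chi2_fun <- function(x) {
      p <- base; p[nm] <- x
      if (profile && length(problem$free) > 1L) {
        sub <- problem
        sub$free <- setdiff(problem$free, nm)
        sub$lower <- problem$lower[sub$free]
        sub$upper <- problem$upper[sub$free]
        sub$template[nm] <- x
        sub$n_free <- length(sub$free)
        f <- fit_once(base[sub$free], sub, maxiter = 40)
        # keep nu of the parent problem so the threshold is comparable
        f$chi2_nu * f$nu / (problem$n_obs - problem$n_free)
      } else {
        score_fit(p, problem)$chi2_nu
      }
    }
    ex <- chi2_excursion(chi2_fun, base[[nm]],
                         problem$lower[[nm]], problem$upper[[nm]])
    exc <- c(if (!ex$censored_lower) base[[nm]] - ex$lower,
             if (!ex$censored_upper) ex$upper - base[[nm]])
    data.frame(param = nm, estimate = base[[nm]], lower = ex$lower,
               upper = ex$upper,
               err = if (length(exc)) mean(exc) else NA_real_,
               censored_lower = ex$censored_lower,
               censored_upper = ex$censored_upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
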