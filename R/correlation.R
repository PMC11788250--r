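#' Near-optimal subset of a multistart ensemble
#'
#' All ensemble results whose reduced chi-square lies within `delta`
#' (default 1) of the best fit. The spread of parameter values inside
#' this set is what the error bars and the correlation analysis are
#' computed from: the set depends only on the chi-square values, not on
#' whether the best fit or the KDE mode is taken as the point estimate.
#'
#' @param ensemble a `multistart_ensemble`.
#' @param delta chi-square window (default 1).
#' @return list with `par_matrix` (members x free params), `chi2_nu`,
#'   `indices`, `n_points`.
#' @export
near_optimal_set <- function(ensemble, delta = 1) {
  stopifnot(inherits(ensemble, "multistart_ensemble"))
  chi2 <- ensemble$chi2_nu
  keep <- which(is.finite(chi2) & chi2 <= ensemble$best$chi2_nu + delta)
  out <- list(par_matrix = ensemble$par_matrix[keep, , drop = FALSE],
              chi2_nu = chi2[keep], indices = keep, n_points = length(keep))
  if (length(keep) < 3L)
    attr(out, "too_small") <- TRUE
  out
}

#' Pearson correlation matrix over a near-optimal set
#'
#' Pairwise Pearson r between parameter values across the near-optimal
#' ensemble members, for one organ's block (its rates, blood volume and
#' delay) together with the shared `gamma` and `tau` columns. A
#' zero-variance parameter has undefined correlations, which are reported
#' as `NA`, never as 0.
#'
#' @param subset result of [near_optimal_set()] (or a plain members x
#'   params matrix with column names).
#' @param organ organ id selecting the parameter block, or `NULL` to use
#'   every column present.
#' @return a `correlation_report`: list with `r` (symmetric matrix, unit
#'   diagonal), `n_points`, `organ`.
#' @export
correlation_matrix <- function(subset, organ = NULL) {
  pm <- if (is.list(subset) && !is.null(subset$par_matrix)) subset$par_matrix
        else as.matrix(subset)
  if (nrow(pm) < 3L)
    stop("near-optimal set has fewer than 3 points; correlation undefined")
  cols <- colnames(pm)
  if (!is.null(organ)) {
    organ <- match.arg(organ, ORGANS)
    want <- c(grep(paste0("_", organ, "$"), cols, value = TRUE),
              intersect(c("gamma", "tau"), cols))
    pm <- pm[, want, drop = FALSE]
  }
  nz <- apply(pm, 2, stats::sd)
  r <- suppressWarnings(stats::cor(pm, method = "pearson"))
  r[nz == 0, ] <- NA_real_
  r[, nz == 0] <- NA_real_
  diag(r) <- ifelse(nz > 0, 1, NA_real_)
  structure(list(r = r, n_points = nrow(pm), organ = organ),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report%s: %d near-optimal points>\n",
              if (is.null(x$organ)) "" else paste0(" [", x$organ, "]"),
              x$n_points))
  print(round(x$r, 2))
  invisible(x)
}

#' Cross-subject significance of a parameter correlation
#'
#' Tests whether a parameter pair's Pearson r values, one per subject,
#' differ from zero across the cohort, with the two-sided Wilcoxon
#' signed-rank test; zero r values are dropped per the standard
#' treatment. For n <= 12 the exact null distribution is obtained by
#' enumerating all 2^n sign assignments (average ranks, so ties in |r|
#' are handled exactly rather than by a normal approximation); larger
#' cohorts fall back to [stats::wilcox.test()]. Significance is declared
#' at p < 0.05.
#'
#' @param r_values numeric vector of per-subject correlation values; any
#'   `NA` (undefined r for a subject) is an error — exclude the pair
#'   upstream.
#' @param alpha significance level (default 0.05).
#' @return list with `p_value`, `significant`, `n`.
#' @export
significance_across_subjects <- function(r_values, alpha = 0.05) {
  if (anyNA(r_values))
    stop("undefined correlation for at least one subject; exclude the pair")
  r <- r_values[r_values != 0]
  n <- length(r)
  if (n < 1L)
    return(list(p_value = 1, significant = FALSE, n = 0L))
  if (n <= 12L) {
    rk <- rank(abs(r))
    centre <- n * (n + 1) / 4
    W <- sum(rk[r > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.numeric(signs %*% rk)
    p <- mean(abs(W_all - centre) >= abs(W - centre) - 1e-12)
  } else {
    p <- stats::wilcox.test(r, mu = 0, exact = FALSE,
                            alternative = "two.sided")$p.value
  }
  list(p_value = p, significant = p < alpha, n = n)
}

#' Two-dimensional kernel density of a parameter pair
#'
#' Gaussian-kernel 2-D density of a near-optimal set projected on two
#' parameters — the joint distribution view in which ridge-shaped
#' (practically non-identifiable) pairs show up as elongated crests.
#'
#' @param subset result of [near_optimal_set()].
#' @param px,py parameter names.
#' @param n grid resolution per axis.
#' @param expand fractional margin added around the observed range.
#' @return list with `x`, `y`, `z` (density grid) as from
#'   [MASS::kde2d()], plus the points.
#' @export
kde2d_pair <- function(subset, px, py, n = 101, expand = 0.35) {
  pm <- subset$par_matrix
  stopifnot(all(c(px, py) %in% colnames(pm)))
  x <- pm[, px]; y <- pm[, py]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance parameter; 2-D density undefined")
  pad <- function(v) {
    r <- range(v); m <- expand * diff(r) + 4 * stats::bw.nrd0(v)
    c(r[1] - m, r[2] + m)
  }
  kd <- MASS::kde2d(x, y, n = n, lims = c(pad(x), pad(y)))
  kd$points <- data.frame(x = x, y = y)
  kd$px <- px; kd$py <- py
  kd
}
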