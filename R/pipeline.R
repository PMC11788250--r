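#' Simulate a cohort and write it to disk
#'
#' Draws `n_subjects` ground-truth subjects, simulates their noisy framed
#' TACs and writes one CSV per subject plus the configuration, the true
#' parameters and a manifest.
#'
#' @param config a [study_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of `tac_dataset`s.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sch <- frame_schedule(config$frame_durations_s)
  noise <- noise_spec(config$sc)
  datasets <- list()
  truth <- NULL
  for (s in seq_len(config$n_subjects)) {
    gt <- default_ground_truth(subject_seed = config$seed + s,
                               schedule = sch, noise = noise)
    ds <- simulate_dataset(gt)
    id <- sprintf("subject%02d", s)
    write_tac_csv(ds, file.path(out_dir, paste0(id, ".csv")))
    truth <- rbind(truth, data.frame(subject = id, param = names(gt$par),
                                     value = unname(gt$par)))
    datasets[[id]] <- ds
  }
  utils::write.csv(truth, file.path(out_dir, "ground_truth_synthetic.csv"),
                   row.names = FALSE)
  write_study_config(config, file.path(out_dir, "config.yaml"))
  invisible(datasets)
}

.fit_subject_scale <- function(ds, idif, config, scale) {
  sigma <- if (config$use_true_sigma && inherits(ds, "tac_dataset"))
    ds$sigma_fit else NULL
  prob <- fit_problem(ds, idif, scale = scale, sigma = sigma,
                      gamma_direction = config$gamma_direction)
  ens <- multistart(prob, n_starts = config$restarts,
                    seed = config$seed + 7919L)
  eb <- error_bars(ens$best, prob)
  nos <- near_optimal_set(ens)
  reports <- if (isTRUE(attr(nos, "too_small"))) NULL else
    lapply(stats::setNames(ORGANS, ORGANS),
           function(o) correlation_matrix(nos, o))
  list(problem = prob, ensemble = ens, error_bars = eb,
       near_optimal = nos, correlations = reports)
}

#' Run the full multi-organ kinetic analysis
#'
#' End-to-end pipeline: simulate (or load) a cohort, smooth each subject's
#' IDIF, run the multistart joint fit on each requested time scale, and
#' collect parameter tables with error bars, reduced chi-square summaries
#' (total and per organ) and per-organ correlation reports.
#'
#' @param config a [study_config].
#' @param data_dir directory of per-subject TAC CSVs to load instead of
#'   simulating.
#' @param out_dir optional directory for the CSV tables and run manifest.
#' @return a `study_report`: list with `param_table`, `chi2_table`,
#'   `organ_chi2_table`, `fits` (nested per subject/scale), `manifest`.
#' @export
run_study <- function(config = study_config(), data_dir = NULL,
                      out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  sch <- frame_schedule(config$frame_durations_s)
  noise <- noise_spec(config$sc)
  if (is.null(data_dir)) {
    datasets <- list()
    for (s in seq_len(config$n_subjects)) {
      gt <- default_ground_truth(subject_seed = config$seed + s,
                                 schedule = sch, noise = noise)
      datasets[[sprintf("subject%02d", s)]] <- simulate_dataset(gt)
    }
  } else {
    files <- sort(list.files(data_dir, pattern = "^subject.*\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no subject CSVs found in ", data_dir)
    datasets <- lapply(files, function(f) {
      raw <- read_tac_csv(f)
      if (is.null(raw$idif)) stop(f, ": an idif column is required")
      raw$noise <- noise
      raw
    })
    names(datasets) <- sub("\\.csv$", "", basename(files))
  }

  param_table <- chi2_table <- organ_chi2_table <- NULL
  fits <- list()
  for (id in names(datasets)) {
    ds <- datasets[[id]]
    noise_ds <- if (inherits(ds, "tac_dataset")) ds$noise else noise
    sigma_idif <- noise_sigma(noise_ds, "idif", pmax(ds$idif, 0),
                              ds$schedule$mid_min, ds$schedule$duration_min)
    sigma_idif <- pmax(sigma_idif, 0.01 * max(sigma_idif))
    idif <- fit_idif(ds$idif, ds$schedule, n_terms = config$idif_n_terms,
                     sigma = sigma_idif)
    fits[[id]] <- list(idif = idif)
    if (!inherits(ds, "tac_dataset")) {
      ds <- structure(list(tacs = ds$tacs, idif = ds$idif,
                           schedule = ds$schedule, noise = noise_ds),
                      class = "tac_dataset")
    }
    for (scale in config$scales) {
      res <- .fit_subject_scale(ds, idif, config, scale)
      fits[[id]][[scale]] <- res
      eb <- res$error_bars
      param_table <- rbind(param_table, data.frame(
        subject = id, scale = scale, param = eb$param,
        estimate = eb$estimate, err = eb$err,
        censored = eb$censored_lower | eb$censored_upper,
        converged = res$ensemble$best$converged))
      sc <- res$ensemble$best
      chi2_table <- rbind(chi2_table, data.frame(
        subject = id, scale = scale, chi2_nu = sc$chi2_nu, nu = sc$nu))
      organ_chi2_table <- rbind(organ_chi2_table, data.frame(
        subject = id, scale = scale, organ = names(sc$per_organ_chi2),
        chi2_nu_contrib = unname(sc$per_organ_chi2) / sc$nu))
      for (p in eb$param[eb$censored_lower | eb$censored_upper])
        message(id, " [", scale, "]: ", p, " is bound-censored")
    }
  }

  manifest <- list(seed = config$seed, config_hash = .config_hash(config),
                   package_version = as.character(utils::packageVersion("nafkin")),
                   r_version = R.version.string,
                   n_subjects = length(datasets), scales = config$scales,
                   restarts = config$restarts)
  report <- structure(list(param_table = param_table,
                           chi2_table = chi2_table,
                           organ_chi2_table = organ_chi2_table,
                           fits = fits, config = config,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(param_table, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    utils::write.csv(chi2_table, file.path(out_dir, "chi2_by_subject.csv"),
                     row.names = FALSE)
    utils::write.csv(organ_chi2_table,
                     file.path(out_dir, "chi2_by_organ.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    write_study_config(config, file.path(out_dir, "config.yaml"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d subject(s), scales: %s, %d restarts>\n",
              x$manifest$n_subjects, paste(x$manifest$scales, collapse = "+"),
              x$manifest$restarts))
  print(x$chi2_table, row.names = FALSE)
  invisible(x)
}
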