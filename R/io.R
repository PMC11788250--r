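#' Write a framed TAC dataset to CSV
#'
#' One file per subject: columns `frame_start_s`, `frame_duration_s`, one
#' column per organ and an `idif` column, activities in kBq/mL,
#' decay-corrected to injection time. Frames are in seconds in files;
#' everything internal is in minutes.
#'
#' @param dataset a `tac_dataset` (or a list with `tacs`, `idif`,
#'   `schedule`).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_tac_csv <- function(dataset, path) {
  sch <- dataset$schedule
  df <- data.frame(frame_start_s = sch$start_s,
                   frame_duration_s = sch$duration_s)
  df <- cbind(df, as.data.frame(dataset$tacs))
  df$idif <- dataset$idif
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a framed TAC dataset from CSV
#'
#' @param path CSV written in the [write_tac_csv()] dialect.
#' @return list with `tacs` (frames x organs matrix), `idif`, `schedule`.
#' @export
read_tac_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stop(path, ": missing required columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  sch <- frame_schedule(df$frame_duration_s)
  if (max(abs(sch$start_s - df$frame_start_s)) > 1e-6)
    stop(path, ": frames are not contiguous from 0 (first bad line: ",
         which(abs(sch$start_s - df$frame_start_s) > 1e-6)[1] + 1L, ")")
  organs <- intersect(ORGANS, names(df))
  if (length(organs) == 0L) stop(path, ": no organ columns found")
  tacs <- as.matrix(df[, organs, drop = FALSE])
  if (any(!is.finite(tacs)))
    stop(path, ": non-numeric activity values (line ",
         which(!stats::complete.cases(df))[1] + 1L, ")")
  list(tacs = tacs,
       idif = if ("idif" %in% names(df)) df$idif else NULL,
       schedule = sch)
}

#' Read a PMOD-style .tac file
#'
#' Tab-separated with two header lines (a description line, then column
#' names); first two columns are frame start and end in seconds, the
#' remaining columns are region TACs.
#'
#' @param path path to the `.tac` file.
#' @return list with `tacs` (matrix of region columns), `idif` (if a
#'   region named `idif`/`vena_cava` is present), `schedule`.
#' @export
read_pmod_tac <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop(path, ": too short for a .tac file")
  hdr <- strsplit(lines[2], "\t")[[1]]
  df <- utils::read.delim(path, skip = 2, header = FALSE, sep = "\t")
  if (ncol(df) != length(hdr))
    stop(path, ": header/body column mismatch at line 3")
  names(df) <- make.names(tolower(hdr), unique = TRUE)
  start_s <- df[[1]]; end_s <- df[[2]]
  sch <- frame_schedule(end_s - start_s)
  if (max(abs(sch$start_s - start_s)) > 1e-6)
    stop(path, ": frames are not contiguous from 0")
  regions <- df[, -(1:2), drop = FALSE]
  idif_col <- intersect(c("idif", "vena_cava", "vena.cava"), names(regions))
  list(tacs = as.matrix(regions[, setdiff(names(regions), idif_col),
                                drop = FALSE]),
       idif = if (length(idif_col)) regions[[idif_col[1]]] else NULL,
       schedule = sch)
}

#' Study configuration
#'
#' All knobs of a full analysis run in one validated object: framing,
#' noise scales, restart count, scales to fit, IDIF smoothing settings and
#' the gamma convention.
#'
#' @param n_subjects subjects to simulate (ignored when data are loaded).
#' @param seed base integer seed; subject s uses `seed + s` offsets.
#' @param restarts multistart size per subject and scale.
#' @param scales character subset of `c("short", "long")`.
#' @param frame_durations_s frame durations, s.
#' @param sc per-organ (+ idif) noise scales.
#' @param idif_n_terms exponential terms in the IDIF smoothing fit.
#' @param gamma_direction `"divide"` or `"multiply"`.
#' @param use_true_sigma weight residuals with the simulation's true
#'   noise SDs instead of data-derived ones (simulated data only).
#' @return a validated `study_config` list.
#' @export
study_config <- function(n_subjects = 6, seed = 1L, restarts = 200,
                         scales = c("short", "long"),
                         frame_durations_s = c(rep(10, 18), rep(30, 2), 60,
                                               rep(120, 2), rep(300, 10)),
                         sc = c(heart = 0.7, lungs = 0.6, liver = 0.4,
                                kidneys = 0.5, femur = 0.4, idif = 1.2),
                         idif_n_terms = 3,
                         gamma_direction = c("divide", "multiply"),
                         use_true_sigma = FALSE) {
  gamma_direction <- match.arg(gamma_direction)
  scales <- match.arg(scales, c("short", "long"), several.ok = TRUE)
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              restarts = as.integer(restarts), scales = scales,
              frame_durations_s = frame_durations_s, sc = sc,
              idif_n_terms = as.integer(idif_n_terms),
              gamma_direction = gamma_direction,
              use_true_sigma = isTRUE(use_true_sigma),
              schema_version = 1L)
  # touching the constructors validates every component up front
  frame_schedule(cfg$frame_durations_s)
  noise_spec(cfg$sc)
  stopifnot(cfg$n_subjects >= 1, cfg$restarts >= 1, cfg$seed >= 0)
  structure(cfg, class = "study_config")
}

#' Write / read a study configuration as YAML
#' @param config a [study_config].
#' @param path file path.
#' @return `read_study_config` returns a validated [study_config].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  raw <- unclass(config)
  raw$sc <- as.list(raw$sc) # yaml drops names of atomic vectors
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    stop("unsupported study_config schema version")
  study_config(n_subjects = raw$n_subjects, seed = raw$seed,
               restarts = raw$restarts, scales = raw$scales,
               frame_durations_s = raw$frame_durations_s,
               sc = unlist(raw$sc), idif_n_terms = raw$idif_n_terms,
               gamma_direction = raw$gamma_direction,
               use_true_sigma = raw$use_true_sigma)
}

# small polynomial string hash for run manifests
.config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
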