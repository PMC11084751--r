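#' Read a simulation configuration from YAML
#'
#' The file mirrors [generator_config()] and [noise_model()]: top-level keys
#' `generator:` (any subset of the generator arguments) and `noise:`
#' (`sigma`, `cv_sigma`, optional `per_landmark_sigma`).  Omitted fields take
#' the package defaults.  An optional top-level `seed` overrides
#' `generator$seed`.
#'
#' @param path YAML file path.
#' @return List with elements `config` ([generator_config()]) and `noise`
#'   ([noise_model()]).
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) {
    cm_stop(sprintf("config file '%s' does not exist", path), "io_error")
  }
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) cm_stop(
                    sprintf("cannot parse YAML '%s': %s", path,
                            conditionMessage(e)), "parse_error"))
  gen_args <- if (is.null(doc$generator)) list() else doc$generator
  if (!is.null(doc$seed)) gen_args$seed <- doc$seed
  bad <- setdiff(names(gen_args), names(formals(generator_config)))
  if (length(bad)) {
    cm_stop(sprintf("unknown generator fields in '%s': %s", path,
                    paste(bad, collapse = ", ")), "config_error")
  }
  noise_args <- if (is.null(doc$noise)) list() else doc$noise
  bad <- setdiff(names(noise_args), names(formals(noise_model)))
  if (length(bad)) {
    cm_stop(sprintf("unknown noise fields in '%s': %s", path,
                    paste(bad, collapse = ", ")), "config_error")
  }
  list(config = do.call(generator_config, gen_args),
       noise = do.call(noise_model, noise_args))
}

resolve_config <- function(config) {
  if (is.character(config)) return(read_simulation_config(config))
  if (inherits(config, "generator_config")) {
    return(list(config = config, noise = noise_model()))
  }
  if (is.list(config) && inherits(config$config, "generator_config")) {
    if (is.null(config$noise)) config$noise <- noise_model()
    return(config)
  }
  cm_stop("config must be a YAML path, a generator_config, or a list(config, noise)",
          "config_error")
}

config_fingerprint <- function(cfg, noise) {
  label_hash(paste(yaml::as.yaml(unclass(cfg)),
                   yaml::as.yaml(unclass(noise))))
}

write_manifest <- function(path, command, cfg, noise, inputs, outputs) {
  manifest <- list(
    command = command,
    config_hash = config_fingerprint(cfg, noise),
    seed = cfg$seed,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cervimetrics")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Measure a landmark file into a wide measurement CSV
#'
#' @param landmarks_file Landmark JSON or CSV (see [read_landmark_file()]).
#' @param out_csv Optional output path for the wide measurement table.
#' @param format Input format (`"auto"`, `"json"`, `"csv"`).
#' @return The measurement data frame, invisibly when `out_csv` is given.
#' @export
measure_file <- function(landmarks_file, out_csv = NULL, format = "auto") {
  study <- read_landmark_file(landmarks_file, format = format)
  m <- measure_study(study)
  if (!is.null(out_csv)) {
    write_measurement_csv(m, out_csv)
    return(invisible(m))
  }
  m
}

#' Compare two measurement tables into a reliability report
#'
#' @param a,b Measurement CSV paths or data frames.
#' @param label Comparison label (e.g. `"US1 vs US2"`).
#' @param out_report Optional output CSV path.
#' @param strata Optional stratification column (see [reliability_report()]).
#' @return The report data frame, invisibly when `out_report` is given.
#' @export
compare_files <- function(a, b, label, out_report = NULL, strata = NULL) {
  ta <- if (is.character(a)) read_measurement_csv(a) else a
  tb <- if (is.character(b)) read_measurement_csv(b) else b
  rep <- reliability_report(ta, tb, label = label, strata = strata)
  if (!is.null(out_report)) {
    write_report_csv(rep, out_report)
    return(invisible(rep))
  }
  rep
}

#' Simulate a study and write its artifacts to a directory
#'
#' Writes one landmark JSON per trial (`landmarks_US1.json`,
#' `landmarks_US2.json`, `landmarks_CV.json`), the ground truth
#' (`truth.csv`) and a run manifest (`manifest.json`).
#'
#' @param config YAML path, [generator_config()], or
#'   `list(config =, noise =)`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the simulation result of [simulate_study()] plus
#'   `$paths`.
#' @export
simulate_to_dir <- function(config, out_dir) {
  rc <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(rc$config, rc$noise)
  paths <- list(
    US1 = file.path(out_dir, "landmarks_US1.json"),
    US2 = file.path(out_dir, "landmarks_US2.json"),
    CV = file.path(out_dir, "landmarks_CV.json"),
    truth = file.path(out_dir, "truth.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  for (tr in c("US1", "US2", "CV")) {
    write_landmark_file(sim$trials[[tr]], paths[[tr]], format = "json")
  }
  write_measurement_csv(sim$truth, paths$truth)
  write_manifest(paths$manifest, "simulate", rc$config, rc$noise,
                 inputs = list(),
                 outputs = unname(unlist(paths[c("US1", "US2", "CV",
                                                 "truth")])))
  sim$paths <- paths
  invisible(sim)
}

#' Run the full repeated-measures replication experiment
#'
#' One-shot pipeline mirroring the study design: simulate a cohort, measure
#' the two human trials and the deterministic CV annotator (the CV trial is
#' measured twice), and emit the three comparison reports -- US-vs-US,
#' CV-vs-US, and CV-vs-CV -- plus a summary asserting the CV-vs-CV identity
#' (every variable: ICC = 1, RMSE = 0, R-squared = 1).
#'
#' @param config YAML path, [generator_config()], or
#'   `list(config =, noise =)`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the three reports, the summary, and all
#'   artifact paths.
#' @export
replicate_experiment <- function(config, out_dir) {
  rc <- resolve_config(config)
  sim <- simulate_to_dir(rc, out_dir)
  m_us1 <- measure_study(sim$trials$US1)
  m_us2 <- measure_study(sim$trials$US2)
  m_cv1 <- measure_study(sim$trials$CV)
  m_cv2 <- measure_study(sim$trials$CV)   # second pass over the same input
  paths <- sim$paths
  paths$m_us1 <- file.path(out_dir, "measurements_US1.csv")
  paths$m_us2 <- file.path(out_dir, "measurements_US2.csv")
  paths$m_cv1 <- file.path(out_dir, "measurements_CV_run1.csv")
  paths$m_cv2 <- file.path(out_dir, "measurements_CV_run2.csv")
  write_measurement_csv(m_us1, paths$m_us1)
  write_measurement_csv(m_us2, paths$m_us2)
  write_measurement_csv(m_cv1, paths$m_cv1)
  write_measurement_csv(m_cv2, paths$m_cv2)
  rep_us <- reliability_report(m_us1, m_us2, "US vs US")
  rep_cv_us <- reliability_report(m_cv1, m_us1, "CV vs US")
  rep_cv_cv <- reliability_report(m_cv1, m_cv2, "CV vs CV")
  paths$report_us_vs_us <- file.path(out_dir, "report_us_vs_us.csv")
  paths$report_cv_vs_us <- file.path(out_dir, "report_cv_vs_us.csv")
  paths$report_cv_vs_cv <- file.path(out_dir, "report_cv_vs_cv.csv")
  write_report_csv(rep_us, paths$report_us_vs_us)
  write_report_csv(rep_cv_us, paths$report_cv_vs_us)
  write_report_csv(rep_cv_cv, paths$report_cv_vs_cv)
  identity_ok <- all(rep_cv_cv$icc == 1) && all(rep_cv_cv$rmse == 0) &&
    all(rep_cv_cv$r2 == 1)
  summary <- list(
    n_images = rc$config$n_images,
    seed = rc$config$seed,
    cv_vs_cv_identity = identity_ok,
    cv_vs_cv = list(icc_min = min(rep_cv_cv$icc),
                    rmse_max = max(rep_cv_cv$rmse),
                    r2_min = min(rep_cv_cv$r2)),
    us_vs_us = list(icc_range = range(rep_us$icc),
                    rmse_range = range(rep_us$rmse),
                    r2_range = range(rep_us$r2)))
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_manifest(file.path(out_dir, "manifest.json"), "replicate",
                 rc$config, rc$noise, inputs = list(),
                 outputs = unname(unlist(paths[setdiff(names(paths),
                                                       "manifest")])))
  invisible(list(reports = list(us_vs_us = rep_us, cv_vs_us = rep_cv_us,
                                cv_vs_cv = rep_cv_cv),
                 summary = summary, paths = paths))
}
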