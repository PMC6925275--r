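# End-to-end orchestration: simulate synthetic cohorts, fit models, compare
# them at the group level, run the behavioral analyses, and emit a combined
# report. Every stage derives its RNG stream from the single run seed via
# derive_seed(), so adding a stage never perturbs earlier streams.

#' Default pipeline configuration
#'
#' Cohort sizes, generating-model parameters and fitting settings for the
#' synthetic-cohort pipeline. Serializable to JSON via [write_run_config()].
#'
#' @param experiment `"exp1"` (between-subjects) or `"exp2"`
#'   (within-subject).
#' @param n_per_condition agents per condition (exp1) or total agents
#'   (exp2).
#' @param beta,theta0,eta0 generating parameters shared by both internal
#'   learners.
#' @param n_restarts multistart count for fitting.
#' @param seed global run seed.
#' @return Named list of configuration blocks.
#' @export
default_run_config <- function(experiment = "exp1", n_per_condition = 50,
                               beta = 3, theta0 = 0.5, eta0 = 2,
                               n_restarts = 10, seed = 0) {
  list(experiment = experiment,
       n_per_condition = n_per_condition,
       model = list(beta = beta, theta0 = theta0, eta0 = eta0, L0 = 0.5),
       fitting = list(n_restarts = n_restarts, evidence = "bic"),
       seed = seed)
}

#' Write / read a run configuration as JSON
#'
#' @param config configuration list.
#' @param path file path.
#' @return `read_run_config` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("experiment", "n_per_condition", "model", "seed")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0)
    stop_config("run config missing key(s): %s",
                paste(missing_keys, collapse = ", "))
  config
}

config_spec <- function(config) {
  m <- config$model
  model_spec("adaptive", beta = m$beta,
             theta0_u = m$theta0, eta0_u = m$eta0,
             theta0_c = m$theta0, eta0_c = m$eta0, L0 = m$L0 %||% 0.5)
}

#' Simulate a synthetic cohort to CSV
#'
#' Experiment 1: `n_per_condition` adaptive agents per condition; Experiment
#' 2: `n_per_condition` agents, each seeing both conditions in randomized
#' block order. Writes `trials.csv` and `weights.csv` (generating-model
#' weight timeseries) under `out_dir`.
#'
#' @param config run configuration ([default_run_config()]).
#' @param out_dir output directory (created if absent).
#' @return Invisibly, list with the two file paths.
#' @export
cmd_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config_spec(config)
  seed <- derive_seed(config$seed, "simulate")
  if (config$experiment == "exp1") {
    lc <- simulate_cohort(config$n_per_condition, spec, "exp1", "lc",
                          seed = seed, id_prefix = "lc")
    hc <- simulate_cohort(config$n_per_condition, spec, "exp1", "hc",
                          seed = seed, id_prefix = "hc")
    trials <- rbind(lc$trials, hc$trials)
    weights <- rbind(lc$weights, hc$weights)
  } else {
    co <- simulate_cohort(config$n_per_condition, spec, "exp2",
                          seed = seed, id_prefix = "p")
    trials <- co$trials
    weights <- co$weights
  }
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                weights = file.path(out_dir, "weights.csv"))
  write_trials(trials, paths$trials)
  write.csv(weights, paths$weights, row.names = FALSE, quote = FALSE)
  message(sprintf("simulated %d participants, %d trials",
                  length(unique(trials$participant_id)), nrow(trials)))
  invisible(paths)
}

#' Fit both model variants to a trial CSV
#'
#' @param trials_csv path to a trial CSV ([write_trials()] schema).
#' @param config run configuration.
#' @param out_dir output directory; writes `fits.csv`.
#' @return Invisibly, the fits file path.
#' @export
cmd_fit <- function(trials_csv, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_csv)
  settings <- fit_settings(
    n_restarts = config$fitting$n_restarts %||% 10,
    seed = derive_seed(config$seed, "fit"),
    evidence = config$fitting$evidence %||% "bic")
  fits <- fit_cohort(trials, c("adaptive", "fixed"), settings)
  path <- file.path(out_dir, "fits.csv")
  write.csv(fits, path, row.names = FALSE, quote = FALSE)
  message(sprintf("fitted %d participants x 2 variants (%d converged)",
                  length(unique(fits$participant_id)), sum(fits$converged)))
  invisible(path)
}

#' Group-level model comparison from a fits CSV
#'
#' @param fits_csv path to a [cmd_fit()] output.
#' @param config run configuration.
#' @param out_dir output directory; writes `bms.json`.
#' @return Invisibly, the [bms()] result.
#' @export
cmd_compare <- function(fits_csv, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- read.csv(fits_csv, stringsAsFactors = FALSE,
                   colClasses = c(participant_id = "character"))
  res <- bms(evidence_matrix(fits), seed = derive_seed(config$seed, "bms"))
  write_bms(res, file.path(out_dir, "bms.json"))
  invisible(res)
}

#' Behavioral analysis of a trial CSV
#'
#' Applies the exclusion rules, then computes the group comparison of Go
#' bias, bias and variance across conditions; with a weight CSV it adds the
#' weight-quantile Go bias curve and, with a fits CSV, the weight
#' correlation. Writes `summaries.csv` and `report.json`.
#'
#' @param trials_csv path to a trial CSV.
#' @param config run configuration.
#' @param out_dir output directory.
#' @param weights_csv optional weight timeseries CSV.
#' @param fits_csv optional fits CSV.
#' @return Invisibly, the report list.
#' @export
cmd_analyze <- function(trials_csv, config, out_dir,
                        weights_csv = NULL, fits_csv = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- read_trials(trials_csv)
  summaries <- summarize_participants(trials)
  excl <- apply_exclusions(summaries)
  kept_trials <- trials[trials$participant_id %in%
                          excl$kept$participant_id, , drop = FALSE]
  weights <- if (!is.null(weights_csv))
    read.csv(weights_csv, stringsAsFactors = FALSE,
             colClasses = c(participant_id = "character"))
  fits <- if (!is.null(fits_csv))
    read.csv(fits_csv, stringsAsFactors = FALSE,
             colClasses = c(participant_id = "character"))
  gs <- group_stats(kept_trials, weights = weights, fits = fits)
  tc <- go_bias_timecourse(kept_trials)
  report <- list(
    n_participants = nrow(summaries),
    n_excluded = nrow(excl$excluded),
    group_tests = gs$tests,
    slope_mean = unname(tc$slope_test$estimate),
    slope_t = unname(tc$slope_test$statistic),
    slope_p = tc$slope_test$p.value)
  if (!is.null(weights)) {
    kept_w <- weights[weights$participant_id %in%
                        excl$kept$participant_id, , drop = FALSE]
    report$quantile_go_bias <- go_bias_by_weight_quantile(kept_trials, kept_w)
  }
  if (!is.null(gs$w_correlation)) report$w_correlation <- gs$w_correlation
  write.csv(summaries, file.path(out_dir, "summaries.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  message(sprintf("analyzed %d participants (%d excluded)",
                  nrow(summaries), nrow(excl$excluded)))
  invisible(report)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulate, fit, compare and analyze under one seed, writing all artifacts
#' under `out_dir`. This is the programmatic counterpart of the `reproduce`
#' CLI command.
#'
#' @param config run configuration ([default_run_config()]).
#' @param out_dir output directory.
#' @return Invisibly, list with the analysis `report` and the `bms` result.
#' @export
cmd_reproduce <- function(config, out_dir) {
  paths <- cmd_simulate(config, out_dir)
  fits_path <- cmd_fit(paths$trials, config, out_dir)
  bms_res <- cmd_compare(fits_path, config, out_dir)
  report <- cmd_analyze(paths$trials, config, out_dir,
                        weights_csv = paths$weights, fits_csv = fits_path)
  report$pxp <- as.list(bms_res$pxp)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(report = report, bms = bms_res))
}
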