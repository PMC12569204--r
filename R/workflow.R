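#' Run one of the three pipeline workflows
#'
#' Orchestrates `simulate`, `methfrac` and `calcium` end to end: reads the
#' inputs named in the configuration, runs the pipeline, writes result CSVs
#' plus a JSON run report into the output directory. Deterministic given
#' the configuration and seed.
#'
#' The configuration is a named list (or a JSON file via
#' [read_run_config()]) with fields:
#' \describe{
#'   \item{workflow}{`"simulate"`, `"methfrac"` or `"calcium"`.}
#'   \item{out_dir}{output directory, created if absent.}
#'   \item{seed}{integer seed (simulate only).}
#'   \item{arm}{simulate only: `"meth"` or `"calcium"`.}
#'   \item{fractions, samples, noise_sd, n_replicates, ...}{simulate/meth:
#'     calibration fractions, a list of `list(id, methylated, unmethylated)`
#'     sample genotypes, and [digestion_sim_spec()] parameters.}
#'   \item{n_cells, n_samples, ...}{simulate/calcium:
#'     [calcium_sim_spec()] parameters.}
#'   \item{calibration, samples_file}{methfrac: CSV paths; the calibration
#'     table needs a `known_fraction` column.}
#'   \item{traces, sampling_interval}{calcium: trace-matrix CSV and its
#'     sampling interval in seconds.}
#'   \item{pcr_efficiency, max_residual, mad_multiplier, threshold_floor,
#'     f0_percentile}{analysis parameters; defaults are the pipeline's
#'     stated constants (efficiency 2, residual 0.05, multiplier 2,
#'     floor 0.1, percentile 5).}
#' }
#'
#' @param config Named list as described above.
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_workflow <- function(config) {
  stopifnot(is.list(config), !is.null(config$workflow))
  workflow <- match.arg(config$workflow, c("simulate", "methfrac", "calcium"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  outputs <- withCallingHandlers(
    switch(workflow,
           simulate = workflow_simulate(config, out_dir),
           methfrac = workflow_methfrac(config, out_dir),
           calcium = workflow_calcium(config, out_dir)),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  report <- list(
    workflow = workflow,
    package_version = as.character(packageVersion("epiassay")),
    seed = config$seed %||% NA,
    parameters = config[setdiff(names(config), c("workflow", "out_dir"))],
    outputs = outputs,
    warnings = warnings_log
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digestion_spec_from_config <- function(config, allele, seed) {
  digestion_sim_spec(
    config = allele,
    cut_efficiency_sensitive = config$cut_efficiency_sensitive %||% 1,
    cut_efficiency_insensitive = config$cut_efficiency_insensitive %||% 1,
    pcr_efficiency = config$pcr_efficiency %||% 2,
    base_ct = config$base_ct %||% 20,
    noise_sd = config$noise_sd %||% 0.2,
    n_replicates = config$n_replicates %||% 3,
    seed = seed
  )
}

detection_params_from_config <- function(config) {
  detection_params(
    mad_multiplier = config$mad_multiplier %||% 2,
    threshold_floor = config$threshold_floor %||% 0.1,
    f0_percentile = config$f0_percentile %||% 5
  )
}

workflow_simulate <- function(config, out_dir) {
  arm <- match.arg(config$arm %||% "meth", c("meth", "calcium"))
  seed <- as.integer(config$seed %||% 1L)
  if (arm == "meth") {
    fractions <- config$fractions %||% c(0, 0.25, 0.5, 0.75, 1)
    samples <- config$samples %||%
      list(list(id = "sample_1", methylated = 1, unmethylated = 1))
    base_spec <- digestion_spec_from_config(config, allele_config(1, 0), seed)
    series <- simulate_calibration_series(fractions, base_spec)
    cal_entries <- lapply(series, function(p) {
      list(measurements = list(sensitive_digest = p$sensitive,
                               control_digest = p$control),
           known_fraction = p$known_fraction)
    })
    names(cal_entries) <- vapply(series, function(p) p$sensitive$sample_id,
                                 character(1))
    cal_path <- file.path(out_dir, "calibration.csv")
    write_ct_table(cal_entries, cal_path)

    sample_entries <- list()
    truth <- list()
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      allele <- allele_config(s$methylated %||% 1, s$unmethylated %||% 0)
      spec <- digestion_spec_from_config(config, allele, seed + i)
      sim <- simulate_digestion_qpcr(spec, sample_id = s$id %||%
                                       sprintf("sample_%d", i))
      sample_entries[[sim$measurements$control_digest$sample_id]] <-
        list(measurements = sim$measurements)
      truth[[sim$measurements$control_digest$sample_id]] <-
        sim$truth$true_methylation_fraction
    }
    samples_path <- file.path(out_dir, "samples.csv")
    write_ct_table(sample_entries, samples_path)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(true_methylation_fraction = truth), truth_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(calibration = cal_path, samples = samples_path, truth = truth_path)
  } else {
    spec <- calcium_sim_spec(
      n_cells = config$n_cells %||% 100,
      n_samples = config$n_samples %||% 600,
      sampling_interval = config$sampling_interval %||% 1,
      event_rate = config$event_rate %||% 2,
      amplitude_range = config$amplitude_range %||% c(0.4, 0.8),
      decay_tau = config$decay_tau %||% 2,
      rise_samples = config$rise_samples %||% 2,
      baseline = config$baseline %||% 100,
      drift_amplitude = config$drift_amplitude %||% 0.05,
      noise_sd = config$noise_sd %||% 2,
      refractory_samples = config$refractory_samples %||% 10,
      seed = seed
    )
    sim <- simulate_calcium_traces(spec)
    traces_path <- file.path(out_dir, "traces.csv")
    write_trace_matrix(sim$traces, traces_path)
    truth_path <- file.path(out_dir, "truth.json")
    onsets_0based <- lapply(sim$truth$event_onsets, function(v) v - 1L)
    jsonlite::write_json(list(event_onsets_0based = onsets_0based),
                         truth_path, digits = NA, pretty = TRUE)
    list(traces = traces_path, truth = truth_path)
  }
}

workflow_methfrac <- function(config, out_dir) {
  stopifnot(!is.null(config$calibration), !is.null(config$samples_file))
  eff <- config$pcr_efficiency %||% 2
  cal <- read_ct_table(config$calibration)
  has_kf <- vapply(cal, function(e) !is.null(e$known_fraction), logical(1))
  if (!all(has_kf)) {
    stop("calibration table must carry known_fraction for every sample",
         call. = FALSE)
  }
  series <- structure(lapply(cal, function(e) {
    list(known_fraction = e$known_fraction,
         sensitive = e$measurements$sensitive_digest,
         control = e$measurements$control_digest)
  }), class = "calibration_series")
  curve <- fit_standard_curve(calibration_points(series, eff))

  samples <- read_ct_table(config$samples_file)
  estimates <- lapply(samples, function(e) {
    estimate_sample_methylation(e$measurements, curve,
                                pcr_efficiency = eff,
                                max_residual = config$max_residual %||% 0.05)
  })
  est_path <- file.path(out_dir, "estimates.csv")
  write_estimates_csv(estimates, est_path)
  list(estimates = est_path,
       curve = list(slope = curve$slope, intercept = curve$intercept,
                    r_squared = curve$r_squared))
}

workflow_calcium <- function(config, out_dir) {
  stopifnot(!is.null(config$traces), !is.null(config$sampling_interval))
  params <- detection_params_from_config(config)
  traces <- read_trace_matrix(config$traces, config$sampling_interval)
  results <- lapply(traces, detect_events, params = params)
  events_path <- file.path(out_dir, "events.csv")
  write_events_csv(lapply(results, `[[`, "events"), events_path)
  activity_path <- file.path(out_dir, "activity.csv")
  write_activity_csv(lapply(results, `[[`, "summary"), activity_path)
  list(events = events_path, activity = activity_path)
}
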