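# Orchestration: gas compliance checks and the end-to-end pipeline.

#' Compliance constraints for a gas treatment
#'
#' The per-phase constraints a stunning cycle must meet: the two-phase CO2
#' treatment must stay below 40% CO2 in its first 2 min and above 90% CO2
#' with residual O2 below 2% in the second; the nitrogen mixtures must hold
#' CO2 within a tolerance of their nominal level with residual O2 below 2%;
#' AIR must remain at atmospheric composition.
#'
#' @param treatment_label one of [treatment_labels()]
#' @param exposure_duration window length, s (default 240)
#' @param co2_tol tolerance (percentage points) around nominal CO2 for the
#'   mixture treatments (default 10)
#' @return tibble with one row per phase: `phase`, `start_s`, `end_s`,
#'   `co2_min`, `co2_max`, `o2_max` (`NA` where unconstrained)
#' @export
treatment_definition <- function(treatment_label, exposure_duration = 240,
                                 co2_tol = 10) {
  half <- exposure_duration / 2
  switch(treatment_label,
    "40C90C" = tibble::tibble(
      phase = 1:2, start_s = c(0, half), end_s = c(half, exposure_duration),
      co2_min = c(NA, 90), co2_max = c(40, NA), o2_max = c(NA, 2)),
    "40C60N" = tibble::tibble(
      phase = 1, start_s = 0, end_s = exposure_duration,
      co2_min = 40 - co2_tol, co2_max = 40 + co2_tol, o2_max = 2),
    "20C80N" = tibble::tibble(
      phase = 1, start_s = 0, end_s = exposure_duration,
      co2_min = 20 - co2_tol, co2_max = 20 + co2_tol, o2_max = 2),
    "AIR" = tibble::tibble(
      phase = 1, start_s = 0, end_s = exposure_duration,
      co2_min = NA, co2_max = 1, o2_max = NA),
    stop("unknown treatment_label: ", treatment_label))
}

#' Check a gas profile against treatment constraints
#'
#' Compares per-phase mean concentrations with the treatment's constraints.
#' An optional settle window excludes the initial lift-descent seconds from
#' each cycle's first phase before averaging.
#'
#' @param profile tibble from [simulate_gas_profile()] or equivalent, with
#'   `time_s`, `co2_pct`, `o2_pct`
#' @param definition constraint table from [treatment_definition()]
#' @param settle_s seconds excluded at the start of the cycle (default 0)
#' @return tibble of class `compliance_report`: one row per phase with
#'   observed means, the constraints, and `pass`; attribute `"pass"` is the
#'   conjunction over phases
#' @export
check_gas_compliance <- function(profile, definition, settle_s = 0) {
  stopifnot(all(c("time_s", "co2_pct", "o2_pct") %in% names(profile)))
  if (max(profile$time_s) < max(definition$end_s) - 1e-9 ||
      min(profile$time_s) > min(definition$start_s) + 1e-9)
    stop("profile does not cover all phases")
  rows <- lapply(seq_len(nrow(definition)), function(i) {
    d <- definition[i, ]
    lo <- max(d$start_s, settle_s)
    sel <- profile$time_s >= lo & profile$time_s < d$end_s
    if (!any(sel)) stop("profile gap: no samples in phase ", d$phase)
    co2 <- mean(profile$co2_pct[sel])
    o2 <- mean(profile$o2_pct[sel])
    ok <- (is.na(d$co2_min) || co2 > d$co2_min) &&
          (is.na(d$co2_max) || co2 < d$co2_max) &&
          (is.na(d$o2_max) || o2 < d$o2_max)
    tibble::tibble(phase = d$phase, start_s = d$start_s, end_s = d$end_s,
                   co2_mean = co2, o2_mean = o2,
                   co2_min = d$co2_min, co2_max = d$co2_max, o2_max = d$o2_max,
                   pass = ok)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("compliance_report", class(out))
  out
}

#' Pipeline run configuration
#'
#' @param seed master RNG seed; every stage derives its own stream from it
#' @param out_dir output directory (created if missing)
#' @param eeg_treatments treatments to simulate EEG cohorts for
#' @param n_eeg birds per EEG treatment
#' @param behaviour_treatments treatments to simulate behaviour cohorts for
#' @param n_behaviour birds per behaviour treatment
#' @param gas_treatments treatments to simulate gas cycles for
#' @param detection a [detection_config()]
#' @param verbose print stage progress
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1, out_dir = "stunEEG_run",
                       eeg_treatments = c("40C60N", "20C80N"), n_eeg = 2,
                       behaviour_treatments = c("40C90C", "40C60N", "20C80N"),
                       n_behaviour = 6,
                       gas_treatments = c("40C90C", "40C60N", "20C80N"),
                       detection = detection_config(),
                       verbose = FALSE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 eeg_treatments = eeg_treatments, n_eeg = n_eeg,
                 behaviour_treatments = behaviour_treatments,
                 n_behaviour = n_behaviour,
                 gas_treatments = gas_treatments,
                 detection = detection, verbose = verbose),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; keys under
#' `detection:` mirror [detection_config()].
#'
#' @param path YAML file
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_config, y$detection %||% list())
  y$detection <- NULL
  do.call(run_config, c(y, list(detection = det)))
}

#' Run the full pipeline: simulate, detect, summarise, check
#'
#' Simulates EEG cohorts, runs per-bird detection, simulates behaviour
#' cohorts and builds their summary tables, simulates gas profiles and checks
#' compliance, then writes everything as CSV plus a JSON manifest (seed,
#' package version, file checksums). Re-running with the same configuration
#' reproduces byte-identical outputs.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()]
#' @return (invisibly) list with the in-memory results and `manifest`
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  outfile <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit <- function(df, name) {
    utils::write.csv(df, outfile(name), row.names = FALSE)
    written <<- c(written, name)
  }

  say("stage: eeg simulation + detection")
  det_rows <- list(); truth_rows <- list()
  for (tr in config$eeg_treatments) {
    cohort <- default_eeg_cohort(tr, config$n_eeg,
                                 seed = derive_seed(config$seed, paste0("eeg_", tr)))
    res <- simulate_cohort(cohort, trace_handler = function(trace, truth) {
      say("  bird %s", trace$subject_id)
      as.data.frame(analyze_bird(trace, config$detection))
    })
    det_rows[[tr]] <- dplyr::bind_rows(res$handler_results)
    truth_rows[[tr]] <- res$truth_table
  }
  detection <- dplyr::bind_rows(det_rows)
  truth <- dplyr::bind_rows(truth_rows)
  emit(detection, "detection.csv")
  emit(truth, "eeg_truth.csv")

  say("stage: behaviour simulation + tables")
  records <- list()
  for (tr in config$behaviour_treatments) {
    cohort <- default_behaviour_cohort(tr, config$n_behaviour,
                                       seed = derive_seed(config$seed, paste0("beh_", tr)))
    records <- c(records, simulate_behaviour_cohort(cohort))
  }
  write_events(records, outfile("behaviour_events.csv"))
  written <- c(written, "behaviour_events.csv")
  tabs <- cohort_tables(records)
  emit(tabs$anchor_table, "anchor_times.csv")
  emit(tabs$behaviour_table, "behaviour_summary.csv")

  say("stage: gas profiles + compliance")
  gas_rows <- list(); comp_rows <- list()
  for (tr in config$gas_treatments) {
    prof <- simulate_gas_profile(
      default_gas_spec(tr, seed = derive_seed(config$seed, paste0("gas_", tr))))
    prof$treatment <- tr
    gas_rows[[tr]] <- prof
    comp <- check_gas_compliance(prof, treatment_definition(tr),
                                 settle_s = attr(prof, "spec")$fill_latency)
    comp$treatment <- tr
    comp_rows[[tr]] <- comp
  }
  emit(dplyr::bind_rows(gas_rows), "gas_profiles.csv")
  compliance <- dplyr::bind_rows(comp_rows)
  emit(compliance, "gas_compliance.csv")

  manifest <- list(
    seed = config$seed,
    package = "stunEEG",
    version = as.character(utils::packageVersion("stunEEG")),
    config = list(eeg_treatments = config$eeg_treatments, n_eeg = config$n_eeg,
                  behaviour_treatments = config$behaviour_treatments,
                  n_behaviour = config$n_behaviour,
                  gas_treatments = config$gas_treatments),
    files = lapply(stats::setNames(written, written), function(f) {
      list(md5 = unname(tools::md5sum(outfile(f))))
    }))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(detection = detection, truth = truth,
                 behaviour_tables = tabs, compliance = compliance,
                 manifest = manifest, out_dir = config$out_dir))
}
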