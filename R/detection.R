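#' Detection configuration
#'
#' Thresholds and persistence settings for the loss-of-consciousness (LOC),
#' spectral-death and isoelectric rules. Defaults follow the established
#' poultry-stunning EEG criteria: LOC when per-epoch F50 falls below 50% of
#' the bird's baseline median and/or the Delta contribution rises 65% above
#' the baseline median, sustained over four consecutive 1 s epochs; spectral
#' death when Ptot drops by 90% relative to baseline over four consecutive
#' epochs; isoelectric trace when Ptot stays below an absolute 2.5 microvolt^2
#' level. Baseline epochs with F50 below 4 Hz are treated as movement
#' artifacts and excluded before medians are taken.
#'
#' @param f50_ratio_threshold LOC criterion A: qualifying epochs have
#'   `f50 < f50_ratio_threshold * baseline median f50` (default 0.50)
#' @param delta_increase_threshold LOC criterion B (relative mode): qualifying
#'   epochs have `delta_frac > (1 + delta_increase_threshold) * baseline
#'   median delta fraction` (default 0.65)
#' @param delta_mode `"relative"` (default) compares against baseline as
#'   above; `"absolute"` qualifies epochs with
#'   `delta_frac > delta_increase_threshold` outright
#' @param ptot_drop_threshold spectral-death criterion: qualifying epochs have
#'   `ptot < (1 - ptot_drop_threshold) * baseline median ptot` (default 0.90)
#' @param persistence number of consecutive qualifying epochs required for LOC
#'   and spectral death (default 4)
#' @param isoelectric_ptot_level absolute Ptot level (microvolt^2) below which
#'   an epoch counts as isoelectric (default 2.5)
#' @param isoelectric_persistence consecutive epochs required for the
#'   isoelectric call (default 4)
#' @param loc_rule_combiner `"either"` (default; an epoch qualifies under
#'   criterion A or B) or `"both"`
#' @param baseline_f50_artifact_floor baseline epochs with F50 below this
#'   frequency (Hz) are excluded as movement artifacts (default 4)
#' @param gamma_quality_limit maximum acceptable per-epoch Gamma fraction
#'   before the high-noise flag is raised (default 0.02)
#' @return a list of class `detection_config`
#' @export
detection_config <- function(f50_ratio_threshold = 0.50,
                             delta_increase_threshold = 0.65,
                             delta_mode = c("relative", "absolute"),
                             ptot_drop_threshold = 0.90,
                             persistence = 4L,
                             isoelectric_ptot_level = 2.5,
                             isoelectric_persistence = 4L,
                             loc_rule_combiner = c("either", "both"),
                             baseline_f50_artifact_floor = 4,
                             gamma_quality_limit = 0.02) {
  delta_mode <- match.arg(delta_mode)
  loc_rule_combiner <- match.arg(loc_rule_combiner)
  for (th in c(f50_ratio_threshold, ptot_drop_threshold))
    if (!is_scalar_number(th) || th <= 0 || th >= 1)
      stop("ratio thresholds must lie in (0, 1)")
  if (!is_scalar_number(delta_increase_threshold) || delta_increase_threshold <= 0)
    stop("delta_increase_threshold must be positive")
  if (persistence < 1 || isoelectric_persistence < 1)
    stop("persistence must be >= 1")
  structure(list(
    f50_ratio_threshold = f50_ratio_threshold,
    delta_increase_threshold = delta_increase_threshold,
    delta_mode = delta_mode,
    ptot_drop_threshold = ptot_drop_threshold,
    persistence = as.integer(persistence),
    isoelectric_ptot_level = isoelectric_ptot_level,
    isoelectric_persistence = as.integer(isoelectric_persistence),
    loc_rule_combiner = loc_rule_combiner,
    baseline_f50_artifact_floor = baseline_f50_artifact_floor,
    gamma_quality_limit = gamma_quality_limit
  ), class = "detection_config")
}

#' Baseline summary with artifact exclusion
#'
#' Computes per-bird baseline medians of Ptot, F50 and the Delta fraction over
#' the baseline-phase epochs, after removing epochs whose F50 lies below the
#' artifact floor (low-frequency transients from bird movement) and epochs
#' with undefined features.
#'
#' @param series feature tibble from [feature_series()]
#' @param config a [detection_config()]
#' @return list of class `baseline_summary`: `median_ptot`, `median_f50`,
#'   `median_delta_fraction`, `n_epochs_used`, `n_epochs_excluded`
#' @export
compute_baseline <- function(series, config = detection_config()) {
  bl <- series[series$phase == "baseline", , drop = FALSE]
  if (nrow(bl) == 0) stop_stage("baseline", "no baseline epochs in series")
  keep <- bl$defined & !is.na(bl$f50_hz) &
    bl$f50_hz >= config$baseline_f50_artifact_floor
  used <- bl[keep, , drop = FALSE]
  if (nrow(used) == 0)
    stop_stage("baseline",
               "no usable baseline epochs after artifact exclusion (no_baseline)")
  structure(list(
    median_ptot = stats::median(used$ptot_uv2),
    median_f50 = stats::median(used$f50_hz),
    median_delta_fraction = stats::median(used$delta_frac),
    n_epochs_used = nrow(used),
    n_epochs_excluded = nrow(bl) - nrow(used)
  ), class = "baseline_summary")
}

# First start time of a run of >= persistence consecutive TRUE values.
# NA entries (undefined epochs) break runs. Returns NA_real_ if no such run.
first_persistent_run <- function(qualify, start_s, persistence) {
  q <- !is.na(qualify) & qualify
  if (!any(q)) return(NA_real_)
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0) return(NA_real_)
  start_s[starts[hit[1]]]
}

loc_qualify <- function(ex, baseline, config) {
  qa <- ex$f50_hz < config$f50_ratio_threshold * baseline$median_f50
  qb <- if (config$delta_mode == "relative") {
    ex$delta_frac > (1 + config$delta_increase_threshold) * baseline$median_delta_fraction
  } else {
    ex$delta_frac > config$delta_increase_threshold
  }
  q <- if (config$loc_rule_combiner == "either") qa | qb else qa & qb
  q[!ex$defined] <- NA
  q
}

#' Detect onset of loss of consciousness
#'
#' Scans exposure-phase epochs for the first run of at least `persistence`
#' consecutive epochs satisfying the LOC criteria (F50 below half the baseline
#' median, and/or Delta fraction 65% above the baseline median, per the
#' configured combiner) and returns the start time of the first epoch of that
#' run, in seconds from exposure start. Returns `NA` when no qualifying run
#' exists. Epochs with undefined features break runs.
#'
#' @param series feature tibble from [feature_series()]
#' @param baseline a [compute_baseline()] summary
#' @param config a [detection_config()]
#' @return onset time in seconds, or `NA_real_` if undetected
#' @export
detect_loc <- function(series, baseline, config = detection_config()) {
  stopifnot(inherits(baseline, "baseline_summary"))
  ex <- series[series$phase == "exposure", , drop = FALSE]
  if (nrow(ex) == 0) return(NA_real_)
  first_persistent_run(loc_qualify(ex, baseline, config),
                       ex$epoch_start_s, config$persistence)
}

#' Detect brain death by spectral power collapse
#'
#' First run of at least `persistence` consecutive exposure epochs whose Ptot
#' has dropped by at least `ptot_drop_threshold` (default 90%) relative to the
#' baseline median.
#'
#' @inheritParams detect_loc
#' @return onset time in seconds, or `NA_real_` if undetected
#' @export
detect_death_spectral <- function(series, baseline, config = detection_config()) {
  stopifnot(inherits(baseline, "baseline_summary"))
  ex <- series[series$phase == "exposure", , drop = FALSE]
  if (nrow(ex) == 0) return(NA_real_)
  q <- ex$ptot_uv2 < (1 - config$ptot_drop_threshold) * baseline$median_ptot
  q[!ex$defined] <- NA
  first_persistent_run(q, ex$epoch_start_s, config$persistence)
}

#' Detect the isoelectric pattern
#'
#' First run of at least `isoelectric_persistence` consecutive exposure epochs
#' with Ptot below the absolute isoelectric level (default 2.5 microvolt^2).
#' Unlike the spectral-death rule this criterion is independent of the
#' baseline, mirroring its use as a visual near-flat-line call. Epochs with
#' undefined (zero-power) features count as isoelectric here: a flat-zero
#' trace is the extreme of the pattern.
#'
#' @param series feature tibble from [feature_series()]
#' @param config a [detection_config()]
#' @return onset time in seconds, or `NA_real_` if undetected
#' @export
detect_isoelectric <- function(series, config = detection_config()) {
  ex <- series[series$phase == "exposure", , drop = FALSE]
  if (nrow(ex) == 0) return(NA_real_)
  q <- ex$ptot_uv2 < config$isoelectric_ptot_level
  first_persistent_run(q, ex$epoch_start_s, config$isoelectric_persistence)
}

#' Gamma-band quality check
#'
#' The Gamma band (32-200 Hz) lies outside the 1-30 Hz passband, so after
#' filtering its share of the spectrum reflects residual broadband noise. This
#' reports the maximum and mean per-epoch Gamma fraction and raises a flag
#' when the maximum reaches the configured limit (default 2%).
#'
#' @param series feature tibble from [feature_series()]
#' @param config a [detection_config()]
#' @return list with `max_gamma_fraction`, `mean_gamma_fraction`, `high_gamma`
#'   (logical; `TRUE` also when no epoch has defined features)
#' @export
gamma_quality <- function(series, config = detection_config()) {
  if (nrow(series) == 0) stop("empty feature series")
  g <- series$gamma_frac[series$defined]
  if (length(g) == 0)
    return(list(max_gamma_fraction = NA_real_, mean_gamma_fraction = NA_real_,
                high_gamma = TRUE))
  list(max_gamma_fraction = max(g), mean_gamma_fraction = mean(g),
       high_gamma = max(g) >= config$gamma_quality_limit)
}

#' Full per-bird analysis
#'
#' Runs the complete detection chain on a raw trace: 1-30 Hz zero-phase
#' band-pass, 1 s epoch split, per-epoch spectral features, baseline summary
#' with artifact exclusion, then the LOC, spectral-death and isoelectric
#' detectors plus the Gamma quality check. Deterministic for a fixed trace and
#' configuration.
#'
#' @param trace an [eeg_trace()]
#' @param config a [detection_config()]
#' @param band passband corners in Hz for the pre-filter (default `c(1, 30)`)
#' @param epoch_length epoch duration in seconds (default 1)
#' @return list of class `detection_result`: `subject_id`, `treatment_label`,
#'   `t_loc`, `t_death_spectral`, `t_death_isoelectric` (seconds from exposure
#'   start, `NA` when undetected), `gamma_max_fraction`, `qc_flags` (character
#'   vector drawn from `no_baseline`, `high_gamma`, `undetected_loc`,
#'   `undetected_death`, `death_before_loc`), `baseline`, `features`
#' @export
analyze_bird <- function(trace, config = detection_config(),
                         band = c(1, 30), epoch_length = 1) {
  stopifnot(inherits(trace, "eeg_trace"))
  filt <- bandpass(trace, band[1], band[2])
  feats <- feature_series(epoch_split(filt, epoch_length))
  flags <- character(0)
  baseline <- tryCatch(compute_baseline(feats, config), error = function(e) NULL)
  gq <- gamma_quality(feats, config)
  if (isTRUE(gq$high_gamma)) flags <- c(flags, "high_gamma")
  if (is.null(baseline)) {
    flags <- c(flags, "no_baseline")
    t_loc <- t_death <- NA_real_
  } else {
    t_loc <- detect_loc(feats, baseline, config)
    t_death <- detect_death_spectral(feats, baseline, config)
  }
  t_iso <- detect_isoelectric(feats, config)
  if (is.na(t_loc)) flags <- c(flags, "undetected_loc")
  if (is.na(t_death) && is.na(t_iso)) flags <- c(flags, "undetected_death")
  if (!is.na(t_loc) && !is.na(t_death) && t_death < t_loc)
    flags <- c(flags, "death_before_loc")
  structure(list(
    subject_id = trace$subject_id,
    treatment_label = trace$treatment_label,
    t_loc = t_loc,
    t_death_spectral = t_death,
    t_death_isoelectric = t_iso,
    gamma_max_fraction = gq$max_gamma_fraction,
    qc_flags = flags,
    baseline = baseline,
    features = feats
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undetected" else sprintf("%.1f s", v)
  cat(sprintf("<detection_result> %s (%s)\n", x$subject_id, x$treatment_label))
  cat(sprintf("  LOC: %s | death (spectral): %s | death (isoelectric): %s\n",
              fmt(x$t_loc), fmt(x$t_death_spectral), fmt(x$t_death_isoelectric)))
  cat(sprintf("  max Gamma fraction: %s | flags: %s\n",
              ifelse(is.na(x$gamma_max_fraction), "NA",
                     sprintf("%.4f", x$gamma_max_fraction)),
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ",") else "none"))
  invisible(x)
}

#' Detection results as a one-row data frame
#'
#' @param x a `detection_result`
#' @param ... unused
#' @return tibble with the columns of the pipeline's detection CSV
#' @export
as.data.frame.detection_result <- function(x, ...) {
  tibble::tibble(
    subject = x$subject_id,
    treatment = x$treatment_label,
    t_loc_s = x$t_loc,
    t_death_spectral_s = x$t_death_spectral,
    t_death_isoelectric_s = x$t_death_isoelectric,
    gamma_max_frac = x$gamma_max_fraction,
    qc_flags = paste(x$qc_flags, collapse = ";"))
}
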