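# Synthetic gas-concentration profiles per stunning cycle.

#' Specification of a gas cycle
#'
#' Phase targets for the CO2 and O2 concentration (percent by volume) over
#' the exposure window, with Gaussian measurement noise and an initial fill
#' ramp covering the lift descent into the pre-filled pit.
#'
#' @param treatment_label one of [treatment_labels()]
#' @param phase_boundaries strictly increasing vector of phase edges in
#'   seconds, starting at 0 and ending at the exposure end (phases tile the
#'   window, so they cannot overlap)
#' @param co2_target,o2_target percent by volume per phase (length =
#'   number of phases, values in `[0, 100]`)
#' @param noise_sd measurement noise sd, percentage points (default 0.3)
#' @param fill_latency seconds over which concentrations ramp from ambient
#'   air to the first-phase target while the lift descends (default 23)
#' @param sample_interval sampling interval of the profile, s (default 1)
#' @param seed integer RNG seed
#' @return list of class `gas_cycle_spec`
#' @export
gas_cycle_spec <- function(treatment_label,
                           phase_boundaries,
                           co2_target, o2_target,
                           noise_sd = 0.3,
                           fill_latency = 23,
                           sample_interval = 1,
                           seed = NULL) {
  if (!treatment_label %in% treatment_labels())
    stop("unknown treatment_label: ", treatment_label)
  if (length(phase_boundaries) < 2 || any(diff(phase_boundaries) <= 0))
    stop("phase_boundaries must be strictly increasing (phases cannot overlap)")
  n_phase <- length(phase_boundaries) - 1
  if (length(co2_target) != n_phase || length(o2_target) != n_phase)
    stop("need one CO2 and one O2 target per phase")
  if (any(co2_target < 0 | co2_target > 100) || any(o2_target < 0 | o2_target > 100))
    stop("gas percentages must lie in [0, 100]")
  if (noise_sd < 0 || fill_latency < 0) stop("noise_sd and fill_latency must be non-negative")
  structure(list(treatment_label = treatment_label,
                 phase_boundaries = phase_boundaries,
                 co2_target = co2_target, o2_target = o2_target,
                 noise_sd = noise_sd, fill_latency = fill_latency,
                 sample_interval = sample_interval, seed = seed),
            class = "gas_cycle_spec")
}

#' Default gas-cycle specification per treatment
#'
#' Targets emulate the observed concentrations: two-phase CO2 runs just under
#' 40% CO2 for the first 2 min then above 90% CO2 with residual O2 near 1%;
#' the nitrogen mixtures hold their CO2 level with residual O2 below 2%
#' throughout; AIR stays at atmospheric composition (0.04% CO2, 20.9% O2).
#'
#' @param treatment_label one of [treatment_labels()]
#' @param exposure_duration window length, s (default 240)
#' @param seed integer RNG seed
#' @return a [gas_cycle_spec()]
#' @export
default_gas_spec <- function(treatment_label, exposure_duration = 240, seed = NULL) {
  switch(treatment_label,
    "40C90C" = gas_cycle_spec("40C90C",
                              c(0, exposure_duration / 2, exposure_duration),
                              co2_target = c(38.1, 92.2), o2_target = c(13.0, 1.0),
                              seed = seed),
    "40C60N" = gas_cycle_spec("40C60N", c(0, exposure_duration),
                              co2_target = 36.3, o2_target = 1.6, seed = seed),
    "20C80N" = gas_cycle_spec("20C80N", c(0, exposure_duration),
                              co2_target = 18.0, o2_target = 1.9, seed = seed),
    "AIR" = gas_cycle_spec("AIR", c(0, exposure_duration),
                           co2_target = 0.04, o2_target = 20.9,
                           noise_sd = 0.02, fill_latency = 0, seed = seed),
    stop("unknown treatment_label: ", treatment_label))
}

#' Simulate a gas-concentration time series
#'
#' Produces piecewise-constant CO2 and O2 targets per phase with additive
#' Gaussian noise (clamped to `[0, 100]`), preceded by a linear ramp from
#' ambient air over `fill_latency` seconds at the start of the cycle (the
#' lift descending into the pre-filled pit). With `noise_sd = 0` and no fill
#' latency the profile is exactly piecewise constant.
#'
#' @param spec a [gas_cycle_spec()]
#' @return tibble with `time_s`, `co2_pct`, `o2_pct`; the spec is attached as
#'   attribute `"spec"`
#' @export
simulate_gas_profile <- function(spec) {
  stopifnot(inherits(spec, "gas_cycle_spec"))
  t <- seq(spec$phase_boundaries[1],
           spec$phase_boundaries[length(spec$phase_boundaries)],
           by = spec$sample_interval)
  phase <- findInterval(t, spec$phase_boundaries, rightmost.closed = TRUE)
  phase <- pmin(pmax(phase, 1), length(spec$co2_target))
  co2 <- spec$co2_target[phase]
  o2 <- spec$o2_target[phase]
  if (spec$fill_latency > 0) {
    w <- pmin(t / spec$fill_latency, 1)
    co2 <- 0.04 + w * (co2 - 0.04)
    o2 <- 20.9 + w * (o2 - 20.9)
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, list(
      co2 = stats::rnorm(length(t), 0, spec$noise_sd),
      o2 = stats::rnorm(length(t), 0, spec$noise_sd)))
    co2 <- co2 + noise$co2
    o2 <- o2 + noise$o2
  }
  out <- tibble::tibble(time_s = t,
                        co2_pct = pmin(pmax(co2, 0), 100),
                        o2_pct = pmin(pmax(o2, 0), 100))
  attr(out, "spec") <- spec
  out
}
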