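# Synthetic EEG generator.
#
# The trace is modelled as a sum of amplitude-modulated narrowband oscillators
# (one to three fixed-frequency components per EEG band, random phase per
# bird, slow sinusoidal amplitude modulation) plus a band-limited Gaussian
# background. Band powers cross-fade linearly over `transition_width` seconds
# starting at the programmed loss-of-consciousness time, and the whole signal
# decays exponentially towards a low-amplitude broadband floor after the
# programmed death time, emulating the conscious -> Delta-dominated ->
# isoelectric progression seen in gas-stunned birds. Oscillators (rather than
# filtered white noise alone) keep single-epoch spectral estimates stable
# enough that threshold rules operating on 1 s epochs are meaningful, which
# matches how rhythmic real EEG behaves and white noise does not.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# fixed oscillator layout: component frequencies per band (Hz)
sim_components <- function() {
  data.frame(
    band = c("Delta", "Theta", "Theta", "Alpha", "Alpha", "Beta", "Beta", "Beta"),
    freq = c(2.5, 5.1, 6.9, 9.0, 11.2, 14.6, 19.5, 24.4),
    stringsAsFactors = FALSE)
}

#' Default band powers for the conscious and unconscious states
#'
#' Band powers (microvolt^2) used by the generator: the conscious baseline is
#' dominated by activity above 4 Hz (median frequency near 9 Hz, Delta
#' fraction about 0.24), the unconscious state is Delta-dominated (median
#' frequency below 4 Hz, Delta fraction about 0.6).
#'
#' @param state `"baseline"` or `"unconscious"`
#' @return named numeric vector over Delta, Theta, Alpha, Beta
#' @export
default_band_powers <- function(state = c("baseline", "unconscious")) {
  state <- match.arg(state)
  if (state == "baseline")
    c(Delta = 55, Theta = 45, Alpha = 80, Beta = 45)
  else
    c(Delta = 110, Theta = 40, Alpha = 20, Beta = 10)
}

#' Specification of one synthetic EEG trace
#'
#' @param sampling_rate Hz (default 1000)
#' @param baseline_duration conscious pre-exposure recording, s (default 90)
#' @param exposure_duration gas-exposure window, s (default 240)
#' @param t_loc_true programmed onset of loss of consciousness, s from
#'   exposure start, or `NULL` for a stationary conscious trace
#' @param t_death_true programmed brain-death time, s from exposure start, or
#'   `NULL`
#' @param transition_width duration of the linear band-power cross-fade that
#'   begins at `t_loc_true`, s (default 2)
#' @param baseline_band_powers,unconscious_band_powers named vectors of band
#'   power (microvolt^2) over Delta/Theta/Alpha/Beta; defaults
#'   [default_band_powers()]
#' @param isoelectric_level RMS amplitude of the post-death floor, microvolts
#'   (default 1)
#' @param decay_tau time constant of the post-death amplitude decay, s
#'   (default 1)
#' @param artifact_rate baseline movement-artifact rate, events per minute
#'   (default 2)
#' @param artifact_amplitude artifact peak amplitude, microvolts (default 150)
#' @param broadband_power power of the band-limited Gaussian background,
#'   microvolt^2 (default 5)
#' @param am_depth relative depth of the slow amplitude modulation applied to
#'   each oscillator (default 0.05)
#' @param seed integer RNG seed, or `NULL` to use the current RNG state
#' @param subject_id,treatment_label labels carried into the trace
#' @return list of class `eeg_sim_spec`
#' @export
eeg_sim_spec <- function(sampling_rate = 1000,
                         baseline_duration = 90,
                         exposure_duration = 240,
                         t_loc_true = NULL,
                         t_death_true = NULL,
                         transition_width = 2,
                         baseline_band_powers = default_band_powers("baseline"),
                         unconscious_band_powers = default_band_powers("unconscious"),
                         isoelectric_level = 1.0,
                         decay_tau = 1.0,
                         artifact_rate = 2,
                         artifact_amplitude = 150,
                         broadband_power = 5,
                         am_depth = 0.05,
                         seed = NULL,
                         subject_id = "sim", treatment_label = "40C60N") {
  spec <- mget(names(formals()))
  if (baseline_duration < 0 || exposure_duration <= 0)
    stop("durations must be positive (baseline may be zero)")
  need <- c("Delta", "Theta", "Alpha", "Beta")
  for (p in list(baseline_band_powers, unconscious_band_powers)) {
    if (!all(need %in% names(p))) stop("band powers must name Delta, Theta, Alpha, Beta")
    if (any(p[need] < 0)) stop("band powers must be non-negative")
  }
  if (!is.null(t_loc_true)) {
    if (t_loc_true <= 0 || t_loc_true >= exposure_duration)
      stop("t_loc_true must lie inside (0, exposure_duration)")
  }
  if (!is.null(t_death_true)) {
    if (t_death_true <= 0 || t_death_true >= exposure_duration)
      stop("t_death_true must lie inside (0, exposure_duration)")
    if (!is.null(t_loc_true) && t_loc_true >= t_death_true)
      stop("need t_loc_true < t_death_true")
  }
  if (transition_width < 0) stop("transition_width must be non-negative")
  if (artifact_rate < 0 || artifact_amplitude < 0) stop("artifact parameters must be non-negative")
  if (isoelectric_level < 0 || broadband_power < 0) stop("levels must be non-negative")
  structure(spec, class = "eeg_sim_spec")
}

#' Simulate one EEG trace with known ground truth
#'
#' See the generator description in the package vignette. The returned trace
#' spans `baseline_duration + exposure_duration` seconds at `sampling_rate`,
#' with exposure time zero at lift-descent start. Identical seeds give
#' bit-identical traces.
#'
#' @param spec an [eeg_sim_spec()]
#' @return list with `trace` (an [eeg_trace()]) and `ground_truth` (list with
#'   `t_loc_true`, `t_death_true`; `NA` where not programmed)
#' @export
simulate_eeg_trace <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  fs <- spec$sampling_rate
  t <- seq(-spec$baseline_duration, spec$exposure_duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  comp <- sim_components()
  n_per_band <- table(comp$band)

  x <- with_seed(spec$seed, {
    osc <- numeric(n)
    for (j in seq_len(nrow(comp))) {
      b <- comp$band[j]
      p0 <- spec$baseline_band_powers[[b]] / n_per_band[[b]]
      p1 <- spec$unconscious_band_powers[[b]] / n_per_band[[b]]
      fj <- comp$freq[j] + stats::runif(1, -0.15, 0.15)
      phi <- stats::runif(1, 0, 2 * pi)
      f_am <- stats::runif(1, 0.05, 0.15)
      psi <- stats::runif(1, 0, 2 * pi)
      ramp <- if (is.null(spec$t_loc_true)) 0 else {
        if (spec$transition_width > 0)
          pmin(pmax((t - spec$t_loc_true) / spec$transition_width, 0), 1)
        else as.numeric(t >= spec$t_loc_true)
      }
      pj <- p0 + ramp * (p1 - p0)
      aj <- sqrt(2 * pj) * (1 + spec$am_depth * sin(2 * pi * f_am * t + psi))
      osc <- osc + aj * cos(2 * pi * fj * t + phi)
    }
    bb <- fft_bandpass(stats::rnorm(n), fs, 1, 30)
    bb <- bb * sqrt(spec$broadband_power) / stats::sd(bb)

    if (!is.null(spec$t_death_true)) {
      dt <- pmax(t - spec$t_death_true, 0)
      g <- exp(-dt / spec$decay_tau)
      osc <- osc * g
      iso_ratio <- spec$isoelectric_level / sqrt(spec$broadband_power)
      bb_env <- ifelse(t < spec$t_death_true, 1,
                       iso_ratio + (1 - iso_ratio) * exp(-dt / spec$decay_tau))
      bb <- bb * bb_env
    }
    x <- osc + bb

    # sparse low-frequency movement artifacts on the conscious baseline
    if (spec$artifact_rate > 0 && spec$artifact_amplitude > 0 &&
        spec$baseline_duration > 1) {
      n_art <- stats::rpois(1, spec$artifact_rate * spec$baseline_duration / 60)
      if (n_art > 0) {
        centers <- stats::runif(n_art, -spec$baseline_duration + 0.5, -0.5)
        for (ct in centers) {
          idx <- which(abs(t - ct) <= 0.3)
          tt <- t[idx] - ct
          burst <- spec$artifact_amplitude * cos(2 * pi * 1.5 * tt) *
            0.5 * (1 + cos(pi * tt / 0.3))
          x[idx] <- x[idx] + burst
        }
      }
    }
    x
  })

  trace <- eeg_trace(x, fs,
                     baseline_window = c(-spec$baseline_duration, 0),
                     exposure_window = c(0, spec$exposure_duration),
                     subject_id = spec$subject_id,
                     treatment_label = spec$treatment_label)
  list(trace = trace,
       ground_truth = list(
         t_loc_true = if (is.null(spec$t_loc_true)) NA_real_ else spec$t_loc_true,
         t_death_true = if (is.null(spec$t_death_true)) NA_real_ else spec$t_death_true))
}

#' Specification of a simulated cohort
#'
#' Onset times are drawn per bird from truncated normal distributions, the
#' form in which the field reports them (mean +/- sd within a bounded
#' observation window).
#'
#' @param n_birds number of birds (>= 1)
#' @param treatment_label one of [treatment_labels()]
#' @param loc_time_distribution `c(mean, sd)` in seconds for the
#'   loss-of-consciousness (or loss-of-posture) time; `NULL` for none (AIR)
#' @param death_time_distribution `c(mean, sd)` for the death (or motionless)
#'   time; its mean must exceed the loss mean
#' @param behaviour_rate_table tibble with columns `behaviour`, `phase`
#'   (`pre`/`post`), `rate_per_min`, `mean_duration_s`; see
#'   [default_behaviour_rates()]
#' @param eeg_template an [eeg_sim_spec()] providing all per-trace parameters
#'   other than the programmed times
#' @param seed integer RNG seed
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_birds,
                        treatment_label = "40C60N",
                        loc_time_distribution = c(25.7, 7.0),
                        death_time_distribution = c(65.8, 14.1),
                        behaviour_rate_table = NULL,
                        eeg_template = eeg_sim_spec(),
                        seed = NULL) {
  if (!is_scalar_number(n_birds) || n_birds < 1) stop("n_birds must be >= 1")
  if (!treatment_label %in% treatment_labels())
    stop("unknown treatment_label: ", treatment_label)
  chk <- function(d, what) {
    if (is.null(d)) return(invisible())
    if (length(d) != 2 || d[1] <= 0) stop(what, " must be c(mean > 0, sd)")
    if (d[2] < 0) stop(what, " sd must be non-negative")
  }
  chk(loc_time_distribution, "loc_time_distribution")
  chk(death_time_distribution, "death_time_distribution")
  if (!is.null(loc_time_distribution) && !is.null(death_time_distribution) &&
      death_time_distribution[1] <= loc_time_distribution[1])
    stop("death time mean must exceed loss time mean")
  if (!is.null(behaviour_rate_table)) {
    req <- c("behaviour", "phase", "rate_per_min", "mean_duration_s")
    if (!all(req %in% names(behaviour_rate_table)))
      stop("behaviour_rate_table needs columns ", paste(req, collapse = ", "))
    if (any(behaviour_rate_table$rate_per_min < 0) ||
        any(behaviour_rate_table$mean_duration_s < 0))
      stop("rates and durations must be non-negative")
  }
  structure(list(
    n_birds = as.integer(n_birds),
    treatment_label = treatment_label,
    loc_time_distribution = loc_time_distribution,
    death_time_distribution = death_time_distribution,
    behaviour_rate_table = behaviour_rate_table,
    eeg_template = eeg_template,
    seed = seed
  ), class = "cohort_spec")
}

#' Default EEG cohort specifications per treatment
#'
#' Onset-time distributions emulating the spectral findings for each gas
#' treatment: loss of consciousness 25.7 +/- 7.0 s and spectral death
#' 65.8 +/- 14.1 s for 40% CO2 / 60% N2; 20.7 +/- 6.6 s and 122 +/- 53.2 s for
#' 20% CO2 / 80% N2. No usable EEG exists for the two-phase CO2 treatment, so
#' its times fall back on the behavioural anchors (posture loss
#' 59.2 +/- 21.9 s, motionless 168.8 +/- 27.2 s). AIR birds get a stationary
#' conscious trace.
#'
#' @param treatment_label one of [treatment_labels()]
#' @param n_birds cohort size
#' @param seed integer RNG seed
#' @return a [cohort_spec()]
#' @export
default_eeg_cohort <- function(treatment_label, n_birds, seed = NULL) {
  dists <- switch(treatment_label,
    "40C60N" = list(loc = c(25.7, 7.0), death = c(65.8, 14.1)),
    "20C80N" = list(loc = c(20.7, 6.6), death = c(122, 53.2)),
    "40C90C" = list(loc = c(59.2, 21.9), death = c(168.8, 27.2)),
    "AIR"    = list(loc = NULL, death = NULL),
    stop("unknown treatment_label: ", treatment_label))
  cohort_spec(n_birds, treatment_label,
              loc_time_distribution = dists$loc,
              death_time_distribution = dists$death,
              eeg_template = eeg_sim_spec(treatment_label = treatment_label),
              seed = seed)
}

#' Simulate an EEG cohort
#'
#' Draws per-bird ground-truth times from the cohort's truncated normal
#' distributions (truncated to the exposure window; the death draw is further
#' truncated to fall at least 5 s after that bird's loss time) and synthesises
#' one trace per bird. With a `trace_handler`, each trace is passed to the
#' handler and released immediately, so large cohorts run in bounded memory.
#'
#' @param cohort a [cohort_spec()]
#' @param trace_handler optional `function(trace, truth_row)`; its return
#'   values are collected in `handler_results`
#' @return list with `truth_table` (tibble: `subject`, `treatment`,
#'   `t_loc_true`, `t_death_true`) and either `birds` (list of
#'   [simulate_eeg_trace()] results) or `handler_results`
#' @export
simulate_cohort <- function(cohort, trace_handler = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  expo <- cohort$eeg_template$exposure_duration
  width <- cohort$eeg_template$transition_width

  truths <- with_seed(cohort$seed, {
    n <- cohort$n_birds
    if (is.null(cohort$loc_time_distribution)) {
      data.frame(t_loc = rep(NA_real_, n), t_death = rep(NA_real_, n))
    } else {
      ld <- cohort$loc_time_distribution
      dd <- cohort$death_time_distribution
      t_loc <- rtruncnorm(n, ld[1], ld[2], lower = 1, upper = expo - width - 8)
      t_death <- vapply(t_loc, function(tl) {
        rtruncnorm(1, dd[1], dd[2], lower = tl + 5, upper = expo - 1)
      }, numeric(1))
      data.frame(t_loc = t_loc, t_death = t_death)
    }
  })
  seeds <- vapply(seq_len(cohort$n_birds), function(i) {
    derive_seed(cohort$seed %||% 0, paste0("eeg_bird_", i))
  }, integer(1))

  truth_table <- tibble::tibble(
    subject = sprintf("%s_b%03d", cohort$treatment_label, seq_len(cohort$n_birds)),
    treatment = cohort$treatment_label,
    t_loc_true = truths$t_loc,
    t_death_true = truths$t_death)

  out <- vector("list", cohort$n_birds)
  for (i in seq_len(cohort$n_birds)) {
    sp <- cohort$eeg_template
    sp$t_loc_true <- if (is.na(truths$t_loc[i])) NULL else truths$t_loc[i]
    sp$t_death_true <- if (is.na(truths$t_death[i])) NULL else truths$t_death[i]
    sp$seed <- if (is.null(cohort$seed)) NULL else seeds[i]
    sp$subject_id <- truth_table$subject[i]
    sp$treatment_label <- cohort$treatment_label
    sim <- simulate_eeg_trace(sp)
    out[[i]] <- if (is.null(trace_handler)) sim
                else trace_handler(sim$trace, truth_table[i, ])
  }
  res <- list(truth_table = truth_table)
  if (is.null(trace_handler)) res$birds <- out else res$handler_results <- out
  res
}
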