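# Synthetic ethogram event streams with treatment-dependent rates.

# Per-treatment means used to parameterise the default generator: events per
# bird and total state duration per bird in each phase, and the anchor-time
# distributions (mean, sd in seconds). Values emulate the reported summaries
# for each gas treatment; the ataxia event count, which the summaries omit,
# is set to a nominal 1.3 events/bird.
behaviour_reference_means <- function() {
  tribble_row <- function(behaviour, phase, e1, e2, e3, d1 = NA, d2 = NA, d3 = NA) {
    tibble::tibble(behaviour = behaviour, phase = phase,
                   treatment = c("40C90C", "40C60N", "20C80N"),
                   events_mean = c(e1, e2, e3),
                   duration_total_mean = c(d1, d2, d3))
  }
  dplyr::bind_rows(
    tribble_row("head_shaking", "pre", 5.4, 4.8, 5.1),
    tribble_row("deep_inhalation", "pre", 9.4, 3.9, 4.8),
    tribble_row("HPV", "pre", 2.9, 2.0, 3.3),
    tribble_row("gasping", "pre", 0.7, 0, 0),
    tribble_row("sitting", "pre", 2.1, 1.3, 1.6, 35.9, 7.4, 6.9),
    tribble_row("standing", "pre", 2.0, 1.1, 1.3, 13.4, 7.5, 8.5),
    tribble_row("walking", "pre", 1.2, 0.6, 0.7, 2.6, 1.5, 1.5),
    tribble_row("ataxia", "pre", 1.3, 1.3, 1.3, 4.6, 2.7, 3.6),
    tribble_row("wing_flapping", "pre", 0.4, 0.6, 1.0, 0.7, 1.1, 2.3),
    tribble_row("gasping", "post", 2.5, 0.4, 0.3),
    tribble_row("jumping", "post", 0.1, 0.2, 0.4),
    tribble_row("leg_paddling", "post", 3.9, 4.3, 4.6, 14.3, 18.2, 19.0),
    tribble_row("wing_flapping", "post", 1.5, 2.4, 3.1, 0.7, 1.1, 2.3),
    tribble_row("HPV", "post", 1.8, 1.5, 1.8))
}

behaviour_anchor_defaults <- function(treatment_label) {
  switch(treatment_label,
         "40C90C" = list(lop = c(59.2, 21.9), motionless = c(168.8, 27.2)),
         "40C60N" = list(lop = c(19.8, 4.5), motionless = c(66.1, 10.3)),
         "20C80N" = list(lop = c(22.3, 4.5), motionless = c(70.4, 10.3)),
         stop("no default behaviour anchors for treatment ", treatment_label))
}

#' Default behaviour event rates per treatment
#'
#' Converts the per-treatment mean event counts and state durations into the
#' `(rate per minute, mean event duration)` form the generator consumes,
#' using the treatment's mean phase lengths (time to posture loss, and from
#' posture loss to motionlessness) as exposure denominators.
#'
#' @param treatment_label `"40C90C"`, `"40C60N"` or `"20C80N"`
#' @return tibble with `behaviour`, `phase`, `rate_per_min`, `mean_duration_s`
#' @export
default_behaviour_rates <- function(treatment_label) {
  anc <- behaviour_anchor_defaults(treatment_label)
  pre_min <- anc$lop[1] / 60
  post_min <- (anc$motionless[1] - anc$lop[1]) / 60
  ref <- behaviour_reference_means()
  ref <- ref[ref$treatment == treatment_label, , drop = FALSE]
  ref$rate_per_min <- ref$events_mean / ifelse(ref$phase == "pre", pre_min, post_min)
  ref$mean_duration_s <- ifelse(
    is.na(ref$duration_total_mean) | ref$events_mean == 0, 0,
    ref$duration_total_mean / ref$events_mean)
  ref[, c("behaviour", "phase", "rate_per_min", "mean_duration_s")]
}

#' Default behavioural cohort specification per treatment
#'
#' @param treatment_label `"40C90C"`, `"40C60N"` or `"20C80N"`
#' @param n_birds cohort size
#' @param seed integer RNG seed
#' @return a [cohort_spec()] with anchor-time distributions and event rates
#'   emulating the treatment
#' @export
default_behaviour_cohort <- function(treatment_label, n_birds, seed = NULL) {
  anc <- behaviour_anchor_defaults(treatment_label)
  cohort_spec(n_birds, treatment_label,
              loc_time_distribution = anc$lop,
              death_time_distribution = anc$motionless,
              behaviour_rate_table = default_behaviour_rates(treatment_label),
              seed = seed)
}

#' Simulate a cohort of behaviour records
#'
#' Draws one loss-of-posture and one motionless anchor per bird from the
#' cohort's truncated normal distributions (posture loss strictly before
#' motionlessness, which is at or before the end of the observation window),
#' then lays Poisson-count events into each phase: counts are Poisson with
#' mean `rate_per_min x phase length`, onsets uniform within the phase, and
#' state-event durations exponential with the configured mean, truncated at
#' the phase boundary so pre-posture-loss events end at the anchor. Point
#' behaviours get zero duration. Birds are grouped into stunning cycles of
#' three, matching how gas-treatment birds were dipped.
#'
#' @param cohort a [cohort_spec()] with a `behaviour_rate_table`
#' @param observation_length observation window, s (default 240)
#' @param ethogram behaviour catalogue used for validation
#' @return list of [behaviour_record()]s
#' @export
simulate_behaviour_cohort <- function(cohort, observation_length = 240,
                                      ethogram = default_ethogram()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  rt <- cohort$behaviour_rate_table
  if (is.null(rt)) stop("cohort has no behaviour_rate_table")
  ethogram_check_label(rt$behaviour, ethogram)
  if (any(rt$behaviour %in% ethogram$behaviour[ethogram$type == "anchor"]))
    stop("anchor behaviours cannot carry rates; they occur exactly once")
  # an active rate in a phase the ethogram forbids is a configuration error
  allowed <- ethogram$phase[match(rt$behaviour, ethogram$behaviour)]
  bad <- rt$rate_per_min > 0 & allowed != "both" & allowed != rt$phase
  if (any(bad))
    stop("rate configured in a disallowed phase for: ",
         paste(unique(rt$behaviour[bad]), collapse = ", "))
  types <- ethogram$type[match(rt$behaviour, ethogram$behaviour)]

  ld <- cohort$loc_time_distribution
  dd <- cohort$death_time_distribution
  if (is.null(ld) || is.null(dd))
    stop("behaviour simulation needs anchor-time distributions")

  records <- vector("list", cohort$n_birds)
  for (i in seq_len(cohort$n_birds)) {
    records[[i]] <- with_seed(
      if (is.null(cohort$seed)) NULL
      else derive_seed(cohort$seed, paste0("beh_bird_", i)), {
      t_lop <- rtruncnorm(1, ld[1], ld[2], lower = 1,
                          upper = observation_length - 2)
      t_mot <- rtruncnorm(1, dd[1], dd[2], lower = t_lop + 1,
                          upper = observation_length)
      evs <- list(tibble::tibble(
        behaviour = c("loss_of_posture", "motionless"),
        type = "POINT", start_s = c(t_lop, t_mot), stop_s = c(t_lop, t_mot)))
      for (j in seq_len(nrow(rt))) {
        win <- if (rt$phase[j] == "pre") c(0, t_lop) else c(t_lop, t_mot)
        len_min <- (win[2] - win[1]) / 60
        cnt <- stats::rpois(1, rt$rate_per_min[j] * len_min)
        if (cnt == 0) next
        is_state <- types[j] == "state"
        start <- sort(stats::runif(cnt, win[1],
                                   if (is_state) max(win[1], win[2] - 0.05) else win[2]))
        if (is_state) {
          dur <- pmax(stats::rexp(cnt, 1 / max(rt$mean_duration_s[j], 0.05)), 0.05)
          stop_t <- pmin(start + dur, win[2])
        } else {
          stop_t <- start
        }
        evs[[length(evs) + 1]] <- tibble::tibble(
          behaviour = rt$behaviour[j],
          type = if (is_state) "STATE" else "POINT",
          start_s = start, stop_s = stop_t)
      }
      behaviour_record(
        subject_id = sprintf("%s_beh%03d", cohort$treatment_label, i),
        treatment_label = cohort$treatment_label,
        cycle_id = ceiling(i / 3),
        events = dplyr::bind_rows(evs),
        observation_length = observation_length,
        ethogram = ethogram)
    })
  }
  records
}
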