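test_that("identical seeds give bit-identical traces, different seeds differ", {
  sp <- function(s) eeg_sim_spec(baseline_duration = 5, exposure_duration = 10,
                                 t_loc_true = 4, t_death_true = 8, seed = s)
  a <- simulate_eeg_trace(sp(123))
  b <- simulate_eeg_trace(sp(123))
  c <- simulate_eeg_trace(sp(124))
  expect_identical(a$trace$samples, b$trace$samples)
  expect_false(identical(a$trace$samples, c$trace$samples))
  expect_equal(a$ground_truth$t_loc_true, 4)
  # the generator leaves the global RNG stream untouched
  set.seed(9); before <- rnorm(3)
  set.seed(9); invisible(simulate_eeg_trace(sp(5))); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("invalid simulation specifications are rejected", {
  expect_error(eeg_sim_spec(t_loc_true = 300), "t_loc_true")
  expect_error(eeg_sim_spec(t_loc_true = 50, t_death_true = 40), "t_loc_true < t_death_true")
  expect_error(eeg_sim_spec(baseline_band_powers = c(Delta = -1, Theta = 1,
                                                     Alpha = 1, Beta = 1)),
               "non-negative")
  expect_error(eeg_sim_spec(baseline_band_powers = c(Delta = 1)), "must name")
  expect_error(eeg_sim_spec(exposure_duration = 0), "positive")
  expect_error(cohort_spec(0), "n_birds")
  expect_error(cohort_spec(5, loc_time_distribution = c(20, -1)), "sd")
  expect_error(cohort_spec(5, loc_time_distribution = c(60, 5),
                           death_time_distribution = c(50, 5)),
               "must exceed")
  expect_error(cohort_spec(5, treatment_label = "50C50N"), "unknown")
})

test_that("baseline epochs satisfy the conscious spectral contract", {
  feats <- dplyr::bind_rows(lapply(1:3, function(s) {
    sim <- simulate_eeg_trace(eeg_sim_spec(baseline_duration = 100,
                                           exposure_duration = 10, seed = s))
    fs <- feature_series(epoch_split(bandpass(sim$trace)))
    fs[fs$phase == "baseline", ]
  }))
  expect_gte(nrow(feats), 300)
  expect_gte(median(feats$f50_hz), 7)
  expect_lte(median(feats$delta_frac), 0.35)
  expect_lt(max(feats$gamma_frac), 0.02)
  # artifact epochs exist but are a small minority
  expect_lt(mean(feats$f50_hz < 4), 0.15)
})

test_that("the unconscious plateau is Delta-dominated with halved F50", {
  sim <- simulate_eeg_trace(eeg_sim_spec(baseline_duration = 30,
                                         exposure_duration = 60,
                                         t_loc_true = 5, seed = 42,
                                         artifact_rate = 0))
  fs <- feature_series(epoch_split(bandpass(sim$trace)))
  plateau <- fs[fs$phase == "exposure" & fs$epoch_start_s >= 10, ]
  base <- fs[fs$phase == "baseline", ]
  expect_lte(median(plateau$f50_hz), 5)
  expect_lt(median(plateau$f50_hz), 0.5 * median(base$f50_hz))
  expect_gt(median(plateau$delta_frac),
            1.65 * median(base$delta_frac))
})

test_that("the trace collapses towards the isoelectric floor after death", {
  spec <- eeg_sim_spec(baseline_duration = 5, exposure_duration = 40,
                       t_loc_true = 5, t_death_true = 20, seed = 8,
                       isoelectric_level = 1)
  sim <- simulate_eeg_trace(spec)
  tr <- sim$trace
  t <- seq(-5, 40 - 1e-3, by = 1 / tr$sampling_rate)
  tail_rms <- sqrt(mean(tr$samples[t >= 30]^2))
  expect_lt(tail_rms, 2 * spec$isoelectric_level)
  head_rms <- sqrt(mean(tr$samples[t >= 0 & t < 5]^2))
  expect_gt(head_rms, 10 * tail_rms)
})

test_that("rtruncnorm respects bounds and matches the target moments", {
  set.seed(101)
  x <- stunEEG:::rtruncnorm(4000, 25.7, 7.0, lower = 1, upper = 220)
  expect_true(all(x >= 1 & x <= 220))
  expect_equal(mean(x), 25.7, tolerance = 0.02)
  expect_equal(sd(x), 7.0, tolerance = 0.05)
  # hard truncation: narrow window draws stay inside it
  y <- stunEEG:::rtruncnorm(500, 0, 10, lower = 19, upper = 21)
  expect_true(all(y >= 19 & y <= 21))
})

test_that("cohort truth tables are ordered, bounded and deterministic", {
  short <- eeg_sim_spec(baseline_duration = 5, exposure_duration = 120)
  co <- cohort_spec(6, "40C60N", c(25.7, 7.0), c(65.8, 14.1),
                    eeg_template = short, seed = 2024)
  res <- simulate_cohort(co, trace_handler = function(trace, truth) {
    length(trace$samples)
  })
  tt <- res$truth_table
  expect_equal(nrow(tt), 6)
  expect_true(all(tt$t_loc_true < tt$t_death_true))
  expect_true(all(tt$t_loc_true >= 1))
  expect_true(all(tt$t_death_true <= 119))
  expect_true(all(unlist(res$handler_results) == 125 * 1000))
  res2 <- simulate_cohort(co, trace_handler = function(trace, truth) NULL)
  expect_identical(tt, res2$truth_table)
})

test_that("behaviour cohorts respect the ethogram phase structure", {
  recs <- simulate_behaviour_cohort(default_behaviour_cohort("40C60N", 9, seed = 31))
  expect_length(recs, 9)
  expect_equal(vapply(recs, function(r) r$cycle_id, numeric(1)),
               rep(1:3, each = 3))
  for (r in recs) {
    expect_true(r$usable)
    expect_lt(r$t_lop, r$t_motionless)
    expect_lte(r$t_motionless, 240)
    ev <- r$events
    eth <- default_ethogram()
    ty <- eth$type[match(ev$behaviour, eth$behaviour)]
    ph <- eth$phase[match(ev$behaviour, eth$behaviour)]
    expect_true(all(ev$stop_s[ty == "point"] == ev$start_s[ty == "point"]))
    expect_true(all(ev$stop_s[ty == "state"] > ev$start_s[ty == "state"]))
    # pre-only behaviours never start after posture loss; post-only never before
    expect_true(all(ev$start_s[ph == "pre"] <= r$t_lop))
    expect_true(all(ev$stop_s[ph == "pre"] <= r$t_lop + 1e-9))
    expect_true(all(ev$start_s[ph == "post"] >= r$t_lop))
    expect_true(all(ev$stop_s[ph == "post"] <= r$t_motionless + 1e-9))
  }
  # determinism
  recs2 <- simulate_behaviour_cohort(default_behaviour_cohort("40C60N", 9, seed = 31))
  expect_identical(recs[[4]]$events, recs2[[4]]$events)
})

test_that("zero event rates produce anchor-only records; bad rates error", {
  rt <- default_behaviour_rates("40C60N")
  rt$rate_per_min <- 0
  co <- cohort_spec(2, "40C60N", c(19.8, 4.5), c(66.1, 10.3),
                    behaviour_rate_table = rt, seed = 5)
  recs <- simulate_behaviour_cohort(co)
  for (r in recs) {
    expect_setequal(r$events$behaviour, c("loss_of_posture", "motionless"))
  }
  bad <- rt
  bad$rate_per_min[bad$behaviour == "leg_paddling"] <- 2
  bad$phase[bad$behaviour == "leg_paddling"] <- "pre"  # post-only behaviour
  co_bad <- cohort_spec(2, "40C60N", c(19.8, 4.5), c(66.1, 10.3),
                        behaviour_rate_table = bad, seed = 5)
  expect_error(simulate_behaviour_cohort(co_bad), "disallowed phase")
})

test_that("gas profiles hit phase targets and honour noise settings", {
  sp <- default_gas_spec("40C90C", seed = 3)
  sp$noise_sd <- 0
  prof <- simulate_gas_profile(sp)
  # past the fill ramp, phase 1 sits exactly at its target
  expect_true(all(prof$co2_pct[prof$time_s >= 23 & prof$time_s < 120] == 38.1))
  expect_true(all(prof$co2_pct[prof$time_s >= 120] == 92.2))
  expect_true(all(prof$o2_pct[prof$time_s >= 120] == 1.0))
  # the ramp starts at ambient air
  expect_equal(prof$co2_pct[prof$time_s == 0], 0.04)
  expect_equal(prof$o2_pct[prof$time_s == 0], 20.9)

  air <- simulate_gas_profile(default_gas_spec("AIR", seed = 3))
  expect_lt(max(abs(air$co2_pct - 0.04)), 0.2)
  expect_lt(max(abs(air$o2_pct - 20.9)), 0.2)

  a <- simulate_gas_profile(default_gas_spec("40C60N", seed = 11))
  b <- simulate_gas_profile(default_gas_spec("40C60N", seed = 11))
  expect_identical(a, b)
  expect_error(gas_cycle_spec("40C60N", c(0, 100, 50), c(30, 30), c(2, 2)),
               "strictly increasing")
  expect_error(gas_cycle_spec("40C60N", c(0, 100), 130, 2), "0, 100")
})
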