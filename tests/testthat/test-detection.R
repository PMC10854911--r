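test_that("baseline medians exclude low-F50 artifact epochs", {
  fs <- make_features(f50 = c(20, 3.5, 18, 22), delta = c(0.2, 0.8, 0.25, 0.22),
                      ptot = c(200, 900, 210, 190), phase = "baseline",
                      start = 0:3)
  bl <- compute_baseline(fs)
  expect_equal(bl$n_epochs_used, 3)
  expect_equal(bl$n_epochs_excluded, 1)
  expect_equal(bl$median_f50, 20)
  expect_equal(bl$median_ptot, 200)

  all_art <- make_features(f50 = c(2, 3, 3.9), delta = 0.8, ptot = 500,
                           phase = "baseline", start = 0:2)
  expect_error(compute_baseline(all_art), "no_baseline")
  expect_error(compute_baseline(make_features(10, 0.2, 100, phase = "exposure")),
               "no baseline")
})

test_that("LOC rule fires at the first persistent qualifying run", {
  bl <- make_baseline(median_f50 = 20, median_delta = 0.20)
  # F50 halves from epoch 15 onward
  f50 <- c(rep(18, 15), rep(8, 45))
  fs <- make_features(f50, delta = 0.2, ptot = 200)
  expect_equal(detect_loc(fs, bl), 15)

  # a 3-epoch dip does not qualify under persistence 4
  f50b <- rep(18, 60); f50b[10:12] <- 8
  expect_true(is.na(detect_loc(make_features(f50b, 0.2, 200), bl)))
  # ...but does under persistence 3
  expect_equal(detect_loc(make_features(f50b, 0.2, 200), bl,
                          detection_config(persistence = 3)), 9)

  # delta criterion alone triggers under "either", not under "both"
  delta <- c(rep(0.2, 20), rep(0.40, 40))  # > 1.65 * 0.20
  fsd <- make_features(rep(18, 60), delta, 200)
  expect_equal(detect_loc(fsd, bl), 20)
  expect_true(is.na(detect_loc(fsd, bl,
                               detection_config(loc_rule_combiner = "both"))))

  # absolute delta mode compares against the threshold directly
  expect_true(is.na(detect_loc(fsd, bl,
                               detection_config(delta_mode = "absolute"))))
  expect_equal(detect_loc(make_features(rep(18, 60), c(rep(0.2, 20), rep(0.7, 40)), 200),
                          bl, detection_config(delta_mode = "absolute")), 20)
})

test_that("spectral-death and isoelectric rules follow their definitions", {
  bl <- make_baseline(median_ptot = 200)
  ptot <- c(rep(180, 60), rep(15, 20), rep(1.5, 20))  # drop at 60, iso at 80
  fs <- make_features(rep(8, 100), 0.5, ptot)
  expect_equal(detect_death_spectral(fs, bl), 60)
  expect_equal(detect_isoelectric(fs), 80)
  # isoelectric needs the absolute level, not the relative drop
  expect_true(is.na(detect_isoelectric(make_features(rep(8, 30), 0.5, rep(15, 30)))))
  # undefined (zero-power) epochs count as isoelectric
  fz <- make_features(rep(8, 10), 0.5, c(rep(100, 5), rep(0, 5)),
                      defined = c(rep(TRUE, 5), rep(FALSE, 5)))
  fz$f50_hz[6:10] <- NA; fz$ptot_uv2[6:10] <- 0
  expect_equal(detect_isoelectric(fz, detection_config(isoelectric_persistence = 4)), 5)
  # but they break LOC/death runs
  expect_true(is.na(detect_death_spectral(fz, bl)))
})

test_that("persistence and combiner behave monotonically", {
  bl <- make_baseline()
  set.seed(7)
  f50 <- ifelse(runif(120) < 0.5, 8, 18)
  delta <- ifelse(runif(120) < 0.3, 0.5, 0.2)
  fs <- make_features(f50, delta, 200)
  times <- vapply(1:6, function(p)
    detect_loc(fs, bl, detection_config(persistence = p)), numeric(1))
  # once undetected at persistence p, undetected for all larger p
  if (anyNA(times)) expect_true(all(is.na(times[which(is.na(times))[1]:6])))
  ok <- times[!is.na(times)]
  expect_true(all(diff(ok) >= 0))  # longer persistence cannot detect earlier
  # "either" can never detect later than "both"
  t_e <- detect_loc(fs, bl, detection_config(loc_rule_combiner = "either"))
  t_b <- detect_loc(fs, bl, detection_config(loc_rule_combiner = "both"))
  if (!is.na(t_b)) { expect_false(is.na(t_e)); expect_lte(t_e, t_b) }
})

test_that("gamma quality flags broadband contamination", {
  fs <- make_features(rep(10, 20), 0.2, 200)
  fs$gamma_frac <- 0.001
  gq <- gamma_quality(fs)
  expect_false(gq$high_gamma)
  fs$gamma_frac[7] <- 0.05
  gq2 <- gamma_quality(fs)
  expect_true(gq2$high_gamma)
  expect_equal(gq2$max_gamma_fraction, 0.05)
  # all-undefined series is flagged
  fs$defined <- FALSE
  expect_true(gamma_quality(fs)$high_gamma)
})

test_that("an unfiltered 60 Hz tone is caught by the gamma check", {
  sim <- simulate_eeg_trace(eeg_sim_spec(baseline_duration = 5,
                                         exposure_duration = 10, seed = 79,
                                         artifact_rate = 0))
  tr <- sim$trace
  tt <- seq_along(tr$samples) / tr$sampling_rate
  tr$samples <- tr$samples + 20 * sin(2 * pi * 60 * tt)  # mains interference
  feats <- feature_series(epoch_split(tr))   # deliberately no band-pass
  expect_true(gamma_quality(feats)$high_gamma)
  filt <- feature_series(epoch_split(bandpass(tr)))
  expect_false(gamma_quality(filt)$high_gamma)
})

test_that("analyze_bird recovers programmed times on a synthetic bird", {
  sim <- simulate_eeg_trace(eeg_sim_spec(t_loc_true = 20, t_death_true = 65,
                                         seed = 77))
  res <- analyze_bird(sim$trace)
  expect_s3_class(res, "detection_result")
  expect_gte(res$t_loc, 20); expect_lte(res$t_loc, 24)
  expect_gte(res$t_death_spectral, 65); expect_lte(res$t_death_spectral, 71)
  expect_gte(res$t_death_isoelectric, res$t_death_spectral)
  expect_lt(res$gamma_max_fraction, 0.02)
  expect_length(res$qc_flags, 0)
  df <- as.data.frame(res)
  expect_equal(df$t_loc_s, res$t_loc)
  expect_match(paste(capture.output(print(res)), collapse = "\n"), "LOC")
})

test_that("a stationary conscious bird yields no detections and clean QC", {
  sim <- simulate_eeg_trace(eeg_sim_spec(exposure_duration = 60, seed = 78,
                                         treatment_label = "AIR"))
  res <- analyze_bird(sim$trace)
  expect_true(is.na(res$t_loc))
  expect_true(is.na(res$t_death_spectral))
  expect_true(is.na(res$t_death_isoelectric))
  expect_setequal(res$qc_flags, c("undetected_loc", "undetected_death"))
})
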