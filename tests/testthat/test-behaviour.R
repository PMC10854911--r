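# Small fixture: one bird with a state spanning the anchor, point events on
# both sides, and both anchors present.
fixture_record <- function(t_lop = 20, t_mot = 60) {
  ev <- tibble::tibble(
    behaviour = c("loss_of_posture", "motionless",
                  "sitting", "wing_flapping", "head_shaking", "gasping",
                  "leg_paddling"),
    type = c("POINT", "POINT", "STATE", "STATE", "POINT", "POINT", "STATE"),
    start_s = c(t_lop, t_mot, 0, 15, 5, t_lop, 30),
    stop_s = c(t_lop, t_mot, 30, 18, 5, t_lop, 45))
  behaviour_record("bird1", "40C60N", 1, ev)
}

test_that("partition splits a spanning state at the anchor and conserves time", {
  parts <- partition_by_lop(fixture_record())
  sit_pre <- parts$pre[parts$pre$behaviour == "sitting", ]
  sit_post <- parts$post[parts$post$behaviour == "sitting", ]
  expect_equal(c(sit_pre$start_s, sit_pre$stop_s), c(0, 20))
  expect_equal(c(sit_post$start_s, sit_post$stop_s), c(20, 30))
  # a point event exactly at the anchor counts as post
  expect_false("gasping" %in% parts$pre$behaviour)
  expect_true("gasping" %in% parts$post$behaviour)
  # anchors themselves are excluded
  expect_false(any(c("loss_of_posture", "motionless") %in%
                     c(parts$pre$behaviour, parts$post$behaviour)))
  # total state time is conserved across the split
  dur <- function(d) sum(d$stop_s[d$type == "STATE"] - d$start_s[d$type == "STATE"])
  expect_equal(dur(parts$pre) + dur(parts$post), (30 - 0) + (18 - 15) + (45 - 30))
})

test_that("partition conserves state time on simulated cohorts", {
  recs <- simulate_behaviour_cohort(default_behaviour_cohort("20C80N", 6, seed = 9))
  for (r in recs) {
    parts <- partition_by_lop(r)
    ev <- r$events[!r$events$behaviour %in% c("loss_of_posture", "motionless"), ]
    orig <- sum(ev$stop_s[ev$type == "STATE"] - ev$start_s[ev$type == "STATE"])
    dur <- function(d) sum(d$stop_s[d$type == "STATE"] - d$start_s[d$type == "STATE"])
    expect_equal(dur(parts$pre) + dur(parts$post), orig, tolerance = 1e-12)
    # event counts: every non-anchor event lands in at least one side
    expect_gte(nrow(parts$pre) + nrow(parts$post), nrow(ev))
  }
})

test_that("per-bird summaries cover the full behaviour-by-phase grid", {
  s <- summarize_bird(fixture_record())
  expect_equal(nrow(s), 2 * 11)  # 11 non-anchor behaviours x 2 phases
  get <- function(b, p) s[s$behaviour == b & s$phase == p, ]
  expect_equal(get("sitting", "pre")$n_events, 1L)
  expect_equal(get("sitting", "pre")$total_duration_s, 20)
  expect_equal(get("sitting", "post")$total_duration_s, 10)
  expect_equal(get("head_shaking", "pre")$n_events, 1L)
  expect_equal(get("head_shaking", "pre")$total_duration_s, 0)
  expect_equal(get("leg_paddling", "post")$total_duration_s, 15)
  expect_equal(get("walking", "pre")$n_events, 0L)  # never expressed
  expect_equal(get("jumping", "post")$n_events, 0L)
})

test_that("cohort tables aggregate anchors, cycles and behaviours", {
  recs <- simulate_behaviour_cohort(default_behaviour_cohort("40C60N", 6, seed = 12))
  tb <- cohort_tables(recs)
  expect_equal(tb$anchor_table$n, 6)
  expect_equal(tb$anchor_table$lop_mean,
               mean(vapply(recs, function(r) r$t_lop, numeric(1))))
  expect_gte(tb$anchor_table$lop_min, 1)
  expect_lte(tb$anchor_table$lop_max, 240)
  expect_equal(nrow(tb$cycle_table), 2)  # 6 birds in cycles of 3
  expect_equal(tb$cycle_table$n, c(3, 3))
  bt <- tb$behaviour_table
  expect_true(all(bt$proportion >= 0 & bt$proportion <= 1))
  expect_true(all(is.na(bt$duration_mean[bt$type == "point"])))
  expect_true(all(bt$events_min <= bt$events_mean & bt$events_mean <= bt$events_max))

  # a single-bird cohort collapses mean, min and max
  tb1 <- cohort_tables(recs[1])
  b1 <- tb1$behaviour_table
  expect_equal(b1$events_min, b1$events_max)
  expect_equal(b1$events_mean, as.numeric(b1$events_min))
  expect_equal(tb1$anchor_table$lop_mean, recs[[1]]$t_lop)
})

test_that("unusable records are excluded from cohort aggregation", {
  good <- fixture_record()
  no_anchor <- behaviour_record("bird2", "40C60N", 1, tibble::tibble(
    behaviour = "loss_of_posture", type = "POINT", start_s = 20, stop_s = 20))
  expect_false(no_anchor$usable)
  tb <- cohort_tables(list(good, no_anchor))
  expect_equal(tb$anchor_table$n, 1)
  expect_error(cohort_tables(list(no_anchor)), "no usable")
})

test_that("first occurrences order by onset with catalogue-order ties", {
  ev <- tibble::tibble(
    behaviour = c("loss_of_posture", "motionless", "head_shaking",
                  "deep_inhalation", "sitting"),
    type = c("POINT", "POINT", "POINT", "POINT", "STATE"),
    start_s = c(30, 60, 5, 5, 1), stop_s = c(30, 60, 5, 5, 10))
  r <- behaviour_record("b", "40C60N", 1, ev)
  fo <- first_occurrence_order(r)
  expect_equal(fo$behaviour, c("sitting", "head_shaking", "deep_inhalation"))
  expect_equal(fo$tied, c(FALSE, TRUE, TRUE))
  # record with nothing before posture loss
  r2 <- behaviour_record("b2", "40C60N", 1, tibble::tibble(
    behaviour = c("loss_of_posture", "motionless"), type = "POINT",
    start_s = c(10, 50), stop_s = c(10, 50)))
  expect_equal(nrow(first_occurrence_order(r2)), 0)
})

test_that("event files round-trip and invalid ones are rejected", {
  recs <- simulate_behaviour_cohort(default_behaviour_cohort("40C90C", 3, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(recs, f)
  back <- read_events(f)
  expect_length(back, 3)
  for (r in recs) {
    b <- back[[r$subject_id]]
    expect_equal(b$t_lop, r$t_lop, tolerance = 1e-9)
    expect_equal(nrow(b$events), nrow(r$events))
    expect_equal(b$treatment_label, r$treatment_label)
  }

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,behavior,behavior_type,start_s,stop_s",
               "b1,preening,POINT,5,5"), g)
  expect_error(read_events(g), "not in the ethogram")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,behavior,behavior_type,start_s,stop_s",
               "b1,sitting,STATE,10,4"), h)
  expect_error(read_events(h), "stop before start")

  # missing-anchor subjects come back flagged unusable, not dropped
  j <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,behavior,behavior_type,start_s,stop_s",
               "b1,sitting,STATE,0,10"), j)
  expect_false(read_events(j)$b1$usable)
})
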