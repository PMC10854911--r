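#' Read behaviour event logs (BORIS-style CSV)
#'
#' Parses a tabular export with columns `subject`, `behavior`,
#' `behavior_type` (`POINT`/`STATE`), `start_s`, `stop_s` and optional
#' `treatment`, `cycle` columns into per-bird records. Point events are given
#' zero duration (`stop_s` equal to `start_s`). Labels are validated against
#' the ethogram; records missing a loss-of-posture or motionless anchor are
#' flagged unusable rather than dropped.
#'
#' @param path CSV file path
#' @param ethogram behaviour catalogue, default [default_ethogram()]
#' @param observation_length observation window, s (default 240)
#' @return list of [behaviour_record()] objects, one per subject
#' @export
read_events <- function(path, ethogram = default_ethogram(),
                        observation_length = 240) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(dat)[names(dat) == "behaviour"] <- "behavior"
  req <- c("subject", "behavior", "behavior_type", "start_s", "stop_s")
  if (!all(req %in% names(dat)))
    stop("event file needs columns ", paste(req, collapse = ", "))
  if (any(dat$stop_s < dat$start_s)) stop("event with stop before start")
  dat$stop_s[toupper(dat$behavior_type) == "POINT"] <-
    dat$start_s[toupper(dat$behavior_type) == "POINT"]
  split_idx <- split(seq_len(nrow(dat)), dat$subject)
  lapply(split_idx, function(idx) {
    d <- dat[idx, , drop = FALSE]
    behaviour_record(
      subject_id = d$subject[1],
      treatment_label = if ("treatment" %in% names(d)) d$treatment[1] else "unknown",
      cycle_id = if ("cycle" %in% names(d)) d$cycle[1] else NA_integer_,
      events = tibble::tibble(behaviour = d$behavior,
                              type = toupper(d$behavior_type),
                              start_s = d$start_s, stop_s = d$stop_s),
      observation_length = observation_length,
      ethogram = ethogram)
  })
}

#' Write behaviour records as a BORIS-style CSV
#'
#' @param records list of [behaviour_record()]s
#' @param path output path
#' @return `path`, invisibly
#' @export
write_events <- function(records, path) {
  rows <- lapply(records, function(r) {
    tibble::tibble(subject = r$subject_id, treatment = r$treatment_label,
                   cycle = r$cycle_id, behavior = r$events$behaviour,
                   behavior_type = r$events$type,
                   start_s = r$events$start_s, stop_s = r$events$stop_s)
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Partition a record's events around loss of posture
#'
#' Splits the non-anchor events of a record into those occurring before and
#' after the loss-of-posture anchor. Point events go to one side by their
#' time stamp (an event exactly at the anchor counts as post: the bird is no
#' longer standing). State events spanning the anchor are split into a pre
#' part ending at the anchor and a post part starting there, so counts on
#' each side are whole events but the union of parts reproduces the original
#' timeline exactly.
#'
#' @param record a [behaviour_record()] with a loss-of-posture anchor
#' @return list with tibbles `pre` and `post`
#' @export
partition_by_lop <- function(record) {
  stopifnot(inherits(record, "behaviour_record"))
  if (is.na(record$t_lop)) stop("record has no loss_of_posture anchor")
  ev <- record$events[record$events$behaviour != "loss_of_posture" &
                        record$events$behaviour != "motionless", , drop = FALSE]
  lop <- record$t_lop
  pre <- ev[ev$start_s < lop, , drop = FALSE]
  pre$stop_s <- pmin(pre$stop_s, lop)
  post <- ev[ev$stop_s > lop | (ev$start_s >= lop), , drop = FALSE]
  post$start_s <- pmax(post$start_s, lop)
  # point events sitting exactly on the anchor belong to one side only
  pre <- pre[!(pre$type == "POINT" & pre$start_s >= lop), , drop = FALSE]
  post <- post[!(post$type == "POINT" & post$start_s < lop), , drop = FALSE]
  post <- post[!(post$type == "STATE" & post$stop_s <= post$start_s), , drop = FALSE]
  pre <- pre[!(pre$type == "STATE" & pre$stop_s <= pre$start_s), , drop = FALSE]
  list(pre = pre, post = post)
}

#' Per-bird behaviour summary by phase
#'
#' Event counts and total state durations for each ethogram behaviour before
#' and after loss of posture. Behaviours the bird never expressed appear as
#' zero rows, so cohort aggregation sees every bird in every cell.
#'
#' @param record a [behaviour_record()]
#' @param ethogram behaviour catalogue
#' @return tibble with `behaviour`, `phase` (`pre`/`post`), `type`,
#'   `n_events`, `total_duration_s` (0 for point behaviours)
#' @export
summarize_bird <- function(record, ethogram = default_ethogram()) {
  parts <- partition_by_lop(record)
  beh <- ethogram[ethogram$type != "anchor", , drop = FALSE]
  grid <- tibble::tibble(
    behaviour = rep(beh$behaviour, 2),
    type = rep(beh$type, 2),
    phase = rep(c("pre", "post"), each = nrow(beh)))
  one <- function(ev, phase_label) {
    if (nrow(ev) == 0)
      return(tibble::tibble(behaviour = character(0), phase = character(0),
                            n_events = integer(0), total_duration_s = numeric(0)))
    agg <- dplyr::summarise(
      dplyr::group_by(ev, .data$behaviour),
      n_events = dplyr::n(),
      total_duration_s = sum(.data$stop_s - .data$start_s),
      .groups = "drop")
    agg$phase <- phase_label
    agg
  }
  obs <- dplyr::bind_rows(one(parts$pre, "pre"), one(parts$post, "post"))
  out <- dplyr::left_join(grid, obs, by = c("behaviour", "phase"))
  out$n_events[is.na(out$n_events)] <- 0L
  out$total_duration_s[is.na(out$total_duration_s)] <- 0
  out
}

#' Cohort summary tables
#'
#' Aggregates per-bird summaries into the standard reporting layout: an
#' anchor-time table (mean and min-max of time to loss of posture and to
#' motionlessness per treatment, plus per-cycle means for cycle-level
#' inspection) and a behaviour table giving, per treatment, behaviour and
#' phase, the proportion of birds expressing the behaviour (k/n), events per
#' bird (mean, min-max) and total duration per bird (mean, min-max; state
#' behaviours only). Only usable records (both anchors present) contribute.
#'
#' @param records list of [behaviour_record()]s
#' @param ethogram behaviour catalogue
#' @return list with tibbles `anchor_table`, `cycle_table`, `behaviour_table`
#' @export
cohort_tables <- function(records, ethogram = default_ethogram()) {
  records <- Filter(function(r) r$usable, records)
  if (length(records) == 0) stop("no usable records")
  anchors <- dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(subject = r$subject_id, treatment = r$treatment_label,
                   cycle = r$cycle_id, t_lop = r$t_lop,
                   t_motionless = r$t_motionless)
  }))
  anchor_table <- dplyr::summarise(
    dplyr::group_by(anchors, .data$treatment),
    n = dplyr::n(),
    lop_mean = mean(.data$t_lop), lop_min = min(.data$t_lop),
    lop_max = max(.data$t_lop),
    motionless_mean = mean(.data$t_motionless),
    motionless_min = min(.data$t_motionless),
    motionless_max = max(.data$t_motionless),
    .groups = "drop")
  cycle_table <- dplyr::summarise(
    dplyr::group_by(anchors, .data$treatment, .data$cycle),
    n = dplyr::n(), lop_mean = mean(.data$t_lop),
    motionless_mean = mean(.data$t_motionless), .groups = "drop")

  per_bird <- dplyr::bind_rows(lapply(records, function(r) {
    s <- summarize_bird(r, ethogram)
    s$subject <- r$subject_id
    s$treatment <- r$treatment_label
    s
  }))
  behaviour_table <- dplyr::summarise(
    dplyr::group_by(per_bird, .data$treatment, .data$behaviour, .data$phase,
                    .data$type),
    n = dplyr::n(),
    k = sum(.data$n_events > 0),
    proportion = .data$k / .data$n,
    events_mean = mean(.data$n_events),
    events_min = min(.data$n_events), events_max = max(.data$n_events),
    duration_mean = mean(.data$total_duration_s),
    duration_min = min(.data$total_duration_s),
    duration_max = max(.data$total_duration_s),
    .groups = "drop")
  pt <- behaviour_table$type == "point"
  behaviour_table$duration_mean[pt] <- NA_real_
  behaviour_table$duration_min[pt] <- NA_real_
  behaviour_table$duration_max[pt] <- NA_real_
  list(anchor_table = anchor_table, cycle_table = cycle_table,
       behaviour_table = behaviour_table)
}

#' Order of first behaviour occurrences before loss of posture
#'
#' Ranks the behaviours a bird expressed before losing posture by their first
#' onset time. Simultaneous onsets are kept in catalogue order and flagged as
#' tied.
#'
#' @param record a [behaviour_record()]
#' @param ethogram behaviour catalogue (its row order breaks ties)
#' @return tibble with `behaviour`, `first_onset_s`, `tied`, ordered by onset
#' @export
first_occurrence_order <- function(record, ethogram = default_ethogram()) {
  pre <- partition_by_lop(record)$pre
  if (nrow(pre) == 0)
    return(tibble::tibble(behaviour = character(0), first_onset_s = numeric(0),
                          tied = logical(0)))
  firsts <- dplyr::summarise(dplyr::group_by(pre, .data$behaviour),
                             first_onset_s = min(.data$start_s), .groups = "drop")
  cat_order <- match(firsts$behaviour, ethogram$behaviour)
  firsts <- firsts[order(firsts$first_onset_s, cat_order), , drop = FALSE]
  firsts$tied <- duplicated(firsts$first_onset_s) |
    duplicated(firsts$first_onset_s, fromLast = TRUE)
  firsts
}
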