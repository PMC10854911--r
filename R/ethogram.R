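#' Default ethogram for gas-stunning observations
#'
#' The behaviour catalogue used to code broiler observations during gas
#' exposure. Two anchor events occur exactly once per bird: `loss_of_posture`
#' (cessation of standing with the head resting, the behavioural proxy for
#' loss of consciousness) and `motionless` (limp carcass, proxy for brain
#' death). State behaviours carry a duration (sitting, standing, walking,
#' ataxia, wing flapping, leg paddling); point behaviours are counted only
#' (head shaking, deep inhalation, gasping, jumping, high-pitch vocalisation).
#' `phase` records where a behaviour is scored relative to loss of posture:
#' `pre`, `post`, or `both`.
#'
#' @return tibble with columns `behaviour`, `type` (`point`/`state`/`anchor`),
#'   `phase` (`pre`/`post`/`both`/`anchor`)
#' @export
default_ethogram <- function() {
  tibble::tibble(
    behaviour = c("loss_of_posture", "motionless",
                  "sitting", "standing", "walking", "ataxia",
                  "wing_flapping", "leg_paddling",
                  "head_shaking", "deep_inhalation", "gasping", "jumping", "HPV"),
    type = c("anchor", "anchor",
             "state", "state", "state", "state", "state", "state",
             "point", "point", "point", "point", "point"),
    phase = c("anchor", "anchor",
              "pre", "pre", "pre", "pre", "both", "post",
              "pre", "pre", "both", "post", "both"))
}

ethogram_check_label <- function(labels, ethogram = default_ethogram()) {
  bad <- setdiff(unique(labels), ethogram$behaviour)
  if (length(bad) > 0)
    stop("behaviour label(s) not in the ethogram: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Per-bird behaviour record
#'
#' Timed ethogram events for one bird with its loss-of-posture and motionless
#' anchors. Point events have `start_s == stop_s`; state events have
#' `start_s < stop_s`. A record missing either anchor is flagged unusable
#' rather than rejected.
#'
#' @param subject_id,treatment_label,cycle_id identifying labels
#' @param events tibble with columns `behaviour`, `type` (`POINT`/`STATE`),
#'   `start_s`, `stop_s`, including the anchor events as points
#' @param observation_length observation window length, s (default 240)
#' @param ethogram catalogue used to validate labels
#' @return list of class `behaviour_record` with `t_lop`, `t_motionless`
#'   (`NA` when the anchor is missing) and `usable`
#' @export
behaviour_record <- function(subject_id, treatment_label, cycle_id, events,
                             observation_length = 240,
                             ethogram = default_ethogram()) {
  req <- c("behaviour", "type", "start_s", "stop_s")
  if (!all(req %in% names(events)))
    stop("events need columns ", paste(req, collapse = ", "))
  ethogram_check_label(events$behaviour, ethogram)
  if (any(events$stop_s < events$start_s))
    stop("event with stop before start")
  if (any(events$start_s < 0) ||
      any(events$stop_s > observation_length + 1e-9))
    stop("event times outside the observation window")
  st <- events$type == "STATE"
  if (any(st & events$stop_s <= events$start_s))
    stop("state events must have start < stop")
  anchor_time <- function(label) {
    i <- which(events$behaviour == label)
    if (length(i) == 0) return(NA_real_)
    if (length(i) > 1) stop("anchor '", label, "' must occur exactly once")
    events$start_s[i]
  }
  t_lop <- anchor_time("loss_of_posture")
  t_mot <- anchor_time("motionless")
  usable <- !is.na(t_lop) && !is.na(t_mot)
  if (usable && t_lop >= t_mot)
    stop("loss_of_posture must precede motionless")
  structure(list(
    subject_id = as.character(subject_id),
    treatment_label = as.character(treatment_label),
    cycle_id = cycle_id,
    events = tibble::as_tibble(events),
    t_lop = t_lop, t_motionless = t_mot,
    observation_length = observation_length,
    usable = usable
  ), class = "behaviour_record")
}

#' @export
print.behaviour_record <- function(x, ...) {
  cat(sprintf("<behaviour_record> %s (%s, cycle %s): %d events, LOP %s, motionless %s%s\n",
              x$subject_id, x$treatment_label, as.character(x$cycle_id),
              nrow(x$events),
              ifelse(is.na(x$t_lop), "missing", sprintf("%.1f s", x$t_lop)),
              ifelse(is.na(x$t_motionless), "missing", sprintf("%.1f s", x$t_motionless)),
              if (x$usable) "" else " [UNUSABLE]"))
  invisible(x)
}
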