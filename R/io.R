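# Session event logs (JSONL), structured configuration (YAML).

SCHEMA_VERSION <- 1L

EVENT_TYPES <- c("trial", "utterance", "reminder", "alert", "fatigue",
                 "assessment", "action")

#' Construct a session event log
#'
#' An ordered log of events for one session: trials, utterances, reminders,
#' alerts, fatigue reports, assessments and coordination actions. Each
#' event is a list with `t` (session-relative seconds), `type` and a named
#' `payload` list.
#'
#' @param participant_id Participant identifier.
#' @param session_index 1-based session number.
#' @param slot_index Schedule slot the session belongs to.
#' @param completed Was the session completed?
#' @param duration_minutes Session duration (NA for skipped sessions).
#' @param date Session date (string or Date).
#' @param events List of events.
#' @return An object of class `session_log`.
#' @export
session_log <- function(participant_id, session_index, slot_index,
                        completed = TRUE, duration_minutes = NA_real_,
                        date = NA_character_, events = list()) {
  for (e in events) {
    if (!is.list(e) || is.null(e$type) || !e$type %in% EVENT_TYPES)
      stop("unknown or malformed event type: ",
           if (is.list(e)) e$type else "<not a list>", call. = FALSE)
  }
  structure(list(schema_version = SCHEMA_VERSION,
                 participant_id = participant_id,
                 session_index = as.integer(session_index),
                 slot_index = as.integer(slot_index),
                 completed = isTRUE(completed),
                 duration_minutes = as.numeric(duration_minutes),
                 date = as.character(date),
                 events = events),
            class = "session_log")
}

#' Extract events of one type as a data frame
#'
#' Flattens the payloads of all events of the given type into a data frame
#' with a leading `t` column.
#'
#' @param log A [session_log()].
#' @param type Event type.
#' @return Data frame (zero rows when no such events).
#' @export
events_of_type <- function(log, type) {
  ev <- Filter(function(e) e$type == type, log$events)
  if (length(ev) == 0) return(data.frame())
  rows <- lapply(ev, function(e) {
    c(list(t = e$t), e$payload)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a session log as JSONL
#'
#' First line is the session header (schema version, identifiers,
#' completion, duration); each further line is one event in order.
#'
#' @param log A [session_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  meta <- list(schema_version = log$schema_version, record = "meta",
               participant_id = log$participant_id,
               session_index = log$session_index,
               slot_index = log$slot_index,
               completed = log$completed,
               duration_minutes = log$duration_minutes,
               date = log$date)
  lines <- c(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             vapply(log$events, function(e)
               as.character(jsonlite::toJSON(
                 list(t = e$t, type = e$type, payload = e$payload),
                 auto_unbox = TRUE, digits = NA, null = "null", na = "null")),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a session log from JSONL
#'
#' Inverse of [write_session_log()]; write-then-read is an identity on the
#' log structure. Malformed lines raise a parse error naming the line;
#' unknown event types raise a schema error.
#'
#' @param path JSONL file path.
#' @return A [session_log()]; an empty file yields an empty log.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(session_log(NA_character_, 0, 0, completed = FALSE))
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e)
               stop("parse error in ", path, " at line ", i, ": ",
                    conditionMessage(e), call. = FALSE))
  }
  meta <- parse_line(1)
  if (is.null(meta$record) || meta$record != "meta")
    stop("parse error in ", path, " at line 1: missing session header",
         call. = FALSE)
  events <- lapply(seq_along(lines)[-1], function(i) {
    e <- parse_line(i)
    if (is.null(e$type) || !e$type %in% EVENT_TYPES)
      stop("schema error in ", path, " at line ", i,
           ": unknown event type '", e$type, "'", call. = FALSE)
    list(t = as.numeric(e$t), type = e$type,
         payload = lapply(e$payload, identity))
  })
  session_log(participant_id = meta$participant_id,
              session_index = meta$session_index,
              slot_index = meta$slot_index,
              completed = isTRUE(meta$completed),
              duration_minutes = if (is.null(meta$duration_minutes))
                NA_real_ else as.numeric(meta$duration_minutes),
              date = if (is.null(meta$date)) NA_character_
                     else as.character(meta$date),
              events = events)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session %s/%d (slot %d, %s): %d events\n",
              x$participant_id, x$session_index, x$slot_index,
              if (x$completed) sprintf("completed, %.1f min", x$duration_minutes)
              else "skipped",
              length(x$events)))
  invisible(x)
}

#' Default run configuration
#'
#' All engine, coordination, safety, protocol, simulation and instrument
#' parameters with their defaults. The engine target success (0.85) and
#' load weights (0.4, 0.35, 0.25) are the intervention's stated design
#' parameters; the remaining values are engine and simulator choices,
#' documented in the package vignette.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = SCHEMA_VERSION,
    engine = list(
      discrimination = 1.0, learning_rate = 0.5, target_success = 0.85,
      b_min = -3, b_max = 3, theta_min = -4, theta_max = 4,
      mle_window = 100, smoothing = 0.8, update_from_outcome = FALSE,
      w1 = 0.4, w2 = 0.35, w3 = 0.25,
      load_low_cut = 0.5, load_high_cut = 1.2
    ),
    coordination = list(
      context_capacity = 5, delta_b_easy = 0.5, emotion_rate = 0.3,
      fallback_persona = "companion",
      contradictions = list(c("suggest_activity", "suggest_break"),
                            c("train", "rest"),
                            c("suggest_activity", "rest"))
    ),
    safety = list(
      na_k_sd = 1.5, na_consecutive = 2,
      fatigue_threshold = 7, fatigue_consecutive = 3,
      cars_k_sd = 2, cars_norm_mean = 2.0, cars_norm_sd = 0.5,
      sample_fraction = 0.10
    ),
    protocol = list(
      weeks = 6, sessions_per_week = 5, session_minutes = 30,
      start_date = "2026-01-05",
      morning_anchor = "09:00", afternoon_anchor = "15:00"
    ),
    simulate = list(
      n_enrolled = 14, attrition_rate = 0.10, seed = 1,
      theta_mean = 0, theta_sd = 1, day_sd = 0.1,
      rt_median = 2.5, rt_sigma = 0.4,
      na_baseline_mean = 15, na_baseline_sd = 4, na_phi = 0.5,
      fatigue_gain = 0.02, skip_prob = 0.1,
      trial_overhead_s = 60, guessing = 0,
      sus_mean = 75, sus_sd = 10
    ),
    instruments = list(
      panas_na_items = c(2, 4, 6, 7, 8, 11, 13, 15, 18, 20),
      bpns_autonomy = c(1, 4, 8, 11, 14, 17, 20),
      bpns_competence = c(3, 5, 10, 13, 15, 19),
      bpns_relatedness = c(2, 6, 7, 9, 12, 16, 18, 21),
      bpns_reverse = integer(0)
    )
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Rejects unknown keys (relative to [default_config()]) and out-of-range
#' threshold values.
#'
#' @param config A configuration list.
#' @return The validated config (invisibly classed `run_config`).
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown_top <- setdiff(names(config), names(ref))
  if (length(unknown_top))
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  for (sec in setdiff(names(ref), "schema_version")) {
    if (is.null(config[[sec]])) next
    unknown <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  e <- config$engine
  if (!is.null(e)) {
    # constructor enforces engine ranges
    difficulty_policy(e$discrimination %||% 1, e$learning_rate %||% 0.5,
                      e$target_success %||% 0.85, e$b_min %||% -3,
                      e$b_max %||% 3, e$theta_min %||% -4, e$theta_max %||% 4,
                      e$mle_window %||% 100)
    load_weights(e$w1 %||% 0.4, e$w2 %||% 0.35, e$w3 %||% 0.25)
    if (!is.null(e$smoothing) && (e$smoothing < 0 || e$smoothing > 1))
      stop("engine.smoothing must lie in [0, 1]", call. = FALSE)
    lc <- e$load_low_cut %||% 0.5; hc <- e$load_high_cut %||% 1.2
    if (!(lc >= 0 && lc < hc && hc <= 2))
      stop("load cut points must satisfy 0 <= low < high <= 2", call. = FALSE)
  }
  s <- config$safety
  if (!is.null(s)) {
    if (!is.null(s$sample_fraction) &&
        (s$sample_fraction <= 0 || s$sample_fraction > 1))
      stop("safety.sample_fraction must lie in (0, 1]", call. = FALSE)
    if (!is.null(s$fatigue_threshold) &&
        (s$fatigue_threshold < 0 || s$fatigue_threshold > 10))
      stop("safety.fatigue_threshold must lie in [0, 10]", call. = FALSE)
  }
  sim <- config$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$skip_prob) && (sim$skip_prob < 0 || sim$skip_prob > 1))
      stop("simulate.skip_prob must lie in [0, 1]", call. = FALSE)
    if (!is.null(sim$attrition_rate) &&
        (sim$attrition_rate < 0 || sim$attrition_rate >= 1))
      stop("simulate.attrition_rate must lie in [0, 1)", call. = FALSE)
    if (!is.null(sim$day_sd) && sim$day_sd < 0)
      stop("simulate.day_sd must be >= 0", call. = FALSE)
  }
  invisible(structure(config, class = "run_config"))
}

#' Load a configuration file
#'
#' Reads a YAML configuration, fills unset keys with defaults and
#' validates.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  merged <- merge_config(default_config(), user)
  validate_config(merged)
  merged
}

merge_config <- function(ref, user) {
  out <- ref
  for (sec in names(user)) {
    if (is.list(ref[[sec]]) && is.list(user[[sec]])) {
      for (k in names(user[[sec]])) out[[sec]][[k]] <- user[[sec]][[k]]
    } else {
      out[[sec]] <- user[[sec]]
    }
  }
  out
}

#' Write a configuration file
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Difficulty policy from a configuration
#'
#' @param config A `run_config`.
#' @return A [difficulty_policy()].
#' @export
policy_from_config <- function(config = default_config()) {
  e <- config$engine
  difficulty_policy(discrimination = e$discrimination,
                    learning_rate = e$learning_rate,
                    target_success = e$target_success,
                    b_min = e$b_min, b_max = e$b_max,
                    theta_min = e$theta_min, theta_max = e$theta_max,
                    mle_window = e$mle_window,
                    update_from_outcome = e$update_from_outcome)
}
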