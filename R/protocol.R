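# Six-week protocol: schedule generation, task placement, adherence
# metrics, feasibility criteria, enrollment arithmetic.

#' Build the intervention schedule
#'
#' Generates `weeks * sessions_per_week` session slots on weekdays
#' (Monday-Friday by default), starting the Monday on or after
#' `start_date`. Each slot holds a morning cognitive block and an afternoon
#' social block: cognitive tasks are scheduled in the morning when cognitive
#' performance peaks, social activities in the afternoon. The default
#' protocol is 30 sessions over six weeks (five sessions/week, 30
#' min/session; 15 hours total).
#'
#' @param weeks Number of intervention weeks.
#' @param sessions_per_week Sessions per week (1-7).
#' @param session_minutes Session duration in minutes.
#' @param start_date Date (or string) the schedule may begin; sessions start
#'   the following Monday (or that day if a Monday).
#' @param morning_anchor,afternoon_anchor Clock times ("HH:MM") anchoring
#'   the cognitive and social blocks.
#' @return An object of class `study_schedule` with a `slots` data frame
#'   (index, week, date, cognitive_start, social_start, minutes).
#' @export
#' @examples
#' sched <- build_schedule()
#' nrow(sched$slots)                # 30
#' sum(sched$slots$minutes) / 60    # 15 hours
build_schedule <- function(weeks = 6, sessions_per_week = 5,
                           session_minutes = 30,
                           start_date = as.Date("2026-01-05"),
                           morning_anchor = "09:00",
                           afternoon_anchor = "15:00") {
  if (weeks < 1 || sessions_per_week < 1 || session_minutes < 1)
    stop("weeks, sessions_per_week and session_minutes must be >= 1",
         call. = FALSE)
  if (sessions_per_week > 7)
    stop("sessions_per_week cannot exceed 7", call. = FALSE)
  start_date <- as.Date(start_date)
  # advance to Monday (ISO weekday 1)
  wd <- as.integer(format(start_date, "%u"))
  first_monday <- start_date + ((8 - wd) %% 7)
  slots <- do.call(rbind, lapply(seq_len(weeks), function(w) {
    days <- first_monday + 7 * (w - 1) + (seq_len(sessions_per_week) - 1)
    data.frame(week = w, date = days)
  }))
  slots$index <- seq_len(nrow(slots))
  slots$cognitive_start <- morning_anchor
  slots$social_start <- afternoon_anchor
  slots$minutes <- session_minutes
  slots <- slots[, c("index", "week", "date", "cognitive_start",
                     "social_start", "minutes")]
  structure(list(weeks = weeks, sessions_per_week = sessions_per_week,
                 session_minutes = session_minutes, slots = slots),
            class = "study_schedule")
}

#' Place a task into a session block
#'
#' Cognitive tasks go to the morning block, social activities to the
#' afternoon block.
#'
#' @param task_kind `"cognitive"` or `"social"`.
#' @param slot One row of a schedule's `slots` data frame.
#' @return List with `block` (`"morning"`/`"afternoon"`) and `start` (clock
#'   time).
#' @export
place_task <- function(task_kind, slot) {
  switch(task_kind,
         cognitive = list(block = "morning", start = slot$cognitive_start),
         social = list(block = "afternoon", start = slot$social_start),
         stop("unknown task kind: ", task_kind, call. = FALSE))
}

#' Adherence metrics from session logs
#'
#' Computes the exploratory digital adherence metrics over a schedule and
#' its session logs: session completion rate (percent of scheduled sessions
#' completed), mean session duration over completed sessions (absent, NA,
#' when none were completed), task completion rate (percent of initiated
#' trials carrying a terminal status), per-persona counts of user-initiated
#' interactions, and the least-squares slope of per-session mean response
#' latency against session index (seconds/session).
#'
#' @param schedule A [build_schedule()] result.
#' @param logs List of `session_log` objects referencing slots of the
#'   schedule.
#' @return An object of class `adherence_report`.
#' @export
adherence_metrics <- function(schedule, logs) {
  scheduled <- nrow(schedule$slots)
  slot_ids <- vapply(logs, function(l) l$slot_index, numeric(1))
  if (any(!slot_ids %in% schedule$slots$index))
    stop("log references a slot not in the schedule", call. = FALSE)
  completed <- vapply(logs, function(l) isTRUE(l$completed), logical(1))
  durations <- vapply(logs, function(l) l$duration_minutes %||% NA_real_,
                      numeric(1))
  mean_duration <- if (any(completed))
    mean(durations[completed], na.rm = TRUE) else NA_real_

  # trial-level metrics across completed sessions
  n_trials <- 0L; n_terminal <- 0L
  latency <- data.frame(session = numeric(0), mean_rt = numeric(0))
  interactions <- stats::setNames(rep(0L, 3), persona_ids())
  for (l in logs) {
    trials <- events_of_type(l, "trial")
    if (nrow(trials) > 0) {
      n_trials <- n_trials + nrow(trials)
      n_terminal <- n_terminal + sum(isTRUE_vec(trials$completed))
      latency <- rbind(latency,
                       data.frame(session = l$session_index,
                                  mean_rt = mean(trials$response_time)))
    }
    utts <- events_of_type(l, "utterance")
    if (nrow(utts) > 0) {
      user <- utts[utts$speaker == "user", , drop = FALSE]
      if (nrow(user) > 0) {
        tab <- table(factor(user$addressee, levels = persona_ids()))
        interactions <- interactions + as.integer(tab)
      }
    }
  }
  trend <- if (nrow(latency) >= 2)
    unname(stats::coef(stats::lm(mean_rt ~ session, data = latency))[2])
  else NA_real_

  structure(list(
    scheduled_sessions = scheduled,
    completed_sessions = sum(completed),
    session_completion_rate = 100 * sum(completed) / scheduled,
    mean_session_duration = mean_duration,
    task_completion_rate = if (n_trials > 0) 100 * n_terminal / n_trials
                           else NA_real_,
    agent_interaction_frequency = interactions,
    response_latency_trend = trend
  ), class = "adherence_report")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the feasibility criteria
#'
#' The protocol passes feasibility iff (1) session completion >= 70%,
#' (2) SUS >= 70, and (3) no sustained negative affect requiring
#' discontinuation.
#'
#' @param report An [adherence_metrics()] report (or any list with a
#'   `session_completion_rate` field).
#' @param sus_score SUS score in \[0, 100\] (cohort mean or individual).
#' @param negative_affect_discontinuation Logical: was any sustained
#'   negative-affect discontinuation triggered?
#' @param completion_threshold,sus_threshold Criterion thresholds.
#' @return An object of class `feasibility_verdict`: list with `pass` and a
#'   per-criterion `criteria` data frame.
#' @export
evaluate_feasibility <- function(report, sus_score,
                                 negative_affect_discontinuation = FALSE,
                                 completion_threshold = 70,
                                 sus_threshold = 70) {
  if (!is.finite(sus_score) || sus_score < 0 || sus_score > 100)
    stop("sus_score must lie in [0, 100]", call. = FALSE)
  completion <- report$session_completion_rate
  criteria <- data.frame(
    criterion = c("session_completion", "usability", "emotional_safety"),
    value = c(completion, sus_score,
              as.numeric(!negative_affect_discontinuation)),
    threshold = c(completion_threshold, sus_threshold, 1),
    met = c(completion >= completion_threshold,
            sus_score >= sus_threshold,
            !negative_affect_discontinuation)
  )
  structure(list(pass = all(criteria$met), criteria = criteria),
            class = "feasibility_verdict")
}

#' Enrollment size under anticipated attrition
#'
#' Smallest n such that `floor((1 - attrition_rate) * n)` meets the required
#' number of completers. With 12 required completers and 10% anticipated
#' attrition this yields an enrollment of 14.
#'
#' @param required_completers Number of completers needed (>= 1).
#' @param attrition_rate Anticipated attrition in \[0, 1).
#' @return Integer enrollment size.
#' @export
#' @examples
#' enrollment_size(12, 0.10)  # 14
enrollment_size <- function(required_completers, attrition_rate) {
  if (!is.finite(attrition_rate) || attrition_rate < 0 || attrition_rate >= 1)
    stop("attrition_rate must lie in [0, 1)", call. = FALSE)
  if (required_completers < 1)
    stop("required_completers must be >= 1", call. = FALSE)
  n <- as.integer(required_completers)
  repeat {
    if (floor((1 - attrition_rate) * n + 1e-9) >= required_completers)
      return(n)
    n <- n + 1L
  }
}

#' @export
print.study_schedule <- function(x, ...) {
  cat(sprintf("Study schedule: %d weeks x %d sessions/week x %d min = %d sessions (%.1f h)\n",
              x$weeks, x$sessions_per_week, x$session_minutes,
              nrow(x$slots), sum(x$slots$minutes) / 60))
  cat(sprintf("  %s to %s; cognitive block %s, social block %s\n",
              min(x$slots$date), max(x$slots$date),
              x$slots$cognitive_start[1], x$slots$social_start[1]))
  invisible(x)
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("Adherence report\n")
  cat(sprintf("  session completion: %.1f%% (%d/%d)\n",
              x$session_completion_rate, x$completed_sessions,
              x$scheduled_sessions))
  cat(sprintf("  mean session duration: %s min\n",
              if (is.na(x$mean_session_duration)) "absent"
              else sprintf("%.1f", x$mean_session_duration)))
  cat(sprintf("  task completion: %s%%\n",
              if (is.na(x$task_completion_rate)) "absent"
              else sprintf("%.1f", x$task_completion_rate)))
  cat(sprintf("  user-initiated interactions: coach %d, teacher %d, companion %d\n",
              x$agent_interaction_frequency[["coach"]],
              x$agent_interaction_frequency[["teacher"]],
              x$agent_interaction_frequency[["companion"]]))
  cat(sprintf("  response latency trend: %s s/session\n",
              if (is.na(x$response_latency_trend)) "absent"
              else sprintf("%+.3f", x$response_latency_trend)))
  invisible(x)
}

#' @export
print.feasibility_verdict <- function(x, ...) {
  cat(sprintf("Feasibility: %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$criteria))) {
    r <- x$criteria[i, ]
    cat(sprintf("  %-20s %6.1f (threshold %g): %s\n", r$criterion, r$value,
                r$threshold, if (r$met) "met" else "NOT met"))
  }
  invisible(x)
}

#' Export a schedule as CSV
#'
#' One row per slot: index, week, date, block anchors and duration.
#'
#' @param schedule A [build_schedule()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$slots, path, row.names = FALSE)
  invisible(path)
}
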