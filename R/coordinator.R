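# Tri-persona coordination: event routing, action proposal, conflict
# resolution, context window, reminder escalation, emotion tracking,
# single-agent fallback.

PERSONAS <- c("coach", "teacher", "companion")

ACTION_TYPES <- c("train", "encourage", "suggest_break", "suggest_activity",
                  "empathize", "remind", "rest")

# Safety-conservative total order: lower rank = more conservative.
# "remind" is neutral plumbing and sits between encourage and train.
SAFETY_RANK <- c(rest = 1, suggest_break = 2, empathize = 3, encourage = 4,
                 remind = 5, train = 6, suggest_activity = 7)

#' The three persona identifiers
#'
#' @return Character vector `c("coach", "teacher", "companion")`.
#' @export
persona_ids <- function() PERSONAS

#' Valence-arousal emotion state
#'
#' Two-dimensional affect representation; both components are clipped to
#' \[-1, 1\].
#'
#' @param valence,arousal Affect coordinates.
#' @return An object of class `emotion_state`.
#' @export
emotion_state <- function(valence = 0, arousal = 0) {
  clip1 <- function(x) min(1, max(-1, x))
  structure(list(valence = clip1(valence), arousal = clip1(arousal)),
            class = "emotion_state")
}

#' Coordination state shared across personas
#'
#' Mirrors the engine difficulty, carries the current emotion estimate and
#' load band, and records the interaction mode. In single-agent mode all
#' events are handled by the fallback persona (the companion by default).
#'
#' @param difficulty Current task difficulty (logit scale).
#' @param emotion An [emotion_state()].
#' @param load_band One of `"low"`, `"moderate"`, `"high"`.
#' @param mode `"multi_agent"` or `"single_agent"`.
#' @param fallback_persona Persona used in single-agent mode.
#' @return An object of class `coordination_state`.
#' @export
coordination_state <- function(difficulty = 0, emotion = emotion_state(),
                               load_band = "moderate", mode = "multi_agent",
                               fallback_persona = "companion") {
  stopifnot(load_band %in% c("low", "moderate", "high"),
            mode %in% c("multi_agent", "single_agent"),
            fallback_persona %in% PERSONAS)
  structure(list(difficulty = difficulty, emotion = emotion,
                 load_band = load_band, mode = mode,
                 fallback_persona = fallback_persona,
                 active_persona = if (mode == "single_agent") fallback_persona
                                  else "companion"),
            class = "coordination_state")
}

#' An action proposed by a persona
#'
#' @param persona One of the three persona ids.
#' @param action_type One of train, encourage, suggest_break,
#'   suggest_activity, empathize, remind, rest.
#' @param payload Template text or a named list (e.g. a difficulty for a
#'   train action).
#' @return An object of class `agent_action` with its `safety_rank`.
#' @export
agent_action <- function(persona, action_type, payload = list()) {
  if (!persona %in% PERSONAS) stop("unknown persona: ", persona, call. = FALSE)
  if (!action_type %in% ACTION_TYPES)
    stop("unknown action type: ", action_type, call. = FALSE)
  structure(list(persona = persona, action_type = action_type,
                 payload = payload,
                 safety_rank = unname(SAFETY_RANK[action_type])),
            class = "agent_action")
}

#' Route an event to the persona responsible for it
#'
#' Activity planning goes to the coach (daily activity management,
#' behavioral nudges), cognitive tasks to the teacher (memory, attention,
#' language training), emotional cues to the companion (emotional support,
#' reminiscence). In single-agent mode every event goes to the fallback
#' persona.
#'
#' @param kind Event kind: `"activity_planning"`, `"cognitive_task"` or
#'   `"emotional_cue"`.
#' @param state A [coordination_state()].
#' @return A persona id.
#' @export
route_event <- function(kind, state = coordination_state()) {
  routes <- c(activity_planning = "coach", cognitive_task = "teacher",
              emotional_cue = "companion")
  if (!kind %in% names(routes))
    stop("cannot route unknown event kind: ", kind, call. = FALSE)
  if (state$mode == "single_agent") return(state$fallback_persona)
  unname(routes[kind])
}

#' Propose coordinated persona actions for the current situation
#'
#' Encodes the coordination scenarios as deterministic rules. When error
#' rates are rising under high load, the companion encourages while the
#' coach suggests a break. At session start under negative valence, the
#' teacher begins with easier exercises (difficulty reduced by
#' `delta_b_easy`) and the coach suggests a mood-lifting activity. The
#' default path is a teacher training action at the current difficulty.
#'
#' @param state A [coordination_state()].
#' @param error_rate_rising Logical, recent error trend.
#' @param load_band Load band of the current trial block (defaults to the
#'   state's band).
#' @param session_start Logical, is this the start of a session?
#' @param delta_b_easy Easier-start difficulty offset in logits.
#' @return A list of [agent_action()]s.
#' @export
propose_actions <- function(state, error_rate_rising = FALSE,
                            load_band = state$load_band,
                            session_start = FALSE, delta_b_easy = 0.5) {
  if (isTRUE(error_rate_rising) && load_band == "high") {
    return(list(
      agent_action("companion", "encourage", "You are doing well. Keep going!"),
      agent_action("coach", "suggest_break", "How about a short break?")))
  }
  if (isTRUE(session_start) && state$emotion$valence < 0) {
    return(list(
      agent_action("teacher", "train",
                   list(difficulty = state$difficulty - delta_b_easy)),
      agent_action("coach", "suggest_activity",
                   "Shall we start with something you enjoy?")))
  }
  list(agent_action("teacher", "train", list(difficulty = state$difficulty)))
}

#' Default contradiction pairs that alert research staff
#'
#' @return A list of length-2 character vectors of action types.
#' @export
default_contradictions <- function() {
  list(c("suggest_activity", "suggest_break"),
       c("train", "rest"),
       c("suggest_activity", "rest"))
}

#' Resolve conflicting persona actions
#'
#' Chooses the most safety-conservative candidate (minimal safety rank; ties
#' broken by persona order coach < teacher < companion, then lexicographic
#' action type, so the choice is invariant to candidate order). A staff
#' alert is raised iff two candidates' action types form a declared
#' contradiction pair.
#'
#' @param candidates Non-empty list of [agent_action()]s.
#' @param contradictions List of contradiction pairs, as in
#'   [default_contradictions()].
#' @return List with `chosen` (an `agent_action`) and `staff_alert`
#'   (logical).
#' @export
resolve_conflict <- function(candidates, contradictions = default_contradictions()) {
  if (length(candidates) == 0)
    stop("no candidate actions to resolve", call. = FALSE)
  ranks <- vapply(candidates, function(a) a$safety_rank, numeric(1))
  personas <- match(vapply(candidates, function(a) a$persona, character(1)),
                    PERSONAS)
  types <- vapply(candidates, function(a) a$action_type, character(1))
  ord <- order(ranks, personas, types)
  alert <- FALSE
  for (pair in contradictions) {
    if (all(pair %in% types)) alert <- TRUE
  }
  list(chosen = candidates[[ord[1]]], staff_alert = alert)
}

#' Sliding conversational context window
#'
#' FIFO buffer of the most recent utterances shared across personas; the
#' default capacity of 5 matches the context hub's sliding window.
#'
#' @param capacity Maximum number of retained utterances (>= 1).
#' @return An object of class `context_buffer`.
#' @export
context_buffer <- function(capacity = 5) {
  if (capacity < 1) stop("capacity must be >= 1", call. = FALSE)
  structure(list(capacity = as.integer(capacity),
                 utterances = data.frame(speaker = character(0),
                                         text = character(0),
                                         timestamp = numeric(0))),
            class = "context_buffer")
}

#' Push an utterance into the context window
#'
#' Appends in arrival order and evicts the oldest utterance when the buffer
#' exceeds its capacity.
#'
#' @param buffer A [context_buffer()].
#' @param speaker Speaker id (persona id or `"user"`).
#' @param text Utterance text.
#' @param timestamp Session-relative time in seconds.
#' @return The updated `context_buffer`.
#' @export
push_utterance <- function(buffer, speaker, text, timestamp = NA_real_) {
  u <- rbind(buffer$utterances,
             data.frame(speaker = speaker, text = text, timestamp = timestamp))
  if (nrow(u) > buffer$capacity)
    u <- u[(nrow(u) - buffer$capacity + 1):nrow(u), , drop = FALSE]
  rownames(u) <- NULL
  buffer$utterances <- u
  buffer
}

#' Escalating reminder schedule for a task
#'
#' Reminders escalate from a visual cue at the task start to an auditory
#' alert 15 minutes later to haptic feedback 30 minutes later. A logged
#' response cancels all tiers scheduled at or after it.
#'
#' @param task_start Task start time in minutes (>= 0).
#' @param response_at Optional response time in minutes; tiers at or after
#'   it are marked not fired.
#' @return Data frame with columns `tier`, `offset_minutes`, `time_minutes`,
#'   `fired`.
#' @export
#' @examples
#' schedule_reminders(600)
schedule_reminders <- function(task_start, response_at = NULL) {
  if (!is.finite(task_start) || task_start < 0)
    stop("task_start must be a non-negative time in minutes", call. = FALSE)
  out <- data.frame(tier = c("visual", "auditory", "haptic"),
                    offset_minutes = c(0, 15, 30))
  out$time_minutes <- task_start + out$offset_minutes
  out$fired <- if (is.null(response_at)) rep(TRUE, 3) else
    out$time_minutes < response_at
  out
}

#' Exponentially weighted emotion update
#'
#' Componentwise EWMA of the valence-arousal state towards an observation,
#' clipped to \[-1, 1\]: x' = (1 - rate) x + rate obs.
#'
#' @param state Current [emotion_state()].
#' @param observed Observed [emotion_state()].
#' @param rate Update rate in \[0, 1\]; 0 keeps the state, 1 adopts the
#'   observation.
#' @return The updated `emotion_state`.
#' @export
update_emotion <- function(state, observed, rate = 0.3) {
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("rate must lie in [0, 1]", call. = FALSE)
  emotion_state(valence = (1 - rate) * state$valence + rate * observed$valence,
                arousal = (1 - rate) * state$arousal + rate * observed$arousal)
}

#' Weekly confusion check and single-agent fallback decision
#'
#' Participants answer weekly agent-recognition questions; a majority of
#' incorrect answers, or an expressed preference for fewer agents, switches
#' the system to single-agent mode.
#'
#' @param recognition_answers Logical vector, TRUE = correct answer.
#' @param preference_for_fewer Logical, participant prefers fewer agents.
#' @return `"single_agent"` or `"multi_agent"`.
#' @export
check_confusion_fallback <- function(recognition_answers,
                                     preference_for_fewer = FALSE) {
  if (isTRUE(preference_for_fewer)) return("single_agent")
  if (length(recognition_answers) == 0)
    stop("no recognition answers and no stated preference", call. = FALSE)
  incorrect <- sum(!recognition_answers)
  if (incorrect > length(recognition_answers) / 2) "single_agent" else "multi_agent"
}

#' @export
print.agent_action <- function(x, ...) {
  cat(sprintf("[%s] %s (safety rank %d)\n", x$persona, x$action_type,
              x$safety_rank))
  invisible(x)
}
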