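# Safety monitoring: discontinuation rules, anxiety screening, response
# filtering, fidelity sampling, escalation alerts.

ALERT_KINDS <- c("repeated_failure", "distress", "coordination_error",
                 "blocked_response", "conflict")

#' Safe fallback message for blocked responses
#'
#' The message delivered verbatim in place of any response blocked by the
#' safety filter.
#'
#' @return A length-1 character string.
#' @export
safe_fallback_message <- function() {
  "I\u2019m not certain about that. Please consult with your healthcare provider."
}

#' Sustained negative-affect discontinuation check
#'
#' Flags discontinuation when the weekly PANAS negative-affect score is at
#' least `k_sd` baseline SDs above the baseline mean on `consecutive`
#' consecutive weekly assessments (defaults 1.5 SD, two weeks). The flag is
#' raised at the first week completing such a run.
#'
#' @param na_scores Numeric vector of weekly NA scores, in week order
#'   (week 1 first).
#' @param baseline_mean,baseline_sd Baseline NA mean and SD
#'   (`baseline_sd > 0`).
#' @param k_sd Elevation threshold in baseline SDs.
#' @param consecutive Required run length of elevated weeks.
#' @return List with `flag` (logical) and `trigger_week` (integer or NA).
#' @export
#' @examples
#' check_negative_affect(c(22, 18, 23, 24), 15, 4)  # triggers at week 4
check_negative_affect <- function(na_scores, baseline_mean, baseline_sd,
                                  k_sd = 1.5, consecutive = 2) {
  if (!is.finite(baseline_sd) || baseline_sd <= 0)
    stop("baseline_sd must be > 0", call. = FALSE)
  threshold <- baseline_mean + k_sd * baseline_sd
  elevated <- na_scores >= threshold
  run <- 0L
  for (w in seq_along(elevated)) {
    run <- if (elevated[w]) run + 1L else 0L
    if (run >= consecutive)
      return(list(flag = TRUE, trigger_week = w, threshold = threshold))
  }
  list(flag = FALSE, trigger_week = NA_integer_, threshold = threshold)
}

#' Sustained high-fatigue discontinuation check
#'
#' Flags discontinuation at the first session ending a run of `consecutive`
#' consecutive completed sessions whose self-reported fatigue score (0-10
#' visual analog) is at least `threshold` (defaults: score >= 7 for three
#' consecutive sessions). A skipped (not completed) session breaks the run.
#'
#' @param scores Numeric vector of fatigue scores in session order.
#' @param completed Logical vector, was each session completed (default all
#'   TRUE).
#' @param threshold Fatigue threshold on the 0-10 scale.
#' @param consecutive Required run length.
#' @return List with `flag` (logical) and `trigger_session` (integer or NA).
#' @export
check_fatigue <- function(scores, completed = rep(TRUE, length(scores)),
                          threshold = 7, consecutive = 3) {
  stopifnot(length(completed) == length(scores))
  if (any(scores < 0 | scores > 10, na.rm = TRUE))
    stop("fatigue scores must lie in [0, 10]", call. = FALSE)
  run <- 0L
  for (s in seq_along(scores)) {
    run <- if (isTRUE(completed[s]) && !is.na(scores[s]) &&
               scores[s] >= threshold) run + 1L else 0L
    if (run >= consecutive)
      return(list(flag = TRUE, trigger_session = s))
  }
  list(flag = FALSE, trigger_session = NA_integer_)
}

#' Technology-anxiety screening
#'
#' CARS scores more than `k_sd` SDs above the normative mean trigger
#' enhanced onboarding support; such participants additionally receive
#' weekly CARS assessments during check-in calls.
#'
#' @param cars_score Participant CARS score (item mean).
#' @param norm_mean,norm_sd Normative mean and SD (`norm_sd > 0`);
#'   instrument norms vary by population, so these are parameters.
#' @param k_sd Threshold in normative SDs.
#' @return `"enhanced_onboarding"` (with attribute `weekly_cars = TRUE`) or
#'   `"standard"`.
#' @export
screen_technology_anxiety <- function(cars_score, norm_mean, norm_sd, k_sd = 2) {
  if (!is.finite(norm_sd) || norm_sd <= 0)
    stop("norm_sd must be > 0", call. = FALSE)
  if (cars_score > norm_mean + k_sd * norm_sd)
    structure("enhanced_onboarding", weekly_cars = TRUE)
  else
    "standard"
}

#' Default response-filter blocklist
#'
#' Pattern categories (regular expressions, case-insensitive) flagging
#' medical advice and financial guidance. Semantic plausibility checking is
#' out of scope; this honors the block + fallback + notify contract.
#'
#' @return Named list of character vectors of regex patterns.
#' @export
default_blocklist <- function() {
  list(
    medical_advice = c(
      "\\b\\d+\\s?(mg|mcg|ml)\\b",
      "\\b(take|increase|decrease|stop|double)\\b.{0,40}\\b(dose|dosage|medication|pills?|tablets?)\\b",
      "\\byou should (take|stop taking)\\b",
      "\\bdiagnos(is|e|ed)\\b.{0,30}\\byou\\b"
    ),
    financial_guidance = c(
      "\\b(invest|buy|sell)\\b.{0,40}\\b(stocks?|shares?|crypto|bonds?|fund)\\b",
      "\\btransfer\\b.{0,30}\\b(money|savings|funds)\\b",
      "\\b(loan|mortgage|pension)\\b.{0,30}\\b(should|advise|recommend)\\b"
    )
  )
}

#' Filter a candidate response through the safety blocklist
#'
#' Responses matching any blocklist pattern are blocked from delivery and
#' replaced verbatim by the safe fallback message; a `blocked_response`
#' alert is raised for staff review. Empty text passes.
#'
#' @param text Candidate response text.
#' @param blocklist Named list of regex pattern vectors (see
#'   [default_blocklist()]).
#' @param raised_at Timestamp used for the alert if blocked (seconds or
#'   POSIXct).
#' @return List with `blocked` (logical), `text` (the delivered text),
#'   `category` (matched category or NA) and `alert` (an alert event or
#'   NULL).
#' @export
filter_response <- function(text, blocklist = default_blocklist(),
                            raised_at = 0) {
  if (is.null(text) || !nzchar(text))
    return(list(blocked = FALSE, text = text, category = NA_character_,
                alert = NULL))
  for (cat in names(blocklist)) {
    hits <- vapply(blocklist[[cat]],
                   function(p) grepl(p, text, ignore.case = TRUE, perl = TRUE),
                   logical(1))
    if (any(hits)) {
      return(list(blocked = TRUE, text = safe_fallback_message(),
                  category = cat,
                  alert = raise_alert("blocked_response", raised_at)))
    }
  }
  list(blocked = FALSE, text = text, category = NA_character_, alert = NULL)
}

# Half-away-from-zero rounding (base round() is half-to-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Weekly fidelity sampling of interaction logs
#'
#' Uniform sample without replacement of `round(fraction * N)` logs
#' (half-away-from-zero rounding, minimum one when any logs exist),
#' deterministic under a fixed seed. Supports the weekly 10% response
#' fidelity audit.
#'
#' @param logs List (or vector) of log identifiers or objects.
#' @param fraction Sampling fraction in (0, 1\].
#' @param seed Integer seed making the draw reproducible; NULL uses the
#'   current RNG state.
#' @return The sampled subset of `logs` (same type as the input).
#' @export
#' @examples
#' length(sample_logs_weekly(1:200, 0.10, seed = 1))  # 20
sample_logs_weekly <- function(logs, fraction = 0.10, seed = NULL) {
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  n <- length(logs)
  if (n == 0) return(logs[0])
  size <- max(1L, as.integer(round_half_up(fraction * n)))
  idx <- if (is.null(seed)) {
    sample.int(n, size)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sample.int(n, size)
  }
  logs[sort(idx)]
}

#' Raise a staff alert
#'
#' Alerts are generated for repeated task failures, participant distress,
#' agent-coordination errors, blocked responses, and contradictory guidance.
#' Staff must contact the participant within 24 hours of alert generation.
#'
#' @param kind One of `repeated_failure`, `distress`, `coordination_error`,
#'   `blocked_response`, `conflict`.
#' @param raised_at Timestamp (numeric seconds or POSIXct).
#' @return An object of class `alert_event` with `contact_deadline` exactly
#'   24 h after `raised_at`.
#' @export
raise_alert <- function(kind, raised_at) {
  if (!kind %in% ALERT_KINDS)
    stop("unknown alert kind: ", kind, call. = FALSE)
  deadline <- raised_at + 24 * 3600
  structure(list(kind = kind, raised_at = raised_at,
                 contact_deadline = deadline),
            class = "alert_event")
}

#' @export
print.alert_event <- function(x, ...) {
  cat(sprintf("Alert [%s] raised at %s; contact deadline %s (24 h)\n",
              x$kind, format(x$raised_at), format(x$contact_deadline)))
  invisible(x)
}
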