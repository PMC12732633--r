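# Simulated participants: latent-ability 2PL learners with day-to-day
# ability drift, lognormal response times with fatigue inflation, AR(1)
# weekly negative affect, adherence behavior, and full six-week cohort
# runs exercising the engine, coordinator and safety monitor end to end.

#' Construct a simulated participant
#'
#' A latent generative model standing in for a study subject. Responses are
#' Bernoulli draws from the same 2PL the engine assumes (well-specified
#' recovery by construction); an optional guessing floor makes the model
#' deliberately misspecified to probe robustness. Latent ability follows a
#' Gaussian random walk across days (`day_sd`), response times are
#' lognormal around `rt_median` inflated by within-session fatigue, weekly
#' negative affect is AR(1) around `na_baseline_mean`, and each scheduled
#' session is skipped independently with probability `skip_prob`.
#'
#' @param theta_true Latent ability on the logit scale.
#' @param day_sd SD of the daily ability increment (>= 0).
#' @param rt_median Median response time in seconds (> 0).
#' @param rt_sigma Lognormal shape parameter of response times.
#' @param na_baseline_mean,na_baseline_sd Baseline PANAS negative-affect
#'   mean and SD.
#' @param fatigue_gain Per-trial fatigue increment.
#' @param skip_prob Per-session skip probability in \[0, 1\].
#' @param guessing Lower asymptote of the response model (0 = well
#'   specified; e.g. 0.1 for a misspecification probe).
#' @param id Participant identifier.
#' @return An object of class `simulated_participant`.
#' @export
simulated_participant <- function(theta_true = 0, day_sd = 0.1,
                                  rt_median = 2.5, rt_sigma = 0.4,
                                  na_baseline_mean = 15, na_baseline_sd = 4,
                                  fatigue_gain = 0.02, skip_prob = 0.1,
                                  guessing = 0, id = "p01") {
  if (day_sd < 0) stop("day_sd must be >= 0", call. = FALSE)
  if (rt_median <= 0) stop("rt_median must be > 0", call. = FALSE)
  if (skip_prob < 0 || skip_prob > 1)
    stop("skip_prob must lie in [0, 1]", call. = FALSE)
  if (guessing < 0 || guessing >= 1)
    stop("guessing must lie in [0, 1)", call. = FALSE)
  structure(list(theta_true = theta_true, day_sd = day_sd,
                 rt_median = rt_median, rt_sigma = rt_sigma,
                 na_baseline_mean = na_baseline_mean,
                 na_baseline_sd = na_baseline_sd,
                 fatigue_gain = fatigue_gain, skip_prob = skip_prob,
                 guessing = guessing, id = id),
            class = "simulated_participant")
}

#' Advance a participant's latent state by one day
#'
#' Adds a Normal(0, day_sd) increment to the latent ability; all other
#' latent parameters are unchanged. Draws from the current RNG stream.
#'
#' @param p A [simulated_participant()].
#' @return The updated participant.
#' @export
advance_day <- function(p) {
  if (p$day_sd > 0) p$theta_true <- p$theta_true + stats::rnorm(1, 0, p$day_sd)
  p
}

#' Simulate one cognitive-task trial
#'
#' Outcome ~ Bernoulli(g + (1 - g) 2PL(theta_true, difficulty)); response
#' time is lognormal around the participant median, inflated by the current
#' fatigue level; the cognitive load is computed from the observation via
#' [cognitive_load()]. Draws from the current RNG stream.
#'
#' @param p A [simulated_participant()].
#' @param difficulty Trial difficulty on the logit scale.
#' @param policy A [difficulty_policy()].
#' @param baseline_time Participant baseline response time (defaults to the
#'   median).
#' @param error_rate Recent error rate fed into the load metric.
#' @param attention_variance Attention-variance component of the load.
#' @param fatigue Current fatigue level (response-time multiplier 1 +
#'   fatigue/2).
#' @param weights [load_weights()] for the load metric.
#' @return One-row data frame: `difficulty`, `success_prob`, `outcome`,
#'   `response_time`, `load`.
#' @export
simulate_trial <- function(p, difficulty, policy = difficulty_policy(),
                           baseline_time = p$rt_median, error_rate = 0,
                           attention_variance = 0, fatigue = 0,
                           weights = load_weights()) {
  prob <- p$guessing + (1 - p$guessing) *
    success_probability(p$theta_true, difficulty, policy)
  outcome <- stats::rbinom(1, 1, prob)
  rt <- stats::rlnorm(1, meanlog = log(p$rt_median), sdlog = p$rt_sigma) *
    (1 + fatigue / 2)
  load <- cognitive_load(load_observation(rt, baseline_time, error_rate,
                                          attention_variance), weights)
  data.frame(difficulty = difficulty, success_prob = prob,
             outcome = outcome, response_time = rt, load = load)
}

#' Run the adaptive engine against a simulated learner
#'
#' The full per-trial loop: simulate an outcome at the current difficulty,
#' record it, re-estimate and smooth the ability, and adapt the difficulty
#' towards the target success probability. This is the engine's
#' target-tracking and parameter-recovery workhorse.
#'
#' @param p A [simulated_participant()] (set `day_sd = 0` for a stationary
#'   learner).
#' @param n_trials Number of trials to simulate.
#' @param policy A [difficulty_policy()].
#' @param smoothing Smoothing factor lambda.
#' @param theta0,b0 Initial ability estimate and difficulty.
#' @param seed Optional seed for reproducibility.
#' @param trials_per_day Trials between daily ability-drift steps (ignored
#'   when `day_sd = 0`).
#' @return An object of class `adaptive_run`: list with a per-trial
#'   `trials` data frame (difficulty, outcome, p_model, ability), the final
#'   `state`, final `difficulty` and the empirical `success_rate`.
#' @export
#' @examples
#' p <- simulated_participant(theta_true = 0.5, day_sd = 0)
#' run <- simulate_adaptive_run(p, 300, seed = 7)
#' run$success_rate
simulate_adaptive_run <- function(p, n_trials, policy = difficulty_policy(),
                                  smoothing = 0.8, theta0 = 0, b0 = 0,
                                  seed = NULL, trials_per_day = 30) {
  if (!is.null(seed)) set.seed(seed)
  state <- ability_state(ability = theta0, smoothing = smoothing,
                         window = policy$mle_window)
  b <- b0
  difficulty <- p_model <- ability <- numeric(n_trials)
  outcome <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    prob <- p$guessing + (1 - p$guessing) *
      success_probability(p$theta_true, b, policy)
    y <- stats::rbinom(1, 1, prob)
    step <- engine_step(state, b, y, policy)
    difficulty[t] <- b; outcome[t] <- y
    p_model[t] <- step$p; ability[t] <- step$state$ability
    state <- step$state; b <- step$difficulty
    if (p$day_sd > 0 && t %% trials_per_day == 0) p <- advance_day(p)
  }
  structure(list(trials = data.frame(trial = seq_len(n_trials),
                                     difficulty = difficulty,
                                     outcome = outcome,
                                     p_model = p_model,
                                     ability = ability),
                 state = state, difficulty = b,
                 success_rate = mean(outcome),
                 theta_true = p$theta_true),
            class = "adaptive_run")
}

#' @export
print.adaptive_run <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("Adaptive run: %d trials, success rate %.3f\n", n,
              x$success_rate))
  cat(sprintf("  final ability estimate %.3f (true %.3f), difficulty %.3f\n",
              x$state$ability, x$theta_true, x$difficulty))
  invisible(x)
}

#' @export
plot.adaptive_run <- function(x, ...) {
  tr <- x$trials
  graphics::plot(tr$trial, tr$ability, type = "l", col = "steelblue",
                 xlab = "trial", ylab = "logit scale",
                 ylim = range(c(tr$ability, tr$difficulty, x$theta_true)),
                 main = "Adaptive difficulty and ability tracking", ...)
  graphics::lines(tr$trial, tr$difficulty, col = "firebrick")
  graphics::abline(h = x$theta_true, lty = 2, col = "grey40")
  graphics::legend("bottomright",
                   legend = c("ability estimate", "difficulty", "true ability"),
                   col = c("steelblue", "firebrick", "grey40"),
                   lty = c(1, 1, 2), bty = "n")
  invisible(x)
}

# canned persona templates for utterance events
persona_templates <- function() {
  list(coach = "Let\u2019s plan tomorrow\u2019s schedule together",
       teacher = "Recall three items from the morning list",
       companion = "Tell me about your favorite memory")
}

#' Simulate one intervention session
#'
#' Generates trials until the session's minute budget is exhausted (each
#' trial consumes its response time plus a fixed presentation overhead),
#' applying the full engine update after every trial, tracking the running
#' error rate and attention variance that feed the load metric, emitting
#' persona actions when the coordinator rules fire, and closing with a
#' fatigue report. With probability `skip_prob` the session is skipped and
#' logged as incomplete. Draws from the current RNG stream.
#'
#' @param p A [simulated_participant()].
#' @param state An [ability_state()] carried across sessions.
#' @param difficulty Difficulty carried across sessions.
#' @param slot One row of the schedule's `slots` data frame.
#' @param policy A [difficulty_policy()].
#' @param config A `run_config` (load weights, cut points, overheads).
#' @param baseline_time Frozen calibration baseline; NA during the first
#'   (calibration) session, in which the participant median is used.
#' @param session_index 1-based session number for the log.
#' @param skip Logical override of the skip draw (NULL = draw from
#'   `skip_prob`).
#' @return List with `log` (a [session_log()]), updated `state`,
#'   `difficulty`, `fatigue_score` and `mean_rt` (NA when skipped).
#' @export
simulate_session <- function(p, state, difficulty, slot,
                             policy = difficulty_policy(),
                             config = default_config(),
                             baseline_time = NA_real_,
                             session_index = slot$index, skip = NULL) {
  if (is.null(skip)) skip <- stats::runif(1) < p$skip_prob
  if (skip) {
    return(list(log = session_log(p$id, session_index, slot$index,
                                  completed = FALSE, date = slot$date),
                state = state, difficulty = difficulty,
                fatigue_score = NA_real_, mean_rt = NA_real_))
  }
  weights <- load_weights(config$engine$w1, config$engine$w2, config$engine$w3)
  budget_s <- slot$minutes * 60
  overhead <- config$simulate$trial_overhead_s
  base_t <- if (is.na(baseline_time)) p$rt_median else baseline_time
  events <- list()
  elapsed <- 0; trial_i <- 0; fatigue <- 0
  recent_out <- integer(0); recent_rt <- numeric(0)
  fail_streak <- 0
  while (elapsed < budget_s) {
    trial_i <- trial_i + 1
    err_rate <- if (length(recent_out)) mean(1 - recent_out) else 0
    att_var <- if (length(recent_rt) >= 2) stats::var(recent_rt / base_t) else 0
    tr <- simulate_trial(p, difficulty, policy, base_t, err_rate, att_var,
                         fatigue, weights)
    step <- engine_step(state, difficulty, tr$outcome, policy)
    state <- step$state
    elapsed <- elapsed + overhead + tr$response_time
    events[[length(events) + 1]] <- list(
      t = elapsed, type = "trial",
      payload = list(difficulty = difficulty, success_prob = tr$success_prob,
                     outcome = tr$outcome, response_time = tr$response_time,
                     load = tr$load, ability = state$ability,
                     completed = TRUE))
    # coordinator: rising errors under high load
    band <- classify_load(tr$load, config$engine$load_low_cut,
                          config$engine$load_high_cut)
    err_rising <- length(recent_out) >= 4 && err_rate > 0.4
    if (err_rising && band == "high") {
      cs <- coordination_state(difficulty = difficulty, load_band = band)
      acts <- propose_actions(cs, error_rate_rising = TRUE, load_band = band)
      res <- resolve_conflict(acts,
                              config$coordination$contradictions)
      for (a in acts) {
        events[[length(events) + 1]] <- list(
          t = elapsed, type = "action",
          payload = list(persona = a$persona, action_type = a$action_type,
                         safety_alert = res$staff_alert))
      }
    }
    fail_streak <- if (tr$outcome == 0) fail_streak + 1 else 0
    if (fail_streak == 5) {
      al <- raise_alert("repeated_failure", elapsed)
      events[[length(events) + 1]] <- list(
        t = elapsed, type = "alert",
        payload = list(kind = al$kind, contact_deadline = al$contact_deadline))
    }
    difficulty <- step$difficulty
    fatigue <- fatigue + p$fatigue_gain
    recent_out <- utils::tail(c(recent_out, tr$outcome), 10)
    recent_rt <- utils::tail(c(recent_rt, tr$response_time), 5)
  }
  # a few user-initiated exchanges with the personas
  tpl <- persona_templates()
  for (persona in persona_ids()) {
    k <- stats::rpois(1, if (persona == "teacher") 3 else 2)
    for (j in seq_len(k)) {
      tu <- stats::runif(1, 0, budget_s)
      events[[length(events) + 1]] <- list(
        t = tu, type = "utterance",
        payload = list(speaker = "user", addressee = persona,
                       text = "user request"))
      events[[length(events) + 1]] <- list(
        t = tu + 2, type = "utterance",
        payload = list(speaker = persona, addressee = "user",
                       text = tpl[[persona]]))
    }
  }
  fatigue_score <- round(min(10, max(0, 10 * fatigue * 0.8 +
                                       stats::rnorm(1, 0, 1))))
  events[[length(events) + 1]] <- list(
    t = elapsed, type = "fatigue",
    payload = list(score = fatigue_score, completed = TRUE))
  # order events by time
  events <- events[order(vapply(events, function(e) e$t, numeric(1)))]
  trials <- Filter(function(e) e$type == "trial", events)
  mean_rt <- mean(vapply(trials, function(e) e$payload$response_time,
                         numeric(1)))
  list(log = session_log(p$id, session_index, slot$index, completed = TRUE,
                         duration_minutes = elapsed / 60, date = slot$date,
                         events = events),
       state = state, difficulty = difficulty,
       fatigue_score = fatigue_score, mean_rt = mean_rt)
}

#' Cohort configuration
#'
#' @param n_enrolled Number of enrolled participants (default 14: 12
#'   required completers plus anticipated 10% attrition).
#' @param weeks Intervention weeks.
#' @param seed RNG seed for the whole cohort run.
#' @param attrition_rate Anticipated attrition in \[0, 1).
#' @param config Full `run_config`; the arguments above override its
#'   `simulate`/`protocol` entries.
#' @return The amended `run_config`.
#' @export
cohort_config <- function(n_enrolled = 14, weeks = 6, seed = 1,
                          attrition_rate = 0.10,
                          config = default_config()) {
  if (n_enrolled < 1) stop("n_enrolled must be >= 1", call. = FALSE)
  config$simulate$n_enrolled <- as.integer(n_enrolled)
  config$simulate$seed <- as.integer(seed)
  config$simulate$attrition_rate <- attrition_rate
  config$protocol$weeks <- as.integer(weeks)
  validate_config(config)
  config
}

# Generate Likert items whose instrument score lands near a latent target.
# For SUS: odd items push up, even items push down.
sus_items_for <- function(target) {
  c01 <- target / 100
  odd <- pmin(5, pmax(1, round(1 + 4 * c01 + stats::rnorm(5, 0, 0.5))))
  even <- pmin(5, pmax(1, round(5 - 4 * c01 + stats::rnorm(5, 0, 0.5))))
  as.integer(rbind(odd, even))  # interleave odd/even positions
}

likert_items_for <- function(n, mean_value, sd = 0.7, lo = 1, hi = 5) {
  as.integer(pmin(hi, pmax(lo, round(stats::rnorm(n, mean_value, sd)))))
}

# one response-table row, padded to a common item width so instruments of
# different lengths share one data frame
response_row <- function(id, instrument, timepoint, items, width = 21) {
  padded <- c(items, rep(NA_integer_, width - length(items)))
  cbind(data.frame(participant_id = id, instrument = instrument,
                   timepoint = timepoint),
        as.data.frame(t(stats::setNames(padded, paste0("item_", seq_len(width))))))
}

#' Simulate a full feasibility cohort
#'
#' Runs the entire protocol on synthetic participants: enrollment with
#' screening (MDPQ-16, CARS with enhanced-onboarding tagging), the
#' six-week schedule, per-session adaptive training with engine updates and
#' coordination events, attrition and session skipping, weekly AR(1)
#' negative-affect assessments, fatigue reports, safety monitoring
#' (discontinuation rules, repeated-failure alerts), end-of-study
#' instrument responses (SUS, UEQ-S, BPNS, PANAS), adherence metrics and
#' the feasibility verdict. Fully reproducible from the seed.
#'
#' @param config A `run_config` (see [cohort_config()]).
#' @param seed Seed overriding `config$simulate$seed`.
#' @return An object of class `cohort_run`.
#' @export
#' @examples
#' \donttest{
#' run <- simulate_cohort(cohort_config(n_enrolled = 3, weeks = 2, seed = 42))
#' summary(run)
#' }
simulate_cohort <- function(config = default_config(),
                            seed = config$simulate$seed) {
  validate_config(config)
  set.seed(seed)
  sim <- config$simulate
  policy <- policy_from_config(config)
  schedule <- build_schedule(config$protocol$weeks,
                             config$protocol$sessions_per_week,
                             config$protocol$session_minutes,
                             config$protocol$start_date,
                             config$protocol$morning_anchor,
                             config$protocol$afternoon_anchor)
  n <- sim$n_enrolled
  ids <- sprintf("p%02d", seq_len(n))

  # enrollment: latent abilities and screening instruments
  participants <- data.frame(
    participant_id = ids,
    theta_true = stats::rnorm(n, sim$theta_mean, sim$theta_sd),
    mdpq_total = NA_real_, cars_mean = NA_real_,
    onboarding = NA_character_, dropped = FALSE, dropout_week = NA_integer_)
  responses <- list()
  for (i in seq_len(n)) {
    mdpq <- likert_items_for(16, 3.6)
    cars <- likert_items_for(19, stats::rnorm(1, 2.1, 0.5))
    scr <- score_screening(mdpq, cars)
    participants$mdpq_total[i] <- scr$mdpq_total
    participants$cars_mean[i] <- scr$cars_mean
    participants$onboarding[i] <- as.character(
      screen_technology_anxiety(scr$cars_mean, config$safety$cars_norm_mean,
                                config$safety$cars_norm_sd,
                                config$safety$cars_k_sd))
    responses[[length(responses) + 1]] <-
      response_row(ids[i], "mdpq16", "T0", mdpq)
    responses[[length(responses) + 1]] <-
      response_row(ids[i], "cars", "T0", cars)
  }

  # attrition: dropouts stop attending from a mid-study week
  dropped <- stats::runif(n) < sim$attrition_rate
  participants$dropped <- dropped
  participants$dropout_week[dropped] <-
    sample(2:max(2, config$protocol$weeks), sum(dropped), replace = TRUE)

  logs <- stats::setNames(vector("list", n), ids)
  weekly_affect <- data.frame()
  fatigue_reports <- data.frame()
  safety <- list()
  adherence <- stats::setNames(vector("list", n), ids)

  for (i in seq_len(n)) {
    p <- simulated_participant(theta_true = participants$theta_true[i],
                               day_sd = sim$day_sd,
                               rt_median = sim$rt_median,
                               rt_sigma = sim$rt_sigma,
                               na_baseline_mean = sim$na_baseline_mean,
                               na_baseline_sd = sim$na_baseline_sd,
                               fatigue_gain = sim$fatigue_gain,
                               skip_prob = sim$skip_prob,
                               guessing = sim$guessing, id = ids[i])
    state <- ability_state(0, smoothing = config$engine$smoothing,
                           window = policy$mle_window)
    b <- 0; baseline_time <- NA_real_
    plogs <- vector("list", nrow(schedule$slots))
    na_score <- p$na_baseline_mean
    last_date <- NULL
    for (s in seq_len(nrow(schedule$slots))) {
      slot <- schedule$slots[s, ]
      if (!is.null(last_date)) {
        for (d in seq_len(as.integer(slot$date - last_date))) p <- advance_day(p)
      }
      last_date <- slot$date
      absent <- isTRUE(dropped[i]) && slot$week >= participants$dropout_week[i]
      res <- simulate_session(p, state, b, slot, policy, config,
                              baseline_time, session_index = s,
                              skip = if (absent) TRUE else NULL)
      state <- res$state; b <- res$difficulty
      if (is.na(baseline_time) && !is.na(res$mean_rt))
        baseline_time <- res$mean_rt  # freeze calibration baseline
      plogs[[s]] <- res$log
      if (res$log$completed)
        fatigue_reports <- rbind(fatigue_reports,
                                 data.frame(participant_id = ids[i],
                                            session_index = s,
                                            score = res$fatigue_score,
                                            completed = TRUE))
      # weekly check-in on the week's last slot: AR(1) negative affect
      if (s %% schedule$sessions_per_week == 0) {
        w <- slot$week
        na_score <- p$na_baseline_mean +
          sim$na_phi * (na_score - p$na_baseline_mean) +
          stats::rnorm(1, 0, p$na_baseline_sd * sqrt(1 - sim$na_phi^2))
        na_score <- min(50, max(10, na_score))
        weekly_affect <- rbind(weekly_affect,
                               data.frame(participant_id = ids[i],
                                          week = w, na_score = na_score))
        plogs[[s]]$events[[length(plogs[[s]]$events) + 1]] <- list(
          t = slot$minutes * 60, type = "assessment",
          payload = list(instrument = "panas", scale = "na",
                         score = na_score, week = w))
      }
    }
    logs[[i]] <- plogs

    # end-of-study instruments for participants still enrolled at week 6
    if (!dropped[i]) {
      sus_target <- min(100, max(5, stats::rnorm(1, sim$sus_mean, sim$sus_sd)))
      responses[[length(responses) + 1]] <-
        response_row(ids[i], "sus", "T1", sus_items_for(sus_target))
      responses[[length(responses) + 1]] <-
        response_row(ids[i], "ueq_s", "T1", likert_items_for(8, 5.2, 0.9, 1, 7))
      responses[[length(responses) + 1]] <-
        response_row(ids[i], "bpns", "T1", likert_items_for(21, 3.8))
      responses[[length(responses) + 1]] <-
        response_row(ids[i], "panas", "T1", likert_items_for(20, 2.4))
    }

    # per-participant safety checks
    wa <- weekly_affect[weekly_affect$participant_id == ids[i], ]
    fr <- fatigue_reports[fatigue_reports$participant_id == ids[i], ]
    safety[[ids[i]]] <- list(
      negative_affect = check_negative_affect(
        wa$na_score, sim$na_baseline_mean, sim$na_baseline_sd,
        config$safety$na_k_sd, config$safety$na_consecutive),
      fatigue = check_fatigue(fr$score, fr$completed,
                              config$safety$fatigue_threshold,
                              config$safety$fatigue_consecutive))
    adherence[[ids[i]]] <- adherence_metrics(schedule, plogs)
  }

  responses <- do.call(rbind, responses)
  rownames(responses) <- NULL
  scores <- score_responses(responses)

  # cohort-level feasibility
  completion <- mean(vapply(adherence, function(a) a$session_completion_rate,
                            numeric(1)))
  sus_scores <- scores$score[scores$instrument == "sus"]
  mean_sus <- mean(sus_scores)
  na_flags <- vapply(safety, function(s) s$negative_affect$flag, logical(1))
  pooled <- list(session_completion_rate = completion)
  verdict <- evaluate_feasibility(pooled, mean_sus,
                                  negative_affect_discontinuation = any(na_flags))

  structure(list(config = config, seed = seed, schedule = schedule,
                 participants = participants, logs = logs,
                 responses = responses, scores = scores,
                 weekly_affect = weekly_affect,
                 fatigue_reports = fatigue_reports,
                 safety = safety, adherence = adherence,
                 mean_sus = mean_sus,
                 cohort_completion_rate = completion,
                 feasibility = verdict),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d enrolled, %d weeks, seed %d\n",
              nrow(x$participants), x$config$protocol$weeks, x$seed))
  cat(sprintf("  session completion %.1f%%, mean SUS %.1f\n",
              x$cohort_completion_rate, x$mean_sus))
  cat(sprintf("  feasibility: %s\n", if (x$feasibility$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
summary.cohort_run <- function(object, ...) {
  x <- object
  print(x)
  drops <- sum(x$participants$dropped)
  cat(sprintf("  attrition: %d of %d dropped\n", drops, nrow(x$participants)))
  cat(sprintf("  enhanced onboarding: %d participant(s)\n",
              sum(x$participants$onboarding == "enhanced_onboarding")))
  na_flags <- sum(vapply(x$safety, function(s) s$negative_affect$flag,
                         logical(1)))
  fat_flags <- sum(vapply(x$safety, function(s) s$fatigue$flag, logical(1)))
  cat(sprintf("  discontinuation flags: %d negative affect, %d fatigue\n",
              na_flags, fat_flags))
  print(x$feasibility)
  invisible(x)
}

#' Write a cohort run to a directory
#'
#' Writes the schedule (CSV), participant table (CSV), instrument responses
#' and scores (CSV), per-session JSONL logs under `logs/<participant>/`,
#' and a JSON summary (adherence, feasibility, safety flags).
#'
#' @param run A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_schedule_csv(run$schedule, file.path(dir, "schedule.csv"))
  utils::write.csv(run$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(run$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(run$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  for (pid in names(run$logs)) {
    pdir <- file.path(dir, "logs", pid)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    for (l in run$logs[[pid]]) {
      write_session_log(l, file.path(pdir,
                                     sprintf("session_%03d.jsonl",
                                             l$session_index)))
    }
  }
  summary <- list(
    schema_version = SCHEMA_VERSION,
    seed = run$seed,
    cohort_completion_rate = run$cohort_completion_rate,
    mean_sus = run$mean_sus,
    feasibility_pass = run$feasibility$pass,
    criteria = run$feasibility$criteria,
    negative_affect_flags = vapply(run$safety,
                                   function(s) s$negative_affect$flag,
                                   logical(1)),
    fatigue_flags = vapply(run$safety, function(s) s$fatigue$flag,
                           logical(1)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
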