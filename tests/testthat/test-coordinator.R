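# Persona coordination: routing, action proposal, conflict resolution,
# context window, reminders, emotion, confusion fallback.

test_that("events route to the persona responsible for them", {
  st <- coordination_state()
  expect_identical(route_event("cognitive_task", st), "teacher")
  expect_identical(route_event("activity_planning", st), "coach")
  expect_identical(route_event("emotional_cue", st), "companion")
  expect_error(route_event("weather_report", st), "unknown event kind")
})

test_that("single-agent mode routes everything to the fallback persona", {
  st <- coordination_state(mode = "single_agent")
  for (kind in c("cognitive_task", "activity_planning", "emotional_cue"))
    expect_identical(route_event(kind, st), "companion")
  st2 <- coordination_state(mode = "single_agent", fallback_persona = "coach")
  expect_identical(route_event("cognitive_task", st2), "coach")
})

test_that("rising errors under high load yield encouragement plus a break", {
  st <- coordination_state(load_band = "high")
  acts <- propose_actions(st, error_rate_rising = TRUE, load_band = "high")
  types <- vapply(acts, function(a) paste(a$persona, a$action_type), "")
  expect_setequal(types, c("companion encourage", "coach suggest_break"))
})

test_that("negative valence at session start lowers the teacher's difficulty", {
  st <- coordination_state(difficulty = 0,
                           emotion = emotion_state(valence = -0.5))
  acts <- propose_actions(st, session_start = TRUE, delta_b_easy = 0.5)
  teacher <- Filter(function(a) a$persona == "teacher", acts)[[1]]
  expect_identical(teacher$action_type, "train")
  expect_equal(teacher$payload$difficulty, -0.5)
})

test_that("the default path is a teacher training action at current difficulty", {
  st <- coordination_state(difficulty = 0.3, load_band = "moderate")
  acts <- propose_actions(st)
  expect_length(acts, 1)
  expect_identical(acts[[1]]$persona, "teacher")
  expect_equal(acts[[1]]$payload$difficulty, 0.3)
})

test_that("conflict resolution picks the safety-conservative action", {
  res <- resolve_conflict(list(agent_action("coach", "suggest_activity"),
                               agent_action("teacher", "rest")))
  expect_identical(res$chosen$action_type, "rest")
  expect_true(res$staff_alert)  # activity vs fatigue-rest is a declared pair
  res2 <- resolve_conflict(list(agent_action("teacher", "train")))
  expect_identical(res2$chosen$action_type, "train")
  expect_false(res2$staff_alert)
  res3 <- resolve_conflict(list(agent_action("companion", "empathize"),
                                agent_action("coach", "encourage")))
  expect_identical(res3$chosen$action_type, "empathize")
  expect_false(res3$staff_alert)
  expect_error(resolve_conflict(list()), "no candidate")
})

test_that("contradiction pairs raise the staff alert", {
  res <- resolve_conflict(list(agent_action("coach", "suggest_activity"),
                               agent_action("coach", "suggest_break")))
  expect_true(res$staff_alert)
  res <- resolve_conflict(list(agent_action("teacher", "train"),
                               agent_action("teacher", "rest")))
  expect_true(res$staff_alert)
  res <- resolve_conflict(list(agent_action("teacher", "train"),
                               agent_action("companion", "encourage")))
  expect_false(res$staff_alert)
})

test_that("conflict resolution is invariant to candidate order", {
  set.seed(61)
  pool <- list(agent_action("coach", "suggest_activity"),
               agent_action("teacher", "train"),
               agent_action("companion", "empathize"),
               agent_action("teacher", "rest"),
               agent_action("coach", "encourage"))
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cand <- pool[sample(5, k)]
    base <- resolve_conflict(cand)
    for (j in 1:3) {
      perm <- resolve_conflict(cand[sample(k)])
      expect_identical(perm$chosen, base$chosen)
      expect_identical(perm$staff_alert, base$staff_alert)
    }
  }
})

test_that("context window keeps the last five utterances in arrival order", {
  buf <- context_buffer(5)
  for (i in 1:12) buf <- push_utterance(buf, "user", paste0("u", i), i)
  expect_equal(nrow(buf$utterances), 5)
  expect_equal(buf$utterances$text, paste0("u", 8:12))
})

test_that("context window matches a reference FIFO queue on random pushes", {
  set.seed(71)
  for (cap in c(1, 3, 5)) {
    buf <- context_buffer(cap)
    ref <- list()
    for (i in 1:40) {
      txt <- paste0("m", i)
      buf <- push_utterance(buf, sample(c("user", persona_ids()), 1), txt, i)
      ref <- ref_queue_push(ref, txt, cap)
      expect_true(nrow(buf$utterances) <= cap)
      expect_equal(buf$utterances$text, unlist(ref))
    }
  }
})

test_that("reminders escalate visual -> auditory -> haptic at +0/+15/+30", {
  r <- schedule_reminders(0)
  expect_equal(r$tier, c("visual", "auditory", "haptic"))
  expect_equal(r$offset_minutes, c(0, 15, 30))
  expect_true(all(diff(r$time_minutes) > 0))
  r600 <- schedule_reminders(600)
  expect_equal(r600$time_minutes[r600$tier == "haptic"], 630)
  # a response cancels later tiers
  r10 <- schedule_reminders(0, response_at = 10)
  expect_equal(r10$fired, c(TRUE, FALSE, FALSE))
  expect_error(schedule_reminders(-5), "non-negative")
})

test_that("emotion updates are a clipped componentwise EWMA", {
  e <- update_emotion(emotion_state(0, 0), emotion_state(1, 1), rate = 0.5)
  expect_equal(c(e$valence, e$arousal), c(0.5, 0.5))
  e0 <- update_emotion(emotion_state(0.2, -0.3), emotion_state(1, 1), rate = 0)
  expect_equal(c(e0$valence, e0$arousal), c(0.2, -0.3))
  e1 <- update_emotion(emotion_state(0.2, -0.3), emotion_state(1, 1), rate = 1)
  expect_equal(c(e1$valence, e1$arousal), c(1, 1))
  # clipping
  ec <- emotion_state(5, -5)
  expect_equal(c(ec$valence, ec$arousal), c(1, -1))
})

test_that("confusion or preference for fewer agents falls back to single agent", {
  expect_identical(check_confusion_fallback(c(FALSE, FALSE, TRUE)),
                   "single_agent")
  expect_identical(check_confusion_fallback(c(TRUE, TRUE)), "multi_agent")
  expect_identical(check_confusion_fallback(c(TRUE), preference_for_fewer = TRUE),
                   "single_agent")
  expect_error(check_confusion_fallback(logical(0)), "no recognition answers")
})
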