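# Protocol scheduling, adherence metrics, feasibility, enrollment.

test_that("default schedule is 30 weekday sessions totalling 15 hours", {
  s <- build_schedule()
  expect_equal(nrow(s$slots), 30)
  expect_equal(sum(s$slots$minutes), 900)  # 15 h
  expect_true(all(format(s$slots$date, "%u") %in% as.character(1:5)))
  expect_equal(s$slots$index, 1:30)
  expect_equal(s$slots$cognitive_start[1], "09:00")
  expect_equal(s$slots$social_start[1], "15:00")
})

test_that("slot count and total minutes hold across parameter combinations", {
  set.seed(111)
  for (i in 1:20) {
    w <- sample(1:8, 1); k <- sample(1:7, 1); m <- sample(10:60, 1)
    s <- build_schedule(w, k, m)
    expect_equal(nrow(s$slots), w * k)
    expect_equal(sum(s$slots$minutes), w * k * m)
  }
  expect_equal(nrow(build_schedule(1, 1, 30)$slots), 1)
  expect_error(build_schedule(6, 8, 30), "exceed 7")
})

test_that("schedule starts the Monday on or after the start date", {
  s <- build_schedule(start_date = "2026-01-07")  # a Wednesday
  expect_equal(format(s$slots$date[1], "%u"), "1")
  expect_true(s$slots$date[1] >= as.Date("2026-01-07"))
  mon <- build_schedule(start_date = "2026-01-05")  # already a Monday
  expect_equal(mon$slots$date[1], as.Date("2026-01-05"))
})

test_that("tasks are placed by circadian rule: cognitive morning, social afternoon", {
  s <- build_schedule()
  slot <- s$slots[1, ]
  expect_identical(place_task("cognitive", slot)$block, "morning")
  expect_identical(place_task("social", slot)$block, "afternoon")
  expect_error(place_task("gardening", slot), "unknown task kind")
})

make_log <- function(pid, session, slot, completed, duration = 30,
                     mean_rt = 3, n_trials = 3) {
  events <- list()
  if (completed) {
    for (j in seq_len(n_trials)) {
      events[[j]] <- list(t = j * 60, type = "trial",
                          payload = list(difficulty = 0, outcome = 1L,
                                         response_time = mean_rt,
                                         load = 0.2, completed = TRUE))
    }
  }
  session_log(pid, session, slot, completed = completed,
              duration_minutes = if (completed) duration else NA_real_,
              events = events)
}

test_that("adherence metrics compute completion, duration and latency trend", {
  s <- build_schedule()
  logs <- lapply(1:30, function(i) make_log("p01", i, i, completed = i <= 24))
  rep <- adherence_metrics(s, logs)
  expect_equal(rep$session_completion_rate, 80)  # 24 of 30
  expect_equal(rep$mean_session_duration, 30)
  expect_equal(rep$task_completion_rate, 100)

  # exactly linear latency growth of 2 s/session recovers slope 2
  logs2 <- lapply(1:10, function(i) make_log("p01", i, i, TRUE,
                                             mean_rt = 5 + 2 * i))
  rep2 <- adherence_metrics(s, logs2)
  expect_equal(rep2$response_latency_trend, 2, tolerance = 1e-6)
})

test_that("all-complete logs give 100% and session-duration equal to the slot", {
  s <- build_schedule(2, 3, 30)
  logs <- lapply(1:6, function(i) make_log("p01", i, i, TRUE, duration = 30))
  rep <- adherence_metrics(s, logs)
  expect_equal(rep$session_completion_rate, 100)
  expect_equal(rep$mean_session_duration, 30)
})

test_that("zero completed sessions report 0% and absent mean duration", {
  s <- build_schedule()
  logs <- lapply(1:30, function(i) make_log("p01", i, i, FALSE))
  rep <- adherence_metrics(s, logs)
  expect_equal(rep$session_completion_rate, 0)
  expect_true(is.na(rep$mean_session_duration))
})

test_that("logs referencing unknown slots are an integrity error", {
  s <- build_schedule(1, 2, 30)
  expect_error(adherence_metrics(s, list(make_log("p01", 1, 99, TRUE))),
               "not in the schedule")
})

test_that("feasibility requires completion >= 70, SUS >= 70 and no NA flag", {
  ok <- evaluate_feasibility(list(session_completion_rate = 80), 72)
  expect_true(ok$pass)
  f1 <- evaluate_feasibility(list(session_completion_rate = 65), 90)
  expect_false(f1$pass)
  expect_false(f1$criteria$met[f1$criteria$criterion == "session_completion"])
  f3 <- evaluate_feasibility(list(session_completion_rate = 80), 72,
                             negative_affect_discontinuation = TRUE)
  expect_false(f3$pass)
  expect_false(f3$criteria$met[f3$criteria$criterion == "emotional_safety"])
  expect_error(evaluate_feasibility(list(session_completion_rate = 80), 120),
               "sus_score")
})

test_that("improving any feasibility criterion never flips pass to fail", {
  set.seed(121)
  for (i in 1:50) {
    comp <- runif(1, 0, 100); sus <- runif(1, 0, 100)
    flag <- runif(1) < 0.5
    v <- evaluate_feasibility(list(session_completion_rate = comp), sus,
                              negative_affect_discontinuation = flag)
    better <- evaluate_feasibility(
      list(session_completion_rate = min(100, comp + runif(1, 0, 20))),
      min(100, sus + runif(1, 0, 20)),
      negative_affect_discontinuation = flag && (runif(1) < 0.5))
    if (v$pass) expect_true(better$pass)
  }
})

test_that("enrollment sizing covers anticipated attrition", {
  expect_equal(enrollment_size(12, 0.10), 14)
  expect_equal(enrollment_size(12, 0), 12)
  expect_equal(enrollment_size(1, 0.5), 2)
  # definition check: smallest n with floor((1-r) n) >= k
  expect_true(floor(0.9 * 13) < 12)
  expect_error(enrollment_size(12, 1), "attrition_rate")
})
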