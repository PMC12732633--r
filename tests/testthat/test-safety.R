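# Safety monitoring: discontinuation rules, screening, response filter,
# fidelity sampling, alerts.

test_that("negative-affect rule needs two consecutive elevated weeks", {
  # baseline 15 +/- 4 -> threshold 21
  r <- check_negative_affect(c(22, 18, 23, 24), 15, 4)
  expect_true(r$flag)
  expect_equal(r$trigger_week, 4)
  expect_equal(r$threshold, 21)
  r2 <- check_negative_affect(c(22, 18, 22, 18), 15, 4)
  expect_false(r2$flag)
  r3 <- check_negative_affect(numeric(0), 15, 4)
  expect_false(r3$flag)
  expect_error(check_negative_affect(c(20), 15, 0), "baseline_sd")
})

test_that("fatigue rule needs three consecutive completed sessions at 7+", {
  r <- check_fatigue(c(7, 6, 7, 7, 7))
  expect_true(r$flag)
  expect_equal(r$trigger_session, 5)
  expect_false(check_fatigue(c(7, 7, 6, 7, 7))$flag)
  expect_false(check_fatigue(numeric(0))$flag)
  # a skipped session breaks the run
  r2 <- check_fatigue(c(7, 7, 7, 7), completed = c(TRUE, TRUE, FALSE, TRUE))
  expect_false(r2$flag)
  expect_error(check_fatigue(c(11)), "\\[0, 10\\]")
})

test_that("discontinuation rules match brute-force window scans", {
  set.seed(81)
  for (i in 1:300) {
    n <- sample(0:12, 1)
    scores <- round(runif(n, 10, 30))
    r <- check_negative_affect(scores, 15, 4)
    expect_equal(r$trigger_week, scan_first_run(scores, 21, 2))
    expect_equal(r$flag, !is.na(scan_first_run(scores, 21, 2)))

    m <- sample(0:10, 1)
    fat <- sample(0:10, m, replace = TRUE)
    comp <- runif(m) < 0.8
    f <- check_fatigue(fat, comp)
    expect_equal(f$trigger_session, scan_first_run(fat, 7, 3, comp))
    expect_equal(f$flag, !is.na(scan_first_run(fat, 7, 3, comp)))
  }
})

test_that("discontinuation flags are prefix-monotone", {
  set.seed(91)
  for (i in 1:50) {
    scores <- round(runif(10, 10, 30))
    full <- check_negative_affect(scores, 15, 4)
    for (k in 1:10) {
      pre <- check_negative_affect(scores[1:k], 15, 4)
      if (pre$flag) {
        expect_true(full$flag)
        expect_equal(full$trigger_week, pre$trigger_week)
        break
      }
    }
  }
})

test_that("technology-anxiety screening uses a strict 2 SD cut", {
  expect_identical(as.character(screen_technology_anxiety(3.2, 2.0, 0.5)),
                   "enhanced_onboarding")
  expect_identical(as.character(screen_technology_anxiety(3.0, 2.0, 0.5)),
                   "standard")
  expect_identical(as.character(screen_technology_anxiety(1.0, 2.0, 0.5)),
                   "standard")
  enh <- screen_technology_anxiety(3.5, 2.0, 0.5)
  expect_true(attr(enh, "weekly_cars"))
  expect_error(screen_technology_anxiety(2, 2, 0), "norm_sd")
})

test_that("medical or financial advice is blocked with the exact fallback", {
  res <- filter_response("you should take 500 mg of ibuprofen tonight")
  expect_true(res$blocked)
  expect_identical(res$text, safe_fallback_message())
  expect_identical(
    res$text,
    "I’m not certain about that. Please consult with your healthcare provider.")
  expect_false(grepl("ibuprofen", res$text))
  expect_identical(res$alert$kind, "blocked_response")

  fin <- filter_response("you could invest your savings in crypto funds")
  expect_true(fin$blocked)
  expect_identical(fin$category, "financial_guidance")
})

test_that("benign and empty responses pass unmodified", {
  ok <- filter_response("Let's plan tomorrow's schedule together")
  expect_false(ok$blocked)
  expect_identical(ok$text, "Let's plan tomorrow's schedule together")
  expect_null(ok$alert)
  expect_false(filter_response("")$blocked)
})

test_that("blocked source text never leaks through the filter", {
  set.seed(101)
  phrases <- c("take 20 mg of this", "double your dose of pills",
               "sell your shares now", "transfer your savings today")
  for (ph in phrases) {
    res <- filter_response(ph)
    expect_true(res$blocked)
    expect_identical(res$text, safe_fallback_message())
  }
})

test_that("fidelity sampling draws round(fraction*N), minimum one, reproducibly", {
  expect_length(sample_logs_weekly(1:200, 0.10, seed = 1), 20)
  expect_length(sample_logs_weekly(1:5, 0.10, seed = 1), 1)
  expect_length(sample_logs_weekly(integer(0), 0.10, seed = 1), 0)
  expect_identical(sample_logs_weekly(1:100, 0.10, seed = 7),
                   sample_logs_weekly(1:100, 0.10, seed = 7))
  # half-away-from-zero rounding: 0.10 * 15 = 1.5 -> 2
  expect_length(sample_logs_weekly(1:15, 0.10, seed = 1), 2)
  for (n in c(1, 3, 9, 37, 200)) {
    expect_length(sample_logs_weekly(seq_len(n), 0.10, seed = 3),
                  max(1, sign(0.1 * n) * floor(abs(0.1 * n) + 0.5)))
  }
  expect_error(sample_logs_weekly(1:10, 0), "fraction")
})

test_that("sampling with a seed does not disturb the global RNG stream", {
  set.seed(11)
  a <- runif(1)
  set.seed(11)
  invisible(sample_logs_weekly(1:50, 0.1, seed = 99))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("alerts carry a contact deadline exactly 24 h after being raised", {
  a <- raise_alert("repeated_failure", 1000)
  expect_equal(a$contact_deadline - a$raised_at, 24 * 3600)
  t0 <- as.POSIXct("2026-02-03 10:00:00", tz = "UTC")
  d <- raise_alert("distress", t0)
  expect_equal(as.numeric(difftime(d$contact_deadline, t0, units = "hours")), 24)
  expect_error(raise_alert("sunspots", 0), "unknown alert kind")
})
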