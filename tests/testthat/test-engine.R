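# Adaptive engine: 2PL model, difficulty update, load metric, ability MLE,
# smoothing.

test_that("2PL success probability matches the logistic and its symmetry", {
  pol <- difficulty_policy()
  expect_equal(success_probability(0, 0, pol), 0.5)
  expect_equal(success_probability(1, 0, pol), 0.7310586, tolerance = 1e-6)
  # difficulty solving P = P* sits logit(0.85) below ability
  b_star <- -qlogis(0.85)
  expect_equal(success_probability(0, b_star, pol), 0.85, tolerance = 1e-9)
  expect_equal(qlogis(0.85), 1.734601, tolerance = 1e-6)
  expect_error(success_probability(NaN, 0, pol), "finite")
})

test_that("success probability is monotone in ability and difficulty", {
  set.seed(11)
  pol <- difficulty_policy(discrimination = 1.7)
  for (i in 1:50) {
    th <- runif(2, -4, 4); b <- runif(2, -3, 3)
    expect_true((success_probability(max(th), b[1], pol) >
                   success_probability(min(th), b[1], pol)) ||
                  th[1] == th[2])
    expect_true((success_probability(th[1], max(b), pol) <
                   success_probability(th[1], min(b), pol)) ||
                  b[1] == b[2])
  }
})

test_that("difficulty update has the target as exact fixed point and clips", {
  pol <- difficulty_policy(learning_rate = 0.5, target_success = 0.85)
  expect_identical(update_difficulty(0, 0.85, pol), 0)
  expect_equal(update_difficulty(0, 1.0, pol), 0.075)
  expect_equal(update_difficulty(2.99, 1.0, pol), 3.0)  # clip at b_max
  expect_error(update_difficulty(0, 1.5, pol), "\\[0, 1\\]")
  bad <- pol; bad$b_min <- 5
  expect_error(update_difficulty(0, 0.5, bad), "b_min")
})

test_that("difficulty stays within bounds for any input sequence", {
  set.seed(21)
  pol <- difficulty_policy(b_min = -2, b_max = 2, learning_rate = 1)
  b <- 0
  for (i in 1:500) {
    b <- update_difficulty(b, runif(1), pol)
    expect_true(b >= pol$b_min && b <= pol$b_max)
  }
})

test_that("cognitive load matches the weighted composite and clips to [0, 2]", {
  # 0.4 * 0.5 + 0.35 * 0.2 + 0.25 * 0.1 = 0.295
  expect_equal(cognitive_load(load_observation(3, 2, 0.2, 0.1)), 0.295)
  # all-zero components
  expect_equal(cognitive_load(load_observation(2, 2, 0, 0)), 0)
  # faster than baseline contributes zero, not negative, load
  expect_equal(cognitive_load(load_observation(1, 2, 0, 0)), 0)
  # adversarial inputs are clipped exactly at the ceiling
  expect_identical(cognitive_load(load_observation(22, 2, 1, 10)), 2)
  expect_error(load_observation(1, 0, 0, 0), "baseline_time")
  expect_error(load_observation(1, 1, 1.2, 0), "error_rate")
})

test_that("cognitive load is contained in [0, 2] over random inputs", {
  set.seed(31)
  for (i in 1:2000) {
    obs <- load_observation(runif(1, 0.1, 60), runif(1, 0.5, 10),
                            runif(1), runif(1, 0, 12))
    l <- cognitive_load(obs)
    expect_true(l >= 0 && l <= 2)
  }
})

test_that("load bands split at the cut points with the boundary going up", {
  expect_identical(classify_load(0.0), "low")
  expect_identical(classify_load(0.7), "moderate")
  expect_identical(classify_load(1.2), "high")   # boundary -> upper band
  expect_identical(classify_load(0.5), "moderate")
  expect_error(classify_load(2.5), "\\[0, 2\\]")
  expect_error(classify_load(1, low_cut = 1.5, high_cut = 1.2), "low_cut")
})

test_that("ability MLE matches the closed form and returns bounds when degenerate", {
  pol <- difficulty_policy()
  h <- data.frame(difficulty = rep(0, 10), outcome = c(rep(1, 7), rep(0, 3)))
  expect_equal(estimate_ability(h, pol), qlogis(0.7), tolerance = 1e-4)
  all_correct <- data.frame(difficulty = rep(0, 10), outcome = rep(1, 10))
  expect_identical(estimate_ability(all_correct, pol), pol$theta_max)
  all_wrong <- data.frame(difficulty = rep(0, 10), outcome = rep(0, 10))
  expect_identical(estimate_ability(all_wrong, pol), pol$theta_min)
  expect_error(estimate_ability(data.frame()), "empty")
})

test_that("ability MLE agrees with exhaustive grid search on mixed histories", {
  pol <- difficulty_policy()
  h <- data.frame(difficulty = c(-1, 0, 1), outcome = c(1, 1, 0))
  expect_lt(abs(estimate_ability(h, pol) - grid_mle(h$difficulty, h$outcome)),
            1e-3)
  set.seed(41)
  for (i in 1:100) {
    h <- random_history(sample(1:20, 1))
    expect_lt(abs(estimate_ability(h, pol) -
                    grid_mle(h$difficulty, h$outcome)), 1e-3)
  }
})

test_that("smoothing interpolates between the old estimate and the MLE", {
  st <- ability_state(1.0, smoothing = 1)
  expect_equal(smooth_ability(st, 0.5)$ability, 1.0)
  st <- ability_state(1.0, smoothing = 0)
  expect_equal(smooth_ability(st, 0.5)$ability, 0.5)
  st <- ability_state(1.0, smoothing = 0.8)
  expect_equal(smooth_ability(st, 0.5)$ability, 0.9)
  expect_error(smooth_ability(st, Inf), "finite")
  # betweenness for arbitrary lambda
  set.seed(51)
  for (i in 1:100) {
    lam <- runif(1); th <- runif(1, -4, 4); est <- runif(1, -4, 4)
    out <- smooth_ability(ability_state(th, smoothing = lam), est)$ability
    expect_true(out >= min(th, est) - 1e-12 && out <= max(th, est) + 1e-12)
  }
})

test_that("history window caps the retained trials, oldest evicted first", {
  st <- ability_state(window = 5)
  for (i in 1:12) st <- record_trial(st, i, i %% 2)
  expect_equal(nrow(st$history), 5)
  expect_equal(st$history$difficulty, 8:12)
})

test_that("difficulty converges to theta - logit(P*)/a under converged estimates", {
  # deterministic iteration with P computed at the true ability
  pol <- difficulty_policy(discrimination = 1, learning_rate = 0.5)
  theta_star <- 1
  b <- 0
  for (i in 1:500)
    b <- update_difficulty(b, success_probability(theta_star, b, pol), pol)
  expect_equal(b, theta_star - qlogis(0.85) / 1, tolerance = 0.05)
})
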