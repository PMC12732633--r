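# Adaptive-difficulty engine: 2PL success model, difficulty update,
# cognitive-load metric, ability MLE and exponential smoothing.

#' Cognitive-load weights
#'
#' Weights of the three components of the cognitive-load metric: normalized
#' response-time deviation, error rate, and attention variance. The defaults
#' (0.4, 0.35, 0.25) prioritize processing speed, the primary mediator of
#' age-related cognitive performance. Weights must be non-negative and sum
#' to one.
#'
#' @param w1 Weight for response-time deviation.
#' @param w2 Weight for error rate.
#' @param w3 Weight for attention variance.
#' @return An object of class `load_weights`.
#' @seealso [cognitive_load()]
#' @export
#' @examples
#' load_weights()
load_weights <- function(w1 = 0.4, w2 = 0.35, w3 = 0.25) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (!all(is.finite(w)) || any(w < 0))
    stop("load weights must be finite and non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("load weights must sum to 1 (got ", sum(w), ")", call. = FALSE)
  structure(as.list(w), class = "load_weights")
}

#' Per-trial observation feeding the cognitive-load metric
#'
#' @param response_time Observed response time in seconds (> 0).
#' @param baseline_time Participant baseline response time in seconds (> 0),
#'   typically the mean response time of the first (calibration) session,
#'   frozen thereafter.
#' @param error_rate Recent error rate, a fraction in \[0, 1\].
#' @param attention_variance Non-negative scalar; variance of normalized
#'   within-session inter-response intervals, supplied by the logger or
#'   simulator.
#' @return An object of class `load_observation`.
#' @export
load_observation <- function(response_time, baseline_time, error_rate,
                             attention_variance) {
  if (!is.finite(baseline_time) || baseline_time <= 0)
    stop("baseline_time must be a positive finite number", call. = FALSE)
  if (!is.finite(response_time) || response_time <= 0)
    stop("response_time must be a positive finite number", call. = FALSE)
  if (!is.finite(error_rate) || error_rate < 0 || error_rate > 1)
    stop("error_rate must lie in [0, 1]", call. = FALSE)
  if (!is.finite(attention_variance) || attention_variance < 0)
    stop("attention_variance must be non-negative", call. = FALSE)
  structure(list(response_time = response_time, baseline_time = baseline_time,
                 error_rate = error_rate,
                 attention_variance = attention_variance),
            class = "load_observation")
}

#' Difficulty-adaptation policy
#'
#' Parameters of the 2PL adaptive-difficulty system. `target_success` is the
#' success probability the difficulty update steers towards (default 0.85,
#' the optimal-challenge target); `learning_rate` scales each update step;
#' difficulty is clipped to `[b_min, b_max]` and ability estimates to
#' `[theta_min, theta_max]`. `mle_window` bounds how many recent trials feed
#' the ability MLE. When `update_from_outcome` is TRUE the difficulty update
#' uses the observed 0/1 outcome in place of the model probability
#' (stochastic-approximation variant); the default uses the model
#' probability, which has the deterministic fixed point
#' b = theta - logit(target_success)/discrimination.
#'
#' @param discrimination 2PL discrimination parameter a (> 0).
#' @param learning_rate Update step size eta, in (0, 1].
#' @param target_success Target success probability P*, in (0, 1).
#' @param b_min,b_max Difficulty bounds on the logit scale.
#' @param theta_min,theta_max Ability-estimate bounds on the logit scale.
#' @param mle_window Number of recent trials used by [estimate_ability()].
#' @param update_from_outcome Use the realized outcome instead of the model
#'   probability in the difficulty update.
#' @return An object of class `difficulty_policy`.
#' @export
#' @examples
#' difficulty_policy()
difficulty_policy <- function(discrimination = 1.0, learning_rate = 0.5,
                              target_success = 0.85,
                              b_min = -3, b_max = 3,
                              theta_min = -4, theta_max = 4,
                              mle_window = 100,
                              update_from_outcome = FALSE) {
  if (!is.finite(discrimination) || discrimination <= 0)
    stop("discrimination must be > 0", call. = FALSE)
  if (!is.finite(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]", call. = FALSE)
  if (!is.finite(target_success) || target_success <= 0 || target_success >= 1)
    stop("target_success must lie in (0, 1)", call. = FALSE)
  if (b_min >= b_max)
    stop("b_min must be < b_max", call. = FALSE)
  if (theta_min >= theta_max)
    stop("theta_min must be < theta_max", call. = FALSE)
  if (mle_window < 1) stop("mle_window must be >= 1", call. = FALSE)
  structure(list(discrimination = discrimination,
                 learning_rate = learning_rate,
                 target_success = target_success,
                 b_min = b_min, b_max = b_max,
                 theta_min = theta_min, theta_max = theta_max,
                 mle_window = as.integer(mle_window),
                 update_from_outcome = isTRUE(update_from_outcome)),
            class = "difficulty_policy")
}

#' Ability-tracking state
#'
#' Holds the current smoothed ability estimate, the smoothing factor lambda
#' (weight on the previous estimate; lambda balances historical stability
#' against recent responsiveness), and the bounded history of recent
#' (difficulty, outcome) pairs feeding the MLE.
#'
#' @param ability Current smoothed ability estimate on the logit scale.
#' @param smoothing Smoothing factor lambda in \[0, 1\].
#' @param window Maximum history length retained.
#' @return An object of class `ability_state`.
#' @export
ability_state <- function(ability = 0, smoothing = 0.8, window = 100) {
  if (!is.finite(ability)) stop("ability must be finite", call. = FALSE)
  if (!is.finite(smoothing) || smoothing < 0 || smoothing > 1)
    stop("smoothing must lie in [0, 1]", call. = FALSE)
  structure(list(ability = ability, smoothing = smoothing,
                 window = as.integer(window),
                 history = data.frame(difficulty = numeric(0),
                                      outcome = integer(0))),
            class = "ability_state")
}

#' 2PL success probability
#'
#' P = 1 / (1 + exp(-a (theta - b))): strictly increasing in ability,
#' strictly decreasing in difficulty.
#'
#' @param ability Ability theta on the logit scale.
#' @param difficulty Task difficulty b on the logit scale.
#' @param policy A [difficulty_policy()] (supplies the discrimination a).
#' @return Success probability in (0, 1). Vectorized over `ability` and
#'   `difficulty`.
#' @export
#' @examples
#' success_probability(0, 0, difficulty_policy())   # 0.5
#' success_probability(1, 0, difficulty_policy())   # ~0.731
success_probability <- function(ability, difficulty, policy = difficulty_policy()) {
  if (!all(is.finite(ability)) || !all(is.finite(difficulty)))
    stop("ability and difficulty must be finite", call. = FALSE)
  stats::plogis(policy$discrimination * (ability - difficulty))
}

#' Difficulty update
#'
#' b' = clip(b + eta (P - P*), b_min, b_max). Difficulty rises when observed
#' (or modeled) success exceeds the target and falls when it is below it;
#' when P equals the target the difficulty is an exact fixed point.
#'
#' @param current Current difficulty b on the logit scale.
#' @param success_prob Success probability P of the trial, in (0, 1) (or the
#'   0/1 outcome under the stochastic-approximation variant, in \[0, 1\]).
#' @param policy A [difficulty_policy()].
#' @return Updated difficulty, always within `[b_min, b_max]`.
#' @export
update_difficulty <- function(current, success_prob, policy = difficulty_policy()) {
  if (policy$b_min >= policy$b_max)
    stop("policy has b_min >= b_max", call. = FALSE)
  if (!all(is.finite(current)) || !all(is.finite(success_prob)) ||
      any(success_prob < 0) || any(success_prob > 1))
    stop("success_prob must lie in [0, 1]", call. = FALSE)
  b <- current + policy$learning_rate * (success_prob - policy$target_success)
  pmin(policy$b_max, pmax(policy$b_min, b))
}

#' Cognitive-load metric
#'
#' Weighted composite of normalized response-time deviation, error rate and
#' attention variance, clipped to \[0, 2\]:
#' L = w1 max(0, (t - t_base)/t_base) + w2 e + w3 s2.
#' Faster-than-baseline responses contribute zero (not negative) load.
#'
#' @param obs A [load_observation()].
#' @param weights A [load_weights()].
#' @return Load value in \[0, 2\].
#' @export
#' @examples
#' cognitive_load(load_observation(3, 2, 0.2, 0.1))
cognitive_load <- function(obs, weights = load_weights()) {
  if (!inherits(obs, "load_observation"))
    obs <- do.call(load_observation, as.list(obs))
  deviation <- max(0, (obs$response_time - obs$baseline_time) / obs$baseline_time)
  raw <- weights$w1 * deviation + weights$w2 * obs$error_rate +
    weights$w3 * obs$attention_variance
  min(2, max(0, raw))
}

#' Classify a load value into a band
#'
#' Strategy selector for the emotionally adaptive response stage: values
#' below `low_cut` are "low", values at or above `high_cut` are "high",
#' everything between is "moderate".
#'
#' @param load Load value in \[0, 2\].
#' @param low_cut,high_cut Band cut points, 0 <= low_cut < high_cut <= 2.
#' @return One of `"low"`, `"moderate"`, `"high"`.
#' @export
classify_load <- function(load, low_cut = 0.5, high_cut = 1.2) {
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 2))
    stop("need 0 <= low_cut < high_cut <= 2", call. = FALSE)
  if (!all(is.finite(load)) || any(load < 0) || any(load > 2))
    stop("load must lie in [0, 2]", call. = FALSE)
  ifelse(load < low_cut, "low", ifelse(load >= high_cut, "high", "moderate"))
}

#' Maximum-likelihood ability estimate
#'
#' Maximizes the Bernoulli 2PL log-likelihood of a history of
#' (difficulty, outcome) pairs over a bounded ability range. All-correct and
#' all-incorrect histories have no interior maximum and return the upper or
#' lower bound respectively.
#'
#' @param history Data frame with columns `difficulty` (logit scale) and
#'   `outcome` (0/1), or a two-column matrix in that order.
#' @param policy A [difficulty_policy()] (supplies the discrimination and
#'   default bounds).
#' @param bounds Length-2 numeric, the ability search range; defaults to
#'   `c(policy$theta_min, policy$theta_max)`.
#' @return The ability estimate theta-hat on the logit scale.
#' @export
#' @examples
#' h <- data.frame(difficulty = rep(0, 10), outcome = c(rep(1, 7), rep(0, 3)))
#' estimate_ability(h)  # ~ logit(0.7) = 0.847
estimate_ability <- function(history, policy = difficulty_policy(),
                             bounds = c(policy$theta_min, policy$theta_max)) {
  if (is.matrix(history))
    history <- data.frame(difficulty = history[, 1], outcome = history[, 2])
  if (is.null(history) || nrow(history) == 0)
    stop("history is empty: no data to estimate ability from", call. = FALSE)
  b <- history$difficulty
  y <- history$outcome
  if (!all(y %in% c(0, 1))) stop("outcomes must be 0/1", call. = FALSE)
  if (all(y == 1)) return(bounds[2])
  if (all(y == 0)) return(bounds[1])
  a <- policy$discrimination
  loglik <- function(theta) {
    p <- stats::plogis(a * (theta - b))
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  stats::optimize(loglik, interval = bounds, maximum = TRUE, tol = 1e-6)$maximum
}

#' Record a trial into the ability-tracking history
#'
#' Appends a (difficulty, outcome) pair, evicting the oldest entries beyond
#' the state's window.
#'
#' @param state An [ability_state()].
#' @param difficulty Trial difficulty on the logit scale.
#' @param outcome 0/1 trial outcome.
#' @return The updated `ability_state`.
#' @export
record_trial <- function(state, difficulty, outcome) {
  h <- rbind(state$history,
             data.frame(difficulty = difficulty, outcome = as.integer(outcome)))
  if (nrow(h) > state$window)
    h <- h[(nrow(h) - state$window + 1):nrow(h), , drop = FALSE]
  rownames(h) <- NULL
  state$history <- h
  state
}

#' Exponential smoothing of the ability estimate
#'
#' theta' = lambda theta + (1 - lambda) theta-hat. The smoothed value always
#' lies between the previous estimate and the new MLE, balancing historical
#' stability against day-to-day variability.
#'
#' @param state An [ability_state()].
#' @param estimate Fresh ability MLE theta-hat.
#' @return The updated `ability_state` with the smoothed `ability`.
#' @export
smooth_ability <- function(state, estimate) {
  if (!is.finite(estimate)) stop("estimate must be finite", call. = FALSE)
  lam <- state$smoothing
  state$ability <- lam * state$ability + (1 - lam) * estimate
  state
}

#' One engine step: record an outcome, re-estimate, smooth, adapt difficulty
#'
#' The per-trial adaptation loop: the realized outcome at the current
#' difficulty is appended to the history; the ability MLE over the recent
#' window is smoothed into the running estimate; the success probability at
#' the current difficulty is computed from the smoothed estimate (or taken
#' as the outcome under the stochastic-approximation variant) and drives the
#' clipped difficulty update.
#'
#' @param state An [ability_state()].
#' @param difficulty Difficulty at which the trial was administered.
#' @param outcome 0/1 trial outcome.
#' @param policy A [difficulty_policy()].
#' @return List with the updated `state`, the next `difficulty`, and the
#'   model success probability `p` used in the update.
#' @export
engine_step <- function(state, difficulty, outcome, policy = difficulty_policy()) {
  state <- record_trial(state, difficulty, outcome)
  est <- estimate_ability(state$history, policy)
  state <- smooth_ability(state, est)
  p <- success_probability(state$ability, difficulty, policy)
  drive <- if (policy$update_from_outcome) as.numeric(outcome) else p
  list(state = state,
       difficulty = update_difficulty(difficulty, drive, policy),
       p = p)
}

#' @export
print.difficulty_policy <- function(x, ...) {
  cat("Adaptive difficulty policy (2PL)\n")
  cat(sprintf("  discrimination a = %.3g, learning rate eta = %.3g\n",
              x$discrimination, x$learning_rate))
  cat(sprintf("  target success P* = %.3g\n", x$target_success))
  cat(sprintf("  difficulty in [%.3g, %.3g], ability in [%.3g, %.3g]\n",
              x$b_min, x$b_max, x$theta_min, x$theta_max))
  cat(sprintf("  MLE window = %d trials, update from %s\n", x$mle_window,
              if (x$update_from_outcome) "outcomes" else "model probability"))
  invisible(x)
}

#' @export
print.ability_state <- function(x, ...) {
  cat(sprintf("Ability state: theta = %.4f (lambda = %.2f, %d/%d trials in window)\n",
              x$ability, x$smoothing, nrow(x$history), x$window))
  invisible(x)
}
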