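# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive grid search for the 2PL likelihood,
# brute-force window scans for the discontinuation rules, and a plain
# reference queue for the context window.

# Two-stage exhaustive grid search of the Bernoulli 2PL log-likelihood:
# coarse grid over the full range, then a fine grid around the coarse
# maximum (final resolution 1e-4).
grid_mle <- function(difficulty, outcome, a = 1, lo = -4, hi = 4) {
  if (all(outcome == 1)) return(hi)
  if (all(outcome == 0)) return(lo)
  ll <- function(grid) {
    sapply(grid, function(th) {
      p <- 1 / (1 + exp(-a * (th - difficulty)))
      sum(outcome * log(p) + (1 - outcome) * log(1 - p))
    })
  }
  coarse <- seq(lo, hi, by = 0.01)
  c0 <- coarse[which.max(ll(coarse))]
  fine <- seq(max(lo, c0 - 0.02), min(hi, c0 + 0.02), by = 1e-4)
  fine[which.max(ll(fine))]
}

# Brute-force scan: first index w such that the window of `consecutive`
# values ending at w are all >= threshold (and, when given, all completed).
scan_first_run <- function(values, threshold, consecutive,
                           completed = rep(TRUE, length(values))) {
  ok <- values >= threshold & completed
  for (w in seq_along(ok)) {
    if (w >= consecutive && all(ok[(w - consecutive + 1):w])) return(w)
  }
  NA_integer_
}

# Plain FIFO reference for the context buffer.
ref_queue_push <- function(queue, item, capacity) {
  queue <- c(queue, list(item))
  if (length(queue) > capacity) queue <- queue[-1]
  queue
}

random_history <- function(n, a = 1) {
  b <- runif(n, -3, 3)
  theta <- runif(1, -3, 3)
  y <- rbinom(n, 1, 1 / (1 + exp(-a * (theta - b))))
  data.frame(difficulty = b, outcome = y)
}
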