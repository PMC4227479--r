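# Independent brute-force oracles used to cross-check the fast paths.

# Trial-by-trial replay of the Q-learning likelihood using the scalar
# public primitives (independent of the compiled sequence code).
replay_loglik <- function(trials, alpha, beta) {
  trials <- trials[trials$block >= 1L, , drop = FALSE]
  q <- c(A = 0, B = 0)
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    p_a <- choice_prob(q[["A"]], q[["B"]], beta)
    p <- if (trials$choice[i] == "A") p_a else 1 - p_a
    ll <- ll + log(max(p, 1e-12))
    ch <- trials$choice[i]
    q[[ch]] <- q_update(q[[ch]], trials$reward[i], alpha)
  }
  ll
}

# Closed-form simple-regression estimates from the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Build a subject around hand-made trials without schedule validation.
custom_subject <- function(trials, id = "T1", group = "g") {
  subject_data(id, group, "custom", trials)
}

# A degenerate one-block schedule for targeted simulations.
one_block_schedule <- function(prob_A, prob_B, n_trials, label = "custom") {
  drtlearn:::new_schedule(
    data.frame(prob_A = prob_A, prob_B = prob_B, n_trials = n_trials),
    label = label, total_gain = prob_A + prob_B)
}
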