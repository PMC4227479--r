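test_that("delta-rule update is a convex step toward the reward", {
  expect_equal(q_update(0, 1, 0.5), 0.5)
  expect_equal(q_update(0.8, 0.8, 0.3), 0.8)  # zero RPE is a fixed point
  expect_equal(q_update(0.2, 1, 1), 1)        # alpha = 1 copies the reward
  expect_error(q_update(0.5, 1, 1.5), "alpha")
  expect_error(q_update(0.5, 1, -0.1), "alpha")

  # boundedness: binary rewards, alpha in [0,1], start in [0,1]
  set.seed(3)
  for (rep in 1:20) {
    q <- runif(1)
    alpha <- runif(1)
    for (t in 1:100) {
      q <- q_update(q, rbinom(1, 1, 0.5), alpha)
      expect_true(q >= 0 && q <= 1)
    }
  }
})

test_that("softmax choice rule is symmetric, normalized and monotone", {
  expect_equal(choice_prob(0.3, 0.3, 5), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)  # beta = 0: random choice
  expect_equal(choice_prob(1, 0, log(3)), 0.75)
  expect_error(choice_prob(0.5, 0.5, -1), "beta")

  set.seed(4)
  qa <- runif(50); qb <- runif(50); beta <- runif(50, 0, 10)
  # normalization / label symmetry
  expect_equal(choice_prob(qa, qb, beta) + choice_prob(qb, qa, beta),
               rep(1, 50))
  # strictly increasing in the value difference for beta > 0
  d <- seq(-1, 1, by = 0.05)
  p <- choice_prob(d, 0, 3)
  expect_true(all(diff(p) > 0))
  # strictly increasing in beta when q_a > q_b
  betas <- seq(0, 10, by = 0.5)
  expect_true(all(diff(choice_prob(0.7, 0.2, betas)) > 0))
})

test_that("sequence log-likelihood matches known cases and a replay oracle", {
  ag <- simulate_agent(0.5, 4, drt_schedule("sequence-1"), seed = 2)
  # beta = 0 makes every choice probability one half
  expect_equal(log_likelihood(ag, 0.3, 0), 480 * log(0.5))
  # one-trial dataset from the symmetric (0, 0) start
  one <- custom_subject(data.frame(block = 1L, trial = 1L,
                                   choice = "A", reward = 1L))
  expect_equal(log_likelihood(one, 0.5, 6), log(0.5))

  # oracle equivalence on small instances
  set.seed(9)
  for (k in 1:20) {
    tr <- data.frame(block = 1L, trial = 1:10,
                     choice = sample(c("A", "B"), 10, replace = TRUE),
                     reward = rbinom(10, 1, 0.5))
    alpha <- runif(1); beta <- runif(1, 0, 8)
    expect_equal(log_likelihood(custom_subject(tr), alpha, beta),
                 replay_loglik(tr, alpha, beta), tolerance = 1e-12)
  }
})

test_that("the generative model is self-consistent under its likelihood", {
  sched <- drt_schedule("sequence-1")
  set.seed(21)
  ll_true <- ll_wrong <- numeric(300)
  for (i in 1:300) {
    ag <- simulate_agent(0.5, 4, sched)
    ll_true[i] <- log_likelihood(ag, 0.5, 4)
    ll_wrong[i] <- log_likelihood(ag, 0.5, 0.5)
  }
  expect_gt(mean(ll_true), mean(ll_wrong))
})

test_that("simulated agents behave sensibly across choice regimes", {
  # near-greedy agent on a deterministic schedule locks onto deck A
  greedy_sched <- one_block_schedule(1, 0, 60)
  set.seed(31)
  frac <- replicate(20, {
    ag <- simulate_agent(1, 10, greedy_sched)
    tr <- ag$trials[ag$trials$trial > 5, ]
    mean(tr$choice == "A")
  })
  expect_gte(mean(frac), 0.95)

  # beta = 0 is a fair coin regardless of alpha
  set.seed(32)
  a_frac <- replicate(200, mean(simulate_agent(0.7, 0,
    drt_schedule("sequence-1"))$trials$choice == "A"))
  se <- sqrt(0.25 / (200 * 480))
  expect_lt(abs(mean(a_frac) - 0.5), 3 * se)

  # a tuned agent outperforms a fast-forgetting, near-random one
  seeds <- 1:100
  tuned <- vapply(seeds, function(s)
    total_score(simulate_agent(0.35, 7, drt_schedule("sequence-1"),
                               seed = s)), 0L)
  sloppy <- vapply(seeds, function(s)
    total_score(simulate_agent(1, 0.5, drt_schedule("sequence-1"),
                               seed = s)), 0L)
  expect_gt(mean(tuned), mean(sloppy))
})

test_that("grid maximum-likelihood re-estimation recovers the parameters", {
  sched <- drt_schedule("sequence-1")
  set.seed(41)
  sessions <- lapply(1:10, function(i) simulate_agent(0.4, 4, sched))
  alphas <- seq(0.05, 1, by = 0.05)
  betas <- seq(0.5, 10, by = 0.5)
  grid <- expand.grid(alpha = alphas, beta = betas)
  ll <- vapply(seq_len(nrow(grid)), function(i)
    sum(vapply(sessions, log_likelihood, 0, grid$alpha[i], grid$beta[i])),
    0)
  best <- grid[which.max(ll), ]
  expect_lte(abs(best$alpha - 0.4), 0.05)
  expect_lte(abs(best$beta - 4), 1)
})

test_that("trial records are validated against their schedule", {
  ag <- simulate_agent(0.5, 3, drt_schedule("sequence-1"), seed = 1)
  expect_s3_class(ag, "subject_data")
  short <- ag$trials[-1, ]
  expect_error(subject_data("x", "g", "sequence-1", short), "counts")
  bad <- ag$trials; bad$reward[3] <- 2L
  expect_error(subject_data("x", "g", "sequence-1", bad), "reward")
})
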