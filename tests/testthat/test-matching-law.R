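make_block_trials <- function(block, choice, reward) {
  data.frame(block = block, trial = seq_along(choice),
             choice = choice, reward = reward)
}

test_that("steady-state aggregation counts the window correctly", {
  # a 70-trial block: the 21-70 window covers exactly 50 trials
  tr <- make_block_trials(1L, rep(c("A", "B"), 35), rep(0L, 70))
  agg <- aggregate_blocks(custom_subject(tr))
  expect_equal(agg$c_A + agg$c_B, 50)

  # all window choices A, all rewarded
  tr <- make_block_trials(1L, rep("A", 70), rep(1L, 70))
  agg <- aggregate_blocks(custom_subject(tr))
  expect_equal(agg[, c("c_A", "c_B", "r_A", "r_B")],
               data.frame(c_A = 50, c_B = 0, r_A = 50, r_B = 0))

  # brute-force tally on a random 90-trial block
  set.seed(17)
  tr <- make_block_trials(1L, sample(c("A", "B"), 90, replace = TRUE),
                          rbinom(90, 1, 0.4))
  agg <- aggregate_blocks(custom_subject(tr))
  w <- tr[21:70, ]
  expect_equal(agg$c_A, sum(w$choice == "A"))
  expect_equal(agg$c_B, sum(w$choice == "B"))
  expect_equal(agg$r_A, sum(w$reward[w$choice == "A"]))
  expect_equal(agg$r_B, sum(w$reward[w$choice == "B"]))

  # blocks shorter than the window end: error by default, clip if asked
  short <- make_block_trials(1L, rep("A", 60), rep(1L, 60))
  expect_error(aggregate_blocks(custom_subject(short)), "shorter")
  agg <- aggregate_blocks(custom_subject(short), truncate = TRUE)
  expect_equal(agg$c_A, 40)
})

test_that("blocks without rewards from both decks are excluded", {
  agg <- data.frame(subject_id = "s", group = "g", block_index = 1:4,
                    c_A = c(25, 25, 0, 25), c_B = c(25, 25, 50, 25),
                    r_A = c(0, 5, 0, 12), r_B = c(12, 7, 20, 0))
  kept <- filter_steady_state(agg)
  expect_equal(kept$block_index, 2L)

  set.seed(23)
  big <- data.frame(subject_id = "s", group = "g", block_index = 1:100,
                    c_A = rbinom(100, 50, 0.5))
  big$c_B <- 50 - big$c_A
  big$r_A <- rbinom(100, big$c_A, 0.3)
  big$r_B <- rbinom(100, big$c_B, 0.3)
  kept <- filter_steady_state(big)
  manual <- sum(big$r_A > 0 & big$r_B > 0 & big$c_A > 0 & big$c_B > 0)
  expect_equal(nrow(kept), manual)
  expect_true(all(kept$r_A > 0 & kept$r_B > 0))
})

test_that("matching regression matches closed-form least squares", {
  # noiseless points generated exactly on y = 0.37 x
  r_A <- c(4, 9, 16, 25, 30); r_B <- c(30, 20, 12, 6, 3)
  c_B <- rep(64, 5)
  c_A <- c_B * (r_A / r_B)^0.37
  agg <- data.frame(subject_id = "s", group = "g", block_index = 1:5,
                    c_A = c_A, c_B = c_B, r_A = r_A, r_B = r_B)
  fit <- suppressWarnings(fit_matching(agg))  # lm flags the perfect fit
  expect_equal(fit$sensitivity, 0.37, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # strict matching: choice ratio equals reward ratio
  agg2 <- agg
  agg2$c_A <- agg2$r_A * 3; agg2$c_B <- agg2$r_B * 3
  fit2 <- suppressWarnings(fit_matching(agg2))
  expect_equal(fit2$sensitivity, 1, tolerance = 1e-10)
  expect_equal(fit2$bias, 0, tolerance = 1e-10)

  # random points against the normal-equations oracle
  set.seed(29)
  agg3 <- data.frame(subject_id = "s", group = "g", block_index = 1:20,
                     c_A = sample(5:45, 20, TRUE),
                     c_B = sample(5:45, 20, TRUE),
                     r_A = sample(1:20, 20, TRUE),
                     r_B = sample(1:20, 20, TRUE))
  fit3 <- fit_matching(agg3)
  orc <- ols_oracle(log2(agg3$r_A / agg3$r_B), log2(agg3$c_A / agg3$c_B))
  expect_equal(fit3$sensitivity, orc$slope, tolerance = 1e-10)
  expect_equal(fit3$bias, orc$intercept, tolerance = 1e-10)
  expect_equal(fit3$se_sensitivity, orc$se_slope, tolerance = 1e-10)
  expect_equal(fit3$r_squared, orc$r2, tolerance = 1e-10)

  expect_error(fit_matching(agg3[1:2, ]), "at least 3")
})

test_that("sensitivity comparisons behave like slope t-tests", {
  mk <- function(s, se, n) structure(
    list(sensitivity = s, se_sensitivity = se, n_points = n),
    class = "matching_fit")
  f1 <- mk(0.37, 0.02, 100); f2 <- mk(0.31, 0.03, 125)

  same <- compare_sensitivity(f1, f1)
  expect_equal(same$t, 0)
  expect_equal(same$p_one_tailed, 0.5)

  cmp <- compare_sensitivity(f1, f2)
  expect_equal(cmp$t, 0.06 / sqrt(0.02^2 + 0.03^2), tolerance = 1e-12)
  expect_equal(cmp$df, 100 + 125 - 4)
  expect_lt(cmp$p_one_tailed, 0.5)

  flipped <- compare_sensitivity(f2, f1)
  expect_equal(flipped$t, -cmp$t)
})

test_that("relabeling decks flips the bias but not the sensitivity", {
  set.seed(37)
  agg <- data.frame(subject_id = "s", group = "g", block_index = 1:15,
                    c_A = sample(10:40, 15, TRUE),
                    c_B = sample(10:40, 15, TRUE),
                    r_A = sample(2:15, 15, TRUE),
                    r_B = sample(2:15, 15, TRUE))
  fit <- fit_matching(agg)
  swapped <- agg
  names(swapped)[match(c("c_A", "c_B", "r_A", "r_B"), names(swapped))] <-
    c("c_B", "c_A", "r_B", "r_A")
  fit_sw <- fit_matching(swapped)
  expect_equal(fit_sw$sensitivity, fit$sensitivity, tolerance = 1e-10)
  expect_equal(fit_sw$bias, -fit$bias, tolerance = 1e-10)
  expect_equal(fit_sw$r_squared, fit$r_squared, tolerance = 1e-10)
})

test_that("higher perseveration yields higher fitted sensitivity", {
  sched <- drt_schedule("sequence-1")
  betas <- c(1, 2, 4, 7, 10)
  sens <- vapply(seq_along(betas), function(i) {
    subs <- lapply(1:8, function(j)
      simulate_agent(0.5, betas[i], sched, subject_id = paste0("s", j),
                     seed = 1000 * i + j))
    fit_matching(filter_steady_state(aggregate_blocks(subs)))$sensitivity
  }, 0)
  expect_gt(cor(sens, betas, method = "spearman"), 0)
  # all simulated groups undermatch
  expect_true(all(sens < 1))
})
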