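test_that("retained-sample arithmetic matches the protocol", {
  st <- mcmc_settings()
  expect_equal(st$n_chains, 3L)
  expect_equal(st$n_iterations, 28000L)
  expect_equal(st$burn_in, 8000L)
  expect_equal(st$thin, 5L)
  expect_equal(st$n_retained, 12000L)

  expect_equal(mcmc_settings(3, 4000, 1000, 3)$n_retained, 3000L)
  expect_equal(mcmc_settings(2, 1100, 100, 7)$n_retained, 2L * (1000L %/% 7L))
  expect_error(mcmc_settings(3, 1000, 1000, 5), "burn_in")
  expect_error(mcmc_settings(0, 1000, 100, 5), "n_chains")
})

test_that("posterior difference probabilities match enumeration", {
  x <- c(1, 1, 1); y <- c(0, 0, 0)
  expect_equal(prob_diff_positive(x, y), 1)
  expect_equal(prob_diff_positive(y, x), 0)
  expect_equal(prob_diff_positive(x, x), 0)  # ties are not-greater

  set.seed(43)
  a <- round(rnorm(500), 1)  # rounding forces some ties
  b <- round(rnorm(500), 1)
  manual <- sum(a > b) / 500
  expect_equal(prob_diff_positive(a, b), manual)
  ties <- mean(a == b)
  expect_equal(prob_diff_positive(a, b) + prob_diff_positive(b, a) + ties, 1)
  expect_error(prob_diff_positive(a, b[-1]), "length")
})

test_that("Savage-Dickey density ratios match closed forms", {
  set.seed(47)
  # posterior far from zero: closed-form normal ratio
  d <- rnorm(2e5, 2, 0.5)
  bf <- suppressWarnings(savage_dickey_bf(d))
  expect_equal(bf$bf10, dnorm(0, 0, 1) / dnorm(0, 2, 0.5), tolerance = 0.1)
  expect_equal(bf$prior_density0, dnorm(0))

  # posterior identical to the prior: no evidence either way
  d0 <- rnorm(2e5)
  bf0 <- savage_dickey_bf(d0)
  expect_equal(bf0$bf10, 1, tolerance = 0.05)

  # invariance under a common affine rescaling of prior and posterior
  d1 <- rnorm(5000, 0.8, 0.6)
  b_raw <- savage_dickey_bf(d1)$bf10
  b_scaled <- savage_dickey_bf(3 * d1, prior_sd = 3)$bf10
  expect_equal(b_scaled, b_raw, tolerance = 1e-10)

  # order-restricted identity: directional BFs average to the two-sided one
  bg <- savage_dickey_bf(d1, direction = "greater")$bf10
  bl <- savage_dickey_bf(d1, direction = "less")$bf10
  expect_equal((bg + bl) / 2, b_raw, tolerance = 1e-10)

  expect_error(savage_dickey_bf(rep(1, 100)), "degenerate")
})

test_that("partial correlations match an independent formula", {
  # covariate an exact linear function of the estimate
  est <- c(1, 2, 3, 4, 5, 6)
  res <- correlate_params(est, 10 - 2 * est, dose = c(3, 1, 4, 1, 5, 9))
  expect_equal(res$partial_r, -1, tolerance = 1e-8)

  # six-row hand dataset against the correlation-algebra identity
  est <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.9)
  pan <- c(6, 3, 8, 2, 5, 4)
  dos <- c(120, 300, 180, 240, 90, 400)
  res <- correlate_params(est, pan, dos)
  rxy <- cor(est, pan); rxz <- cor(est, dos); ryz <- cor(pan, dos)
  expect_equal(res$partial_r,
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-10)
  expect_equal(res$pearson_r, rxy, tolerance = 1e-12)
  expect_equal(res$n, 6L)

  # independence: mean correlation near zero over replicates
  set.seed(53)
  rs <- replicate(50, {
    b <- rlnorm(45, 1, 0.5)
    correlate_params(b, rpois(45, 5), rlnorm(45, 5.5, 0.5))$partial_r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(50))

  expect_error(correlate_params(1:3, 1:3, 1:3), "at least 4")
})

test_that("the sampler recovers parameters of a homogeneous group", {
  sched <- drt_schedule("sequence-1")
  subs <- lapply(1:12, function(i)
    simulate_agent(0.7, 4, sched, subject_id = paste0("s", i),
                   group = "only", seed = 100 + i))
  st <- mcmc_settings(3, 2000, 500, 2, seed = 11)
  fit <- suppressWarnings(fit_hierarchical(subs, settings = st))

  expect_equal(nrow(fit$group_draws), st$n_retained)
  expect_equal(dim(fit$subject_draws$alpha), c(st$n_retained, 12L))
  a <- mean(group_mean_draws(fit, "alpha", "only"))
  b <- mean(group_mean_draws(fit, "beta", "only"))
  expect_lt(abs(a - 0.7), 0.1)
  expect_lt(abs(b - 4), 1.2)
  # credible-interval bounds are ordered and on the natural scales
  gm <- fit$summary[grepl("^mean_", fit$summary$parameter), ]
  expect_true(all(gm$lower95 <= gm$upper95))
  al <- fit$summary[grepl("^alpha\\.", fit$summary$parameter), ]
  expect_true(all(al$mean >= 0 & al$mean <= 1))
})

test_that("prior-only sampling reproduces the hyperpriors", {
  sched <- drt_schedule("sequence-1")
  subs <- lapply(1:4, function(i)
    simulate_agent(0.5, 3, sched, subject_id = paste0("p", i),
                   group = if (i <= 2) "g1" else "g2", seed = 200 + i))
  st <- mcmc_settings(3, 3000, 500, 2, seed = 19)
  fit <- fit_hierarchical(subs, settings = st, prior_only = TRUE)
  mu_a <- group_mean_draws(fit, "alpha", "g1", scale = "transformed")
  mu_b <- group_mean_draws(fit, "beta", "g1", scale = "transformed")
  expect_lt(abs(mean(mu_a)), 0.1)       # prior Normal(0, 1)
  expect_lt(abs(sd(mu_a) - 1), 0.15)
  expect_lt(abs(mean(mu_b)), 0.15)      # prior Normal(0, 1.5)
  expect_lt(abs(sd(mu_b) - 1.5), 0.2)
})

test_that("group differences combine draws, probabilities and BFs", {
  # two synthetic 'groups' with a known separation, via a hand-built fit
  set.seed(59)
  n <- 4000
  gd <- data.frame(chain = rep(1:2, each = n / 2), draw = rep(1:(n / 2), 2))
  gd[["mu_logbeta.x"]] <- rnorm(n, 1.4, 0.1)
  gd[["mu_logbeta.y"]] <- rnorm(n, 1.0, 0.1)
  gd[["sigma_logbeta.x"]] <- abs(rnorm(n, 0.5, 0.05))
  gd[["sigma_logbeta.y"]] <- abs(rnorm(n, 0.5, 0.05))
  fit <- structure(list(group_draws = gd, groups = c("x", "y")),
                   class = "posterior_result")
  res <- suppressWarnings(group_difference(fit, "beta", "x", "y"))
  manual <- mean(gd[["mu_logbeta.x"]] > gd[["mu_logbeta.y"]])
  expect_equal(res$p_greater, manual)
  expect_gt(res$p_greater, 0.95)
  expect_gt(res$bf$bf10, 1)
  expect_equal(res$delta,
               (gd[["mu_logbeta.x"]] - gd[["mu_logbeta.y"]]) /
                 sqrt((gd[["sigma_logbeta.x"]]^2 +
                       gd[["sigma_logbeta.y"]]^2) / 2))
})
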