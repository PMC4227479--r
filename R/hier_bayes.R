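#' Hierarchical model specification
#'
#' Subject-level parameters are modelled on transformed scales:
#' `alpha_i = pnorm(z_i)` with `z_i ~ Normal(mu_alpha[g], sigma_alpha[g])`
#' and `log(beta_i) ~ Normal(mu_logbeta[g], sigma_logbeta[g])`, one
#' `(mu, sigma)` pair per group.  Hyperpriors are weakly informative:
#' `mu_alpha ~ Normal(0, 1)`, `mu_logbeta ~ Normal(0, 1.5)`,
#' `sigma ~ Uniform(0, sigma_upper)` for both scales.  All prior
#' settings are exposed here so sensitivity analyses are a single
#' argument away.
#'
#' @param mu_alpha_prior,mu_logbeta_prior Length-2 `(mean, sd)` of the
#'   normal hyperpriors on the group-level means.
#' @param sigma_upper Upper bound of the uniform hyperprior on the
#'   group-level scales.
#' @return A `hier_model_spec` list.
#' @export
hier_model_spec <- function(mu_alpha_prior = c(0, 1),
                            mu_logbeta_prior = c(0, 1.5),
                            sigma_upper = 5) {
  if (mu_alpha_prior[2] <= 0 || mu_logbeta_prior[2] <= 0 || sigma_upper <= 0)
    stop_invalid("prior scales must be positive")
  structure(list(mu_alpha_prior = mu_alpha_prior,
                 mu_logbeta_prior = mu_logbeta_prior,
                 sigma_upper = sigma_upper),
            class = "hier_model_spec")
}

#' MCMC settings
#'
#' The retained-sample contract: each of `n_chains` chains runs
#' `n_iterations` iterations; the first `burn_in` are discarded and the
#' remainder kept at an interval of `thin`, so
#' `(n_iterations - burn_in) %/% thin * n_chains` draws are retained.
#' The historical defaults (3 chains of 28,000, burn-in 8,000, thinning
#' 5) retain exactly 12,000 draws per parameter.
#'
#' @param n_chains,n_iterations,burn_in,thin Integers as described.
#' @param seed Optional master seed; chain seeds are derived from it.
#' @return An `mcmc_settings` list including the derived `n_retained`.
#' @examples
#' mcmc_settings()$n_retained  # 12000
#' @export
mcmc_settings <- function(n_chains = 3L, n_iterations = 28000L,
                          burn_in = 8000L, thin = 5L, seed = NULL) {
  n_chains <- as.integer(n_chains); n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (n_chains < 1L || thin < 1L || burn_in < 0L ||
      n_iterations <= burn_in)
    stop_invalid("need n_chains >= 1, thin >= 1, 0 <= burn_in < n_iterations")
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 burn_in = burn_in, thin = thin, seed = seed,
                 n_retained = ((n_iterations - burn_in) %/% thin) * n_chains),
            class = "mcmc_settings")
}

#' Fit the hierarchical Q-learning model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler for the hierarchical model of
#' [hier_model_spec()] with the Q-learning/softmax sequence likelihood.
#' Each iteration proposes a joint random walk on every subject's
#' `(z_i, log beta_i)`, Gibbs-updates the group means from their
#' normal-normal conditionals, and random-walk-updates the group scales
#' under the uniform prior.  Proposal scales adapt toward standard
#' acceptance targets during burn-in only and are frozen afterwards.
#' Convergence is summarised by the split-chain scale-reduction statistic
#' (R-hat) on every group-level parameter; values above 1.1 set
#' `converged = FALSE` (flagged, never silently ignored).
#'
#' @param subjects List of `subject_data` (or a `drt_cohort`), at least
#'   two subjects per group.
#' @param model A [hier_model_spec()].
#' @param settings An [mcmc_settings()].
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler draws from the prior (useful for prior-recovery checks).
#' @param verbose Print progress per chain.
#' @return A `posterior_result` list: `group_draws` (data frame of
#'   retained draws with chain id and, per group, `mu_alpha`,
#'   `sigma_alpha`, `mu_logbeta`, `sigma_logbeta` plus the natural-scale
#'   group means `mean_alpha = pnorm(mu_alpha)` and
#'   `mean_beta = exp(mu_logbeta)`), `subject_draws` (list of matrices
#'   `alpha`, `beta`: retained draws x subjects), `summary` (means and
#'   central 95% credible intervals), `rhat`, `converged`, `groups`,
#'   `subject_ids`, `settings`, `model`.
#' @export
fit_hierarchical <- function(subjects, model = hier_model_spec(),
                             settings = mcmc_settings(),
                             prior_only = FALSE, verbose = FALSE) {
  if (inherits(subjects, "drt_cohort")) subjects <- subjects$subjects
  if (!is.list(subjects) || !all(vapply(subjects, inherits, TRUE, "subject_data")))
    stop_invalid("`subjects` must be a list of subject_data")
  groups <- vapply(subjects, `[[`, "", "group")
  glev <- unique(groups)
  if (any(table(groups) < 2L))
    stop_invalid("need at least two subjects per group")
  g <- match(groups, glev)
  n <- length(subjects)
  G <- length(glev)
  choices <- lapply(subjects, function(s) {
    tr <- testing_trials(s); as.integer(tr$choice == "B")
  })
  rewards <- lapply(subjects, function(s) {
    tr <- testing_trials(s); as.integer(tr$reward)
  })

  chain_seeds <- derive_seeds(settings$seed, settings$n_chains)
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    if (verbose) message("chain ", ch, "/", settings$n_chains)
    chains[[ch]] <- with_seed(chain_seeds[ch],
      run_chain(choices, rewards, g, G, model, settings, prior_only))
  }

  assemble_posterior(chains, glev, vapply(subjects, `[[`, "", "subject_id"),
                     settings, model)
}

# One MCMC chain.  Returns retained draws as matrices.
run_chain <- function(choices, rewards, g, G, model, settings, prior_only) {
  n <- length(g)
  n_iter <- settings$n_iterations
  burn <- settings$burn_in
  thin <- settings$thin
  n_keep <- (n_iter - burn) %/% thin

  m0z <- model$mu_alpha_prior[1];  s0z <- model$mu_alpha_prior[2]
  m0l <- model$mu_logbeta_prior[1]; s0l <- model$mu_logbeta_prior[2]
  upper <- model$sigma_upper

  # overdispersed start around plausible task values
  z <- rnorm(n, 0.8, 0.6)
  l <- rnorm(n, log(3), 0.6)
  mu_z <- vapply(seq_len(G), function(gi) mean(z[g == gi]), 0)
  mu_l <- vapply(seq_len(G), function(gi) mean(l[g == gi]), 0)
  sig_z <- rep(0.5, G); sig_l <- rep(0.5, G)

  ll <- if (prior_only) numeric(n)
        else loglik_all_cpp(choices, rewards, pnorm(z), exp(l))

  prop_sd <- rep(0.2, n)         # subject-level joint RW scale
  sig_prop <- rep(0.25, 2L * G)  # scales for (sig_z, sig_l) RW updates
  acc_sub <- numeric(n); acc_sig <- numeric(2L * G); adapt_n <- 0L

  keep_gz <- matrix(NA_real_, n_keep, G); keep_sz <- matrix(NA_real_, n_keep, G)
  keep_gl <- matrix(NA_real_, n_keep, G); keep_sl <- matrix(NA_real_, n_keep, G)
  keep_z <- matrix(NA_real_, n_keep, n); keep_l <- matrix(NA_real_, n_keep, n)
  krow <- 0L

  for (it in seq_len(n_iter)) {
    # --- subject-level joint RW Metropolis ------------------------------
    zp <- z + prop_sd * rnorm(n)
    lp <- l + prop_sd * rnorm(n)
    llp <- if (prior_only) numeric(n)
           else loglik_all_cpp(choices, rewards, pnorm(zp), exp(lp))
    logr <- llp - ll +
      dnorm(zp, mu_z[g], sig_z[g], log = TRUE) -
      dnorm(z,  mu_z[g], sig_z[g], log = TRUE) +
      dnorm(lp, mu_l[g], sig_l[g], log = TRUE) -
      dnorm(l,  mu_l[g], sig_l[g], log = TRUE)
    acc <- log(runif(n)) < logr
    z[acc] <- zp[acc]; l[acc] <- lp[acc]; ll[acc] <- llp[acc]
    acc_sub <- acc_sub + acc

    # --- group-level updates -------------------------------------------
    for (gi in seq_len(G)) {
      idx <- which(g == gi); ng <- length(idx)
      # conjugate normal draw for each group mean
      vz <- 1 / (1 / s0z^2 + ng / sig_z[gi]^2)
      mu_z[gi] <- rnorm(1, vz * (m0z / s0z^2 + sum(z[idx]) / sig_z[gi]^2),
                        sqrt(vz))
      vl <- 1 / (1 / s0l^2 + ng / sig_l[gi]^2)
      mu_l[gi] <- rnorm(1, vl * (m0l / s0l^2 + sum(l[idx]) / sig_l[gi]^2),
                        sqrt(vl))
      # RW Metropolis on each group scale, uniform(0, upper) prior
      sp <- sig_z[gi] + sig_prop[gi] * rnorm(1)
      if (sp > 0 && sp < upper) {
        lr <- sum(dnorm(z[idx], mu_z[gi], sp, log = TRUE)) -
          sum(dnorm(z[idx], mu_z[gi], sig_z[gi], log = TRUE))
        if (log(runif(1)) < lr) { sig_z[gi] <- sp; acc_sig[gi] <- acc_sig[gi] + 1 }
      }
      sp <- sig_l[gi] + sig_prop[G + gi] * rnorm(1)
      if (sp > 0 && sp < upper) {
        lr <- sum(dnorm(l[idx], mu_l[gi], sp, log = TRUE)) -
          sum(dnorm(l[idx], mu_l[gi], sig_l[gi], log = TRUE))
        if (log(runif(1)) < lr) {
          sig_l[gi] <- sp; acc_sig[G + gi] <- acc_sig[G + gi] + 1
        }
      }
    }

    # --- adaptation (burn-in only; frozen afterwards) -------------------
    adapt_n <- adapt_n + 1L
    if (it <= burn && adapt_n == 50L) {
      prop_sd <- pmin(pmax(prop_sd * exp(0.8 * (acc_sub / 50 - 0.30)),
                           0.01), 2)
      sig_prop <- pmin(pmax(sig_prop * exp(0.8 * (acc_sig / 50 - 0.44)),
                            0.01), 2)
      acc_sub[] <- 0; acc_sig[] <- 0; adapt_n <- 0L
    } else if (adapt_n == 50L) {
      acc_sub[] <- 0; acc_sig[] <- 0; adapt_n <- 0L
    }

    if (it > burn && (it - burn) %% thin == 0L) {
      krow <- krow + 1L
      keep_gz[krow, ] <- mu_z;  keep_sz[krow, ] <- sig_z
      keep_gl[krow, ] <- mu_l;  keep_sl[krow, ] <- sig_l
      keep_z[krow, ] <- z;      keep_l[krow, ] <- l
    }
  }
  list(mu_z = keep_gz, sig_z = keep_sz, mu_l = keep_gl, sig_l = keep_sl,
       z = keep_z, l = keep_l)
}

assemble_posterior <- function(chains, glev, subject_ids, settings, model) {
  G <- length(glev)
  n <- length(subject_ids)
  n_chain_keep <- nrow(chains[[1]]$mu_z)
  stack <- function(field) do.call(rbind, lapply(chains, `[[`, field))
  mu_z <- stack("mu_z"); sig_z <- stack("sig_z")
  mu_l <- stack("mu_l"); sig_l <- stack("sig_l")
  zdr <- stack("z"); ldr <- stack("l")

  group_draws <- data.frame(
    chain = rep(seq_along(chains), each = n_chain_keep),
    draw = rep(seq_len(n_chain_keep), times = length(chains)))
  for (gi in seq_len(G)) {
    gl <- glev[gi]
    group_draws[[paste0("mu_alpha.", gl)]] <- mu_z[, gi]
    group_draws[[paste0("sigma_alpha.", gl)]] <- sig_z[, gi]
    group_draws[[paste0("mu_logbeta.", gl)]] <- mu_l[, gi]
    group_draws[[paste0("sigma_logbeta.", gl)]] <- sig_l[, gi]
    group_draws[[paste0("mean_alpha.", gl)]] <- pnorm(mu_z[, gi])
    group_draws[[paste0("mean_beta.", gl)]] <- exp(mu_l[, gi])
  }

  # split-chain R-hat per group-level parameter (on the sampling scale)
  rhat <- c()
  per_chain <- function(mat, gi)
    lapply(chains, function(chn) chn[[mat]][, gi])
  for (gi in seq_len(G)) {
    gl <- glev[gi]
    rhat[paste0("mu_alpha.", gl)] <- split_rhat(per_chain("mu_z", gi))
    rhat[paste0("sigma_alpha.", gl)] <- split_rhat(per_chain("sig_z", gi))
    rhat[paste0("mu_logbeta.", gl)] <- split_rhat(per_chain("mu_l", gi))
    rhat[paste0("sigma_logbeta.", gl)] <- split_rhat(per_chain("sig_l", gi))
  }

  summ <- function(name, draws) {
    q <- quantile(draws, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = name, mean = mean(draws),
               lower95 = q[1], upper95 = q[2])
  }
  rows <- list()
  for (gi in seq_len(G)) {
    gl <- glev[gi]
    rows[[length(rows) + 1L]] <- summ(paste0("mu_alpha.", gl), mu_z[, gi])
    rows[[length(rows) + 1L]] <- summ(paste0("mu_logbeta.", gl), mu_l[, gi])
    rows[[length(rows) + 1L]] <- summ(paste0("mean_alpha.", gl),
                                      pnorm(mu_z[, gi]))
    rows[[length(rows) + 1L]] <- summ(paste0("mean_beta.", gl),
                                      exp(mu_l[, gi]))
  }
  alpha_draws <- pnorm(zdr); beta_draws <- exp(ldr)
  colnames(alpha_draws) <- colnames(beta_draws) <- subject_ids
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- summ(paste0("alpha.", subject_ids[i]),
                                      alpha_draws[, i])
    rows[[length(rows) + 1L]] <- summ(paste0("beta.", subject_ids[i]),
                                      beta_draws[, i])
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL

  structure(list(group_draws = group_draws,
                 subject_draws = list(alpha = alpha_draws, beta = beta_draws),
                 summary = summary_df,
                 rhat = rhat,
                 converged = all(rhat < 1.1, na.rm = TRUE),
                 groups = glev, subject_ids = subject_ids,
                 settings = settings, model = model),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("<posterior_result>", length(x$subject_ids), "subjects,",
      length(x$groups), "groups,", nrow(x$group_draws), "retained draws\n")
  cat("converged:", x$converged,
      sprintf("(max R-hat %.3f)\n", max(x$rhat, na.rm = TRUE)))
  gm <- x$summary[grepl("^mean_", x$summary$parameter), ]
  print(gm, row.names = FALSE, digits = 3)
  invisible(x)
}

# Split-chain scale-reduction statistic: each chain is halved, then the
# classic between/within variance ratio is computed over the 2K halves.
split_rhat <- function(chain_list) {
  halves <- list()
  for (x in chain_list) {
    m <- length(x) %/% 2L
    halves[[length(halves) + 1L]] <- x[seq_len(m)]
    halves[[length(halves) + 1L]] <- x[seq.int(m + 1L, 2L * m)]
  }
  m <- length(halves[[1]])
  if (m < 2L) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- m * var(means)
  if (W <= 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Extract group-mean posterior draws
#'
#' @param fit A `posterior_result`.
#' @param param `"alpha"` or `"beta"`.
#' @param group Group label.
#' @param scale `"natural"` (alpha in 0--1 / beta positive, via the
#'   inverse links) or `"transformed"` (probit / log sampling scale).
#' @return Numeric vector of retained draws.
#' @export
group_mean_draws <- function(fit, param = c("alpha", "beta"), group,
                             scale = c("natural", "transformed")) {
  param <- match.arg(param); scale <- match.arg(scale)
  stopifnot(inherits(fit, "posterior_result"), group %in% fit$groups)
  col <- if (scale == "natural") {
    paste0("mean_", param, ".", group)
  } else {
    paste0(if (param == "alpha") "mu_alpha." else "mu_logbeta.", group)
  }
  fit$group_draws[[col]]
}

#' Posterior probability that one group mean exceeds another
#'
#' Fraction of paired posterior draws (matched by iteration) for which
#' `samples_g1 - samples_g2 > 0`.  Ties count as not-greater (strict
#' inequality), so for identical vectors the result is 0.
#'
#' @param samples_g1,samples_g2 Equal-length draw vectors.
#' @return Probability in \[0, 1\].
#' @export
prob_diff_positive <- function(samples_g1, samples_g2) {
  if (length(samples_g1) != length(samples_g2))
    stop_invalid("sample vectors must have equal length (paired draws)")
  mean(samples_g1 > samples_g2)
}

#' Savage-Dickey Bayes factor for a group-mean difference
#'
#' Bayes factor `BF10` for the point null `delta = 0` of a nested,
#' standardized effect parameter, computed as the ratio of the prior
#' density at zero to the posterior density at zero.  The posterior
#' density is estimated by a normal approximation to the draws (mean/SD),
#' cross-checked against a kernel density estimate; a discrepancy above
#' 20% between the two triggers a warning.  One-sided variants rescale by
#' the posterior and prior mass in the stated direction (order-restricted
#' Savage-Dickey identity).
#'
#' @param delta Posterior draws of the standardized effect.
#' @param prior_mean,prior_sd Normal prior on the effect (default
#'   standard normal).
#' @param direction `"two.sided"`, `"greater"` (evidence for
#'   `delta > 0`) or `"less"`.
#' @return List with `bf10` (the requested Bayes factor),
#'   `posterior_density0`, `kde_density0`, `prior_density0`,
#'   `direction`.
#' @export
savage_dickey_bf <- function(delta, prior_mean = 0, prior_sd = 1,
                             direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (prior_sd <= 0) stop_invalid("`prior_sd` must be positive")
  m <- mean(delta); s <- sd(delta)
  if (!is.finite(s) || s == 0)
    stop_invalid("degenerate posterior: zero variance in `delta` draws")
  post0 <- dnorm(0, m, s)
  kde <- density(delta)
  kde0 <- approx(kde$x, kde$y, xout = 0)$y
  if (is.na(kde0)) kde0 <- 0
  if (post0 > 0 && abs(kde0 - post0) / post0 > 0.2)
    warning("normal and kernel estimates of the posterior density at 0 ",
            sprintf("differ by more than 20%% (%.3g vs %.3g); ", post0, kde0),
            "the posterior may be non-normal near zero")
  prior0 <- dnorm(0, prior_mean, prior_sd)
  bf <- prior0 / post0
  if (direction == "greater") {
    bf <- bf * mean(delta > 0) /
      pnorm(0, prior_mean, prior_sd, lower.tail = FALSE)
  } else if (direction == "less") {
    bf <- bf * mean(delta < 0) / pnorm(0, prior_mean, prior_sd)
  }
  list(bf10 = bf, posterior_density0 = post0, kde_density0 = kde0,
       prior_density0 = prior0, direction = direction)
}

#' Posterior comparison of two groups
#'
#' Computes, from a fitted `posterior_result`, the probability that the
#' first group's mean exceeds the second's (paired draws, transformed
#' scale) and the Savage-Dickey Bayes factor for the standardized
#' group-mean difference
#' `delta = (mu_g1 - mu_g2) / sqrt((sigma_g1^2 + sigma_g2^2) / 2)`
#' under a standard-normal prior.
#'
#' @param fit A `posterior_result`.
#' @param param `"alpha"` or `"beta"`.
#' @param g1,g2 Group labels.
#' @param direction Passed to [savage_dickey_bf()]; default tests the
#'   directional hypothesis `g1 > g2`.
#' @return List with `p_greater`, `bf`, and the `delta` draws.
#' @export
group_difference <- function(fit, param = c("alpha", "beta"), g1, g2,
                             direction = "greater") {
  param <- match.arg(param)
  stopifnot(inherits(fit, "posterior_result"),
            g1 %in% fit$groups, g2 %in% fit$groups)
  pre <- if (param == "alpha") c("mu_alpha.", "sigma_alpha.")
         else c("mu_logbeta.", "sigma_logbeta.")
  mu1 <- fit$group_draws[[paste0(pre[1], g1)]]
  mu2 <- fit$group_draws[[paste0(pre[1], g2)]]
  s1 <- fit$group_draws[[paste0(pre[2], g1)]]
  s2 <- fit$group_draws[[paste0(pre[2], g2)]]
  delta <- (mu1 - mu2) / sqrt((s1^2 + s2^2) / 2)
  list(p_greater = prob_diff_positive(mu1, mu2),
       bf = savage_dickey_bf(delta, direction = direction),
       delta = delta)
}

#' Correlate estimated perseveration (or learning rate) with symptoms
#'
#' Pearson correlation of per-subject parameter estimates (conventionally
#' posterior means) with the PANSS p1+p3 symptom score, plus the partial
#' correlation controlling for the standardized (z-scored)
#' chlorpromazine-equivalent dose, computed as the correlation of the
#' dose-residualized variables with `n - 3` degrees of freedom.
#'
#' @param estimates Numeric vector of per-subject parameter estimates.
#' @param panss_p1p3 Symptom scores, same length.
#' @param dose Dose covariate, same length; rows with missing values are
#'   dropped.
#' @return List with `pearson_r`, `pearson_p`, `partial_r`, `partial_p`,
#'   `n`.
#' @export
correlate_params <- function(estimates, panss_p1p3, dose) {
  d <- data.frame(est = estimates, panss = panss_p1p3, dose = dose)
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 4L)
    stop_invalid("need at least 4 complete subjects (got ", n, ")")
  ct <- cor.test(d$est, d$panss)
  dz <- as.numeric(scale(d$dose))
  re <- resid(lm(d$est ~ dz))
  rp <- resid(lm(d$panss ~ dz))
  r <- cor(re, rp)
  tval <- r * sqrt((n - 3) / (1 - r^2))
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       partial_r = r, partial_p = 2 * pt(-abs(tval), n - 3), n = n)
}
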