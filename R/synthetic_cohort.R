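#' Specify one group of a synthetic cohort
#'
#' A group is described by its size and by the location/scale of the
#' subject-level parameter distributions on the sampling scales used
#' throughout the package: learning rates are probit-normal
#' (`alpha = pnorm(z)`, `z ~ Normal(mu_alpha, sigma_alpha)`) and
#' perseveration is log-normal
#' (`beta = exp(l)`, `l ~ Normal(mu_logbeta, sigma_logbeta)`).
#' An optional covariate model attaches a synthetic PANSS p1+p3 score
#' (weakly, negatively linked to `beta`) and an independent
#' chlorpromazine-equivalent dose.
#'
#' @param label Group label.
#' @param n_subjects Positive integer group size.
#' @param mu_alpha,sigma_alpha Location/scale of the probit-scale
#'   learning-rate distribution (`sigma_alpha >= 0`; 0 collapses the
#'   group to a single alpha).
#' @param mu_logbeta,sigma_logbeta Location/scale of log-perseveration.
#' @param covariate_model Optional list with elements `panss_mean`,
#'   `panss_sd`, `panss_slope` (PANSS points per unit beta, applied to
#'   the deviation of beta from its group mean), `panss_range`
#'   (length-2 clamp), `dose_meanlog`, `dose_sdlog` (log-normal dose,
#'   drawn independently of the parameters).
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n_subjects, mu_alpha, sigma_alpha,
                       mu_logbeta, sigma_logbeta, covariate_model = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop_invalid("`n_subjects` must be a positive integer")
  if (sigma_alpha < 0 || sigma_logbeta < 0)
    stop_invalid("group scales must be non-negative")
  structure(list(label = as.character(label),
                 n_subjects = as.integer(n_subjects),
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_logbeta = mu_logbeta, sigma_logbeta = sigma_logbeta,
                 covariate_model = covariate_model),
            class = "group_spec")
}

#' Mean alpha / beta implied by a group specification
#'
#' Population means of the subject-level parameters under the group's
#' probit-normal / log-normal distributions:
#' `E[alpha] = pnorm(mu_alpha / sqrt(1 + sigma_alpha^2))` and
#' `E[beta] = exp(mu_logbeta + sigma_logbeta^2 / 2)`.
#'
#' @param spec A `group_spec`.
#' @return Named numeric `c(alpha =, beta =)`.
#' @export
implied_means <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  c(alpha = pnorm(spec$mu_alpha / sqrt(1 + spec$sigma_alpha^2)),
    beta = exp(spec$mu_logbeta + spec$sigma_logbeta^2 / 2))
}

# Back-solve mu for a target population mean given sigma.
mu_for_mean_alpha <- function(target, sigma) qnorm(target) * sqrt(1 + sigma^2)
mu_for_mean_beta <- function(target, sigma) log(target) - sigma^2 / 2

#' Default study-like group specifications
#'
#' Three groups emulating the schizophrenia/control study design the
#' package is built around: control (n = 24), low-psychosis (n = 19) and
#' high-psychosis (n = 26).  The location parameters are back-solved so
#' the implied population means equal the fitted group means reported for
#' the task (alpha 0.71 / 0.85 / 0.86; beta 4.11 / 4.16 / 2.91); the
#' between-subject scales (0.4 on the probit scale, 0.55 on the log
#' scale) are generator choices, since between-subject spreads are not
#' part of the reported fits, calibrated once so the lumped patient
#' correlation between beta and the synthetic symptom score is about
#' -0.26 in expectation.  Patient groups carry a synthetic PANSS p1+p3
#' covariate centred on the reported group means (5.92 +/- 1.70 high,
#' 2.42 +/- 0.69 low), clamped to the ranges the group-splitting rule
#' allows, with a weak negative within-group link to beta; the
#' chlorpromazine-equivalent dose is drawn independently of the
#' parameters (no dose-parameter association), moment-matched to the
#' reported 325.38 +/- 243.61 (high) and 267.11 +/- 134.96 (low) mg/day.
#'
#' @return List of three `group_spec`s, in the order control,
#'   low-psychosis, high-psychosis.
#' @export
default_cohort_specs <- function() {
  sa <- 0.4    # probit-scale alpha spread
  sb <- 0.55   # log-scale beta spread
  dose_lnorm <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }
  dh <- dose_lnorm(325.38, 243.61)
  dl <- dose_lnorm(267.11, 134.96)
  list(
    group_spec("control", 24,
               mu_alpha = mu_for_mean_alpha(0.71, sa), sigma_alpha = sa,
               mu_logbeta = mu_for_mean_beta(4.11, sb), sigma_logbeta = sb),
    group_spec("low-psychosis", 19,
               mu_alpha = mu_for_mean_alpha(0.85, sa), sigma_alpha = sa,
               mu_logbeta = mu_for_mean_beta(4.16, sb), sigma_logbeta = sb,
               covariate_model = list(panss_mean = 2.42, panss_sd = 0.69,
                                      panss_slope = -0.05,
                                      panss_range = c(2, 4),
                                      dose_meanlog = dl$meanlog,
                                      dose_sdlog = dl$sdlog)),
    group_spec("high-psychosis", 26,
               mu_alpha = mu_for_mean_alpha(0.86, sa), sigma_alpha = sa,
               mu_logbeta = mu_for_mean_beta(2.91, sb), sigma_logbeta = sb,
               covariate_model = list(panss_mean = 5.92, panss_sd = 1.70,
                                      panss_slope = -0.05,
                                      panss_range = c(4, 14),
                                      dose_meanlog = dh$meanlog,
                                      dose_sdlog = dh$sdlog)))
}

#' Sample a full synthetic cohort
#'
#' For each subject: draws `(alpha, beta)` from the group's hierarchical
#' distributions, assigns one of the two testing sequences at random,
#' randomizes which deck is advantageous in the 40-trial training block,
#' simulates training and the full 480-trial testing session through the
#' Q-learning agent, and attaches covariates per the group's covariate
#' model.  Ground-truth parameters are retained for recovery testing.
#'
#' @param specs List of `group_spec`s (default [default_cohort_specs()]).
#' @param seed Optional seed; the whole cohort is reproducible given the
#'   seed.
#' @return A `drt_cohort`: list with `subjects` (list of
#'   [subject_data()]) and `true_params` (data frame `subject_id`,
#'   `group`, `schedule_label`, `alpha`, `beta`).
#' @examples
#' specs <- default_cohort_specs()
#' coh <- sample_cohort(specs[c(1)], seed = 1)  # control group only
#' length(coh$subjects)
#' @export
sample_cohort <- function(specs = default_cohort_specs(), seed = NULL) {
  if (!is.list(specs) || length(specs) == 0L)
    stop_invalid("`specs` must be a non-empty list of group_spec objects")
  if (inherits(specs, "group_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, TRUE, "group_spec")))
    stop_invalid("every element of `specs` must be a group_spec")
  with_seed(seed, {
    subjects <- list()
    truth <- list()
    k <- 0L
    for (spec in specs) {
      for (i in seq_len(spec$n_subjects)) {
        k <- k + 1L
        id <- sprintf("S%03d", k)
        alpha <- pnorm(rnorm(1, spec$mu_alpha, spec$sigma_alpha))
        beta <- exp(rnorm(1, spec$mu_logbeta, spec$sigma_logbeta))
        seq_label <- sample(c("sequence-1", "sequence-2"), 1L)

        # training block: advantageous deck randomized per subject
        tr_sched <- drt_schedule("training")
        if (runif(1) < 0.5) {
          tmp <- tr_sched$prob_A
          tr_sched$prob_A <- tr_sched$prob_B
          tr_sched$prob_B <- tmp
        }
        high_deck <- if (tr_sched$prob_A[1] >= tr_sched$prob_B[1]) "A" else "B"
        tr_res <- sim_session_cpp(tr_sched$prob_A, tr_sched$prob_B,
                                  tr_sched$n_trials, alpha, beta)
        te_sched <- drt_schedule(seq_label)
        te_res <- sim_session_cpp(te_sched$prob_A, te_sched$prob_B,
                                  te_sched$n_trials, alpha, beta)
        trials <- rbind(
          data.frame(block = 0L, trial = seq_along(tr_res$choice),
                     choice = c("A", "B")[tr_res$choice + 1L],
                     reward = tr_res$reward),
          data.frame(block = te_res$block, trial = seq_along(te_res$choice),
                     choice = c("A", "B")[te_res$choice + 1L],
                     reward = te_res$reward))

        covs <- sample_covariates(spec, beta)
        subjects[[k]] <- subject_data(id, spec$label, seq_label, trials,
                                      covariates = covs,
                                      training_high_deck = high_deck)
        truth[[k]] <- data.frame(subject_id = id, group = spec$label,
                                 schedule_label = seq_label,
                                 alpha = alpha, beta = beta)
      }
    }
    structure(list(subjects = subjects,
                   true_params = do.call(rbind, truth)),
              class = "drt_cohort")
  })
}

sample_covariates <- function(spec, beta) {
  cm <- spec$covariate_model
  if (is.null(cm)) return(list(panss_p1p3 = NA_integer_, dose = NA_real_))
  target_beta <- implied_means(spec)[["beta"]]
  panss <- cm$panss_mean + cm$panss_slope * (beta - target_beta) +
    rnorm(1, 0, cm$panss_sd)
  panss <- as.integer(round(min(max(panss, cm$panss_range[1]),
                                cm$panss_range[2])))
  dose <- rlnorm(1, cm$dose_meanlog, cm$dose_sdlog)
  list(panss_p1p3 = panss, dose = dose)
}

#' @export
print.drt_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("<drt_cohort>", length(x$subjects), "subjects\n")
  print(groups)
  invisible(x)
}
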