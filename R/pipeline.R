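#' Write a cohort to delimited text files
#'
#' Writes `trials.csv` (columns `subject_id`, `group`, `schedule_label`,
#' `block`, `trial`, `choice`, `reward`; block 0 is the training block),
#' `covariates.csv` (`subject_id`, `group`, `panss_p1p3`, `dose`,
#' `training_high_deck`) and, when ground truth is available,
#' `true_params.csv`.
#'
#' @param cohort A `drt_cohort` or list of `subject_data`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  subjects <- if (inherits(cohort, "drt_cohort")) cohort$subjects else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trials <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               schedule_label = s$schedule_label, s$trials)))
  covars <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               panss_p1p3 = s$covariates$panss_p1p3 %||% NA_integer_,
               dose = s$covariates$dose %||% NA_real_,
               training_high_deck = s$training_high_deck)))
  paths <- c(trials = file.path(dir, "trials.csv"),
             covariates = file.path(dir, "covariates.csv"))
  write.csv(trials, paths["trials"], row.names = FALSE)
  write.csv(covars, paths["covariates"], row.names = FALSE)
  if (inherits(cohort, "drt_cohort") && !is.null(cohort$true_params)) {
    paths["true_params"] <- file.path(dir, "true_params.csv")
    write.csv(cohort$true_params, paths["true_params"], row.names = FALSE)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate trial data
#'
#' Reads the trials CSV (and optional covariates CSV), validates every
#' row (choices in A/B, rewards in 0/1) with line-numbered diagnostics,
#' reconstructs one [subject_data()] per subject and verifies each
#' subject's per-block trial counts against their declared schedule.
#'
#' @param trials_path Path to the trials CSV.
#' @param covariates_path Optional path to the covariates CSV.
#' @return List of validated `subject_data`.
#' @export
load_subjects <- function(trials_path, covariates_path = NULL) {
  if (!file.exists(trials_path))
    stop_invalid("trials file not found: ", trials_path)
  tr <- read.csv(trials_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "schedule_label", "block", "trial",
              "choice", "reward")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols))
    stop_invalid("trials file is missing columns: ",
                 paste(missing_cols, collapse = ", "))
  bad <- which(!tr$choice %in% c("A", "B"))
  if (length(bad))
    stop_invalid("invalid choice (must be A or B) at data row ", bad[1],
                 " of ", trials_path)
  bad <- which(!tr$reward %in% c(0L, 1L))
  if (length(bad))
    stop_invalid("invalid reward (must be 0 or 1) at data row ", bad[1],
                 " of ", trials_path)
  bad <- which(!tr$schedule_label %in%
                 c("sequence-1", "sequence-2", "training"))
  if (length(bad))
    stop_invalid("unknown schedule label '", tr$schedule_label[bad[1]],
                 "' at data row ", bad[1], " of ", trials_path)

  covs <- NULL
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path))
      stop_invalid("covariates file not found: ", covariates_path)
    covs <- read.csv(covariates_path, stringsAsFactors = FALSE)
  }
  lapply(split(tr, tr$subject_id), function(d) {
    cv <- NULL; high <- NA_character_
    if (!is.null(covs)) {
      row <- covs[covs$subject_id == d$subject_id[1], , drop = FALSE]
      if (nrow(row) == 1L) {
        cv <- list(panss_p1p3 = row$panss_p1p3, dose = row$dose)
        if (!is.null(row$training_high_deck))
          high <- row$training_high_deck
      }
    }
    subject_data(d$subject_id[1], d$group[1], d$schedule_label[1],
                 d[, c("block", "trial", "choice", "reward")],
                 covariates = cv, training_high_deck = high)
  })
}

#' Behavioral summary of a cohort
#'
#' Computes, per group: mean and SD of total testing score; the number of
#' subjects who chose the higher-probability deck on more than 50% of
#' training trials; and a one-way ANOVA of total score across groups.
#' Also returns each subject's choice time course smoothed with a
#' 10-trial (trailing) moving average, emitted as a data frame so figures
#' are reproducible from the numbers.
#'
#' @param subjects List of `subject_data` or a `drt_cohort`.
#' @param ma_window Moving-average window in trials (default 10).
#' @return A `behavioral_summary` list: `score_summary`,
#'   `training_majority`, `anova` (`F`, `p`), `choice_curves`.
#' @export
summarize_behavior <- function(subjects, ma_window = 10L) {
  if (inherits(subjects, "drt_cohort")) subjects <- subjects$subjects
  if (length(subjects) == 0L) stop_invalid("no subjects")
  groups <- vapply(subjects, `[[`, "", "group")
  scores <- vapply(subjects, total_score, 0L)
  score_summary <- do.call(rbind, lapply(unique(groups), function(g) {
    s <- scores[groups == g]
    data.frame(group = g, n = length(s), mean_score = mean(s),
               sd_score = sd(s))
  }))

  training_majority <- do.call(rbind, lapply(unique(groups), function(g) {
    subs <- subjects[groups == g]
    counts <- vapply(subs, function(s) {
      tr <- s$trials[s$trials$block == 0L, , drop = FALSE]
      if (nrow(tr) == 0L || is.na(s$training_high_deck)) return(NA)
      mean(tr$choice == s$training_high_deck) > 0.5
    }, NA)
    data.frame(group = g, n = length(subs),
               n_majority_high = sum(counts, na.rm = TRUE),
               n_with_training = sum(!is.na(counts)))
  }))

  anova_res <- if (length(unique(groups)) > 1L) {
    fit <- aov(scores ~ factor(groups))
    tab <- summary(fit)[[1]]
    list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"])
  } else list(F = NA_real_, p = NA_real_)

  curves <- do.call(rbind, lapply(subjects, function(s) {
    tr <- testing_trials(s)
    a <- as.numeric(tr$choice == "A")
    ma <- as.numeric(stats::filter(a, rep(1 / ma_window, ma_window),
                                   sides = 1))
    data.frame(subject_id = s$subject_id, group = s$group,
               trial = tr$trial, choice_A = a, ma_choice_A = ma)
  }))
  rownames(curves) <- NULL

  structure(list(score_summary = score_summary,
                 training_majority = training_majority,
                 anova = anova_res, choice_curves = curves,
                 ma_window = as.integer(ma_window)),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat("<behavioral_summary>\n")
  print(x$score_summary, row.names = FALSE, digits = 4)
  cat(sprintf("ANOVA on total score: F = %.2f, p = %.3f\n",
              x$anova$F, x$anova$p))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis stages in their natural order on a cohort:
#' behavioral summaries, group-level matching-law fits with pairwise
#' sensitivity comparisons, the hierarchical Bayesian fit with group
#' comparisons (posterior difference probabilities and Savage-Dickey
#' Bayes factors), symptom correlations for the patient groups, and
#' optionally the (alpha, beta) performance grid.  A machine-readable
#' JSON report plus supporting CSVs (choice curves, posterior draws,
#' grid) are written to `outdir`; the seed is recorded in the report and
#' the output is byte-reproducible for a fixed seed.
#'
#' @param subjects List of `subject_data`, a `drt_cohort`, or `NULL` to
#'   generate a default synthetic cohort from the seed.
#' @param outdir Output directory.
#' @param seed Master seed recorded in the report and used for every
#'   stochastic stage.
#' @param do_matching,do_hier,do_grid Stage toggles.
#' @param settings [mcmc_settings()] for the hierarchical stage.
#' @param grid_reps Repetitions per grid cell when `do_grid = TRUE`.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_full_pipeline <- function(subjects = NULL, outdir, seed = 1L,
                              do_matching = TRUE, do_hier = TRUE,
                              do_grid = FALSE,
                              settings = mcmc_settings(n_iterations = 4000L,
                                                       burn_in = 1000L,
                                                       thin = 3L),
                              grid_reps = 100L, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- derive_seeds(seed, 3L)

  if (is.null(subjects)) {
    say("sampling default synthetic cohort (seed ", stage_seeds[1], ")")
    subjects <- sample_cohort(default_cohort_specs(), seed = stage_seeds[1])
  }
  cohort <- if (inherits(subjects, "drt_cohort")) subjects
            else structure(list(subjects = subjects, true_params = NULL),
                           class = "drt_cohort")
  subs <- cohort$subjects

  report <- list(seed = seed, n_subjects = length(subs),
                 groups = as.list(table(vapply(subs, `[[`, "", "group"))))

  say("behavioral summary")
  beh <- summarize_behavior(subs)
  report$behavior <- list(
    score_summary = beh$score_summary,
    training_majority = beh$training_majority,
    anova = beh$anova)
  write.csv(beh$choice_curves, file.path(outdir, "choice_curves.csv"),
            row.names = FALSE)

  if (do_matching) {
    say("matching-law analysis")
    ml <- matching_by_group(subs)
    report$matching <- list(
      fits = lapply(ml$fits, function(f)
        f[c("sensitivity", "bias", "se_sensitivity", "r_squared",
            "n_points")]),
      comparisons = ml$comparisons,
      n_excluded = ml$n_excluded)
  }

  if (do_hier) {
    say("hierarchical Bayesian fit (", settings$n_chains, " chains x ",
        settings$n_iterations, " iterations)")
    settings$seed <- settings$seed %||% stage_seeds[2]
    fit <- fit_hierarchical(subs, settings = settings)
    gm <- fit$summary[grepl("^(mean_|mu_)", fit$summary$parameter), ]
    report$posterior <- list(
      settings = unclass(fit$settings)[c("n_chains", "n_iterations",
                                         "burn_in", "thin", "seed",
                                         "n_retained")],
      group_summary = gm,
      rhat = as.list(fit$rhat),
      converged = fit$converged)
    glev <- fit$groups
    if (length(glev) > 1L) {
      pairs <- utils::combn(glev, 2L, simplify = FALSE)
      report$posterior$comparisons <- lapply(pairs, function(p) {
        da <- group_difference(fit, "alpha", p[1], p[2])
        db <- group_difference(fit, "beta", p[1], p[2])
        list(g1 = p[1], g2 = p[2],
             alpha = list(p_greater = da$p_greater, bf10 = da$bf$bf10),
             beta = list(p_greater = db$p_greater, bf10 = db$bf$bf10))
      })
    }
    write.csv(cbind(fit$group_draws[, c("chain", "draw")],
                    fit$group_draws[, grepl("^(mu_|sigma_|mean_)",
                                            names(fit$group_draws))]),
              file.path(outdir, "posterior_group_draws.csv"),
              row.names = FALSE)

    # symptom correlations over the patient groups
    patients <- vapply(subs, function(s)
      !is.null(s$covariates) && !is.na(s$covariates$panss_p1p3 %||% NA), NA)
    if (sum(patients) >= 4L) {
      say("symptom correlations (", sum(patients), " patients)")
      idx <- which(patients)
      beta_hat <- colMeans(fit$subject_draws$beta)[idx]
      alpha_hat <- colMeans(fit$subject_draws$alpha)[idx]
      panss <- vapply(subs[idx], function(s) as.numeric(s$covariates$panss_p1p3), 0)
      dose <- vapply(subs[idx], function(s) as.numeric(s$covariates$dose), 0)
      report$correlations <- list(
        beta_panss = correlate_params(beta_hat, panss, dose),
        alpha_panss = correlate_params(alpha_hat, panss, dose))
    }
  }

  if (do_grid) {
    say("performance grid (", grid_reps, " reps/cell)")
    grid <- run_grid(n_reps = grid_reps, seed = stage_seeds[3])
    opt <- locate_optimum(grid)
    report$grid <- list(optimum = opt,
                        sd_range = c(min(grid$sd_score),
                                     max(grid$sd_score)),
                        n_cells = nrow(grid), n_reps = grid_reps,
                        seed = stage_seeds[3])
    write.csv(as.data.frame(grid), file.path(outdir, "grid.csv"),
              row.names = FALSE)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  say("report written to ", file.path(outdir, "report.json"))
  invisible(report)
}
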