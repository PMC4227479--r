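#' Q-learning value update
#'
#' Delta-rule update of the chosen deck's expected value:
#' `q + alpha * (reward - q)`.  The difference `reward - q` is the reward
#' prediction error; `alpha` sets the fraction of it incorporated each
#' trial.  Only the chosen deck is updated in the task model; the other
#' deck's value is left unchanged.
#'
#' @param q Current expected value(s).
#' @param reward Observed reward(s), usually 0/1.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expected value(s).
#' @examples
#' q_update(0, 1, 0.5)   # 0.5
#' q_update(0.2, 1, 1)   # 1: alpha = 1 copies the last reward
#' @export
q_update <- function(q, reward, alpha) {
  check_alpha(alpha)
  q + alpha * (reward - q)
}

#' Softmax probability of choosing deck A
#'
#' Evaluates the softmax (logistic) choice rule
#' `exp(beta * q_a) / (exp(beta * q_a) + exp(beta * q_b))`, computed in
#' the numerically stable differenced form.  `beta` is the choice
#' perseveration (inverse temperature): `beta = 0` gives random 50/50
#' choice; large `beta` means strong exploitation of the currently higher
#' valued deck.
#'
#' @param q_a,q_b Expected values of decks A and B.
#' @param beta Choice perseveration, non-negative.
#' @return Probability of choosing deck A, in (0, 1).
#' @examples
#' choice_prob(1, 0, log(3))  # 0.75
#' choice_prob(0.9, 0.1, 0)   # 0.5
#' @export
choice_prob <- function(q_a, q_b, beta) {
  check_beta(beta)
  stats::plogis(beta * (q_a - q_b))
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0 | alpha > 1))
    stop_invalid("`alpha` (learning rate) must lie in [0, 1]")
  invisible(alpha)
}

check_beta <- function(beta) {
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta < 0))
    stop_invalid("`beta` (choice perseveration) must be non-negative")
  invisible(beta)
}

#' Construct a single subject's task record
#'
#' Bundles one subject's trial-by-trial choices and rewards with group
#' label, schedule label and optional covariates.  Trials are stored as a
#' data frame with columns `block` (0 denotes the 40-trial training
#' block, 1--6 the testing blocks), `trial` (1-based within session),
#' `choice` (`"A"`/`"B"`) and `reward` (0/1).  For a known schedule label
#' the per-block trial counts are validated against the schedule.
#'
#' @param subject_id Character id.
#' @param group Group label, conventionally one of `"control"`,
#'   `"low-psychosis"`, `"high-psychosis"` (other labels are allowed).
#' @param schedule_label Testing-schedule label (`"sequence-1"`,
#'   `"sequence-2"`, or a custom label which skips count validation).
#' @param trials Trial data frame as described above.
#' @param covariates Optional named list (e.g. `panss_p1p3`, `dose`).
#' @param training_high_deck Which deck carried the higher reward
#'   probability in this subject's training block (`"A"`, `"B"` or `NA`).
#' @return A `subject_data` object.
#' @export
subject_data <- function(subject_id, group, schedule_label, trials,
                         covariates = NULL, training_high_deck = NA_character_) {
  if (!is.data.frame(trials) ||
      !all(c("block", "trial", "choice", "reward") %in% names(trials)))
    stop_invalid("`trials` must have columns block, trial, choice, reward")
  if (!all(trials$choice %in% c("A", "B")))
    stop_invalid("trial choices must be \"A\" or \"B\"")
  if (!all(trials$reward %in% c(0L, 1L)))
    stop_invalid("trial rewards must be 0 or 1")
  trials <- trials[order(trials$block != 0L, trials$trial), , drop = FALSE]
  rownames(trials) <- NULL
  x <- structure(list(subject_id = as.character(subject_id),
                      group = as.character(group),
                      schedule_label = schedule_label,
                      trials = trials,
                      covariates = covariates,
                      training_high_deck = training_high_deck),
                 class = "subject_data")
  validate_subject(x)
  x
}

validate_subject <- function(x) {
  if (x$schedule_label %in% c("sequence-1", "sequence-2")) {
    sched <- drt_schedule(x$schedule_label)
    test <- x$trials[x$trials$block >= 1L, , drop = FALSE]
    counts <- tabulate(test$block, nbins = nrow(sched))
    if (!identical(as.integer(counts), sched$n_trials))
      stop_invalid("subject ", x$subject_id, ": per-block trial counts (",
                   paste(counts, collapse = ","),
                   ") do not match schedule ", x$schedule_label, " (",
                   paste(sched$n_trials, collapse = ","), ")")
    ntr <- sum(x$trials$block == 0L)
    if (ntr > 0L && ntr != 40L)
      stop_invalid("subject ", x$subject_id,
                   ": training block must have 40 trials, found ", ntr)
  }
  invisible(x)
}

#' @export
print.subject_data <- function(x, ...) {
  cat("<subject_data>", x$subject_id, "| group:", x$group,
      "| schedule:", x$schedule_label, "\n")
  cat("  trials:", nrow(x$trials),
      "(training:", sum(x$trials$block == 0L), ")",
      "| total score:", total_score(x), "\n")
  invisible(x)
}

#' Total testing-session score
#'
#' Sum of rewards over the testing blocks (training trials excluded).
#'
#' @param x A `subject_data`.
#' @return Integer total score.
#' @export
total_score <- function(x) {
  stopifnot(inherits(x, "subject_data"))
  sum(x$trials$reward[x$trials$block >= 1L])
}

testing_trials <- function(x) {
  tr <- x$trials[x$trials$block >= 1L, , drop = FALSE]
  tr[order(tr$trial), , drop = FALSE]
}

#' Log-likelihood of a choice sequence under the Q-learning model
#'
#' Replays the Q-state forward from `(0, 0)` through the recorded
#' testing-session choices and rewards, summing the natural log of the
#' softmax probability of each recorded choice evaluated at the
#' pre-choice Q-state.  Training trials (block 0) are excluded: they are
#' familiarization, not fitted data.  Per-trial probabilities are floored
#' at 1e-12 before the log so the likelihood stays finite at extreme
#' `beta`.
#'
#' @param x A `subject_data`, or a trial data frame with columns
#'   `block`, `trial`, `choice`, `reward`.
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Choice perseveration, non-negative.
#' @return The log-likelihood (natural log), a single number.
#' @export
log_likelihood <- function(x, alpha, beta) {
  check_alpha(alpha)
  check_beta(beta)
  tr <- if (inherits(x, "subject_data")) testing_trials(x)
        else x[x$block >= 1L, , drop = FALSE]
  if (nrow(tr) == 0L) stop_invalid("no testing trials to evaluate")
  loglik_cpp(as.integer(tr$choice == "B"), as.integer(tr$reward),
             alpha, beta)
}

#' Simulate one agent through a schedule
#'
#' Generates choices from the softmax rule, rewards from the schedule's
#' deck probabilities (chosen deck only, redrawn each trial), and updates
#' the chosen deck's Q-value by the delta rule, starting from Q = (0, 0).
#' Block boundaries carry no signal: the Q-state runs straight through
#' the session.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Choice perseveration, non-negative.
#' @param schedule A `drt_schedule` (testing sequence or training).
#' @param subject_id,group Labels attached to the result.
#' @param seed Optional seed (restores the caller's RNG state afterwards);
#'   with `NULL` the global stream is used.
#' @return A `subject_data` with the simulated trials (blocks numbered
#'   from 1; for the training schedule a single block 0 is used).
#' @examples
#' ag <- simulate_agent(0.35, 7, drt_schedule("sequence-1"), seed = 1)
#' total_score(ag)
#' @export
simulate_agent <- function(alpha, beta, schedule, subject_id = "sim",
                           group = "sim", seed = NULL) {
  check_alpha(alpha)
  check_beta(beta)
  stopifnot(inherits(schedule, "drt_schedule"))
  res <- with_seed(seed,
                   sim_session_cpp(schedule$prob_A, schedule$prob_B,
                                   schedule$n_trials, alpha, beta))
  label <- attr(schedule, "label")
  training <- identical(label, "training")
  trials <- data.frame(
    block = if (training) 0L else res$block,
    trial = seq_along(res$choice),
    choice = c("A", "B")[res$choice + 1L],
    reward = res$reward)
  subject_data(subject_id, group, schedule_label = label, trials = trials,
               training_high_deck = if (training) {
                 if (schedule$prob_A[1] >= schedule$prob_B[1]) "A" else "B"
               } else NA_character_)
}
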