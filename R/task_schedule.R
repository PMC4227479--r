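#' Deck reward probabilities from a gain ratio
#'
#' Splits a total gain probability between two decks according to an
#' integer gain ratio, using exact rational arithmetic before any
#' rounding.  With the task's canonical 1:6 ratio and total 0.6 this
#' yields 3/35 and 18/35, conventionally printed as 0.0857 and 0.5143.
#'
#' @param ratio Length-2 positive numeric, the low:high gain ratio
#'   (e.g. `c(1, 6)`).
#' @param total Total gain probability across both decks, in (0, 1].
#'   Defaults to the task's fixed 0.6.
#' @return Named numeric `c(p_low =, p_high =)` summing to `total`.
#' @examples
#' probs_from_ratio(c(1, 6), 0.6)  # 0.0857..., 0.5143...
#' probs_from_ratio(c(1, 3), 0.6)  # 0.15, 0.45
#' @export
probs_from_ratio <- function(ratio, total = 0.6) {
  if (!is.numeric(ratio) || length(ratio) != 2L || any(!is.finite(ratio)) ||
      any(ratio <= 0))
    stop_invalid("`ratio` must be two positive finite numbers (low:high)")
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) ||
      total <= 0 || total > 1)
    stop_invalid("`total` must be a single probability in (0, 1]")
  p <- total * sort(ratio) / sum(ratio)
  c(p_low = p[[1]], p_high = p[[2]])
}

#' Built-in dynamic reward task schedules
#'
#' Returns one of the three session schedules: the two six-block testing
#' sequences (70--90 trials per block, 480 trials in total, with the
#' advantageous deck alternating between consecutive blocks) or the
#' 40-trial 1:6 training block.  Probabilities are stored as exact
#' rationals (3/35, 18/35, 0.15, 0.45) so that each block's two deck
#' probabilities sum to the total gain probability 0.6 exactly; they are
#' rounded only for display.
#'
#' @param label One of `"sequence-1"`, `"sequence-2"`, `"training"`.
#' @return A `drt_schedule`: a data frame with columns `block`, `prob_A`,
#'   `prob_B`, `n_trials` and attributes `label` and `total_gain`.
#' @examples
#' sched <- drt_schedule("sequence-1")
#' sum(sched$n_trials)  # 480
#' @export
drt_schedule <- function(label = c("sequence-1", "sequence-2", "training")) {
  label <- match.arg(label)
  p16 <- probs_from_ratio(c(1, 6), 0.6)  # 3/35, 18/35
  p13 <- probs_from_ratio(c(1, 3), 0.6)  # 0.15, 0.45
  blocks <- switch(label,
    "sequence-1" = data.frame(
      prob_A   = c(p13[[2]], p16[[1]], p13[[2]], p16[[1]], p16[[2]], p13[[1]]),
      prob_B   = c(p13[[1]], p16[[2]], p13[[1]], p16[[2]], p16[[1]], p13[[2]]),
      n_trials = c(70L, 80L, 90L, 90L, 80L, 70L)),
    "sequence-2" = data.frame(
      prob_A   = c(p13[[2]], p16[[1]], p16[[2]], p13[[1]], p16[[2]], p13[[1]]),
      prob_B   = c(p13[[1]], p16[[2]], p16[[1]], p13[[2]], p16[[1]], p13[[2]]),
      n_trials = c(80L, 70L, 90L, 80L, 70L, 90L)),
    "training" = data.frame(
      prob_A = p16[[1]], prob_B = p16[[2]], n_trials = 40L))
  new_schedule(blocks, label)
}

new_schedule <- function(blocks, label, total_gain = 0.6) {
  blocks <- data.frame(block = seq_len(nrow(blocks)),
                       prob_A = blocks$prob_A, prob_B = blocks$prob_B,
                       n_trials = as.integer(blocks$n_trials))
  out <- structure(blocks, class = c("drt_schedule", "data.frame"),
                   label = label, total_gain = total_gain)
  validate_schedule(out)
  out
}

validate_schedule <- function(x) {
  if (any(x$prob_A < 0 | x$prob_A > 1 | x$prob_B < 0 | x$prob_B > 1))
    stop_invalid("schedule probabilities must lie in [0, 1]")
  if (any(x$n_trials < 1L))
    stop_invalid("schedule trial counts must be positive")
  tg <- attr(x, "total_gain")
  if (!is.null(tg) && any(abs(x$prob_A + x$prob_B - tg) > 1e-9))
    stop_invalid("each block's deck probabilities must sum to the total ",
                 "gain probability (", tg, ")")
  invisible(x)
}

#' @export
print.drt_schedule <- function(x, ...) {
  cat("Dynamic reward task schedule:", attr(x, "label"), "\n")
  shown <- data.frame(block = x$block,
                      prob_A = sprintf("%.2f%%", 100 * x$prob_A),
                      prob_B = sprintf("%.2f%%", 100 * x$prob_B),
                      n_trials = x$n_trials)
  print(shown, row.names = FALSE)
  cat("Total trials:", sum(x$n_trials), "\n")
  invisible(x)
}

#' Serialize a schedule to/from JSON
#'
#' Custom block structures can be exchanged as JSON configuration files
#' holding the label, per-block deck probabilities and trial counts.
#'
#' @param schedule A `drt_schedule`.
#' @param path File path; for `schedule_to_json` with `path = NULL` the
#'   JSON string is returned instead of written.
#' @return `schedule_to_json` returns the JSON string (invisibly when
#'   written to file); `schedule_from_json` returns a `drt_schedule`.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  stopifnot(inherits(schedule, "drt_schedule"))
  obj <- list(label = attr(schedule, "label"),
              total_gain = attr(schedule, "total_gain"),
              prob_A = schedule$prob_A, prob_B = schedule$prob_B,
              n_trials = schedule$n_trials)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname schedule_to_json
#' @export
schedule_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_schedule(data.frame(prob_A = obj$prob_A, prob_B = obj$prob_B,
                          n_trials = obj$n_trials),
               label = obj$label,
               total_gain = if (is.null(obj$total_gain)) 0.6 else obj$total_gain)
}

#' Draw rewards for chosen decks
#'
#' Generates the 0/1 reward outcome for each choice under a block's deck
#' probabilities.  Rewards are drawn independently on every trial for the
#' chosen deck only: the task does not "bait" a deck, so an unclaimed
#' reward never carries over and the non-chosen deck's status is redrawn
#' next time it is sampled.
#'
#' @param block A single-block data frame (one row of a `drt_schedule`)
#'   with columns `prob_A` and `prob_B`.
#' @param choice Character vector of deck identifiers, `"A"` or `"B"`.
#' @return Integer vector of rewards in \{0, 1\}, one per choice.  Uses
#'   the global RNG; seed with [set.seed()] for reproducibility.
#' @export
draw_reward <- function(block, choice) {
  if (nrow(block) != 1L || is.null(block$prob_A) || is.null(block$prob_B))
    stop_invalid("`block` must be a single schedule row with prob_A/prob_B")
  if (!all(choice %in% c("A", "B")))
    stop_invalid("`choice` entries must be \"A\" or \"B\"")
  p <- ifelse(choice == "A", block$prob_A, block$prob_B)
  as.integer(runif(length(p)) < p)
}
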