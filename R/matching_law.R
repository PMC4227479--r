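#' Steady-state block aggregation of choices and rewards
#'
#' Counts choices (`c_A`, `c_B`) and rewards received (`r_A`, `r_B`) per
#' testing block within the steady-state window, by default trials 21--70
#' of each block (1-based within-block, inclusive; 50 trials).  Early
#' trials of a block are excluded because the subject is still adapting
#' to the unsignaled probability reversal.
#'
#' @param x A `subject_data` or a list of them (a cohort's `subjects`).
#' @param window Length-2 integer within-block trial range, inclusive.
#' @param truncate If `TRUE`, blocks shorter than `window[2]` are
#'   truncated at the block end; the default (`FALSE`) treats them as an
#'   error, since all built-in testing blocks have at least 70 trials.
#' @return Data frame with columns `subject_id`, `group`, `block_index`,
#'   `c_A`, `c_B`, `r_A`, `r_B`.
#' @export
aggregate_blocks <- function(x, window = c(21L, 70L), truncate = FALSE) {
  if (inherits(x, "subject_data")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "subject_data")))
    stop_invalid("`x` must be a subject_data or a list of them")
  if (length(window) != 2L || window[1] < 1L || window[2] < window[1])
    stop_invalid("`window` must be an increasing 1-based trial range")
  out <- lapply(x, function(s) {
    tr <- testing_trials(s)
    do.call(rbind, lapply(split(tr, tr$block), function(blk) {
      n <- nrow(blk)
      if (n < window[2] && !truncate)
        stop_invalid("subject ", s$subject_id, " block ", blk$block[1],
                     " has ", n, " trials, shorter than the steady-state ",
                     "window end (", window[2], "); set truncate = TRUE ",
                     "to clip the window")
      blk <- blk[order(blk$trial), , drop = FALSE]
      w <- blk[seq(window[1], min(window[2], n)), , drop = FALSE]
      data.frame(subject_id = s$subject_id, group = s$group,
                 block_index = blk$block[1],
                 c_A = sum(w$choice == "A"), c_B = sum(w$choice == "B"),
                 r_A = sum(w$reward[w$choice == "A"]),
                 r_B = sum(w$reward[w$choice == "B"]))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exclude blocks without rewards from both decks
#'
#' Drops every block aggregate in which the subject gained no reward from
#' one of the decks (`r_A = 0` or `r_B = 0`), since the log reward ratio
#' is undefined there.  A deck never chosen in the window necessarily has
#' zero rewards and is removed by the same rule; a defensive check also
#' drops any zero-choice block that slips through.  Remaining rows are
#' returned unchanged and in order.
#'
#' @param aggregates Data frame from [aggregate_blocks()].
#' @return The filtered data frame.
#' @export
filter_steady_state <- function(aggregates) {
  keep <- aggregates$r_A > 0 & aggregates$r_B > 0 &
    aggregates$c_A > 0 & aggregates$c_B > 0
  out <- aggregates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the generalized matching law
#'
#' Ordinary least squares of `log2(c_A / c_B)` on `log2(r_A / r_B)` over
#' block-level points (pooled across the subjects present in
#' `aggregates`).  The slope is the reward sensitivity `s`; the
#' intercept is the bias `log2 k`.  `s = 1` is strict matching; `s < 1`
#' is undermatching.
#'
#' @param aggregates Filtered data frame ([filter_steady_state()]); at
#'   least 3 rows with all counts positive.
#' @return A `matching_fit` list: `sensitivity`, `bias`,
#'   `se_sensitivity`, `r_squared`, `n_points`, and the fitted `lm`
#'   object as `model`.
#' @export
fit_matching <- function(aggregates) {
  if (nrow(aggregates) < 3L)
    stop_invalid("need at least 3 block-level points to fit the matching ",
                 "law (got ", nrow(aggregates), ")")
  if (any(aggregates$c_A == 0 | aggregates$c_B == 0 |
          aggregates$r_A == 0 | aggregates$r_B == 0))
    stop_invalid("all choice and reward counts must be positive; apply ",
                 "filter_steady_state() first")
  x <- log2(aggregates$r_A / aggregates$r_B)
  y <- log2(aggregates$c_A / aggregates$c_B)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(sensitivity = unname(coef(fit)[2]),
                 bias = unname(coef(fit)[1]),
                 se_sensitivity = unname(sm$coefficients[2, 2]),
                 r_squared = sm$r.squared,
                 n_points = nrow(aggregates),
                 model = fit),
            class = "matching_fit")
}

#' @export
print.matching_fit <- function(x, ...) {
  cat(sprintf(
    "<matching_fit> s = %.3f (SE %.3f), bias log2(k) = %.3f, R^2 = %.3f, n = %d\n",
    x$sensitivity, x$se_sensitivity, x$bias, x$r_squared, x$n_points))
  invisible(x)
}

#' Compare reward sensitivities of two matching fits
#'
#' Two-sample slope-difference t-test,
#' `t = (s1 - s2) / sqrt(se1^2 + se2^2)` on `n1 + n2 - 4` degrees of
#' freedom (two slopes and two intercepts estimated), with a one-tailed
#' p-value for the a priori alternative `s1 > s2`.
#'
#' @param fit1,fit2 `matching_fit` objects.
#' @return List with `t`, `df`, `p_one_tailed`.
#' @export
compare_sensitivity <- function(fit1, fit2) {
  for (f in list(fit1, fit2))
    if (!inherits(f, "matching_fit") || is.na(f$se_sensitivity))
      stop_invalid("both arguments must be matching_fit objects with ",
                   "slope standard errors")
  t_stat <- (fit1$sensitivity - fit2$sensitivity) /
    sqrt(fit1$se_sensitivity^2 + fit2$se_sensitivity^2)
  df <- fit1$n_points + fit2$n_points - 4L
  list(t = t_stat, df = df, p_one_tailed = pt(t_stat, df, lower.tail = FALSE))
}

#' Group-level matching-law analysis of a cohort
#'
#' Aggregates steady-state blocks for every subject, applies the
#' zero-reward exclusion, pools block-level points within each group and
#' fits one matching-law regression per group, plus one-tailed pairwise
#' sensitivity comparisons against the reference group.
#'
#' @param subjects List of `subject_data` (e.g. a cohort's `subjects`).
#' @param window Steady-state window, as in [aggregate_blocks()].
#' @param reference Group label used as the comparison baseline
#'   (default `"control"` when present, else the first group).
#' @return List with `fits` (named list of `matching_fit`),
#'   `comparisons` (data frame of reference-vs-group tests), and
#'   `n_excluded` (blocks dropped by the reward filter).
#' @export
matching_by_group <- function(subjects, window = c(21L, 70L),
                              reference = NULL) {
  agg <- aggregate_blocks(subjects, window = window)
  kept <- filter_steady_state(agg)
  groups <- unique(agg$group)
  if (is.null(reference))
    reference <- if ("control" %in% groups) "control" else groups[1]
  fits <- lapply(groups, function(g)
    fit_matching(kept[kept$group == g, , drop = FALSE]))
  names(fits) <- groups
  others <- setdiff(groups, reference)
  comparisons <- do.call(rbind, lapply(others, function(g) {
    cmp <- compare_sensitivity(fits[[reference]], fits[[g]])
    data.frame(reference = reference, group = g, t = cmp$t, df = cmp$df,
               p_one_tailed = cmp$p_one_tailed)
  }))
  list(fits = fits, comparisons = comparisons,
       n_excluded = nrow(agg) - nrow(kept))
}
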