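#' Grid simulation of task performance over (alpha, beta)
#'
#' Simulates `n_reps` independent sessions for every `(alpha, beta)`
#' combination and records the mean and SD of total score per cell.  The
#' defaults reproduce the canonical 20 x 20 design: alpha from 0.05 to 1
#' in steps of 0.05 crossed with beta from 0.5 to 10 in steps of 0.5
#' (400 pairs), 100 repetitions per pair, on the sequence-1 testing
#' schedule.  Each cell runs on an independent child seed derived from
#' the master seed, so the grid is reproducible cell by cell and
#' parallelizes deterministically.
#'
#' @param alpha_values,beta_values Grid axes.
#' @param n_reps Sessions per cell (>= 1; with `n_reps = 1` the SD is
#'   reported as 0 by convention, with a warning).
#' @param schedule A `drt_schedule` (default sequence-1).
#' @param seed Optional master seed.
#' @return A `drt_grid` data frame with columns `alpha`, `beta`,
#'   `mean_score`, `sd_score`, `n_reps`, and attributes `schedule_label`
#'   and `seed`.
#' @examples
#' g <- run_grid(alpha_values = c(0.2, 0.8), beta_values = c(1, 5),
#'               n_reps = 10, seed = 1)
#' locate_optimum(g)
#' @export
run_grid <- function(alpha_values = seq(0.05, 1, by = 0.05),
                     beta_values = seq(0.5, 10, by = 0.5),
                     n_reps = 100L,
                     schedule = drt_schedule("sequence-1"),
                     seed = NULL) {
  if (length(alpha_values) == 0L || length(beta_values) == 0L)
    stop_invalid("grid axes must be non-empty")
  check_alpha(alpha_values)
  check_beta(beta_values)
  stopifnot(inherits(schedule, "drt_schedule"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop_invalid("`n_reps` must be at least 1")
  if (n_reps == 1L)
    warning("n_reps = 1: per-cell SDs are reported as 0 by convention")
  cells <- expand.grid(alpha = alpha_values, beta = beta_values,
                       KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- derive_seeds(seed, nrow(cells))
  means <- numeric(nrow(cells)); sds <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    scores <- with_seed(cell_seeds[i],
      sim_scores_cpp(schedule$prob_A, schedule$prob_B, schedule$n_trials,
                     cells$alpha[i], cells$beta[i], n_reps))
    means[i] <- mean(scores)
    sds[i] <- if (n_reps > 1L) sd(scores) else 0
  }
  out <- data.frame(alpha = cells$alpha, beta = cells$beta,
                    mean_score = means, sd_score = sds, n_reps = n_reps)
  structure(out, class = c("drt_grid", "data.frame"),
            schedule_label = attr(schedule, "label"), seed = seed)
}

#' Locate the best-performing grid cell
#'
#' Returns the cell with the maximal mean total score.  Ties are broken
#' toward smaller alpha, then smaller beta.
#'
#' @param grid A `drt_grid` (or any data frame with `alpha`, `beta`,
#'   `mean_score`).
#' @return List with `alpha`, `beta`, `score`.
#' @export
locate_optimum <- function(grid) {
  if (nrow(grid) == 0L) stop_invalid("empty grid")
  ord <- order(-grid$mean_score, grid$alpha, grid$beta)
  top <- grid[ord[1], ]
  list(alpha = top$alpha, beta = top$beta, score = top$mean_score)
}

#' @export
print.drt_grid <- function(x, ...) {
  opt <- locate_optimum(x)
  cat("<drt_grid>", nrow(x), "cells x", x$n_reps[1], "reps on",
      attr(x, "schedule_label"), "\n")
  cat(sprintf("  best cell: alpha = %.2f, beta = %.1f, mean score = %.1f\n",
              opt$alpha, opt$beta, opt$score))
  cat(sprintf("  cell SD range: %.2f - %.2f\n",
              min(x$sd_score), max(x$sd_score)))
  invisible(x)
}

#' Heatmap of mean grid scores
#'
#' Base-graphics image of mean total score over the (alpha, beta) grid,
#' with the optimum marked.
#'
#' @param x A `drt_grid`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the score matrix (alpha x beta).
#' @importFrom graphics image points
#' @export
plot.drt_grid <- function(x, ...) {
  av <- sort(unique(x$alpha)); bv <- sort(unique(x$beta))
  m <- matrix(NA_real_, length(av), length(bv))
  m[cbind(match(x$alpha, av), match(x$beta, bv))] <- x$mean_score
  image(av, bv, m, xlab = "learning rate (alpha)",
        ylab = "choice perseveration (beta)",
        main = "Mean total score", ...)
  opt <- locate_optimum(x)
  points(opt$alpha, opt$beta, pch = 4, cex = 1.5, lwd = 2)
  invisible(m)
}
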