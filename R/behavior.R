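#' Psychometric observer for the visual water task
#'
#' A two-alternative Bernoulli observer.  Accuracy is a logistic function of
#' stimulus level, bounded between the guess rate (0.5, two-alternative
#' task) and \code{1 - lapse_rate}.  For acuity the task gets harder as
#' spatial frequency rises past the threshold; for orientation it gets
#' harder as the angular difference shrinks toward the threshold.
#'
#' @param true_threshold threshold stimulus level (cycles/degree for
#'   acuity, degrees for orientation).
#' @param slope logistic slope (per stimulus unit); large values approach a
#'   step function.
#' @param lapse_rate asymptotic error rate on easy trials, in [0, 0.5).
#' @param task \code{"acuity"} or \code{"orientation"}.
#' @param guess_rate chance performance (fixed 0.5 by design).
#' @return an object of class \code{psychometric_observer} with an
#'   \code{$accuracy(level)} function.
#' @export
psychometric_observer <- function(true_threshold, slope = 20,
                                  lapse_rate = 0.02,
                                  task = c("acuity", "orientation"),
                                  guess_rate = 0.5) {
  task <- match.arg(task)
  if (lapse_rate < 0 || lapse_rate >= 0.5) {
    stop("`lapse_rate` must lie in [0, 0.5)", call. = FALSE)
  }
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  accuracy <- function(level) {
    x <- if (task == "acuity") true_threshold - level else level - true_threshold
    guess_rate + (1 - guess_rate - lapse_rate) * stats::plogis(slope * x)
  }
  structure(list(true_threshold = true_threshold, slope = slope,
                 lapse_rate = lapse_rate, guess_rate = guess_rate,
                 task = task, accuracy = accuracy),
            class = "psychometric_observer")
}

#' Simulate a visual-water-task threshold session
#'
#' Tests stimulus levels in protocol order (increasing spatial frequency
#' for acuity; orientation differences decreasing in 5-degree steps for
#' orientation discrimination), running a fixed-size block of Bernoulli
#' trials per level drawn from the observer's psychometric function.
#' Testing stops after the first block whose accuracy falls below the stop
#' criterion (configurable), mirroring the staircase used to bracket the
#' 70%-accuracy threshold.
#'
#' @param observer a \code{\link{psychometric_observer}}.
#' @param levels stimulus levels in testing order; defaults to the task's
#'   conventional set (acuity: 0.086 cycles/degree upward; orientation: 90
#'   down to 5 degrees in 5-degree steps).
#' @param trials_per_block trials per level block (default 10).
#' @param stop_criterion accuracy below which testing stops (default 0.7).
#' @param stop_after_fail stop at the first failing block (default TRUE).
#' @return a trial log: data.frame with \code{block_id}, \code{level},
#'   \code{correct}; attribute \code{"task"}.
#' @export
simulate_vwt_session <- function(observer, levels = NULL,
                                 trials_per_block = 10,
                                 stop_criterion = 0.7,
                                 stop_after_fail = TRUE) {
  stopifnot(inherits(observer, "psychometric_observer"))
  if (is.null(levels)) {
    levels <- if (observer$task == "acuity") {
      c(0.086, seq(0.15, 0.80, by = 0.05))
    } else {
      seq(90, 5, by = -5)
    }
  }
  if (trials_per_block < 1) stop("`trials_per_block` must be >= 1",
                                 call. = FALSE)
  logs <- list()
  for (bi in seq_along(levels)) {
    p <- observer$accuracy(levels[bi])
    correct <- stats::runif(trials_per_block) < p
    logs[[bi]] <- data.frame(block_id = bi, level = levels[bi],
                             correct = correct)
    if (stop_after_fail && mean(correct) < stop_criterion) break
  }
  out <- do.call(rbind, logs)
  attr(out, "task") <- observer$task
  out
}

block_accuracies <- function(log) {
  acc <- tapply(log$correct, log$block_id, mean)
  acc[order(as.numeric(names(acc)))]
}

level_accuracies <- function(log, last_block_only = FALSE) {
  if (last_block_only) {
    last <- tapply(log$block_id, log$level, max)
    keep <- log$block_id == last[as.character(log$level)]
    log <- log[keep, , drop = FALSE]
  }
  lev <- sort(unique(log$level))
  acc <- vapply(lev, function(l) mean(log$correct[log$level == l]),
                numeric(1))
  data.frame(level = lev, accuracy = acc)
}

#' Blocks to learning criterion
#'
#' Index of the first block whose accuracy reaches the learning criterion
#' (90% by default).
#'
#' @param log trial log with \code{block_id} and \code{correct}.
#' @param criterion learning criterion (inclusive).
#' @return block index (integer); if the criterion is never reached, an
#'   error of class \code{silentsyn_not_learned} is signaled.
#' @export
blocks_to_learn <- function(log, criterion = 0.9) {
  acc <- block_accuracies(log)
  hit <- which(acc >= criterion)
  if (!length(hit)) {
    stop(structure(class = c("silentsyn_not_learned", "error", "condition"),
                   list(message = "learning criterion never reached",
                        call = sys.call(-1))))
  }
  unname(hit[1])
}

threshold_from_log <- function(log, criterion, extreme, last_block_only) {
  acc <- level_accuracies(log, last_block_only = last_block_only)
  pass <- acc$level[acc$accuracy >= criterion]
  if (!length(pass)) {
    stop(structure(
      class = c("silentsyn_threshold_not_reached", "error", "condition"),
      list(message = sprintf("no level reached %.0f%% accuracy",
                             100 * criterion),
           call = sys.call(-2))))
  }
  # non-monotone performance (pass, fail, pass) is logged; the extreme
  # passing level is still taken, per the threshold definitions
  ord <- acc$accuracy >= criterion
  if (any(diff(which(ord)) > 1)) {
    message("non-monotone performance across levels; taking the extreme ",
            "passing level")
  }
  extreme(pass)
}

#' Visual acuity threshold
#'
#' The highest spatial frequency at which the accuracy criterion (70% by
#' default, inclusive) was achieved.  Accuracy at a level pools all blocks
#' tested at that level unless \code{last_block_only}.
#'
#' @param log trial log (\code{block_id}, \code{level} in cycles/degree,
#'   \code{correct}).
#' @param criterion accuracy criterion.
#' @param last_block_only use only the final block per level.
#' @return threshold, cycles/degree (always one of the tested levels).
#' @export
acuity_threshold <- function(log, criterion = 0.7, last_block_only = FALSE) {
  threshold_from_log(log, criterion, max, last_block_only)
}

#' Orientation discrimination threshold
#'
#' The smallest orientation difference (degrees) at which the accuracy
#' criterion was achieved, with differences tested downward in 5-degree
#' steps.
#'
#' @inheritParams acuity_threshold
#' @return threshold, degrees (one of the tested levels).
#' @export
orientation_threshold <- function(log, criterion = 0.7,
                                  last_block_only = FALSE) {
  threshold_from_log(log, criterion, min, last_block_only)
}

#' Looming-stimulus response fraction
#'
#' Fraction of looming presentations (at most three per animal) that evoked
#' a defensive response.
#'
#' @param trials logical vector of per-trial responses (length 1 to
#'   \code{max_trials}).
#' @param max_trials maximum presentations per animal (default 3).
#' @return response fraction in [0, 1].
#' @export
looming_response_fraction <- function(trials, max_trials = 3L) {
  if (length(trials) < 1L || length(trials) > max_trials) {
    stop("between 1 and ", max_trials, " trials required", call. = FALSE)
  }
  mean(as.logical(trials))
}
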