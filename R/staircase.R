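#' Simulated observer with a logistic psychometric function
#'
#' Probability correct decreases with difficulty (number of dots in the
#' memory display) from near-ceiling down to the guess rate:
#' `p(L) = guess_rate + (1 - guess_rate) / (1 + exp((L - midpoint) / width))`.
#' The default guess rate of 0.5 reflects the same/different judgement.
#'
#' @param midpoint Difficulty at which performance is halfway between ceiling
#'   and guess rate (dots). The default of 5 reflects a visual short-term
#'   memory capacity limit of a few items.
#' @param width Logistic width (dots); larger = shallower psychometric. The
#'   steep default keeps short staircase runs (10 reversals) in their
#'   stationary regime almost immediately after the 2-dot start, so measured
#'   accuracy reflects the rule's asymptote rather than the approach phase.
#' @param guess_rate Lower asymptote.
#' @return An object of class `observer_model`.
#' @export
logistic_observer <- function(midpoint = 5, width = 0.6, guess_rate = 0.5) {
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (guess_rate < 0 || guess_rate >= 1) {
    stop("`guess_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(list(midpoint = midpoint, width = width, guess_rate = guess_rate),
            class = "observer_model")
}

#' @rdname logistic_observer
#' @param observer An `observer_model`.
#' @param level Difficulty level (number of dots).
#' @export
p_correct <- function(observer, level) {
  stopifnot(inherits(observer, "observer_model"))
  observer$guess_rate + (1 - observer$guess_rate) /
    (1 + exp((level - observer$midpoint) / observer$width))
}

#' One step of the two-down one-up staircase
#'
#' Samples a response from the observer at the current level, then applies
#' the rule: two consecutive correct responses make the task harder (one more
#' dot); a single error makes it easier (one fewer, floor 2). Direction
#' changes are recorded as reversals at the level where the direction turned.
#' The rule converges on the level where P(correct) = sqrt(0.5), about 70.7%.
#'
#' @param state A `staircase_state` from [new_staircase()].
#' @param observer An [logistic_observer()].
#' @return Updated `staircase_state`.
#' @export
staircase_step <- function(state, observer) {
  stopifnot(inherits(state, "staircase_state"))
  lev <- state$level
  correct <- stats::runif(1) < p_correct(observer, lev)
  state$history <- rbind(state$history,
                         data.frame(level = lev, correct = correct))
  move <- 0L
  if (correct) {
    state$streak <- state$streak + 1L
    if (state$streak == 2L) {
      move <- 1L
      state$streak <- 0L
    }
  } else {
    move <- -1L
    state$streak <- 0L
  }
  if (move != 0L) {
    new_level <- max(state$min_level, lev + move)
    if (new_level != lev) {
      if (!is.na(state$direction) && move != state$direction) {
        state$reversals <- c(state$reversals, lev)
      }
      state$direction <- move
      state$level <- new_level
    }
  }
  state
}

#' @rdname staircase_step
#' @param start_level Initial difficulty (dots), default 2.
#' @param min_level Floor difficulty.
#' @export
new_staircase <- function(start_level = 2L, min_level = 2L) {
  structure(
    list(level = as.integer(start_level), min_level = as.integer(min_level),
         streak = 0L, direction = NA_integer_,
         reversals = integer(0),
         history = data.frame(level = integer(0), correct = logical(0))),
    class = "staircase_state"
  )
}

#' Run a staircase to a fixed number of reversals
#'
#' @param observer An [logistic_observer()].
#' @param n_reversals Reversals to collect per run (default 10).
#' @param start_level,min_level Difficulty bounds.
#' @param max_trials Safety cap on trial count.
#' @return Final `staircase_state`.
#' @export
staircase_run <- function(observer, n_reversals = 10L, start_level = 2L,
                          min_level = 2L, max_trials = 10000L) {
  state <- new_staircase(start_level, min_level)
  while (length(state$reversals) < n_reversals &&
         nrow(state$history) < max_trials) {
    state <- staircase_step(state, observer)
  }
  state
}

#' Threshold from staircase reversals
#'
#' Per run, the threshold is the mean of the last two-thirds of the reversal
#' levels (the final `ceiling(2k/3)` of `k` reversals); the score averages
#' the per-run thresholds, conventionally over 3 runs.
#'
#' @param runs A `staircase_state` or list of them.
#' @return Mean threshold (dots).
#' @export
staircase_threshold <- function(runs) {
  if (inherits(runs, "staircase_state")) runs <- list(runs)
  per_run <- vapply(runs, function(st) {
    k <- length(st$reversals)
    if (k < 3L) {
      stop("need at least 3 reversals per run to estimate a threshold",
           call. = FALSE)
    }
    keep <- ceiling(2 * k / 3)
    mean(st$reversals[seq.int(k - keep + 1L, k)])
  }, numeric(1))
  mean(per_run)
}

#' @rdname staircase_threshold
#' @param observer An [logistic_observer()].
#' @param n_runs Runs to average (default 3).
#' @param n_reversals Reversals per run.
#' @export
staircase_score <- function(observer, n_runs = 3L, n_reversals = 10L) {
  staircase_threshold(lapply(seq_len(n_runs), function(i) {
    staircase_run(observer, n_reversals)
  }))
}

#' Post-convergence accuracy of a staircase run
#'
#' Mean proportion correct over trials after the staircase has settled
#' (trials following the first `skip_reversals` reversals); used to verify
#' the 70.7% convergence property of the two-down one-up rule.
#'
#' @param state A completed `staircase_state`.
#' @param skip_reversals Reversals to discard as burn-in (default 3).
#' @return Proportion correct, or `NA` if no post-convergence trials exist.
#' @export
staircase_accuracy <- function(state, skip_reversals = 3L) {
  stopifnot(inherits(state, "staircase_state"))
  k <- length(state$reversals)
  if (k <= skip_reversals) return(NA_real_)
  # trial index of the skip_reversals-th reversal: count direction changes
  # by replaying the history levels
  lev <- state$history$level
  n <- length(lev)
  changes <- which(diff(lev) != 0)
  dirs <- sign(diff(lev))[changes]
  rev_trials <- integer(0)
  last_dir <- NA_integer_
  for (i in seq_along(changes)) {
    if (!is.na(last_dir) && dirs[i] != last_dir) {
      rev_trials <- c(rev_trials, changes[i])
    }
    last_dir <- dirs[i]
  }
  if (length(rev_trials) < skip_reversals) return(NA_real_)
  start <- rev_trials[skip_reversals] + 1L
  if (start > n) return(NA_real_)
  mean(state$history$correct[start:n])
}

#' Cognitive covariates for a synthetic cohort
#'
#' Draws per-participant working-memory scores by running the staircase on
#' observers whose psychometric midpoints vary across the cohort, and
#' synthetic attention scores (display-duration thresholds, lower = better)
#' from a log-normal family. Both are stand-ins for unavailable human
#' covariates and are labelled as such.
#'
#' @param n Number of simulated participants.
#' @param wm_midpoint_mean,wm_midpoint_sd Cohort distribution of observer
#'   midpoints (dots), centred on the capacity-style default.
#' @param attention_meanlog,attention_sdlog Log-normal parameters of the
#'   attention threshold (ms).
#' @return Data frame with `agent_id`, `wm_score`, `attention_score`.
#' @export
cognitive_covariates <- function(n, wm_midpoint_mean = 5, wm_midpoint_sd = 1,
                                 attention_meanlog = log(100),
                                 attention_sdlog = 0.4) {
  wm <- vapply(seq_len(n), function(i) {
    obs <- logistic_observer(
      midpoint = max(2.5, stats::rnorm(1, wm_midpoint_mean, wm_midpoint_sd)))
    staircase_score(obs)
  }, numeric(1))
  data.frame(agent_id = seq_len(n), wm_score = wm,
             attention_score = stats::rlnorm(n, attention_meanlog,
                                             attention_sdlog))
}
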