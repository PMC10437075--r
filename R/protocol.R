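#' Experiment configuration
#'
#' Full description of one training/testing protocol: contingency
#' probability, ISI regime, feedback regime and the session plan. The
#' defaults follow the standard design: a pre-training test session of
#' structured, random, structured blocks (40 trials each), 23 training blocks
#' of 60 trials, and a post-training test session mirroring the pre session.
#'
#' @param group_id Integer 1-6 identifying the group design (bookkeeping).
#' @param p_high Contingency probability of the frequent target.
#' @param isi_mode `"fixed"` (400 ms) or `"jitter"` (uniform 100-700 ms in
#'   20 ms bins).
#' @param feedback_mode `"block"` (PI score at end of block), `"trial"`
#'   (correct/incorrect per trial against the hidden target), `"none"`, or
#'   `"uncorrelated"` (random correct/incorrect independent of the response).
#' @param n_training_blocks,trials_per_training_block Training plan.
#' @param test_block_plan Ordered kinds of the test-session blocks.
#' @param trials_per_test_block Trials per test block.
#' @param retest Append a retest session replicating the post-test plan.
#' @param p_uncorrelated Probability of "correct" under uncorrelated feedback.
#' @param length_range Symbol-stream length interval.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(group_id = 1L, p_high = 0.8,
                              isi_mode = c("fixed", "jitter"),
                              feedback_mode = c("block", "trial", "none",
                                                "uncorrelated"),
                              n_training_blocks = 23L,
                              trials_per_training_block = 60L,
                              test_block_plan = c("structured", "random",
                                                  "structured"),
                              trials_per_test_block = 40L,
                              retest = FALSE,
                              p_uncorrelated = 0.5,
                              length_range = c(9L, 13L)) {
  isi_mode <- match.arg(isi_mode)
  feedback_mode <- match.arg(feedback_mode)
  if (!all(test_block_plan %in% c("structured", "random"))) {
    stop("test_block_plan entries must be 'structured' or 'random'",
         call. = FALSE)
  }
  if (p_high <= 0.5 || p_high > 1) {
    stop("`p_high` must be in (0.5, 1]", call. = FALSE)
  }
  structure(
    list(group_id = as.integer(group_id), p_high = p_high,
         isi_mode = isi_mode, feedback_mode = feedback_mode,
         n_training_blocks = as.integer(n_training_blocks),
         trials_per_training_block = as.integer(trials_per_training_block),
         test_block_plan = test_block_plan,
         trials_per_test_block = as.integer(trials_per_test_block),
         retest = retest, p_uncorrelated = p_uncorrelated,
         length_range = as.integer(length_range)),
    class = "experiment_config"
  )
}

#' Preset configuration for the six group designs
#'
#' Group 1: 80/20 contingencies, fixed ISI, block feedback (the baseline
#' design). Group 2: 60/40 contingencies. Group 3: jittered ISI. Group 4:
#' trial-by-trial feedback. Group 5: no feedback. Group 6: uncorrelated
#' feedback. Groups 2-6 otherwise match Group 1.
#'
#' @param group_id Integer in 1..6.
#' @param ... Field overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
group_config <- function(group_id, ...) {
  if (!is.numeric(group_id) || length(group_id) != 1L ||
      !(group_id %in% 1:6)) {
    stop("`group_id` must be an integer in 1..6", call. = FALSE)
  }
  preset <- switch(as.integer(group_id),
    list(p_high = 0.8, isi_mode = "fixed", feedback_mode = "block"),
    list(p_high = 0.6, isi_mode = "fixed", feedback_mode = "block"),
    list(p_high = 0.8, isi_mode = "jitter", feedback_mode = "block"),
    list(p_high = 0.8, isi_mode = "fixed", feedback_mode = "trial"),
    list(p_high = 0.8, isi_mode = "fixed", feedback_mode = "none"),
    list(p_high = 0.8, isi_mode = "fixed", feedback_mode = "uncorrelated")
  )
  args <- utils::modifyList(c(list(group_id = as.integer(group_id)), preset),
                            list(...))
  do.call(experiment_config, args)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment config (group ", x$group_id, "): p_high = ", x$p_high,
      ", ISI ", x$isi_mode, ", feedback ", x$feedback_mode, "\n", sep = "")
  cat("  training: ", x$n_training_blocks, " blocks x ",
      x$trials_per_training_block, " trials; tests: ",
      paste(substr(x$test_block_plan, 1, 1), collapse = ","), " x ",
      x$trials_per_test_block, " trials",
      if (x$retest) "; retest" else "", "\n", sep = "")
  invisible(x)
}

#' Trial-level feedback
#'
#' Under trial feedback the outcome compares the chosen symbol to the hidden
#' target sampled from the generative model (a null response counts as
#' incorrect). Uncorrelated feedback is a Bernoulli draw independent of the
#' response. Block and no-feedback regimes give no trial-level signal.
#'
#' @param record A `response_record`.
#' @param trial The matching `trial_sequence`.
#' @param mode Feedback mode.
#' @param p_uncorrelated P("correct") under uncorrelated feedback.
#' @return `"correct"`, `"incorrect"` or `"none"`.
#' @export
emit_feedback <- function(record, trial,
                          mode = c("block", "trial", "none", "uncorrelated"),
                          p_uncorrelated = 0.5) {
  mode <- match.arg(mode)
  switch(mode,
    trial = if (!is.na(record$chosen) &&
                record$chosen == trial$hidden_target) "correct" else "incorrect",
    uncorrelated = if (stats::runif(1) < p_uncorrelated) "correct" else "incorrect",
    "none"
  )
}

# block PI with weights renormalized over contexts that actually occurred
block_pi <- function(rows, model, weights = NULL) {
  ct <- estimate_conditionals(rows, model$symbols)
  if (is.null(weights)) weights <- stationary_distribution(model)
  if (!all(ct$supported)) {
    weights[!ct$supported] <- 0
    weights <- weights / sum(weights)
  }
  performance_index(ct, model, weights)$overall
}

trial_log_columns <- function() {
  c("group_id", "agent_id", "session", "block_id", "block_kind", "trial_id",
    "context", "chosen", "hidden_target",
    "p_resp_A", "p_resp_B", "p_resp_C", "p_resp_D", "feedback", "seed")
}

#' Run a full simulated experiment
#'
#' Executes the session plan for one synthetic participant: pre-training test
#' blocks (no feedback), training blocks under the configured feedback
#' regime, post-training test blocks, and optionally a retest session.
#' Learning agents update their transition belief after every trial (exposure
#' plus any feedback bonus) and respond from the current belief; all other
#' policies respond from the generative model.
#'
#' @param config An [experiment_config()] or [group_config()].
#' @param agent A [seq_agent()].
#' @param seed Optional integer; when given, the RNG state is localized and
#'   the run is exactly reproducible.
#' @param agent_id Identifier written to the log.
#' @return A data frame of class `trial_log`, one row per trial, with columns
#'   group_id, agent_id, session, block_id, block_kind, trial_id, context,
#'   chosen, hidden_target, p_resp_A..D, feedback, seed. When
#'   `feedback_mode = "block"` the per-training-block PI scores shown to the
#'   participant are attached as `attr(, "block_feedback")`.
#' @examples
#' \donttest{
#' log <- run_experiment(group_config(1), seq_agent("matching"), seed = 1)
#' nrow(log)  # 240 test + 1380 training rows
#' }
#' @export
run_experiment <- function(config, agent, seed = NULL, agent_id = 1L) {
  stopifnot(inherits(config, "experiment_config"), inherits(agent, "seq_agent"))
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  model <- markov_model(config$p_high)
  learning <- agent$policy == "learning"
  belief <- if (learning) new_belief(agent$prior_weight, model$symbols)

  sessions <- list(
    list(name = "pre", kinds = config$test_block_plan,
         n_trials = config$trials_per_test_block, feedback = "none"),
    list(name = "training",
         kinds = rep("structured", config$n_training_blocks),
         n_trials = config$trials_per_training_block,
         feedback = config$feedback_mode),
    list(name = "post", kinds = config$test_block_plan,
         n_trials = config$trials_per_test_block, feedback = "none")
  )
  if (isTRUE(config$retest)) {
    sessions <- c(sessions, list(
      list(name = "retest", kinds = config$test_block_plan,
           n_trials = config$trials_per_test_block, feedback = "none")))
  }

  chunks <- list()
  block_fb <- list()
  seed_col <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  for (sess in sessions) {
    for (b in seq_along(sess$kinds)) {
      n <- sess$n_trials
      ctx <- chosen <- hidden <- character(n)
      fb <- character(n)
      rv <- matrix(0, n, 4)
      for (t in seq_len(n)) {
        trial <- if (sess$kinds[b] == "structured") {
          generate_trial(model, config$length_range, config$isi_mode)
        } else {
          generate_random_trial(model, config$length_range, config$isi_mode)
        }
        rec <- respond(agent, trial, if (learning) belief else model)
        rec$feedback <- emit_feedback(rec, trial, sess$feedback,
                                      config$p_uncorrelated)
        if (learning) {
          belief <- update_belief(belief, trial, rec, sess$feedback, agent)
        }
        ctx[t] <- rec$context
        chosen[t] <- rec$chosen
        hidden[t] <- trial$hidden_target
        fb[t] <- rec$feedback
        rv[t, ] <- rec$response_vector
      }
      chunk <- data.frame(
        group_id = config$group_id, agent_id = agent_id,
        session = sess$name, block_id = b, block_kind = sess$kinds[b],
        trial_id = seq_len(n), context = ctx, chosen = chosen,
        hidden_target = hidden,
        p_resp_A = rv[, 1], p_resp_B = rv[, 2],
        p_resp_C = rv[, 3], p_resp_D = rv[, 4],
        feedback = fb, seed = seed_col,
        stringsAsFactors = FALSE
      )
      chunks[[length(chunks) + 1L]] <- chunk
      if (sess$name == "training" && sess$feedback == "block") {
        block_fb[[length(block_fb) + 1L]] <-
          data.frame(block_id = b, pi = block_pi(chunk, model))
      }
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  class(out) <- c("trial_log", "data.frame")
  if (length(block_fb)) {
    attr(out, "block_feedback") <- do.call(rbind, block_fb)
  }
  out
}
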