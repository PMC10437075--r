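#' Define a synthetic participant
#'
#' Response policies span the strategy continuum observed in sequence-learning
#' cohorts: `"random"` guessing, probability `"matching"` (respond with the
#' contingency probabilities), `"maximizing"` (always pick the most likely
#' target), an `"interpolated"` mixture of the two, and a `"learning"` agent
#' that applies a matching or maximizing readout to a pseudo-count belief over
#' transitions built up from exposure and feedback.
#'
#' @param policy One of `"random"`, `"matching"`, `"maximizing"`,
#'   `"interpolated"`, `"learning"`.
#' @param lambda_mix Mixing weight in \[-1, 1\] for the interpolated policy,
#'   parameterising the strategy axis: -1 = uniform random, 0 = pure
#'   matching, 1 = pure maximizing (negative values mix matching with the
#'   uniform distribution, positive values with the argmax point mass). Only
#'   meaningful (and only allowed) for `policy = "interpolated"`.
#' @param p_null Lapse probability in \[0, 1\]: with this probability the
#'   agent emits a null response, registered as a uniform 0.25 vector (the
#'   convention for misses under the 2 s response deadline; observed human
#'   rate about 0.009).
#' @param learn_rate Pseudo-count added per observed transition
#'   (learning agents; must be >= 0).
#' @param feedback_sensitivity Multiplier on the extra pseudo-count granted
#'   by a "correct" trial-feedback event.
#' @param prior_weight Dirichlet-style prior pseudo-count per belief cell.
#' @param readout How a learning agent converts its belief conditionals into
#'   a response distribution: `"matching"` or `"maximizing"`.
#' @param tie_break Behaviour when a maximizing readout meets a tied argmax:
#'   `"error"` (default) or `"lexicographic"` (first symbol wins).
#'
#' @return An object of class `seq_agent`.
#' @examples
#' a <- seq_agent("interpolated", lambda_mix = 0.5)
#' policy_distribution(a, "A", markov_model(0.8))
#' @export
seq_agent <- function(policy = c("matching", "maximizing", "random",
                                 "interpolated", "learning"),
                      lambda_mix = NULL, p_null = 0,
                      learn_rate = 1, feedback_sensitivity = 0,
                      prior_weight = 1,
                      readout = c("matching", "maximizing"),
                      tie_break = c("error", "lexicographic")) {
  policy <- match.arg(policy)
  readout <- match.arg(readout)
  tie_break <- match.arg(tie_break)
  if (policy == "interpolated") {
    if (is.null(lambda_mix) || !is.numeric(lambda_mix) ||
        lambda_mix < -1 || lambda_mix > 1) {
      stop("`lambda_mix` must be in [-1, 1] for the interpolated policy",
           call. = FALSE)
    }
  } else if (!is.null(lambda_mix)) {
    stop("`lambda_mix` is only defined for the interpolated policy",
         call. = FALSE)
  }
  if (p_null < 0 || p_null > 1) stop("`p_null` must be in [0, 1]", call. = FALSE)
  if (learn_rate < 0) stop("`learn_rate` must be >= 0", call. = FALSE)
  structure(
    list(policy = policy, lambda_mix = lambda_mix, p_null = p_null,
         learn_rate = learn_rate, feedback_sensitivity = feedback_sensitivity,
         prior_weight = prior_weight, readout = readout,
         tie_break = tie_break),
    class = "seq_agent"
  )
}

#' @export
print.seq_agent <- function(x, ...) {
  cat("Synthetic participant: policy =", x$policy)
  if (x$policy == "interpolated") cat(" (lambda =", x$lambda_mix, ")")
  if (x$policy == "learning") {
    cat(" (readout =", x$readout, ", learn_rate =", x$learn_rate,
        ", feedback_sensitivity =", x$feedback_sensitivity, ")")
  }
  cat(", p_null =", x$p_null, "\n")
  invisible(x)
}

resolve_table <- function(model_or_belief) {
  if (inherits(model_or_belief, "markov_model")) {
    model_or_belief$transitions
  } else if (inherits(model_or_belief, "belief_state")) {
    belief_conditionals(model_or_belief)
  } else if (is.matrix(model_or_belief) &&
             identical(dim(model_or_belief), c(4L, 4L))) {
    model_or_belief
  } else {
    stop("expected a markov_model, belief_state or 4x4 matrix", call. = FALSE)
  }
}

max_point_mass <- function(row, tie_break) {
  top <- which(row == max(row))
  if (length(top) > 1L) {
    if (tie_break != "lexicographic") {
      stop("argmax tie under maximizing policy; set tie_break = ",
           "\"lexicographic\" to break ties by symbol order", call. = FALSE)
    }
    top <- top[1L]
  }
  out <- numeric(length(row))
  out[top] <- 1
  names(out) <- names(row)
  out
}

#' Response distribution of an agent in a given context
#'
#' @param agent A [seq_agent()].
#' @param context Context symbol label (the last symbol of the stream).
#' @param model_or_belief A [markov_model()] (policies that know the true
#'   contingencies) or a `belief_state` (learning agents).
#' @return Named probability vector over the 4 symbols.
#' @export
policy_distribution <- function(agent, context, model_or_belief) {
  stopifnot(inherits(agent, "seq_agent"))
  tab <- resolve_table(model_or_belief)
  if (!context %in% rownames(tab)) stop("unknown context: ", context, call. = FALSE)
  row <- tab[context, ]
  switch(agent$policy,
    random = stats::setNames(rep(0.25, 4), colnames(tab)),
    matching = row,
    maximizing = max_point_mass(row, agent$tie_break),
    interpolated = if (agent$lambda_mix >= 0) {
      (1 - agent$lambda_mix) * row +
        agent$lambda_mix * max_point_mass(row, agent$tie_break)
    } else {
      # negative lambda mixes toward uniform random responding, so the
      # family spans the full random <-> matching <-> maximization axis
      (1 + agent$lambda_mix) * row - agent$lambda_mix * rep(0.25, 4)
    },
    learning = if (agent$readout == "matching") row
               else max_point_mass(row, agent$tie_break)
  )
}

#' Simulate one response
#'
#' With probability `p_null` the agent lapses: a null record is emitted whose
#' response vector is uniform 0.25 (the registration rule for missed
#' responses). Otherwise the choice is sampled from the agent's policy
#' distribution and registered as a point mass.
#'
#' @inheritParams policy_distribution
#' @param trial A `trial_sequence` (supplies the context).
#' @return A `response_record` list: `context`, `response_vector`, `chosen`
#'   (symbol or `NA`), `feedback` (filled in later by [emit_feedback()]).
#' @export
respond <- function(agent, trial, model_or_belief) {
  stopifnot(inherits(trial, "trial_sequence"))
  symbols <- colnames(resolve_table(model_or_belief))
  if (agent$p_null > 0 && stats::runif(1) < agent$p_null) {
    rec <- list(context = trial$context,
                response_vector = stats::setNames(rep(0.25, 4), symbols),
                chosen = NA_character_, feedback = "none")
  } else {
    p <- policy_distribution(agent, trial$context, model_or_belief)
    pick <- sample.int(4L, 1L, prob = p)
    v <- numeric(4L)
    v[pick] <- 1
    rec <- list(context = trial$context,
                response_vector = stats::setNames(v, symbols),
                chosen = symbols[pick], feedback = "none")
  }
  class(rec) <- "response_record"
  rec
}

#' Pseudo-count belief over context-target transitions
#'
#' A learning agent's internal estimate: a 4x4 matrix of (fractional)
#' observation counts plus a Dirichlet-style prior. Conditionals are
#' `(counts + prior_weight)` normalised per row.
#'
#' @param prior_weight Prior pseudo-count per cell (> 0 keeps conditionals
#'   defined before any observation).
#' @param symbols Symbol labels.
#' @return An object of class `belief_state`.
#' @export
new_belief <- function(prior_weight = 1, symbols = c("A", "B", "C", "D")) {
  counts <- matrix(0, 4, 4, dimnames = list(symbols, symbols))
  structure(list(counts = counts, prior_weight = prior_weight),
            class = "belief_state")
}

#' @rdname new_belief
#' @param belief A `belief_state`.
#' @export
belief_conditionals <- function(belief) {
  stopifnot(inherits(belief, "belief_state"))
  m <- belief$counts + belief$prior_weight
  m / rowSums(m)
}

#' Update a belief from one trial
#'
#' Exposure: every consecutive (context, target) pair within the trial's
#' symbol stream adds `learn_rate` to its cell. Feedback bonus: under
#' trial-by-trial feedback a "correct" outcome additionally adds
#' `feedback_sensitivity * learn_rate` to the (context, chosen) cell; under
#' uncorrelated feedback the same bonus lands on a random cell, modelling the
#' corruption of the error-correction signal. Block feedback and no feedback
#' apply exposure updates only.
#'
#' @param belief A `belief_state`.
#' @param trial The `trial_sequence` observed.
#' @param record The agent's `response_record` for that trial (carries the
#'   feedback outcome).
#' @param feedback_mode `"block"`, `"trial"`, `"none"` or `"uncorrelated"`.
#' @param agent The [seq_agent()] whose `learn_rate` and
#'   `feedback_sensitivity` drive the update.
#' @return The updated `belief_state`.
#' @export
update_belief <- function(belief, trial, record,
                          feedback_mode = c("none", "block", "trial",
                                            "uncorrelated"),
                          agent) {
  stopifnot(inherits(belief, "belief_state"), inherits(trial, "trial_sequence"))
  feedback_mode <- match.arg(feedback_mode)
  if (agent$learn_rate < 0) stop("`learn_rate` must be >= 0", call. = FALSE)
  idx <- match(trial$symbols, rownames(belief$counts))
  n <- length(idx)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      belief$counts[idx[i], idx[i + 1L]] <-
        belief$counts[idx[i], idx[i + 1L]] + agent$learn_rate
    }
  }
  bonus <- agent$feedback_sensitivity * agent$learn_rate
  if (bonus > 0 && identical(record$feedback, "correct")) {
    if (feedback_mode == "trial" && !is.na(record$chosen)) {
      belief$counts[record$context, record$chosen] <-
        belief$counts[record$context, record$chosen] + bonus
    } else if (feedback_mode == "uncorrelated") {
      cell <- sample.int(16L, 1L)
      belief$counts[cell] <- belief$counts[cell] + bonus
    }
  }
  belief
}
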