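#' Estimate conditional response distributions from trial records
#'
#' Averages the per-trial response vectors within each context: a key press
#' contributes a point mass, a null response contributes the uniform 0.25
#' vector. Contexts with no trials are flagged unsupported (row of `NA`).
#'
#' @param records A data frame of trial-log rows with columns `context` and
#'   `p_resp_A` ... `p_resp_D` (see [run_experiment()]), or a list of
#'   `response_record` objects from [respond()].
#' @param symbols Symbol labels defining row/column order.
#' @return An object of class `conditional_table`: `table` (4x4 matrix of
#'   P(target | context)), `support` (trial counts per context),
#'   `supported` (logical per context).
#' @export
estimate_conditionals <- function(records, symbols = c("A", "B", "C", "D")) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0L) stop("no records", call. = FALSE)
    ctx <- as.character(records$context)
    rv <- as.matrix(records[, paste0("p_resp_", symbols)])
  } else if (is.list(records) && length(records) &&
             inherits(records[[1]], "response_record")) {
    ctx <- vapply(records, `[[`, character(1), "context")
    rv <- do.call(rbind, lapply(records, `[[`, "response_vector"))
  } else {
    stop("`records` must be a trial-log data frame or a list of ",
         "response_record objects", call. = FALSE)
  }
  tab <- matrix(NA_real_, 4, 4, dimnames = list(symbols, symbols))
  support <- stats::setNames(numeric(4), symbols)
  for (s in symbols) {
    sel <- ctx == s
    support[s] <- sum(sel)
    if (support[s] > 0) tab[s, ] <- colSums(rv[sel, , drop = FALSE]) / support[s]
  }
  structure(list(table = tab, support = support, supported = support > 0),
            class = "conditional_table")
}

as_conditional_matrix <- function(x) {
  if (inherits(x, "conditional_table")) x$table
  else if (inherits(x, "markov_model")) x$transitions
  else if (inherits(x, "reference_model")) x$table
  else if (is.matrix(x) && identical(dim(x), c(4L, 4L))) x
  else stop("expected a conditional_table, markov_model or 4x4 matrix",
            call. = FALSE)
}

supported_contexts <- function(x) {
  if (inherits(x, "conditional_table")) x$supported
  else rep(TRUE, 4)
}

#' Minimum-overlap Performance Index
#'
#' The per-context Performance Index is the sum over targets of the
#' element-wise minimum of the response conditional and the presented-target
#' conditional — the overlap of the two distributions, 1 when they coincide.
#' The overall PI averages the per-context values with the context
#' probabilities P(context).
#'
#' @param p_resp Response conditionals: a `conditional_table` from
#'   [estimate_conditionals()] or a 4x4 matrix.
#' @param p_pres Presented-target conditionals: a [markov_model()] (the
#'   generative rows, the default analysis choice), a `conditional_table`
#'   (empirical per-block tally) or a 4x4 matrix.
#' @param weights Context probabilities; defaults to the model's stationary
#'   distribution when `p_pres` is a `markov_model`, otherwise required.
#'   Positive weight on a context unsupported by either table is an error —
#'   renormalize the weights over the supported contexts first.
#' @param pi_rand Optional random-guess baseline to attach; computed
#'   automatically (via [random_baseline()]) when `p_pres` is a model.
#' @return An object of class `pi_result`: `per_context`, `overall`,
#'   `pi_rand`, `normalized` (`overall - pi_rand`), `weights`.
#' @examples
#' m <- markov_model(0.8)
#' performance_index(matrix(0.25, 4, 4), m)  # random guessing: PI = 0.45
#' @export
performance_index <- function(p_resp, p_pres, weights = NULL, pi_rand = NULL) {
  resp <- as_conditional_matrix(p_resp)
  pres <- as_conditional_matrix(p_pres)
  if (is.null(weights)) {
    if (inherits(p_pres, "markov_model")) {
      weights <- stationary_distribution(p_pres)
    } else {
      stop("`weights` required unless `p_pres` is a markov_model", call. = FALSE)
    }
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("`weights` must be a probability vector", call. = FALSE)
  }
  ok <- supported_contexts(p_resp) & supported_contexts(p_pres)
  if (any(weights > 0 & !ok)) {
    stop("positive weight on unsupported context(s): ",
         paste(rownames(resp)[weights > 0 & !ok], collapse = ", "),
         "; renormalize weights over supported contexts", call. = FALSE)
  }
  per_context <- rowSums(pmin(resp, pres))
  overall <- sum(weights[ok] * per_context[ok])
  if (is.null(pi_rand) && inherits(p_pres, "markov_model")) {
    pi_rand <- random_baseline(p_pres, weights)
  }
  structure(
    list(per_context = per_context, overall = overall,
         pi_rand = pi_rand,
         normalized = if (is.null(pi_rand)) NULL else overall - pi_rand,
         weights = weights),
    class = "pi_result"
  )
}

#' @export
print.pi_result <- function(x, ...) {
  cat("Performance Index:", format(x$overall, digits = 4))
  if (!is.null(x$pi_rand)) {
    cat("  (baseline", format(x$pi_rand, digits = 4),
        "; normalized", format(x$normalized, digits = 4), ")")
  }
  cat("\nPer context:", paste(format(x$per_context, digits = 4),
                              collapse = " "), "\n")
  invisible(x)
}

#' Random-guess Performance Index baseline
#'
#' Closed form PI of a responder assigning probability 0.25 to every target
#' at every context: `sum_c w_c sum_t min(0.25, P(t|c))`. For the default
#' two-target designs this is 0.45 at 80/20 and 0.50 at 60/40.
#'
#' @param model A [markov_model()].
#' @param weights Context probabilities; default stationary.
#' @return Baseline PI in \[0, 1\].
#' @export
random_baseline <- function(model, weights = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (is.null(weights)) weights <- stationary_distribution(model)
  sum(weights * rowSums(pmin(model$transitions, 0.25)))
}

#' Learning improvement and learner classification
#'
#' Improvement is the difference in normalized PI (PI minus the random-guess
#' baseline) between the post- and pre-training test sessions. A participant
#' is classified a `"learner"` when post-training normalized PI reaches the
#' criterion (default 0.10, i.e. 10 percentage points above chance,
#' inclusive), otherwise `"weak_learner"`.
#'
#' @param pre_pi,post_pi `pi_result` objects sharing the same baseline.
#' @param criterion Learner threshold on post-training normalized PI.
#' @return List with `improvement`, `label`, `post_normalized`.
#' @export
normalize_and_classify <- function(pre_pi, post_pi, criterion = 0.10) {
  stopifnot(inherits(pre_pi, "pi_result"), inherits(post_pi, "pi_result"))
  if (is.null(pre_pi$pi_rand) || is.null(post_pi$pi_rand)) {
    stop("both PI results need a pi_rand baseline", call. = FALSE)
  }
  if (abs(pre_pi$pi_rand - post_pi$pi_rand) > 1e-12) {
    stop("pre and post PI were computed against different baselines",
         call. = FALSE)
  }
  list(improvement = post_pi$normalized - pre_pi$normalized,
       label = if (post_pi$normalized >= criterion) "learner" else "weak_learner",
       post_normalized = post_pi$normalized)
}

#' Expected single-trial hit rate of a policy
#'
#' Probability that one sampled choice equals the sampled hidden target:
#' `sum_c w_c sum_t policy(t|c) P(t|c)`. Probability matching on the 80/20
#' design gives 0.68 (the sum of squared contingencies); maximizing gives
#' 0.80; uniform guessing gives 0.25 for any model.
#'
#' @param policy A 4x4 response-conditional matrix, or a [seq_agent()] whose
#'   policy table is derived from the model.
#' @param model A [markov_model()].
#' @param weights Context probabilities; default stationary.
#' @return Hit probability in \[0, 1\].
#' @export
expected_hit_rate <- function(policy, model, weights = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (inherits(policy, "seq_agent")) {
    policy <- t(vapply(model$symbols,
                       function(s) policy_distribution(policy, s, model),
                       numeric(4)))
  }
  policy <- as_conditional_matrix(policy)
  if (is.null(weights)) weights <- stationary_distribution(model)
  sum(weights * rowSums(policy * model$transitions))
}
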