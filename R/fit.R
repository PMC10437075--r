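#' Fit the behavioural measures to one participant's trial log
#'
#' The central analysis: from a trial log (simulated via [run_experiment()]
#' or read from CSV via [read_trial_log()]) it estimates, against the
#' generative model,
#' \itemize{
#'   \item pre- and post-training Performance Index on the structured test
#'     blocks, with the random-guess baseline, normalized PI, PI improvement
#'     and the learner / weak-learner classification (criterion: post
#'     normalized PI >= 0.10);
#'   \item the per-training-block PI learning curve;
#'   \item the per-block delta-KL strategy curve and the
#'     integral-curve-difference strategy index (0 = matching, positive =
#'     toward maximization, negative = toward random).
#' }
#'
#' @param log A `trial_log` data frame.
#' @param model The generative [markov_model()]; reconstructed from the log's
#'   group design when omitted (`group_id` column + [group_config()]).
#' @param epsilon KL smoothing floor.
#' @param criterion Learner criterion on post-training normalized PI.
#' @param weights Context probabilities; default the model's stationary
#'   distribution (uniform for the default topology).
#' @return An object of class `strategy_fit`; see [coef.strategy_fit()],
#'   [summary.strategy_fit()], [plot.strategy_fit()].
#' @examples
#' \donttest{
#' log <- run_experiment(group_config(1), seq_agent("matching"), seed = 7)
#' fit <- strategy_fit(log)
#' coef(fit)
#' }
#' @export
strategy_fit <- function(log, model = NULL, epsilon = 1e-3, criterion = 0.10,
                         weights = NULL) {
  stopifnot(is.data.frame(log))
  if (is.null(model)) {
    gid <- unique(log$group_id)
    if (length(gid) != 1L) stop("log mixes groups; pass `model` explicitly",
                                call. = FALSE)
    model <- markov_model(group_config(gid)$p_high)
  }
  if (is.null(weights)) weights <- stationary_distribution(model)

  session_pi <- function(name) {
    rows <- log[log$session == name & log$block_kind == "structured", ,
                drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    ct <- estimate_conditionals(rows, model$symbols)
    w <- weights
    if (!all(ct$supported)) {
      w[!ct$supported] <- 0
      w <- w / sum(w)
    }
    performance_index(ct, model, w)
  }
  pre_pi <- session_pi("pre")
  post_pi <- session_pi("post")
  if (is.null(pre_pi) || is.null(post_pi)) {
    stop("log must contain structured pre and post test blocks", call. = FALSE)
  }
  cls <- normalize_and_classify(pre_pi, post_pi, criterion)

  train <- log[log$session == "training", , drop = FALSE]
  block_ids <- sort(unique(train$block_id))
  block_pi_curve <- data.frame(
    block_id = block_ids,
    pi = vapply(block_ids, function(b) {
      block_pi(train[train$block_id == b, ], model, weights)
    }, numeric(1))
  )
  curve <- strategy_curve(log, model, epsilon, weights)
  idx <- strategy_index(curve)

  structure(
    list(model = model, weights = weights, epsilon = epsilon,
         criterion = criterion,
         pre_pi = pre_pi, post_pi = post_pi,
         improvement = cls$improvement, label = cls$label,
         block_pi = block_pi_curve,
         strategy_curve = curve, strategy_index = idx,
         n_trials = nrow(log)),
    class = "strategy_fit"
  )
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Sequence-learning strategy fit (", x$n_trials, " trials, p_high = ",
      x$model$p_high, ")\n", sep = "")
  cat(sprintf("  PI pre %.3f  post %.3f  (baseline %.3f)\n",
              x$pre_pi$overall, x$post_pi$overall, x$post_pi$pi_rand))
  cat(sprintf("  normalized PI post %.3f  improvement %.3f  -> %s\n",
              x$post_pi$normalized, x$improvement, x$label))
  cat(sprintf("  strategy index %.3f (0 = matching, >0 toward maximization)\n",
              x$strategy_index))
  invisible(x)
}

#' Summary of a strategy fit
#'
#' @param object A `strategy_fit`.
#' @param ... Unused.
#' @return The object, invisibly, after printing session PIs, the learning
#'   curve range and the strategy summary.
#' @export
summary.strategy_fit <- function(object, ...) {
  print(object)
  cat("\nTraining PI curve: first block", format(object$block_pi$pi[1], digits = 3),
      "-> last block",
      format(object$block_pi$pi[nrow(object$block_pi)], digits = 3), "\n")
  cat("Mean delta-KL over training:",
      format(mean(object$strategy_curve$delta_kl), digits = 3),
      "(matching reference:",
      format(object$strategy_curve$reference[1], digits = 3), ")\n")
  invisible(object)
}

#' Coefficients of a strategy fit
#'
#' @param object A `strategy_fit`.
#' @param ... Unused.
#' @return Named vector: `strategy_index`, `pi_pre`, `pi_post`, `pi_rand`,
#'   `post_normalized`, `improvement`.
#' @export
coef.strategy_fit <- function(object, ...) {
  c(strategy_index = object$strategy_index,
    pi_pre = object$pre_pi$overall,
    pi_post = object$post_pi$overall,
    pi_rand = object$post_pi$pi_rand,
    post_normalized = object$post_pi$normalized,
    improvement = object$improvement)
}

#' Plot a strategy fit
#'
#' Two base-graphics panels: the per-block PI learning curve against the
#' random-guess baseline, and the delta-KL strategy curve against the
#' exact-matching reference.
#'
#' @param x A `strategy_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.strategy_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$block_pi$block_id, x$block_pi$pi, type = "b", pch = 16,
                 xlab = "Training block", ylab = "Performance Index",
                 ylim = range(c(x$block_pi$pi, x$post_pi$pi_rand, 1)), ...)
  graphics::abline(h = x$post_pi$pi_rand, lty = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::plot(x$strategy_curve$block_id, x$strategy_curve$delta_kl,
                 type = "b", pch = 16,
                 xlab = "Training block", ylab = expression(Delta * "KL (nats)"),
                 ...)
  graphics::abline(h = x$strategy_curve$reference[1], lty = 2)
  invisible(x)
}
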