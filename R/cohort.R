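#' Correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two cohort variables, with the 95%
#' Fisher-z interval and the t-distribution p-value (reported for
#' completeness; no multiplicity handling).
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return List with `r`, `ci` (length 2), `p`, `n`.
#' @export
cohort_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (length(x) < 3L) {
    stop("correlation undefined for fewer than 3 observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  n <- length(x)
  r <- unname(ct$estimate)
  ci <- if (n > 3 && abs(r) < 1) {
    tanh(atanh(r) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  } else {
    c(NA_real_, NA_real_)  # Fisher interval undefined at n = 3 or |r| = 1
  }
  list(r = r, ci = ci, p = ct$p.value, n = n)
}

#' Incremental variance explained by an additional regressor
#'
#' Fits least-squares models with and without the added regressor on top of
#' a group-membership design (indicator columns with intercept) and returns
#' the gain in R-squared.
#'
#' @param y Response vector.
#' @param groups Group labels (coerced to factor) forming the base design.
#' @param added Numeric vector of the additional regressor.
#' @return `delta_r2`, with the two R-squared values as attributes.
#' @export
incremental_r2 <- function(y, groups, added) {
  groups <- as.factor(groups)
  if (length(unique(groups)) == length(y)) {
    stop("base design is saturated (one group per observation)", call. = FALSE)
  }
  base_fit <- stats::lm(y ~ groups)
  if (any(is.na(stats::coef(base_fit)))) {
    stop("rank-deficient base design", call. = FALSE)
  }
  full_fit <- stats::lm(y ~ groups + added)
  r2 <- function(fit) summary(fit)$r.squared
  out <- r2(full_fit) - r2(base_fit)
  attr(out, "r2_base") <- r2(base_fit)
  attr(out, "r2_full") <- r2(full_fit)
  out
}

#' Parameter-recovery cohort experiment
#'
#' Simulates a cohort of interpolated agents across a grid of mixing weights
#' lambda spanning the strategy axis (-1 = uniform random, 0 = matching,
#' 1 = maximizing), runs each through the experimental protocol, fits the
#' strategy and performance measures, and summarises the cohort: the
#' correlation between strategy index and post-training normalized PI, and
#' the monotonicity of the mean strategy index in lambda. Spanning the
#' random side of the axis matters for the correlation: among agents at or
#' beyond matching, more maximization lowers the minimum-overlap PI (a pure
#' maximizer caps at p_high), so the positive strategy-performance
#' association characteristic of learning cohorts emerges from the
#' random-to-structured axis, not from the matching-to-maximization end.
#' This is the validation surface: ground-truth strategies are known, so the
#' analysis pipeline can be checked for sign and ordering recovery.
#'
#' @param lambda_grid Mixing weights to simulate.
#' @param n_per_lambda Agents per grid point.
#' @param config An [experiment_config()]; default Group 1.
#' @param epsilon KL smoothing floor passed to the strategy analysis.
#' @param p_null Lapse rate given to every agent.
#' @param seed Integer seed; each agent derives its own stream from it.
#' @param covariates Attach synthetic cognitive covariates
#'   ([cognitive_covariates()]).
#' @return List of class `recovery_result`: `cohort` (one row per agent:
#'   `agent_id`, `group_id`, `true_lambda`, `strategy_index`,
#'   `post_normalized_pi`, `improvement`, `label`, and covariates if
#'   requested), `correlation`, `mean_index_by_lambda`, `monotone_lambda`.
#' @export
recovery_experiment <- function(lambda_grid = c(-1, -0.5, 0, 0.5, 1),
                                n_per_lambda = 20L,
                                config = group_config(1), epsilon = 1e-3,
                                p_null = 0.009, seed = 1L,
                                covariates = FALSE) {
  grid <- rep(lambda_grid, each = n_per_lambda)
  model <- markov_model(config$p_high)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    agent <- seq_agent("interpolated", lambda_mix = grid[i], p_null = p_null)
    log <- run_experiment(config, agent, seed = seed * 10000L + i,
                          agent_id = i)
    fit <- strategy_fit(log, model, epsilon = epsilon)
    rows[[i]] <- data.frame(
      agent_id = i, group_id = config$group_id, true_lambda = grid[i],
      strategy_index = fit$strategy_index,
      post_normalized_pi = fit$post_pi$normalized,
      improvement = fit$improvement, label = fit$label,
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, rows)
  if (covariates) {
    cohort <- merge(cohort, cognitive_covariates(nrow(cohort)),
                    by = "agent_id")
  }
  if (nrow(cohort) < 3L) {
    stop("cohort too small to summarise: correlation needs >= 3 agents",
         call. = FALSE)
  }
  corr <- cohort_correlation(cohort$strategy_index, cohort$post_normalized_pi)
  mean_idx <- tapply(cohort$strategy_index, cohort$true_lambda, mean)
  structure(
    list(cohort = cohort, correlation = corr,
         mean_index_by_lambda = mean_idx,
         monotone_lambda = !is.unsorted(mean_idx, strictly = TRUE)),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Parameter-recovery cohort:", nrow(x$cohort), "agents\n")
  cat("cor(strategy index, post normalized PI) =",
      format(x$correlation$r, digits = 3),
      sprintf("[%.3f, %.3f]", x$correlation$ci[1], x$correlation$ci[2]), "\n")
  cat("Mean strategy index by lambda:\n")
  print(round(x$mean_index_by_lambda, 3))
  cat("Strictly increasing in lambda:", x$monotone_lambda, "\n")
  invisible(x)
}
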