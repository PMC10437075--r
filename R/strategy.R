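#' Reference models for strategy analysis
#'
#' Probability matching: the generative conditional rows themselves.
#' Probability maximization: a point mass on each row's most likely target.
#'
#' @param model A [markov_model()].
#' @param kind `"matching"` or `"maximization"`.
#' @param weights Context probabilities M(context); default stationary.
#' @return An object of class `reference_model` with `kind`, `table`,
#'   `weights`.
#' @export
reference_model <- function(model, kind = c("matching", "maximization"),
                            weights = NULL) {
  stopifnot(inherits(model, "markov_model"))
  kind <- match.arg(kind)
  if (is.null(weights)) weights <- stationary_distribution(model)
  tab <- model$transitions
  if (kind == "maximization") {
    tab <- t(apply(model$transitions, 1, function(row) {
      out <- numeric(4)
      out[which.max(row)] <- 1
      out
    }))
    dimnames(tab) <- dimnames(model$transitions)
  }
  structure(list(kind = kind, table = tab, weights = weights),
            class = "reference_model")
}

#' Kullback-Leibler divergence from a reference model to a response table
#'
#' Computes `sum_c M(c) sum_t M(t|c) log( M(t|c) / R(t|c) )` in nats, where
#' M is the reference model and R the (smoothed) response conditionals.
#' Response rows are smoothed additively, `(r + epsilon) / (1 + 4 epsilon)`,
#' so that zero response cells (e.g. a pure maximizer) stay finite; reference
#' zeros contribute nothing by the `0 log 0 = 0` convention.
#'
#' @param r Response conditionals: `conditional_table` or 4x4 matrix.
#' @param m A [reference_model()].
#' @param epsilon Additive smoothing floor, > 0 (default 1e-3).
#' @return KL divergence in nats (>= 0).
#' @export
kl_to_model <- function(r, m, epsilon = 1e-3) {
  stopifnot(inherits(m, "reference_model"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be > 0", call. = FALSE)
  }
  resp <- as_conditional_matrix(r)
  ok <- supported_contexts(r)
  w <- m$weights
  if (any(w > 0 & !ok)) {
    stop("positive weight on unsupported context(s): ",
         paste(names(w)[w > 0 & !ok], collapse = ", "), call. = FALSE)
  }
  rs <- (resp + epsilon) / (1 + 4 * epsilon)
  total <- 0
  for (c_ in seq_len(4)) {
    if (w[c_] == 0 || !ok[c_]) next
    mr <- m$table[c_, ]
    nz <- mr > 0
    total <- total + w[c_] * sum(mr[nz] * log(mr[nz] / rs[c_, nz]))
  }
  unname(total)
}

#' Per-block strategy choice
#'
#' Delta-KL compares the response distribution to the two reference models:
#' `delta_kl = KL(matching || R) - KL(maximization || R)`. Zero-centred at
#' exact matching once the reference curve is subtracted; positive values
#' mean the responses sit closer to maximization, negative values closer to
#' uniform random responding.
#'
#' @param r Response conditionals (`conditional_table` or 4x4 matrix).
#' @param model A [markov_model()].
#' @param epsilon Smoothing floor, see [kl_to_model()].
#' @param weights Context probabilities; default stationary.
#' @return A `strategy_point` list: `kl_matching`, `kl_maximization`,
#'   `delta_kl`.
#' @export
strategy_choice <- function(r, model, epsilon = 1e-3, weights = NULL) {
  m_match <- reference_model(model, "matching", weights)
  m_max <- reference_model(model, "maximization", weights)
  kl_m <- kl_to_model(r, m_match, epsilon)
  kl_x <- kl_to_model(r, m_max, epsilon)
  structure(list(kl_matching = kl_m, kl_maximization = kl_x,
                 delta_kl = kl_m - kl_x),
            class = "strategy_point")
}

#' Strategy curve across training blocks
#'
#' Estimates the response conditionals per training block and computes the
#' per-block delta-KL strategy choice, together with the analytic reference
#' curve of an exact-matching responder (the generative rows passed through
#' the same smoothing), whose delta-KL is constant across blocks.
#'
#' @param log A trial-log data frame from [run_experiment()].
#' @param model The generative [markov_model()].
#' @param epsilon Smoothing floor.
#' @param weights Context probabilities; default stationary. Blocks missing a
#'   weighted context have their weights renormalized over the supported
#'   contexts.
#' @return A data frame of class `strategy_curve` with columns `block_id`,
#'   `kl_matching`, `kl_maximization`, `delta_kl`, `reference`.
#' @export
strategy_curve <- function(log, model, epsilon = 1e-3, weights = NULL) {
  stopifnot(is.data.frame(log))
  if (is.null(weights)) weights <- stationary_distribution(model)
  train <- log[log$session == "training", , drop = FALSE]
  if (nrow(train) == 0L) stop("log contains no training rows", call. = FALSE)
  blocks <- sort(unique(train$block_id))
  ref_delta <- strategy_choice(model$transitions, model, epsilon, weights)$delta_kl
  rows <- lapply(blocks, function(b) {
    ct <- estimate_conditionals(train[train$block_id == b, ], model$symbols)
    w <- weights
    if (!all(ct$supported)) {
      w[!ct$supported] <- 0
      w <- w / sum(w)
    }
    sc <- strategy_choice(ct, model, epsilon, w)
    data.frame(block_id = b, kl_matching = sc$kl_matching,
               kl_maximization = sc$kl_maximization,
               delta_kl = sc$delta_kl, reference = ref_delta)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("strategy_curve", "data.frame")
  out
}

#' Integral-curve-difference strategy index
#'
#' Summarises a strategy curve as the discrete integral (unit-spaced sum over
#' training blocks) of the participant's delta-KL minus the integral of the
#' exact-matching reference curve. Zero indicates matching; positive values a
#' strategy shifted toward maximization; negative values toward uniform
#' random responding.
#'
#' @param curve A `strategy_curve` from [strategy_curve()], or any data frame
#'   with `delta_kl` and `reference` columns of equal length.
#' @param method `"rectangle"` (unit-spaced sum, default) or `"trapezoid"`
#'   (differs only by halving the endpoints).
#' @return Scalar strategy index (nats x blocks).
#' @export
strategy_index <- function(curve, method = c("rectangle", "trapezoid")) {
  method <- match.arg(method)
  if (!all(c("delta_kl", "reference") %in% names(curve))) {
    stop("`curve` needs `delta_kl` and `reference` columns", call. = FALSE)
  }
  d <- curve$delta_kl - curve$reference
  if (length(d) < 1L) stop("empty strategy curve", call. = FALSE)
  if (any(is.na(d))) stop("NA in strategy curve", call. = FALSE)
  if (method == "rectangle" || length(d) == 1L) {
    sum(d)
  } else {
    sum(d) - (d[1L] + d[length(d)]) / 2
  }
}
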