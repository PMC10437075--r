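#' Construct a four-state first-order Markov sequence model
#'
#' Builds the transition model that generates structured symbol streams for
#' the prediction task. Each of the four contexts (the most recent symbol)
#' allows exactly two targets: one frequent with probability `p_high` and one
#' infrequent with probability `1 - p_high`. The default topology is the
#' cyclic design A -> (B, C), B -> (C, D), C -> (D, A), D -> (A, B), which is
#' doubly stochastic and therefore has a uniform stationary distribution.
#'
#' @param p_high Probability of the frequent target, in (0.5, 1]. The two
#'   designs used in practice are 0.8 (80% vs 20%) and 0.6 (60% vs 40%).
#' @param transitions Optional 4x4 matrix of conditional probabilities
#'   P(target | context), rows = contexts, columns = targets. Each row must
#'   sum to 1 and carry its mass on at most two entries equal to `p_high` and
#'   `1 - p_high`. When `NULL` the default cyclic topology is used.
#' @param symbols Character vector of four distinct symbol labels.
#'
#' @return An object of class `markov_model` with elements `symbols`,
#'   `transitions` (rows and columns named by symbol), `p_high` and `order`.
#'
#' @examples
#' m <- markov_model(0.8)
#' m$transitions["A", ]
#' stationary_distribution(m)
#' @export
markov_model <- function(p_high = 0.8, transitions = NULL,
                         symbols = c("A", "B", "C", "D")) {
  if (!is.numeric(p_high) || length(p_high) != 1L || is.na(p_high) ||
      p_high <= 0.5 || p_high > 1) {
    stop("`p_high` must be a single probability in (0.5, 1]; ",
         "p_high <= 0.5 gives a tie or improper contingency", call. = FALSE)
  }
  if (length(symbols) != 4L || anyDuplicated(symbols) ||
      !is.character(symbols)) {
    stop("`symbols` must be 4 distinct labels", call. = FALSE)
  }
  if (is.null(transitions)) {
    # cyclic two-target topology: each context points at the next symbol
    # (frequent) and the one after (infrequent)
    transitions <- matrix(0, 4, 4)
    for (i in 1:4) {
      transitions[i, (i %% 4) + 1L] <- p_high
      transitions[i, (i %% 4 + 1L) %% 4 + 1L] <- 1 - p_high
    }
  } else {
    transitions <- as.matrix(transitions)
    if (!identical(dim(transitions), c(4L, 4L))) {
      stop("`transitions` must be a 4x4 matrix", call. = FALSE)
    }
  }
  dimnames(transitions) <- list(symbols, symbols)
  validate_transitions(transitions, p_high)
  m <- structure(
    list(symbols = symbols, transitions = transitions,
         p_high = p_high, order = 1L),
    class = "markov_model"
  )
  # cache the stationary vector; left NULL for reducible custom matrices so
  # construction succeeds and stationary_distribution() reports the problem
  m$stationary <- tryCatch(stationary_distribution(m), error = function(e) NULL)
  m
}

validate_transitions <- function(transitions, p_high) {
  if (any(transitions < 0)) stop("negative transition probability", call. = FALSE)
  rs <- rowSums(transitions)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("each transition row must sum to 1 (within 1e-12); row sums: ",
         paste(signif(rs, 15), collapse = ", "), call. = FALSE)
  }
  for (i in 1:4) {
    nz <- sort(transitions[i, transitions[i, ] > 0], decreasing = TRUE)
    want <- if (p_high == 1) 1 else c(p_high, 1 - p_high)
    if (length(nz) != length(want) || any(abs(nz - want) > 1e-12)) {
      stop("row ", rownames(transitions)[i], " must place its mass on ",
           "exactly two targets with probabilities p_high and 1 - p_high",
           call. = FALSE)
    }
  }
  invisible(transitions)
}

#' @export
print.markov_model <- function(x, ...) {
  cat("First-order Markov sequence model (4 symbols)\n")
  cat("p_high =", x$p_high, " (frequent vs infrequent contingency)\n")
  cat("Transition matrix P(target | context):\n")
  print(round(x$transitions, 4))
  invisible(x)
}

#' Stationary distribution of a sequence model
#'
#' Solves for the unique stationary context distribution of the transition
#' matrix. This supplies the default context weights P(context) used when
#' aggregating the Performance Index and the KL strategy measures across
#' contexts; for the default doubly stochastic topology it is uniform.
#'
#' @param model A [markov_model()].
#' @return Named numeric vector of 4 context probabilities.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  if (!is.null(model$stationary)) return(model$stationary)
  P <- model$transitions
  unreachable <- unreachable_states(P)
  if (length(unreachable)) {
    stop("transition matrix is reducible; unreachable states: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  }
  # w P = w, sum(w) = 1 as an overdetermined linear system
  A <- rbind(t(P) - diag(4), rep(1, 4))
  w <- qr.solve(A, c(rep(0, 4), 1))
  w <- pmax(w, 0)
  w <- w / sum(w)
  names(w) <- model$symbols
  w
}

# states not reachable from every other state (strong connectivity check
# via boolean matrix powers on the support pattern)
unreachable_states <- function(P) {
  adj <- P > 0
  reach <- adj | diag(TRUE, nrow(P))
  for (k in seq_len(nrow(P))) reach <- reach | (reach %*% reach) > 0
  bad <- !apply(reach & t(reach), 1, all)
  rownames(P)[bad]
}

#' Inter-stimulus interval schedules
#'
#' Fixed schedules place every interval at 400 ms; jittered schedules draw
#' each interval uniformly from the 31-point grid 100, 120, ..., 700 ms
#' (20 ms bins), the temporal-uncertainty manipulation.
#'
#' @param mode `"fixed"` or `"jitter"`.
#' @param n_intervals Number of intervals to produce (>= 1).
#' @return Integer vector of interval durations in milliseconds.
#' @export
make_isi_schedule <- function(mode = c("fixed", "jitter"), n_intervals) {
  mode <- match.arg(mode)
  if (!is.numeric(n_intervals) || n_intervals < 1) {
    stop("`n_intervals` must be >= 1", call. = FALSE)
  }
  n_intervals <- as.integer(n_intervals)
  if (mode == "fixed") rep(400L, n_intervals)
  else sample(seq(100L, 700L, by = 20L), n_intervals, replace = TRUE)
}

#' Generate one structured trial sequence
#'
#' Draws a symbol stream of random length from the model: the first symbol
#' from the stationary distribution, each subsequent symbol from the current
#' context's transition row. The stream's final symbol is the context for the
#' prediction; a hidden target (never displayed) is sampled from that
#' context's row and used for trial-by-trial feedback.
#'
#' @param model A [markov_model()].
#' @param length_range Integer interval (min, max) of stream lengths,
#'   default `c(9, 13)`; length is uniform on the range.
#' @param isi_mode ISI schedule mode, see [make_isi_schedule()].
#' @return A `trial_sequence` list: `symbols`, `context`, `hidden_target`,
#'   `isi_ms`, `kind`.
#' @export
generate_trial <- function(model, length_range = c(9L, 13L),
                           isi_mode = c("fixed", "jitter")) {
  stopifnot(inherits(model, "markov_model"))
  isi_mode <- match.arg(isi_mode)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1] > length_range[2] || length_range[1] < 2) {
    stop("`length_range` must be a nonempty integer interval within [2, Inf)",
         call. = FALSE)
  }
  n <- sample(seq.int(length_range[1], length_range[2]), 1L)
  w <- stationary_distribution(model)  # cached on the model
  P <- model$transitions
  idx <- integer(n + 1L)
  idx[1L] <- sample.int(4L, 1L, prob = w)
  for (i in seq.int(2L, n + 1L)) {
    idx[i] <- sample.int(4L, 1L, prob = P[idx[i - 1L], ])
  }
  structure(
    list(symbols = model$symbols[idx[seq_len(n)]],
         context = model$symbols[idx[n]],
         hidden_target = model$symbols[idx[n + 1L]],
         isi_ms = make_isi_schedule(isi_mode, n),
         kind = "structured"),
    class = "trial_sequence"
  )
}

#' Generate one random (unstructured) trial sequence
#'
#' All symbols i.i.d. uniform over the four labels, with a uniform hidden
#' target; the control condition used in pre- and post-training test blocks.
#'
#' @inheritParams generate_trial
#' @return A `trial_sequence` with `kind = "random"`.
#' @export
generate_random_trial <- function(model, length_range = c(9L, 13L),
                                  isi_mode = c("fixed", "jitter")) {
  stopifnot(inherits(model, "markov_model"))
  isi_mode <- match.arg(isi_mode)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1] > length_range[2] || length_range[1] < 2) {
    stop("`length_range` must be a nonempty integer interval within [2, Inf)",
         call. = FALSE)
  }
  n <- sample(seq.int(length_range[1], length_range[2]), 1L)
  idx <- sample.int(4L, n + 1L, replace = TRUE)
  structure(
    list(symbols = model$symbols[idx[seq_len(n)]],
         context = model$symbols[idx[n]],
         hidden_target = model$symbols[idx[n + 1L]],
         isi_ms = make_isi_schedule(isi_mode, n),
         kind = "random"),
    class = "trial_sequence"
  )
}

#' Write / read a sequence model as plain text
#'
#' Serializes the symbol labels, `p_high` and the transition rows at full
#' double precision so the model round-trips exactly.
#'
#' @param model A [markov_model()].
#' @param path File path.
#' @return `write_markov_model` returns `path` invisibly;
#'   `read_markov_model` returns the reconstructed [markov_model()].
#' @export
write_markov_model <- function(model, path) {
  stopifnot(inherits(model, "markov_model"))
  lines <- c(
    paste("symbols:", paste(model$symbols, collapse = " ")),
    paste("p_high:", sprintf("%.17g", model$p_high)),
    vapply(1:4, function(i) {
      paste("row:", paste(sprintf("%.17g", model$transitions[i, ]),
                          collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_markov_model
#' @export
read_markov_model <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) stop("missing '", key, "' in model file", call. = FALSE)
    sub(paste0("^", key, ":\\s*"), "", hit)
  }
  symbols <- strsplit(field("symbols"), "\\s+")[[1]]
  p_high <- as.numeric(field("p_high"))
  rows <- lapply(strsplit(field("row"), "\\s+"), as.numeric)
  if (length(rows) != 4L) stop("expected 4 transition rows", call. = FALSE)
  markov_model(p_high, transitions = do.call(rbind, rows), symbols = symbols)
}
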