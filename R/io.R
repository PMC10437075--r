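#' Trial-log CSV schema
#'
#' The on-disk trial log is a plain CSV with a fixed, ordered header. The
#' four `p_resp_*` columns hold the per-trial response vector (a point mass
#' for a key press, uniform 0.25 for a null response) and must sum to 1.
#'
#' @return Character vector of the column names, in order.
#' @export
trial_log_schema <- function() trial_log_columns()

validate_trial_log <- function(log, where = "trial log") {
  cols <- trial_log_columns()
  if (!identical(names(log), cols)) {
    missing <- setdiff(cols, names(log))
    extra <- setdiff(names(log), cols)
    msg <- if (length(missing)) paste("missing column(s):",
                                      paste(missing, collapse = ", "))
           else if (length(extra)) paste("unexpected column(s):",
                                         paste(extra, collapse = ", "))
           else "columns out of order"
    stop(where, " does not match the schema: ", msg, call. = FALSE)
  }
  sums <- log$p_resp_A + log$p_resp_B + log$p_resp_C + log$p_resp_D
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad)) {
    stop(where, ": p_resp_* columns do not sum to 1 in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(log)
}

#' Write / read a trial log as CSV
#'
#' The round trip is lossless: response probabilities are written with 12
#' significant digits and all other fields verbatim. Reading validates the
#' header (exact order) and the response-vector sums, failing with a message
#' that names the offending column or rows.
#'
#' @param log A `trial_log` data frame ([run_experiment()]).
#' @param path File path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the validated `trial_log`.
#' @export
write_trial_log <- function(log, path) {
  validate_trial_log(log)
  out <- as.data.frame(log)
  for (col in paste0("p_resp_", c("A", "B", "C", "D"))) {
    out[[col]] <- sprintf("%.12g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chosen = "character",
                                        context = "character",
                                        hidden_target = "character"))
  log$chosen[log$chosen == "NA" | log$chosen == ""] <- NA_character_
  validate_trial_log(log, where = basename(path))
  class(log) <- c("trial_log", "data.frame")
  log
}

config_keys <- c("group", "p_high", "isi_mode", "feedback_mode",
                 "n_training_blocks", "trials_per_training_block",
                 "trials_per_test_block", "retest", "p_uncorrelated", "seed")
agent_keys <- c("policy", "lambda_mix", "p_null", "learn_rate",
                "feedback_sensitivity", "prior_weight", "readout",
                "tie_break", "replicates")

#' Load an experiment configuration file
#'
#' YAML with an `experiment` section (a `group` preset plus field-by-field
#' overrides) and an optional `agents` list. Unknown keys are rejected so
#' typos fail loudly rather than silently falling back to defaults.
#'
#' ```yaml
#' experiment:
#'   group: 1
#'   p_high: 0.6        # optional override
#'   seed: 42
#' agents:
#'   - policy: matching
#'     p_null: 0.009
#'   - policy: interpolated
#'     lambda_mix: 0.5
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with `config` (an [experiment_config()]), `agents` (list of
#'   [seq_agent()]; `replicates` repeats an entry) and `seed` (or `NULL`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  exp <- raw$experiment
  if (is.null(exp)) stop("config has no `experiment` section", call. = FALSE)
  unknown <- setdiff(names(exp), config_keys)
  if (length(unknown)) {
    stop("unknown experiment key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(config_keys, collapse = ", "), call. = FALSE)
  }
  if (is.null(exp$group)) stop("`experiment.group` is required", call. = FALSE)
  if (!is.null(exp$feedback_mode) &&
      !exp$feedback_mode %in% c("block", "trial", "none", "uncorrelated")) {
    stop("unknown feedback_mode '", exp$feedback_mode,
         "'; allowed: block, trial, none, uncorrelated", call. = FALSE)
  }
  if (!is.null(exp$p_high) && (exp$p_high <= 0.5 || exp$p_high > 1)) {
    stop("`p_high` must be in (0.5, 1]", call. = FALSE)
  }
  seed <- exp$seed
  overrides <- exp[setdiff(names(exp), c("group", "seed"))]
  config <- do.call(group_config, c(list(group_id = exp$group), overrides))
  agents <- list()
  for (a in raw$agents) {
    unknown <- setdiff(names(a), agent_keys)
    if (length(unknown)) {
      stop("unknown agent key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    n <- if (is.null(a$replicates)) 1L else as.integer(a$replicates)
    a$replicates <- NULL
    agent <- do.call(seq_agent, a)
    agents <- c(agents, rep(list(agent), n))
  }
  list(config = config, agents = agents, seed = seed)
}
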