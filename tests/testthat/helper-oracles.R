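# From-definition oracles, kept independent of the package implementations.

# minimum-overlap PI straight from the formula
pi_oracle <- function(resp, pres, w) {
  w <- unname(w)
  total <- 0
  for (c_ in 1:4) {
    overlap <- 0
    for (t_ in 1:4) overlap <- overlap + min(resp[c_, t_], pres[c_, t_])
    total <- total + w[c_] * overlap
  }
  total
}

# KL(M || R) with explicit epsilon smoothing of R, term-by-term
kl_oracle <- function(m_table, w, resp, eps) {
  w <- unname(w)
  rs <- (resp + eps) / (1 + 4 * eps)
  total <- 0
  for (c_ in 1:4) {
    for (t_ in 1:4) {
      if (m_table[c_, t_] > 0) {
        total <- total + w[c_] * m_table[c_, t_] *
          log(m_table[c_, t_] / rs[c_, t_])
      }
    }
  }
  total
}

# random response-conditional table (rows on the simplex)
random_resp_table <- function(symbols = c("A", "B", "C", "D")) {
  m <- matrix(stats::rexp(16), 4, 4, dimnames = list(symbols, symbols))
  m / rowSums(m)
}

# power-iteration stationary distribution
stationary_oracle <- function(P, iters = 1e4) {
  w <- rep(0.25, 4)
  for (i in seq_len(iters)) w <- as.numeric(w %*% P)
  w
}

default_model_80 <- function() markov_model(0.8)

# small trial log built by hand: one agent, known responses
toy_log <- function() {
  run_experiment(
    experiment_config(n_training_blocks = 3L, trials_per_training_block = 20L,
                      trials_per_test_block = 10L, feedback_mode = "none"),
    seq_agent("matching"), seed = 42
  )
}
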