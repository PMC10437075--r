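test_that("policy distributions span random, matching, maximizing and mixtures", {
  m <- markov_model(0.8)
  expect_equal(unname(policy_distribution(seq_agent("random"), "A", m)),
               rep(0.25, 4))
  expect_equal(policy_distribution(seq_agent("matching"), "A", m),
               m$transitions["A", ])
  expect_equal(unname(policy_distribution(seq_agent("maximizing"), "A", m)),
               c(0, 1, 0, 0))
  # interpolated: (1 - lambda) * matching + lambda * point mass
  half <- policy_distribution(seq_agent("interpolated", lambda_mix = 0.5), "A", m)
  expect_equal(unname(half), c(0, 0.9, 0.1, 0))
  expect_equal(policy_distribution(seq_agent("interpolated", lambda_mix = 0), "A", m),
               m$transitions["A", ])
  expect_equal(
    policy_distribution(seq_agent("interpolated", lambda_mix = 1), "A", m),
    policy_distribution(seq_agent("maximizing"), "A", m))
})

test_that("interpolated mass on the frequent target is strictly increasing in lambda", {
  m <- markov_model(0.8)
  mass <- vapply(seq(-1, 1, by = 0.1), function(l) {
    policy_distribution(seq_agent("interpolated", lambda_mix = l), "A", m)[["B"]]
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
  # axis endpoints: uniform random at -1, argmax point mass at +1
  expect_equal(unname(policy_distribution(
    seq_agent("interpolated", lambda_mix = -1), "A", m)), rep(0.25, 4))
})

test_that("agent configuration is validated", {
  expect_error(seq_agent("matching", lambda_mix = 0.5), "interpolated")
  expect_error(seq_agent("interpolated"), "lambda_mix")
  expect_error(seq_agent("interpolated", lambda_mix = 1.5), "lambda_mix")
  expect_error(seq_agent("interpolated", lambda_mix = -1.5), "lambda_mix")
  expect_error(seq_agent("matching", p_null = -0.1), "p_null")
  expect_error(seq_agent("learning", learn_rate = -1), "learn_rate")
})

test_that("maximizing over a tied row errors unless a tie-break is configured", {
  tied <- matrix(0.25, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_error(policy_distribution(seq_agent("maximizing"), "A", tied), "tie")
  lex <- policy_distribution(seq_agent("maximizing", tie_break = "lexicographic"),
                             "A", tied)
  expect_equal(unname(lex), c(1, 0, 0, 0))
})

test_that("responses are sampled from the policy with the configured lapse rate", {
  m <- markov_model(0.8)
  trial <- structure(list(symbols = c("D", "A"), context = "A",
                          hidden_target = "B", isi_ms = rep(400L, 2),
                          kind = "structured"), class = "trial_sequence")
  # forced lapse: every record is the uniform null record
  always_null <- seq_agent("matching", p_null = 1)
  rec <- respond(always_null, trial, m)
  expect_true(is.na(rec$chosen))
  expect_equal(unname(rec$response_vector), rep(0.25, 4))

  set.seed(21)
  a <- seq_agent("matching")
  picks <- replicate(10000, respond(a, trial, m)$chosen)
  p_b <- mean(picks == "B")
  expect_lt(abs(p_b - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))

  # lapse rate 0.009 recovered over many trials
  set.seed(22)
  a2 <- seq_agent("matching", p_null = 0.009)
  nulls <- mean(is.na(replicate(20000, respond(a2, trial, m)$chosen)))
  expect_lt(abs(nulls - 0.009), 0.003)

  # all emitted vectors are probability vectors (point mass or uniform)
  set.seed(23)
  for (i in 1:50) {
    r <- respond(a2, trial, m)
    expect_equal(sum(r$response_vector), 1)
    expect_true(all(r$response_vector %in% c(0, 1)) ||
                  all(r$response_vector == 0.25))
  }
})

test_that("belief conditionals start at the prior and converge with exposure", {
  b <- new_belief(prior_weight = 1)
  expect_equal(unname(belief_conditionals(b)), matrix(0.25, 4, 4))

  m <- markov_model(0.8)
  agent <- seq_agent("learning", learn_rate = 1)
  set.seed(31)
  for (i in 1:2000) {
    tr <- generate_trial(m)
    rec <- respond(agent, tr, b)
    b <- update_belief(b, tr, rec, "none", agent)
  }
  tv <- 0.5 * sum(abs(belief_conditionals(b)["A", ] - c(0, 0.8, 0.2, 0)))
  expect_lt(tv, 0.02)
})

test_that("uncorrelated-feedback bonus degrades the belief relative to exposure only", {
  m <- markov_model(0.8)
  tv_error <- function(counts_belief) {
    bc <- belief_conditionals(counts_belief)
    mean(vapply(1:4, function(i) {
      0.5 * sum(abs(bc[i, ] - m$transitions[i, ]))
    }, numeric(1)))
  }
  worse <- logical(10)
  for (s in 1:10) {
    run_one <- function(sensitivity) {
      agent <- seq_agent("learning", learn_rate = 1,
                         feedback_sensitivity = sensitivity)
      b <- new_belief()
      set.seed(1000 + s)
      for (i in 1:2000) {
        tr <- generate_trial(m)
        rec <- respond(agent, tr, b)
        rec$feedback <- emit_feedback(rec, tr, "uncorrelated")
        b <- update_belief(b, tr, rec, "uncorrelated", agent)
      }
      tv_error(b)
    }
    worse[s] <- run_one(5) > run_one(0)
  }
  expect_true(all(worse))
})

test_that("agent trajectories are reproducible under a fixed seed", {
  m <- markov_model(0.8)
  a <- seq_agent("interpolated", lambda_mix = 0.3, p_null = 0.01)
  go <- function() {
    set.seed(77)
    replicate(50, {
      tr <- generate_trial(m)
      respond(a, tr, m)$chosen
    })
  }
  expect_identical(go(), go())
})
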