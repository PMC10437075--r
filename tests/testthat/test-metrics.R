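make_log_rows <- function(contexts, choices) {
  # choices: symbol or NA (null response)
  rv <- t(vapply(choices, function(ch) {
    if (is.na(ch)) rep(0.25, 4)
    else as.numeric(c("A", "B", "C", "D") == ch)
  }, numeric(4)))
  colnames(rv) <- paste0("p_resp_", c("A", "B", "C", "D"))
  cbind(data.frame(context = contexts, stringsAsFactors = FALSE),
        as.data.frame(rv))
}

test_that("conditional estimation averages point masses and null records", {
  # 3 records at A choosing B, B, C
  ct <- estimate_conditionals(make_log_rows(rep("A", 3), c("B", "B", "C")))
  expect_equal(unname(ct$table["A", ]), c(0, 2 / 3, 1 / 3, 0))
  expect_false(ct$supported["B"])

  # one point mass on B plus one null record
  ct2 <- estimate_conditionals(make_log_rows(c("A", "A"), c("B", NA)))
  expect_equal(unname(ct2$table["A", ]), c(0.125, 0.625, 0.125, 0.125))

  # all-null block: every supported row uniform
  ct3 <- estimate_conditionals(make_log_rows(c("A", "B", "C", "D"),
                                             rep(NA_character_, 4)))
  expect_equal(unname(ct3$table), matrix(0.25, 4, 4))
  expect_true(all(ct3$supported))
})

test_that("PI equals 1 for identical distributions and the printed baselines for uniform responders", {
  m8 <- markov_model(0.8)
  expect_equal(performance_index(m8$transitions, m8)$overall, 1)
  uni <- matrix(0.25, 4, 4, dimnames = dimnames(m8$transitions))
  expect_equal(performance_index(uni, m8)$overall, 0.45)
  expect_equal(performance_index(uni, markov_model(0.6))$overall, 0.50)
  # maximizing responder against the 0.8 model: min(1, .8) + min(0, .2) = .8
  maxr <- reference_model(m8, "maximization")$table
  expect_equal(performance_index(maxr, m8)$overall, 0.8)
})

test_that("random_baseline is the closed form and matches the uniform responder PI", {
  expect_equal(random_baseline(markov_model(0.8)), 0.45)
  expect_equal(random_baseline(markov_model(0.6)), 0.50)
  expect_equal(random_baseline(markov_model(1)), 0.25)
  set.seed(17)
  for (p in runif(10, 0.51, 1)) {
    m <- markov_model(p)
    uni <- matrix(0.25, 4, 4, dimnames = dimnames(m$transitions))
    expect_equal(random_baseline(m), performance_index(uni, m)$overall,
                 tolerance = 1e-12)
  }
})

test_that("PI matches the from-definition oracle on random tables and is symmetric", {
  set.seed(4)
  m <- markov_model(0.8)
  w <- stationary_distribution(m)
  for (i in 1:25) {
    a <- random_resp_table()
    b <- random_resp_table()
    got <- performance_index(a, b, weights = w)$overall
    expect_equal(got, pi_oracle(a, b, w), tolerance = 1e-10)
    expect_equal(got, performance_index(b, a, weights = w)$overall,
                 tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, 1)
    # identity iff equal (on full support): perturbing reduces overlap
    expect_lt(got, 1)
    expect_equal(performance_index(a, a, weights = w)$overall, 1,
                 tolerance = 1e-12)
  }
})

test_that("PI against the model dominates any strictly more divergent responder", {
  # moving response mass away from the presented distribution cannot raise PI
  m <- markov_model(0.8)
  w <- stationary_distribution(m)
  base <- m$transitions
  set.seed(8)
  for (i in 1:20) {
    mix <- runif(1)
    towards_uniform <- (1 - mix) * base + mix * matrix(0.25, 4, 4)
    further <- (1 - min(1, mix * 1.5)) * base +
      min(1, mix * 1.5) * matrix(0.25, 4, 4)
    expect_gte(performance_index(towards_uniform, m)$overall + 1e-12,
               performance_index(further, m)$overall)
  }
})

test_that("unsupported contexts with positive weight raise an error", {
  rows <- make_log_rows(c("A", "A", "B", "C"), c("B", "B", "C", "D"))
  ct <- estimate_conditionals(rows)  # context D unseen
  m <- markov_model(0.8)
  expect_error(performance_index(ct, m), "unsupported context")
  w <- c(A = 1, B = 1, C = 1, D = 0) / 3
  expect_silent(performance_index(ct, m, weights = w))
})

test_that("learner classification is inclusive at the 0.10 boundary", {
  m <- markov_model(0.8)
  w <- stationary_distribution(m)
  mk <- function(overall) {
    structure(list(per_context = rep(overall, 4), overall = overall,
                   pi_rand = 0.45, normalized = overall - 0.45, weights = w),
              class = "pi_result")
  }
  pre <- mk(0.45)
  expect_identical(normalize_and_classify(pre, mk(0.55))$label, "learner")
  expect_identical(normalize_and_classify(pre, mk(0.5499999))$label,
                   "weak_learner")
  res <- normalize_and_classify(mk(0.45), mk(0.80))
  expect_equal(res$improvement, 0.35)
  # mismatched baselines rejected
  post <- mk(0.55); post$pi_rand <- 0.5; post$normalized <- 0.05
  expect_error(normalize_and_classify(pre, post), "baseline")
})

test_that("expected hit rates reproduce the analytic strategy payoffs", {
  m <- markov_model(0.8)
  expect_equal(expected_hit_rate(seq_agent("matching"), m), 0.68)
  expect_equal(expected_hit_rate(seq_agent("maximizing"), m), 0.80)
  expect_equal(expected_hit_rate(seq_agent("random"), m), 0.25)
  expect_equal(expected_hit_rate(seq_agent("random"), markov_model(0.6)), 0.25)
  # affine in lambda between 0.68 and 0.80
  lams <- seq(0, 1, by = 0.25)
  hr <- vapply(lams, function(l) {
    expected_hit_rate(seq_agent("interpolated", lambda_mix = l), m)
  }, numeric(1))
  expect_equal(hr, 0.68 + lams * 0.12, tolerance = 1e-12)
})
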