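test_that("default model has the two-target cyclic structure", {
  m <- markov_model(0.8)
  expect_equal(m$transitions["A", ], c(A = 0, B = 0.8, C = 0.2, D = 0))
  expect_equal(rowSums(m$transitions), c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(colSums(m$transitions), c(A = 1, B = 1, C = 1, D = 1))
  # every row: exactly two nonzero entries at p_high / 1 - p_high
  for (p in c(0.6, 0.75, 0.9)) {
    mm <- markov_model(p)
    for (i in 1:4) {
      nz <- sort(mm$transitions[i, mm$transitions[i, ] > 0])
      expect_equal(unname(nz), c(1 - p, p))
    }
  }
})

test_that("degenerate p_high = 1 gives a deterministic cycle", {
  m <- markov_model(1)
  expect_true(all(rowSums(m$transitions) == 1))
  expect_true(all(rowSums(m$transitions > 0) == 1))
  expect_equal(unname(stationary_distribution(m)), rep(0.25, 4))
})

test_that("invalid contingency probabilities are rejected", {
  expect_error(markov_model(0.5), "0.5, 1]", fixed = TRUE)
  expect_error(markov_model(0.2), "0.5, 1]", fixed = TRUE)
  expect_error(markov_model(1.2), "0.5, 1]", fixed = TRUE)
  bad <- matrix(0.25, 4, 4)
  expect_error(markov_model(0.8, transitions = bad), "exactly two targets")
})

test_that("stationary distribution is uniform for the default model and matches power iteration elsewhere", {
  expect_equal(unname(stationary_distribution(markov_model(0.7))), rep(0.25, 4))
  # hand-built non-doubly-stochastic chain sharing the two-entry row structure
  p <- 0.7
  P <- rbind(c(0, p, 1 - p, 0),
             c(0, 0, p, 1 - p),
             c(0, 1 - p, 0, p),
             c(p, 1 - p, 0, 0))
  m <- markov_model(p, transitions = P)
  expect_equal(unname(stationary_distribution(m)), stationary_oracle(P),
               tolerance = 1e-10)
})

test_that("reducible chains are reported with the unreachable states", {
  # A and B feed each other only; C and D unreachable from them
  P <- rbind(c(0.8, 0.2, 0, 0),
             c(0.2, 0.8, 0, 0),
             c(0, 0, 0.8, 0.2),
             c(0, 0, 0.2, 0.8))
  m <- markov_model(0.8, transitions = P)
  expect_error(stationary_distribution(m), "reducible")
})

test_that("structured trials respect the transition support and length range", {
  m <- markov_model(0.8)
  set.seed(11)
  lens <- integer(300)
  for (i in 1:300) {
    tr <- generate_trial(m)
    lens[i] <- length(tr$symbols)
    pairs <- cbind(tr$symbols[-length(tr$symbols)], tr$symbols[-1])
    expect_true(all(m$transitions[pairs] > 0))
    expect_gt(m$transitions[tr$context, tr$hidden_target], 0)
    expect_identical(tr$context, tr$symbols[length(tr$symbols)])
  }
  expect_true(all(lens %in% 9:13))
  # each length roughly 1/5 of the draws
  expect_true(all(abs(table(factor(lens, levels = 9:13)) / 300 - 0.2) < 0.1))
})

test_that("empirical transition frequencies converge to the model rows", {
  m <- markov_model(0.8)
  set.seed(7)
  n_high <- 0L; n_tot <- 0L
  counts <- matrix(0, 4, 4, dimnames = dimnames(m$transitions))
  for (i in 1:3000) {
    tr <- generate_trial(m)
    s <- c(tr$symbols, tr$hidden_target)
    for (j in seq_len(length(s) - 1L)) {
      counts[s[j], s[j + 1L]] <- counts[s[j], s[j + 1L]] + 1
    }
  }
  emp <- counts / rowSums(counts)
  n_per_row <- rowSums(counts)
  # high-probability transition frequency: 0.80 within 3 SE
  p_hat <- sum(counts[m$transitions > 0.5]) / sum(counts)
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / sum(counts)))
  # row-wise KL(model || empirical) small at this sample size
  for (i in 1:4) {
    nz <- m$transitions[i, ] > 0
    kl <- sum(m$transitions[i, nz] * log(m$transitions[i, nz] / emp[i, nz]))
    expect_lt(kl, 0.001)
  }
})

test_that("random trials are uniform i.i.d. with uniform hidden target", {
  m <- markov_model(0.8)
  set.seed(5)
  syms <- character(0)
  saw_repeat <- FALSE
  for (i in 1:1000) {
    tr <- generate_random_trial(m)
    expect_identical(tr$kind, "random")
    syms <- c(syms, tr$symbols)
    if (any(tr$symbols[-1] == tr$symbols[-length(tr$symbols)])) saw_repeat <- TRUE
  }
  n <- length(syms)
  freq <- table(factor(syms, levels = m$symbols)) / n
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / n)))
  expect_true(saw_repeat)  # no adjacency constraint
  # chi-square uniformity below the 0.999 null quantile
  obs <- table(factor(syms, levels = m$symbols))
  chisq <- sum((obs - n / 4)^2 / (n / 4))
  expect_lt(chisq, qchisq(0.999, df = 3))
})

test_that("ISI schedules follow the fixed and jittered regimes", {
  expect_identical(make_isi_schedule("fixed", 12), rep(400L, 12))
  set.seed(3)
  jit <- make_isi_schedule("jitter", 1e5)
  expect_true(all(jit %in% seq(100L, 700L, by = 20L)))
  expect_true(all(jit %% 20 == 0))
  expect_lt(abs(mean(jit) - 400), 3)  # grid mean 400, SE ~ 0.57
  expect_error(make_isi_schedule("banana", 5))
  expect_error(make_isi_schedule("fixed", 0), ">= 1")
})

test_that("same seed reproduces sequences bit-identically", {
  m <- markov_model(0.8)
  set.seed(99); a <- replicate(20, generate_trial(m), simplify = FALSE)
  set.seed(99); b <- replicate(20, generate_trial(m), simplify = FALSE)
  expect_identical(a, b)
})

test_that("model serialization round-trips exactly", {
  m <- markov_model(2 / 3)
  path <- tempfile(fileext = ".txt")
  write_markov_model(m, path)
  m2 <- read_markov_model(path)
  expect_identical(m2$transitions, m$transitions)
  expect_identical(m2$p_high, m$p_high)
  expect_identical(m2$symbols, m$symbols)
})
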