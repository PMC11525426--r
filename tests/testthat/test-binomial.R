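test_that("marginal likelihoods match the hand-computable cases", {
  h0 <- point_hypothesis(1 / 2)
  h1 <- beta_hypothesis(1, 1)
  hr <- beta_hypothesis(1, 1, lower = 0.5, label = "Hr")

  expect_equal(binom_marginal(h0, 2, 0:2), c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(binom_marginal(h1, 2, 0:2), rep(1 / 3, 3))
  expect_equal(binom_marginal(hr, 1, 1), 0.75)

  # empty experiment: the only outcome is certain under any hypothesis
  for (hyp in list(h0, h1, hr, point_hypothesis(1))) {
    expect_equal(binom_marginal(hyp, 0, 0), 1)
  }
})

test_that("beta and truncated-beta marginals agree with numeric integration", {
  cases <- list(
    list(a = 1, b = 1, lower = 0, upper = 1, n = 7, k = 3),
    list(a = 2.5, b = 0.7, lower = 0, upper = 1, n = 11, k = 11),
    list(a = 1, b = 1, lower = 0.5, upper = 1, n = 6, k = 2),
    list(a = 3, b = 2, lower = 0.2, upper = 0.9, n = 9, k = 5)
  )
  for (cs in cases) {
    hyp <- beta_hypothesis(cs$a, cs$b, cs$lower, cs$upper)
    expect_equal(
      binom_marginal(hyp, cs$n, cs$k),
      oracle_beta_marginal(cs$n, cs$k, cs$a, cs$b, cs$lower, cs$upper),
      tolerance = 1e-9
    )
  }
})

test_that("marginal probabilities sum to one over all outcomes", {
  hyps <- list(
    point_hypothesis(1 / 2), point_hypothesis(0), point_hypothesis(1),
    beta_hypothesis(1, 1), beta_hypothesis(0.5, 0.5),
    beta_hypothesis(3, 7),
    beta_hypothesis(1, 1, lower = 0.5),
    beta_hypothesis(2, 2, lower = 0.1, upper = 0.6)
  )
  for (hyp in hyps) {
    for (n in c(1, 5, 17, 50, 200)) {
      expect_equal(sum(binom_marginal(hyp, n, 0:n)), 1, tolerance = 1e-12)
    }
  }
})

test_that("truncation to the full unit interval is a no-op", {
  plain <- beta_hypothesis(2.2, 3.3)
  trunc <- beta_hypothesis(2.2, 3.3, lower = 0, upper = 1)
  for (n in c(1, 10, 100)) {
    expect_equal(binom_marginal(trunc, n, 0:n), binom_marginal(plain, n, 0:n),
                 tolerance = 1e-12)
  }
})

test_that("hypothesis constructors reject invalid parameters", {
  expect_error(point_hypothesis(1.2), "probability")
  expect_error(beta_hypothesis(0, 1), "positive")
  expect_error(beta_hypothesis(1, 1, lower = 0.7, upper = 0.7), "lower < upper")
  expect_error(binom_marginal(point_hypothesis(0.5), 5, 6), "0 <= k <= n")
})

test_that("Bayes factors reproduce the worked ratios and signal degeneracy", {
  h0 <- point_hypothesis(1 / 2)
  h1 <- beta_hypothesis(1, 1)
  hr <- beta_hypothesis(1, 1, lower = 0.5, label = "Hr")

  expect_equal(binom_bf(h0, h1, 2, 1), 1.5)
  expect_equal(binom_bf(h1, h0, 2, 2), 4 / 3)
  # closed form: I(0.5; 11, 1) = 0.5^11
  expect_equal(binom_bf(hr, h1, 10, 10), 2 * (1 - 0.5^11), tolerance = 1e-12)

  # zero denominator marginal with positive numerator: undefined signal
  expect_identical(binom_bf(h1, point_hypothesis(1), 2, 1), Inf)
  # impossible under both hypotheses: an error, not a value
  expect_error(binom_bf(point_hypothesis(0), point_hypothesis(1), 2, 1),
               "zero probability under both")
})

test_that("exact enumeration reproduces both moment identities", {
  h0 <- point_hypothesis(1 / 2)
  h1 <- beta_hypothesis(1, 1)
  hr <- beta_hypothesis(1, 1, lower = 0.5, label = "Hr")

  expect_equal(exact_bf_moment(h0, h1, true_hyp = h1, n = 2), 1)
  expect_equal(exact_bf_moment(h1, h0, true_hyp = h0, n = 2, order = 2),
               10 / 9, tolerance = 1e-12)

  # expected BF in favor of the false hypothesis is 1 for shared support
  pairs <- list(list(h0, h1), list(hr, h1), list(h0, hr),
                list(beta_hypothesis(2, 5), h1))
  for (p in pairs) {
    for (n in c(1, 2, 5, 10, 25, 50)) {
      expect_equal(exact_bf_moment(p[[1]], p[[2]], true_hyp = p[[2]], n = n),
                   1, tolerance = 1e-10)
      expect_equal(exact_bf_moment(p[[2]], p[[1]], true_hyp = p[[1]], n = n),
                   1, tolerance = 1e-10)
    }
  }

  # k-th moment under the numerator's truth = (k+1)-st under the rival
  for (p in pairs) {
    for (order in 0:3) {
      expect_equal(
        exact_bf_moment(p[[1]], p[[2]], true_hyp = p[[1]], n = 12,
                        order = order),
        exact_bf_moment(p[[1]], p[[2]], true_hyp = p[[2]], n = 12,
                        order = order + 1),
        tolerance = 1e-10
      )
    }
  }
})

test_that("broken support breaks the unit-mean identity and warns", {
  h1 <- beta_hypothesis(1, 1)
  always <- point_hypothesis(1)
  expect_warning(
    m <- exact_bf_moment(h1, always, true_hyp = always, n = 2),
    "shared-support"
  )
  expect_equal(m, 1 / 3) # only k = 2 carries mass under theta = 1
})

test_that("directional-over-encompassing BF is nondecreasing in k", {
  hr <- beta_hypothesis(1, 1, lower = 0.5, label = "Hr")
  he <- beta_hypothesis(1, 1, label = "He")
  n <- 10
  bf <- binom_marginal(hr, n, 0:n) / binom_marginal(he, n, 0:n)
  expect_true(all(diff(bf) >= -1e-14))
})

test_that("prior-predictive simulation is seeded and matches its marginal", {
  expect_identical(as.integer(simulate_binomial(point_hypothesis(1), 5, 3,
                                                seed = 1)),
                   c(5L, 5L, 5L))
  a <- simulate_binomial(beta_hypothesis(1, 1), 10, 50, seed = 99)
  b <- simulate_binomial(beta_hypothesis(1, 1), 10, 50, seed = 99)
  expect_identical(a, b)

  # empirical outcome frequencies track the enumerated marginal
  m <- 100000
  for (hyp in list(beta_hypothesis(1, 1),
                   beta_hypothesis(1, 1, lower = 0.5, label = "Hr"))) {
    k <- simulate_binomial(hyp, 2, m, seed = 7)
    p <- binom_marginal(hyp, 2, 0:2)
    freq <- tabulate(k + 1L, 3L) / m
    se <- sqrt(p * (1 - p) / m)
    expect_true(all(abs(freq - p) <= 4 * se))
  }
})

test_that("support overlap diagnostics flag one-sided zeros", {
  full <- support_overlap_check(point_hypothesis(1 / 2),
                                beta_hypothesis(1, 1), n = 10)
  expect_true(full$pass)
  expect_length(full$zero_a_positive_b, 0)

  broken <- support_overlap_check(point_hypothesis(1),
                                  beta_hypothesis(1, 1), n = 2)
  expect_false(broken$pass)
  expect_identical(broken$zero_a_positive_b, 0:1)

  trunc <- support_overlap_check(beta_hypothesis(1, 1),
                                 beta_hypothesis(1, 1, lower = 0.5), n = 5)
  expect_true(trunc$pass)
})
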