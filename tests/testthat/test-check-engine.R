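# A tiny deterministic model pair exercising the user-supplied-BF contract:
# datasets are integers, the BF procedure maps them through a fixed table.
toy_pair <- function(bf_values, specific = "S", general = "G") {
  model_pair(
    specific_label = specific, general_label = general,
    bf_specific_over_general = function(d) bf_values[[d]],
    sampler_specific = function(m, seed) as.list(rep_len(seq_along(bf_values), m)),
    sampler_general = function(m, seed) as.list(rep_len(seq_along(bf_values), m)),
    support_ok = TRUE
  )
}

test_that("undefined values are recoded per policy", {
  expect_equal(recode_undefined(c(2, Inf, 5)), c(2, 6, 5))
  expect_equal(recode_undefined(c(2, 5)), c(2, 5))
  expect_equal(recode_undefined(c(NaN, Inf, 3), policy = "drop"), 3)
  # all-undefined under drop yields an empty set; the error is downstream
  expect_length(recode_undefined(c(NaN, Inf), policy = "drop"), 0)
  expect_length(recode_undefined(c(Inf, 2), "drop"), 1)
  expect_error(recode_undefined(c(1, Inf), policy = "fail"), "undefined")
  expect_error(recode_undefined(c(Inf, NaN)), "nothing finite")
})

test_that("cumulative means run and close on the overall mean", {
  expect_equal(cumulative_mean(c(1, 3)), c(1, 2))
  expect_equal(cumulative_mean(rep(4.2, 7)), rep(4.2, 7))
  set.seed(1)
  v <- rexp(1000)
  cm <- cumulative_mean(v)
  expect_equal(cm[length(cm)], raw_moment(v, 1)$estimate)
  expect_error(cumulative_mean(numeric(0)), "nonempty")
})

test_that("raw moments and the mean-variance identity agree", {
  expect_equal(raw_moment(c(1, 2, 3), 1)$estimate, 2)
  expect_equal(raw_moment(c(1, 2, 3), 2)$estimate, 14 / 3)
  # asymmetry of the BF scale: the mean of 1/10 and 10 is 5.05, not 1
  expect_equal(raw_moment(c(0.1, 10), 1)$estimate, 5.05)

  set.seed(2)
  v <- rlnorm(500)
  pop_var <- mean((v - mean(v))^2)
  expect_equal(second_moment_from_mean_var(mean(v), pop_var),
               raw_moment(v, 2)$estimate)
  expect_equal(second_moment_from_mean_var(0, 0), 0)
  expect_error(second_moment_from_mean_var(1, -0.1), "nonnegative")
})

test_that("batches are reproducible and orientation inverts values exactly", {
  pair <- default_binom_pair(10)
  s1 <- run_bf_batch(pair, "H1", favor = "H0", m = 2, seed = 4)
  s2 <- run_bf_batch(pair, "H1", favor = "H0", m = 2, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1$values, 2)

  s0 <- run_bf_batch(pair, "H1", favor = "H0", m = 500, seed = 8)
  s0r <- run_bf_batch(pair, "H1", favor = "H1", m = 500, seed = 8)
  expect_equal(s0r$values, 1 / s0$values)
  expect_error(run_bf_batch(pair, "H2", "H0", m = 10, seed = 1), "labels")
  expect_error(run_bf_batch(pair, "H1", "H0", m = 1, seed = 1), ">= 2")
})

test_that("batch bookkeeping accounts for undefined and failed replicates", {
  pair <- toy_pair(list(2, Inf, 5, NA_real_))
  s <- run_bf_batch(pair, "G", favor = "S", m = 8, seed = 1)
  expect_equal(s$undefined_count, 2)
  expect_equal(s$failed_count, 2)
  expect_length(s$values, 6)
  expect_equal(sort(unique(s$values)), c(2, 5, 6))
  expect_equal(nrow(s$draws), 8)
  expect_equal(sum(s$draws$was_undefined), 2)
  expect_equal(sum(s$draws$was_failed), 2)

  # reciprocal orientation turns an exact zero into an undefined marker too
  pair0 <- toy_pair(list(0.5, 0))
  sflip <- run_bf_batch(pair0, "S", favor = "G", m = 4, seed = 1)
  expect_equal(sflip$undefined_count, 2)
  expect_equal(sort(unique(sflip$values)), c(2, 3))
})

test_that("batch moment estimates converge to the enumeration oracle", {
  h0 <- point_hypothesis(1 / 2)
  h1 <- beta_hypothesis(1, 1)
  for (n in c(10, 20)) {
    pair <- binom_model_pair(h0, h1, n = n)
    s <- run_bf_batch(pair, "H1", favor = "H0", m = 20000, seed = 13)
    for (order in 1:2) {
      exact <- exact_bf_moment(h0, h1, true_hyp = h1, n = n, order = order)
      mom <- raw_moment(s, order)
      expect_lt(abs(mom$estimate - exact), 4 * mom$mc_se)
    }
  }
})

test_that("Turing verdict enforces orientation and tolerances", {
  pair <- toy_pair(list(1, 1))
  s <- run_bf_batch(pair, "G", favor = "S", m = 2, seed = 1)
  chk <- theorem1_check(s)
  expect_equal(chk$verdict, "pass")
  expect_equal(chk$mc_se, 0)
  expect_false(chk$heavy_tail_caution)

  wrong <- run_bf_batch(pair, "G", favor = "G", m = 2, seed = 1)
  expect_error(theorem1_check(wrong), "favors the generating")

  off <- run_bf_batch(toy_pair(list(2, 2)), "G", favor = "S", m = 4, seed = 1)
  expect_equal(theorem1_check(off)$verdict, "fail")
})

test_that("Good verdict compares moments across generating hypotheses", {
  ones <- toy_pair(list(1, 1))
  s_spec <- run_bf_batch(ones, "S", favor = "S", m = 4, seed = 1)
  s_gen <- run_bf_batch(ones, "G", favor = "S", m = 4, seed = 2)
  chk <- theorem2_check(s_spec, s_gen)
  expect_equal(chk$verdict, "pass")
  expect_equal(chk$moment_specific_true, 1)
  expect_equal(chk$moment_general_true, 1)
  expect_equal(chk$relative_difference, 0)

  expect_error(theorem2_check(s_gen, s_spec), "generated under the favored")
  expect_error(theorem2_check(s_spec, s_spec), "different models")
})

test_that("the universal bound table flags exceedances", {
  pair <- toy_pair(list(0.5, 0.8, 1))
  s <- run_bf_batch(pair, "G", favor = "S", m = 9, seed = 1)
  tab <- universal_bound_table(s, alphas = c(0.5, 0.1, 1))
  expect_equal(tab$empirical_fraction, c(0, 0, 1 / 3))
  expect_true(all(tab$bound_satisfied))
  expect_error(universal_bound_table(s, alphas = c(0.5, 0)), "0, 1")
  expect_error(universal_bound_table(
    run_bf_batch(pair, "S", favor = "S", m = 4, seed = 1)), "false")
})

test_that("weight of evidence summarizes log Bayes factors", {
  woe <- weight_of_evidence_summary(c(0.1, 10))
  expect_equal(woe$mean_log_bf, 0)
  expect_equal(weight_of_evidence_summary(10)$mean_log_bf, log(10),
               tolerance = 1e-12)

  # in favor of the true hypothesis the expected weight of evidence is >= 0
  pair <- default_binom_pair(100)
  s <- run_bf_batch(pair, "H1", favor = "H1", m = 10000, seed = 23)
  lv <- log(s$values)
  expect_gt(weight_of_evidence_summary(s)$mean_log_bf,
            -4 * sd(lv) / sqrt(length(lv)))
})

test_that("the full check runs end to end and is reproducible", {
  pair <- default_binom_pair(10)
  chk1 <- run_full_check(pair, m = 500, seed = 42)
  chk2 <- run_full_check(pair, m = 500, seed = 42)
  expect_identical(chk1, chk2)
  expect_equal(chk1$theorem1$verdict, "pass")
  expect_equal(unname(chk1$cumulative_means[length(chk1$cumulative_means)]),
               chk1$theorem1$mean)
  expect_s3_class(chk1, "bf_check")

  # observed-data BF is carried through
  chk3 <- run_full_check(pair, observed_data = list(n = 10, k = 8), m = 200,
                         seed = 1)
  expect_equal(chk3$observed_bf,
               binom_bf(point_hypothesis(1 / 2), beta_hypothesis(1, 1), 10, 8))
})

test_that("pairs without shared support are refused unless overridden", {
  pair <- binom_model_pair(point_hypothesis(1), beta_hypothesis(1, 1), n = 2)
  expect_false(pair$support_ok)
  expect_error(run_full_check(pair, m = 100, seed = 1),
               "support diagnostic failed")
  chk <- run_full_check(pair, m = 100, seed = 1, override_support = TRUE,
                        run_theorem2 = FALSE)
  expect_s3_class(chk, "bf_check")
})
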