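#' Pair of rival models for the Turing-Good check
#'
#' Bundles the two hypotheses to be compared, a Bayes factor procedure, and a
#' prior-predictive sampler for each hypothesis. The check engine is generic:
#' any model family can be checked by supplying these contracts, and built-in
#' constructors exist for the binomial ([binom_model_pair()]) and one-way
#' ANOVA ([anova_model_pair()]) families.
#'
#' Contracts: `bf_specific_over_general(data)` returns a single positive
#' number (the Bayes factor for the specific over the general model), where
#' `Inf`, `0` or `NaN` signal an undefined Bayes factor (a zero marginal) and
#' `NA` signals a failed evaluation. `sampler_specific(m, seed)` and
#' `sampler_general(m, seed)` return a list of `m` datasets of the shape the
#' Bayes factor procedure accepts.
#'
#' @param specific_label,general_label Labels of the two models; the
#'   "general" model is the more complex one, recommended for generation.
#' @param bf_specific_over_general Function of one dataset.
#' @param sampler_specific,sampler_general Functions `(m, seed)` returning a
#'   list of datasets.
#' @param support_ok `TRUE`, `FALSE` or `NA`: whether the two models share
#'   support. `FALSE` makes [run_full_check()] refuse to certify Theorem 1.
#' @return An object of class `model_pair`.
#' @export
model_pair <- function(specific_label, general_label,
                       bf_specific_over_general,
                       sampler_specific, sampler_general,
                       support_ok = NA) {
  stopifnot(is.function(bf_specific_over_general),
            is.function(sampler_specific), is.function(sampler_general))
  if (identical(specific_label, general_label)) {
    stop("the two model labels must differ", call. = FALSE)
  }
  structure(
    list(specific_label = specific_label, general_label = general_label,
         bf_specific_over_general = bf_specific_over_general,
         sampler_specific = sampler_specific,
         sampler_general = sampler_general,
         support_ok = support_ok),
    class = "model_pair"
  )
}

#' @export
print.model_pair <- function(x, ...) {
  cat(sprintf("Model pair: %s (specific) vs %s (general); shared support: %s\n",
              x$specific_label, x$general_label,
              ifelse(is.na(x$support_ok), "unknown", x$support_ok)))
  invisible(x)
}

#' Built-in binomial model pair
#'
#' @param specific,general Binomial hypotheses ([point_hypothesis()] or
#'   [beta_hypothesis()]); the specific one is typically the point null.
#' @param n Number of trials per simulated dataset.
#' @return A [model_pair()] whose datasets are lists `list(n, k)` and whose
#'   `support_ok` flag comes from [support_overlap_check()].
#' @examples
#' pair <- binom_model_pair(point_hypothesis(1 / 2), beta_hypothesis(1, 1), n = 10)
#' @export
binom_model_pair <- function(specific, general, n) {
  check_outcome(n, 0)
  support <- support_overlap_check(specific, general, n)
  # closed-form BF looked up from a precomputed table over k = 0..n
  p_s <- binom_marginal(specific, n, 0:n)
  p_g <- binom_marginal(general, n, 0:n)
  bf_tab <- ifelse(p_g == 0 & p_s == 0, NaN, p_s / p_g)
  make_sampler <- function(hyp) {
    force(hyp)
    function(m, seed) {
      k <- simulate_binomial(hyp, n, m, seed)
      lapply(k, function(ki) list(n = n, k = ki))
    }
  }
  model_pair(
    specific_label = specific$label,
    general_label = general$label,
    bf_specific_over_general = function(data) bf_tab[data$k + 1L],
    sampler_specific = make_sampler(specific),
    sampler_general = make_sampler(general),
    support_ok = support$pass
  )
}

#' Built-in one-way ANOVA model pair
#'
#' The specific model is the null of equal group means; the general model is
#' the JZS alternative. Data are generated by [simulate_anova_h0()] and
#' [simulate_anova_h1()] under `cfg`, and the Bayes factor is computed by
#' [jzs_bf10()] under `analysis_prior` (which may deliberately differ from
#' the generation scale `cfg$r_gen` to study misspecified calculations).
#' Failed quadratures are signalled as `NA` per the engine contract.
#'
#' @param cfg An [anova_gen_config()].
#' @param analysis_prior Prior used in the Bayes factor computation; defaults
#'   to the generation scale.
#' @return A [model_pair()] over [anova_data()] datasets.
#' @export
anova_model_pair <- function(cfg = anova_gen_config(),
                             analysis_prior = jzs_prior(cfg$r_gen)) {
  analysis_prior <- as_jzs_prior(analysis_prior)
  model_pair(
    specific_label = "H0",
    general_label = "H1",
    bf_specific_over_general = function(data) {
      tryCatch(
        exp(-log_jzs_bf10_stats(anova_bf_stats(data), analysis_prior$r)),
        error = function(e) NA_real_
      )
    },
    sampler_specific = function(m, seed) simulate_anova_h0(cfg, m, seed),
    sampler_general = function(m, seed) simulate_anova_h1(cfg, m, seed),
    support_ok = TRUE
  )
}

#' Recode undefined Bayes factors in a batch
#'
#' Undefined Bayes factors arise when a marginal likelihood is exactly zero
#' (for example a posterior inclusion probability of 1 gives `1/0`). The
#' default policy replaces each undefined value with one plus the largest
#' observed finite value; `"drop"` removes them; `"fail"` raises an error.
#'
#' @param raw_values Numeric vector; non-finite entries (`Inf`, `NaN`, `NA`)
#'   are treated as undefined markers.
#' @param policy One of `"recode_max_plus_one"`, `"drop"`, `"fail"`.
#' @return Numeric vector of defined values (shorter than the input only
#'   under `"drop"`).
#' @examples
#' recode_undefined(c(2, Inf, 5)) # 2, 6, 5
#' @export
recode_undefined <- function(raw_values,
                             policy = c("recode_max_plus_one", "drop",
                                        "fail")) {
  policy <- match.arg(policy)
  undef <- !is.finite(raw_values)
  if (!any(undef)) {
    return(raw_values)
  }
  if (policy == "fail") {
    stop(sprintf("%d undefined Bayes factor value(s)", sum(undef)),
         call. = FALSE)
  }
  if (policy == "drop") {
    return(raw_values[!undef])
  }
  if (all(undef)) {
    stop("all values undefined: nothing finite to recode from", call. = FALSE)
  }
  raw_values[undef] <- max(raw_values[!undef]) + 1
  raw_values
}

#' Simulate a batch of Bayes factors under one hypothesis
#'
#' Draws `m` datasets from the prior predictive distribution of
#' `generate_under`, evaluates the pair's Bayes factor on each, orients it to
#' favor `favor` (taking reciprocals as needed), excludes failed evaluations,
#' and applies the recode policy to undefined values.
#'
#' @param pair A [model_pair()].
#' @param generate_under,favor Labels of the generating model and of the
#'   model the returned Bayes factors favor.
#' @param m Number of replicates (>= 2).
#' @param seed Integer seed; drawn and recorded if `NULL`.
#' @param recode_policy Passed to [recode_undefined()].
#' @return An object of class `bf_sample_set`: retained `values`, per-replicate
#'   bookkeeping in `draws`, counts of undefined and failed evaluations, the
#'   orientation labels and the seed.
#' @examples
#' pair <- binom_model_pair(point_hypothesis(1 / 2), beta_hypothesis(1, 1), n = 10)
#' s <- run_bf_batch(pair, generate_under = "H1", favor = "H0", m = 500, seed = 7)
#' mean(s$values) # near 1 (Turing identity)
#' @export
run_bf_batch <- function(pair, generate_under, favor, m, seed = NULL,
                         recode_policy = "recode_max_plus_one") {
  stopifnot(inherits(pair, "model_pair"))
  labels <- c(pair$specific_label, pair$general_label)
  if (!generate_under %in% labels || !favor %in% labels) {
    stop("`generate_under` and `favor` must match the pair's labels",
         call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m)) {
    stop("`m` must be a single integer >= 2", call. = FALSE)
  }
  seed <- materialize_seed(seed)
  sampler <- if (generate_under == pair$specific_label) {
    pair$sampler_specific
  } else {
    pair$sampler_general
  }
  datasets <- sampler(m, seed)
  raw <- vapply(datasets, function(d) {
    v <- tryCatch(pair$bf_specific_over_general(d), error = function(e) {
      stop(sprintf("Bayes factor contract violated at replicate: %s",
                   conditionMessage(e)), call. = FALSE)
    })
    as.numeric(v)
  }, numeric(1))
  oriented <- if (favor == pair$specific_label) raw else 1 / raw
  failed <- is.na(raw)
  undefined <- !failed & (!is.finite(oriented) | oriented == 0)
  oriented[undefined] <- NaN
  kept <- oriented[!failed]
  values <- recode_undefined(kept, recode_policy)
  draws <- data.frame(
    replicate = seq_len(m),
    bf = ifelse(failed, NA_real_, oriented),
    was_undefined = undefined,
    was_failed = failed
  )
  if (recode_policy != "drop") {
    draws$bf[!failed] <- values
  }
  if (length(values) == 0) {
    stop("all replicates undefined or failed: empty Bayes factor sample",
         call. = FALSE)
  }
  structure(
    list(values = values, draws = draws,
         undefined_count = sum(undefined), failed_count = sum(failed),
         direction = favor, generated_under = generate_under,
         seed = seed, recode_policy = recode_policy, m = m),
    class = "bf_sample_set"
  )
}

#' @export
print.bf_sample_set <- function(x, ...) {
  cat(sprintf(
    "Bayes factor sample: m = %d favoring %s, generated under %s (seed %d)\n",
    x$m, x$direction, x$generated_under, x$seed))
  cat(sprintf("  retained %d values (undefined: %d, failed: %d); mean = %.4g\n",
              length(x$values), x$undefined_count, x$failed_count,
              mean(x$values)))
  invisible(x)
}

#' Running means of a Bayes factor sequence
#'
#' @param values Nonempty numeric vector.
#' @return Numeric vector whose element `t` is the mean of the first `t`
#'   values; the final element is the overall mean.
#' @examples
#' cumulative_mean(c(1, 3)) # 1, 2
#' @export
cumulative_mean <- function(values) {
  if (length(values) == 0) {
    stop("`values` must be nonempty", call. = FALSE)
  }
  cumsum(values) / seq_along(values)
}

#' Raw moment of a Bayes factor sample with Monte-Carlo standard error
#'
#' @param values Nonempty numeric vector (a [run_bf_batch()] `values` field
#'   or a `bf_sample_set`).
#' @param order Moment order (>= 1); raw moments are about the origin.
#' @return An object of class `moment_report` with fields `order`,
#'   `estimate` (mean of `values^order`), `mc_se` (sample standard deviation
#'   of `values^order` over `sqrt(m)`) and `m_used`.
#' @examples
#' raw_moment(c(1, 2, 3), order = 2)$estimate # 14/3
#' @export
raw_moment <- function(values, order = 1) {
  if (inherits(values, "bf_sample_set")) {
    values <- values$values
  }
  if (length(values) == 0) {
    stop("`values` must be nonempty", call. = FALSE)
  }
  if (!is.numeric(order) || length(order) != 1L || order < 1) {
    stop("`order` must be >= 1", call. = FALSE)
  }
  v <- values^order
  structure(
    list(order = order, estimate = mean(v),
         mc_se = stats::sd(v) / sqrt(length(v)), m_used = length(v)),
    class = "moment_report"
  )
}

#' @export
print.moment_report <- function(x, ...) {
  cat(sprintf("raw moment (order %g): %.6g (mc se %.3g, m = %d)\n",
              x$order, x$estimate, x$mc_se, x$m_used))
  invisible(x)
}

#' Second raw moment from mean and variance
#'
#' Identity `E[X^2] = VAR[X] + E[X]^2`, handy when only summary statistics of
#' a Bayes factor batch are available.
#'
#' @param mean,variance Sample mean and (nonnegative) variance.
#' @return `variance + mean^2`.
#' @export
second_moment_from_mean_var <- function(mean, variance) {
  if (!is.numeric(variance) || variance < 0) {
    stop("`variance` must be nonnegative", call. = FALSE)
  }
  variance + mean^2
}

#' Turing identity verdict: is the mean Bayes factor against the truth 1?
#'
#' The sample must favor the hypothesis the data were *not* generated under.
#' The verdict passes when the sample mean lies within
#' `tolerance_multiplier` Monte-Carlo standard errors of 1. Because the
#' Bayes factor in favor of the false hypothesis is strongly right-skewed, a
#' heavy-tail caution is attached when the sample skewness exceeds
#' `skew_caution` (the standard error estimate itself is then unstable).
#'
#' @param sample A [run_bf_batch()] result.
#' @param tolerance_multiplier Width of the acceptance band in standard
#'   errors (default 3).
#' @param skew_caution Skewness threshold for the caution flag (default 10).
#' @return A list with `mean`, `mc_se`, `m_used`, `verdict` (`"pass"` or
#'   `"fail"`), `tolerance_multiplier` and `heavy_tail_caution`.
#' @export
theorem1_check <- function(sample, tolerance_multiplier = 3,
                           skew_caution = 10) {
  stopifnot(inherits(sample, "bf_sample_set"))
  if (sample$direction == sample$generated_under) {
    stop(paste("sample favors the generating hypothesis; the Turing identity",
               "concerns the Bayes factor in favor of the false hypothesis"),
         call. = FALSE)
  }
  mom <- raw_moment(sample$values, 1)
  pass <- abs(mom$estimate - 1) <= tolerance_multiplier * mom$mc_se
  list(mean = mom$estimate, mc_se = mom$mc_se, m_used = mom$m_used,
       verdict = if (pass) "pass" else "fail",
       tolerance_multiplier = tolerance_multiplier,
       heavy_tail_caution = sample_skewness(sample$values) > skew_caution)
}

#' Good identity verdict: do raw moments match across hypotheses?
#'
#' Compares the order-`order_low` raw moment of the Bayes factors favoring
#' the specific model computed on data where the specific model is true
#' against the order-`order_low + 1` raw moment computed on data where the
#' general model is true. Under a correct implementation the two estimate the
#' same number; the verdict passes when they agree within
#' `tolerance_multiplier` combined (root-sum-square) standard errors.
#'
#' @param sample_specific_true,sample_general_true [run_bf_batch()] results,
#'   both favoring the specific model, generated under different models.
#' @param order_low Lower moment order (default 1).
#' @param tolerance_multiplier Width of the acceptance band (default 3).
#' @return A list with both moment estimates, their standard errors, the
#'   `relative_difference`, and the `verdict`.
#' @export
theorem2_check <- function(sample_specific_true, sample_general_true,
                           order_low = 1, tolerance_multiplier = 3) {
  stopifnot(inherits(sample_specific_true, "bf_sample_set"),
            inherits(sample_general_true, "bf_sample_set"))
  if (sample_specific_true$direction != sample_general_true$direction) {
    stop("both samples must favor the same (specific) hypothesis",
         call. = FALSE)
  }
  if (sample_specific_true$direction != sample_specific_true$generated_under) {
    stop("`sample_specific_true` must be generated under the favored model",
         call. = FALSE)
  }
  if (sample_general_true$generated_under ==
      sample_specific_true$generated_under) {
    stop("the two samples must be generated under different models",
         call. = FALSE)
  }
  m_low <- raw_moment(sample_specific_true$values, order_low)
  m_high <- raw_moment(sample_general_true$values, order_low + 1)
  diff <- m_low$estimate - m_high$estimate
  se <- sqrt(m_low$mc_se^2 + m_high$mc_se^2)
  denom <- max(abs(m_low$estimate), abs(m_high$estimate))
  list(
    order_low = order_low,
    moment_specific_true = m_low$estimate, mc_se_specific = m_low$mc_se,
    moment_general_true = m_high$estimate, mc_se_general = m_high$mc_se,
    relative_difference = if (denom > 0) abs(diff) / denom else 0,
    tolerance_multiplier = tolerance_multiplier,
    verdict = if (abs(diff) <= tolerance_multiplier * se) "pass" else "fail"
  )
}

#' Universal bound diagnostic
#'
#' A consequence of the Turing identity and Markov's inequality: the
#' probability of a Bayes factor of at least `1/alpha` in favor of the false
#' hypothesis is at most `alpha` (e.g. a BF of 100 against the truth occurs
#' with probability at most 1%). Reports the empirical exceedance fraction
#' for each `alpha`.
#'
#' @param sample A [run_bf_batch()] result favoring the non-generating
#'   hypothesis.
#' @param alphas Probabilities in (0, 1].
#' @return A data.frame with columns `alpha`, `threshold`,
#'   `empirical_fraction` and `bound_satisfied`.
#' @export
universal_bound_table <- function(sample,
                                  alphas = c(0.2, 0.1, 0.05, 0.01)) {
  stopifnot(inherits(sample, "bf_sample_set"))
  if (any(alphas <= 0 | alphas > 1)) {
    stop("`alphas` must lie in (0, 1]", call. = FALSE)
  }
  if (sample$direction == sample$generated_under) {
    stop("the universal bound concerns Bayes factors favoring the false",
         " hypothesis", call. = FALSE)
  }
  frac <- vapply(alphas, function(a) mean(sample$values >= 1 / a), numeric(1))
  data.frame(alpha = alphas, threshold = 1 / alphas,
             empirical_fraction = frac, bound_satisfied = frac <= alphas)
}

#' Weight-of-evidence summary of a Bayes factor sample
#'
#' The weight of evidence is the log Bayes factor: additive, symmetric, and
#' approximately normal where the Bayes factor itself is approximately
#' log-normal. Reports the mean and standard deviation of the log values and
#' the skewness of the raw values as a log-normality diagnostic.
#'
#' @param sample A [run_bf_batch()] result or a positive numeric vector.
#' @return A list with `mean_log_bf`, `sd_log_bf`, `skewness_bf`.
#' @examples
#' weight_of_evidence_summary(c(0.1, 10))$mean_log_bf # 0
#' @export
weight_of_evidence_summary <- function(sample) {
  values <- if (inherits(sample, "bf_sample_set")) sample$values else sample
  if (length(values) == 0) {
    stop("empty sample", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("values must be positive", call. = FALSE)
  }
  lv <- log(values)
  list(mean_log_bf = mean(lv),
       sd_log_bf = if (length(lv) > 1) stats::sd(lv) else 0,
       skewness_bf = sample_skewness(values))
}

#' Run the full six-step Turing-Good Bayes factor check
#'
#' The complete workflow: (1) compute the observed-data Bayes factor if data
#' are supplied; (2) simulate `m` datasets under the general model and test
#' that the mean Bayes factor favoring the specific model is 1 (Turing);
#' (3) optionally simulate under the specific model and compare first and
#' second raw moments across the two batches (Good); (4) attach cumulative
#' means, the universal-bound table and a weight-of-evidence summary.
#'
#' Generation defaults to the more complex (general) model: when the
#' specific model generates, rare outcomes with extreme Bayes factors make
#' convergence of the mean extremely slow.
#'
#' @param pair A [model_pair()]; if its `support_ok` flag is `FALSE` the
#'   check is refused unless `override_support = TRUE`.
#' @param observed_data Optional dataset for the step-2 observed Bayes
#'   factor.
#' @param m Number of replicates per batch (>= 100 recommended).
#' @param seed Master seed; split deterministically into per-batch streams.
#' @param run_theorem2 Also run the reverse batch and the moment comparison
#'   (default `TRUE`).
#' @param recode_policy Passed to [run_bf_batch()].
#' @param tolerance_multiplier Acceptance band width for both verdicts.
#' @param override_support Proceed despite a failed support diagnostic.
#' @return An object of class `bf_check` with components `observed_bf`,
#'   `theorem1`, `theorem2` (or `NULL`), `cumulative_means`,
#'   `universal_bound`, `woe`, the two `bf_sample_set`s, `seed` and `m`.
#' @examples
#' pair <- binom_model_pair(point_hypothesis(1 / 2), beta_hypothesis(1, 1), n = 10)
#' chk <- run_full_check(pair, m = 400, seed = 11)
#' chk$theorem1$verdict
#' @export
run_full_check <- function(pair, observed_data = NULL, m = 10000,
                           seed = NULL, run_theorem2 = TRUE,
                           recode_policy = "recode_max_plus_one",
                           tolerance_multiplier = 3,
                           override_support = FALSE) {
  stopifnot(inherits(pair, "model_pair"))
  if (isFALSE(pair$support_ok) && !override_support) {
    stop(paste0(
      "support diagnostic failed: the two models do not assign positive ",
      "probability to the same outcomes, so the expected Bayes factor in ",
      "favor of the false hypothesis need not be 1. Fix the hypotheses or ",
      "pass override_support = TRUE to proceed without the guarantee."
    ), call. = FALSE)
  }
  seed <- materialize_seed(seed)
  seeds <- derive_seeds(seed, 2L)

  observed_bf <- if (!is.null(observed_data)) {
    as.numeric(pair$bf_specific_over_general(observed_data))
  } else {
    NULL
  }

  sample_general <- run_bf_batch(pair, generate_under = pair$general_label,
                                 favor = pair$specific_label, m = m,
                                 seed = seeds[1], recode_policy = recode_policy)
  th1 <- theorem1_check(sample_general, tolerance_multiplier)

  th2 <- NULL
  sample_specific <- NULL
  if (isTRUE(run_theorem2)) {
    sample_specific <- run_bf_batch(pair,
                                    generate_under = pair$specific_label,
                                    favor = pair$specific_label, m = m,
                                    seed = seeds[2],
                                    recode_policy = recode_policy)
    th2 <- theorem2_check(sample_specific, sample_general,
                          order_low = 1,
                          tolerance_multiplier = tolerance_multiplier)
  }

  structure(
    list(
      pair_labels = c(specific = pair$specific_label,
                      general = pair$general_label),
      observed_bf = observed_bf,
      theorem1 = th1,
      theorem2 = th2,
      cumulative_means = cumulative_mean(sample_general$values),
      universal_bound = universal_bound_table(sample_general),
      woe = weight_of_evidence_summary(sample_general),
      sample_general_true = sample_general,
      sample_specific_true = sample_specific,
      seed = seed, m = m
    ),
    class = "bf_check"
  )
}

#' @export
print.bf_check <- function(x, ...) {
  cat("Turing-Good Bayes factor check\n")
  cat(sprintf("  models: %s (specific) vs %s (general); m = %d, seed = %d\n",
              x$pair_labels["specific"], x$pair_labels["general"], x$m,
              x$seed))
  if (!is.null(x$observed_bf)) {
    cat(sprintf("  observed-data BF (%s over %s): %.4g\n",
                x$pair_labels["specific"], x$pair_labels["general"],
                x$observed_bf))
  }
  cat(sprintf(
    "  Theorem 1: mean BF[%s] under %s = %.4f (mc se %.4f) -> %s%s\n",
    x$pair_labels["specific"], x$pair_labels["general"], x$theorem1$mean,
    x$theorem1$mc_se, x$theorem1$verdict,
    if (x$theorem1$heavy_tail_caution) " [heavy-tail caution]" else ""))
  if (!is.null(x$theorem2)) {
    cat(sprintf(
      "  Theorem 2: E[BF | specific true] = %.4f vs E[BF^2 | general true] = %.4f -> %s\n",
      x$theorem2$moment_specific_true, x$theorem2$moment_general_true,
      x$theorem2$verdict))
  }
  invisible(x)
}

#' @export
summary.bf_check <- function(object, ...) {
  print(object)
  cat("  universal bound:\n")
  ub <- object$universal_bound
  for (i in seq_len(nrow(ub))) {
    cat(sprintf("    P(BF >= %g) = %.4f (bound %.2f: %s)\n",
                ub$threshold[i], ub$empirical_fraction[i], ub$alpha[i],
                ifelse(ub$bound_satisfied[i], "ok", "exceeded")))
  }
  cat(sprintf(
    "  weight of evidence: mean log BF = %.4f, sd = %.4f, BF skewness = %.2f\n",
    object$woe$mean_log_bf, object$woe$sd_log_bf, object$woe$skewness_bf))
  invisible(object)
}

#' Plot the cumulative mean Bayes factor of a check
#'
#' Displays the running mean of the Bayes factors in favor of the specific
#' model across simulated datasets, with the reference line at 1 that the
#' Turing identity predicts for a correct implementation.
#'
#' @param x A `bf_check` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bf_check <- function(x, ...) {
  cm <- x$cumulative_means
  graphics::plot(seq_along(cm), cm, type = "l",
                 xlab = "number of simulated data sets m",
                 ylab = sprintf("mean BF[%s] (generated under %s)",
                                x$pair_labels["specific"],
                                x$pair_labels["general"]),
                 ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}
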