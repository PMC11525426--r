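#' Marginal likelihood of a binomial outcome under a hypothesis
#'
#' Computes `p(k | hypothesis)` for `k` successes in `n` trials. For a point
#' hypothesis this is the binomial pmf (with the `0^0 = 1` convention at
#' `theta0` in `{0, 1}`). For a beta hypothesis it is the beta-binomial
#' marginal `C(n,k) B(k+a, n-k+b) / B(a,b)`; for a truncated beta prior the
#' incomplete-beta mass of the truncation interval enters both the numerator
#' (with updated shapes) and the normalizing constant.
#'
#' @param hyp A [point_hypothesis()] or [beta_hypothesis()].
#' @param n Number of trials (single nonnegative integer).
#' @param k Number of successes; may be a vector.
#' @return Numeric vector of probabilities, same length as `k`.
#' @examples
#' binom_marginal(point_hypothesis(1 / 2), n = 2, k = 0:2) # 1/4, 1/2, 1/4
#' binom_marginal(beta_hypothesis(1, 1), n = 2, k = 0:2) # 1/3 each
#' @export
binom_marginal <- function(hyp, n, k) {
  UseMethod("binom_marginal")
}

#' @export
binom_marginal.binom_point_hypothesis <- function(hyp, n, k) {
  check_outcome(n, k)
  stats::dbinom(k, n, hyp$theta0)
}

#' @export
binom_marginal.binom_beta_hypothesis <- function(hyp, n, k) {
  check_outcome(n, k)
  a <- hyp$a
  b <- hyp$b
  base <- exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  if (!is_truncated(hyp)) {
    return(pmin(base, 1))
  }
  num_mass <- stats::pbeta(hyp$upper, k + a, n - k + b) -
    stats::pbeta(hyp$lower, k + a, n - k + b)
  den_mass <- stats::pbeta(hyp$upper, a, b) - stats::pbeta(hyp$lower, a, b)
  pmin(base * num_mass / den_mass, 1)
}

#' Bayes factor for a binomial outcome
#'
#' Ratio of the marginal likelihoods of the outcome `(n, k)` under two
#' hypotheses. A zero denominator marginal with a positive numerator marginal
#' yields `Inf`, the undefined-Bayes-factor signal that the check engine's
#' recode policies know how to handle; an outcome impossible under both
#' hypotheses is an error.
#'
#' @param numerator,denominator Hypotheses (see [point_hypothesis()],
#'   [beta_hypothesis()]).
#' @inheritParams binom_marginal
#' @return A single positive number, possibly `Inf` (undefined).
#' @examples
#' h0 <- point_hypothesis(1 / 2)
#' h1 <- beta_hypothesis(1, 1)
#' binom_bf(h0, h1, n = 2, k = 1) # 1.5
#' @export
binom_bf <- function(numerator, denominator, n, k) {
  check_outcome(n, k)
  if (length(k) != 1L) stop("`k` must be a single outcome", call. = FALSE)
  p_num <- binom_marginal(numerator, n, k)
  p_den <- binom_marginal(denominator, n, k)
  if (p_den == 0 && p_num == 0) {
    stop("outcome has zero probability under both hypotheses", call. = FALSE)
  }
  if (p_den == 0) {
    return(Inf)
  }
  p_num / p_den
}

#' Prior-predictive simulation of binomial success counts
#'
#' Draws `m` replicate success counts for an experiment with `n` trials:
#' for each replicate the success probability is drawn from the hypothesis
#' prior (degenerate at `theta0` for a point hypothesis; inverse-CDF sampling
#' restricted to the truncation interval for beta hypotheses) and the count
#' from the binomial likelihood.
#'
#' @inheritParams binom_marginal
#' @param m Number of replicates.
#' @param seed Integer seed; if `NULL` one is drawn and recorded in the
#'   `"seed"` attribute of the result.
#' @return Integer vector of `m` success counts with attribute `seed`.
#' @examples
#' k <- simulate_binomial(beta_hypothesis(1, 1), n = 10, m = 5, seed = 1)
#' @export
simulate_binomial <- function(hyp, n, m, seed = NULL) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  check_outcome(n, 0)
  seed <- materialize_seed(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  if (inherits(hyp, "binom_point_hypothesis")) {
    theta <- rep_len(hyp$theta0, m)
  } else {
    lo <- stats::pbeta(hyp$lower, hyp$a, hyp$b)
    hi <- stats::pbeta(hyp$upper, hyp$a, hyp$b)
    u <- stats::runif(m, lo, hi)
    theta <- stats::qbeta(u, hyp$a, hyp$b)
  }
  k <- stats::rbinom(m, n, theta)
  attr(k, "seed") <- seed
  k
}

#' Exact raw moment of a binomial Bayes factor by outcome enumeration
#'
#' Computes `E[BF^order | true_hyp]` exactly by summing
#' `(p(k|num)/p(k|den))^order * p(k|true)` over all outcomes `k = 0..n`.
#' This is the enumeration oracle behind both moment identities: with
#' `order = 1` and the numerator set to the false hypothesis the result is 1
#' whenever the two hypotheses share full support (Turing's identity), and
#' `E[BF^k | num] = E[BF^(k+1) | den]` for any order (Good's identity).
#'
#' Outcomes with zero probability under the true hypothesis contribute
#' nothing; if such an outcome has positive probability under the rival
#' hypothesis a support warning is emitted, since the identities are then
#' not guaranteed (see [support_overlap_check()]).
#'
#' @inheritParams binom_bf
#' @param true_hyp The hypothesis the data are generated under; must be one
#'   of `numerator` or `denominator`.
#' @param order Positive integer moment order.
#' @return A single nonnegative number.
#' @examples
#' h0 <- point_hypothesis(1 / 2)
#' h1 <- beta_hypothesis(1, 1)
#' exact_bf_moment(h0, h1, true_hyp = h1, n = 2) # exactly 1
#' exact_bf_moment(h1, h0, true_hyp = h0, n = 2, order = 2) # 10/9
#' @export
exact_bf_moment <- function(numerator, denominator, true_hyp, n, order = 1) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != round(order)) {
    stop("`order` must be a single nonnegative integer", call. = FALSE)
  }
  if (!identical(true_hyp, numerator) && !identical(true_hyp, denominator)) {
    stop("`true_hyp` must be one of the two compared hypotheses",
         call. = FALSE)
  }
  check_outcome(n, 0)
  if (n > 10000) {
    stop("enumeration supports n up to 10,000", call. = FALSE)
  }
  k <- 0:n
  p_num <- binom_marginal(numerator, n, k)
  p_den <- binom_marginal(denominator, n, k)
  p_true <- binom_marginal(true_hyp, n, k)
  p_false <- if (identical(true_hyp, numerator)) p_den else p_num
  skipped <- p_true == 0
  if (any(skipped & p_false > 0)) {
    warning(paste(
      "outcomes with zero probability under the true hypothesis carry",
      "positive probability under the rival; the moment identities are not",
      "guaranteed (shared-support requirement violated)"
    ), call. = FALSE)
  }
  keep <- !skipped
  # log-space ratio avoids overflow of BF^order for extreme outcomes
  log_ratio <- log(p_num[keep]) - log(p_den[keep])
  sum(exp(order * log_ratio + log(p_true[keep])))
}

#' Shared-support diagnostic for a pair of binomial hypotheses
#'
#' The moment identities require both hypotheses to assign positive
#' probability to the same outcomes. This check lists, in each direction,
#' outcomes where one hypothesis has zero marginal probability while the
#' other is positive (e.g. the universal generalization `theta = 1` assigns
#' zero mass to every `k < n`).
#'
#' @inheritParams binom_bf
#' @param hyp_a,hyp_b Hypotheses to compare.
#' @return An object of class `support_report`: a list with the offending
#'   outcome vectors `zero_a_positive_b`, `zero_b_positive_a` and a logical
#'   `pass` (TRUE iff both are empty).
#' @examples
#' support_overlap_check(point_hypothesis(1), beta_hypothesis(1, 1), n = 2)
#' @export
support_overlap_check <- function(hyp_a, hyp_b, n) {
  check_outcome(n, 0)
  k <- 0:n
  p_a <- binom_marginal(hyp_a, n, k)
  p_b <- binom_marginal(hyp_b, n, k)
  zero_a <- k[p_a == 0 & p_b > 0]
  zero_b <- k[p_b == 0 & p_a > 0]
  structure(
    list(
      label_a = hyp_a$label, label_b = hyp_b$label, n = n,
      zero_a_positive_b = zero_a, zero_b_positive_a = zero_b,
      pass = length(zero_a) == 0 && length(zero_b) == 0
    ),
    class = "support_report"
  )
}

#' @export
print.support_report <- function(x, ...) {
  cat(sprintf("Support overlap check (%s vs %s, n = %d): %s\n",
              x$label_a, x$label_b, x$n, if (x$pass) "pass" else "FAIL"))
  if (length(x$zero_a_positive_b)) {
    cat(sprintf("  zero under %s, positive under %s: k = %s\n", x$label_a,
                x$label_b, paste(x$zero_a_positive_b, collapse = ", ")))
  }
  if (length(x$zero_b_positive_a)) {
    cat(sprintf("  zero under %s, positive under %s: k = %s\n", x$label_b,
                x$label_a, paste(x$zero_b_positive_a, collapse = ", ")))
  }
  invisible(x)
}
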