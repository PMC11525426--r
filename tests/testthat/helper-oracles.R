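# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: marginals by numerical integration of the
# binomial likelihood against the prior density, and the ANOVA Bayes factor
# by brute-force nested integration over intercept, effect and log-variance.

oracle_beta_marginal <- function(n, k, a, b, lower = 0, upper = 1) {
  dens_mass <- stats::pbeta(upper, a, b) - stats::pbeta(lower, a, b)
  f <- function(theta) {
    stats::dbinom(k, n, theta) * stats::dbeta(theta, a, b) / dens_mass
  }
  stats::integrate(f, lower, upper, rel.tol = 1e-12)$value
}

# Brute-force conditional BF10 for a two-group design: numerator and
# denominator marginals are computed by integrating the Gaussian likelihood
# over the intercept, the single sum-to-zero effect (prior N(0, g*sigma2))
# and log(sigma2) under the Jeffreys 1/sigma2 prior. Integration bounds
# follow the likelihood spikes (widths scale with sigma) so the adaptive
# rule never loses them.
oracle_conditional_bf10_2group <- function(y, group, g) {
  x <- bfcheck::effect_design(group)[, 1]
  n <- length(y)
  loglik <- function(alpha, beta, s) {
    sum(stats::dnorm(y, alpha + beta * x, sqrt(exp(s)), log = TRUE))
  }
  inner_alpha <- function(beta, s) {
    a_hat <- mean(y - beta * x)
    a_sd <- sqrt(exp(s) / n)
    stats::integrate(
      Vectorize(function(a) exp(loglik(a, beta, s))),
      a_hat - 40 * a_sd, a_hat + 40 * a_sd, rel.tol = 1e-9
    )$value
  }
  s_lo <- log(stats::var(y)) - 14
  s_hi <- log(stats::var(y)) + 10
  m1 <- stats::integrate(Vectorize(function(s) {
    b_hat <- sum(x * y) / sum(x^2)
    b_sd <- max(sqrt(exp(s) / sum(x^2)), sqrt(g * exp(s)))
    stats::integrate(
      Vectorize(function(beta) {
        inner_alpha(beta, s) * stats::dnorm(beta, 0, sqrt(g * exp(s)))
      }),
      min(b_hat, 0) - 40 * b_sd, max(b_hat, 0) + 40 * b_sd, rel.tol = 1e-9
    )$value # Jeffreys 1/sigma2 times jacobian d(sigma2)/ds cancel
  }), s_lo, s_hi, rel.tol = 1e-9)$value
  m0 <- stats::integrate(Vectorize(function(s) {
    inner_alpha(0, s)
  }), s_lo, s_hi, rel.tol = 1e-9)$value
  m1 / m0
}

default_binom_pair <- function(n) {
  binom_model_pair(point_hypothesis(1 / 2), beta_hypothesis(1, 1), n = n)
}
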