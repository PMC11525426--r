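#' Grouped Gaussian data for the one-way ANOVA Bayes factor
#'
#' Light container for a response vector and a grouping factor. The model
#' behind [jzs_bf10()] is `y_i = alpha + effect(group_i) + eps_i` with
#' `eps_i ~ N(0, sigma^2)`; the intercept and error variance carry Jeffreys
#' priors and are integrated out analytically, so the Bayes factor depends on
#' the data only through scale-free quadratic forms.
#'
#' @param y Numeric response vector.
#' @param group Group labels (coerced to factor) of the same length as `y`.
#' @return An object of class `anova_data`.
#' @examples
#' d <- anova_data(rnorm(12), rep(letters[1:3], each = 4))
#' @export
anova_data <- function(y, group) {
  y <- as.numeric(y)
  group <- as.factor(group)
  if (length(y) != length(group)) {
    stop("`y` and `group` must have the same length", call. = FALSE)
  }
  if (anyNA(y) || anyNA(group)) {
    stop("missing values are not supported", call. = FALSE)
  }
  group <- droplevels(group)
  J <- nlevels(group)
  if (any(tabulate(group, J) == 0L)) {
    stop("every group level needs at least one observation", call. = FALSE)
  }
  if (length(y) < J + 2L) {
    stop("need at least J + 2 observations for residual degrees of freedom",
         call. = FALSE)
  }
  structure(list(y = y, group = group), class = "anova_data")
}

as_anova_data <- function(x) {
  if (inherits(x, "anova_data")) {
    return(x)
  }
  if (is.data.frame(x) && all(c("y", "group") %in% names(x))) {
    return(anova_data(x$y, x$group))
  }
  if (is.list(x) && all(c("y", "group") %in% names(x))) {
    return(anova_data(x$y, x$group))
  }
  stop("cannot interpret input as ANOVA data (need columns `y` and `group`)",
       call. = FALSE)
}

#' @export
print.anova_data <- function(x, ...) {
  cat(sprintf("ANOVA data: N = %d observations in %d groups (%s)\n",
              length(x$y), nlevels(x$group),
              paste(levels(x$group), collapse = ", ")))
  invisible(x)
}

#' JZS effect-prior scale for the one-way ANOVA Bayes factor
#'
#' The group effects get a zero-mean normal prior whose variance `g * sigma^2`
#' carries a scaled inverse-chi-squared hyperprior with 1 degree of freedom and
#' scale `r^2` (equivalently `g = r^2 / z^2` with `z` standard normal). The
#' named presets follow the usual default-prior conventions: `"medium"` is
#' `r = 1/2`, `"ultrawide"` is `r = 1`.
#'
#' @param scale Either a positive number `r` or one of `"medium"`,
#'   `"ultrawide"`.
#' @return An object of class `jzs_prior` with fields `r` and `df` (always 1).
#' @examples
#' jzs_prior("medium")$r # 0.5
#' @export
jzs_prior <- function(scale = "medium") {
  if (is.character(scale)) {
    r <- switch(match.arg(scale, c("medium", "ultrawide")),
                medium = 0.5, ultrawide = 1)
  } else {
    if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) ||
        scale <= 0) {
      stop("`scale` must be a positive number or a preset name",
           call. = FALSE)
    }
    r <- as.numeric(scale)
  }
  structure(list(r = r, df = 1L), class = "jzs_prior")
}

as_jzs_prior <- function(x) {
  if (inherits(x, "jzs_prior")) x else jzs_prior(x)
}

#' @export
print.jzs_prior <- function(x, ...) {
  cat(sprintf("JZS effect prior: g ~ scaled-inv-chi^2(df = 1, scale = %g^2)\n",
              x$r))
  invisible(x)
}

# Orthonormal basis of the sum-to-zero subspace of R^J (columns of the
# complete QR of the ones vector beyond the first).
sum_to_zero_basis <- function(J) {
  qr.Q(qr(matrix(1, J, 1)), complete = TRUE)[, -1L, drop = FALSE]
}

#' Sum-to-zero effect design for a grouping factor
#'
#' Maps the `N x J` group indicator matrix through an orthonormal basis of the
#' sum-to-zero subspace of the group-effect space and centers the result.
#' The `J - 1` columns are mutually orthogonal for balanced designs and always
#' orthogonal to the intercept; effects act on the group-mean scale, so for a
#' balanced design `t(X) %*% X = n_per_group * I`. This is the
#' parameterization under which the effect prior of [jzs_prior()] is placed.
#'
#' @param group Factor (or vector coercible to one) with at least two levels.
#' @return Numeric matrix with one row per observation and `J - 1` columns.
#' @examples
#' X <- effect_design(rep(letters[1:3], each = 50))
#' crossprod(X) # 50 * identity
#' @export
effect_design <- function(group) {
  group <- droplevels(as.factor(group))
  J <- nlevels(group)
  if (J < 2L) {
    stop("effect design needs at least two group levels", call. = FALSE)
  }
  Q <- sum_to_zero_basis(J)
  Z <- Q[as.integer(group), , drop = FALSE]
  sweep(Z, 2L, colMeans(Z))
}

# Sufficient statistics for the conditional Bayes factor: eigenstructure of
# X'X, projected data u, residual and total sum of squares. The residual form
# SSE + sum(u^2 / (lambda (1 + g lambda))) is cancellation-free even for
# near-perfect fits, unlike subtracting the quadratic form from y'Cy.
anova_bf_stats <- function(data) {
  data <- as_anova_data(data)
  X <- effect_design(data$group)
  yc <- data$y - mean(data$y)
  ytCy <- sum(yc^2)
  if (ytCy <= 0) {
    stop("constant response: Bayes factor undefined for degenerate data",
         call. = FALSE)
  }
  eig <- eigen(crossprod(X), symmetric = TRUE)
  u <- drop(crossprod(eig$vectors, crossprod(X, yc)))
  u2 <- u^2
  lambda <- eig$values
  sse <- max(ytCy - sum(u2 / lambda), 0)
  list(lambda = lambda, u2 = u2, sse = sse, ytCy = ytCy,
       N = length(data$y), J = nlevels(data$group))
}

log_conditional_bf10_stats <- function(stats, g) {
  vapply(g, function(gg) {
    if (gg == 0) {
      return(0)
    }
    resid <- stats$sse + sum(stats$u2 / (stats$lambda * (1 + gg * stats$lambda)))
    -0.5 * sum(log1p(gg * stats$lambda)) -
      (stats$N - 1) / 2 * (log(resid) - log(stats$ytCy))
  }, numeric(1))
}

#' Bayes factor for a one-way ANOVA effect at a fixed prior variance g
#'
#' Conditional on `g`, the effect prior is zero-mean normal with covariance
#' `g * sigma^2 * I` on the sum-to-zero effects, and the intercept and error
#' variance are integrated under Jeffreys priors, giving
#' `BF10(g) = det(I + g X'X)^(-1/2) *
#'   [(y'Cy - y'X (X'X + I/g)^(-1) X'y) / y'Cy]^(-(N-1)/2)`
#' with `X` the [effect_design()] matrix and `C` the centering projection.
#' The `g = 0` limit is 1 (the prior collapses onto the null). The value is
#' invariant to shifting or rescaling the response.
#'
#' @param data An [anova_data()] object (or data.frame with `y`, `group`).
#' @param g Nonnegative prior variance multiplier; may be a vector.
#' @return Numeric vector of conditional Bayes factors `BF10(g)`.
#' @examples
#' d <- anova_data(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' conditional_bf10(d, g = c(0, 1))
#' @export
conditional_bf10 <- function(data, g) {
  if (!is.numeric(g) || anyNA(g) || any(g < 0)) {
    stop("`g` must be nonnegative", call. = FALSE)
  }
  exp(log_conditional_bf10_stats(anova_bf_stats(data), g))
}

# Log JZS Bayes factor by adaptive quadrature. Integrates the conditional
# Bayes factor against the g hyperprior in the half-normal representation
# g = r^2 / z^2, on the log scale with a mode shift so that prior-predictive
# datasets with enormous conditional Bayes factors do not overflow.
log_jzs_bf10_stats <- function(stats, r, rel_tol = 1e-8) {
  lf <- function(z) {
    v <- log_conditional_bf10_stats(stats, r^2 / z^2) +
      log(2) + stats::dnorm(z, log = TRUE)
    v[!is.finite(v)] <- -Inf
    v
  }
  grid <- c(2^seq(-20, 4, length.out = 41))
  s <- max(lf(grid))
  opt <- try(stats::optimize(lf, c(1e-9, 20), maximum = TRUE), silent = TRUE)
  if (!inherits(opt, "try-error")) {
    s <- max(s, opt$objective)
  }
  val <- tryCatch(
    stats::integrate(function(z) exp(pmin(lf(z) - s, 700)), 0, Inf,
                     rel.tol = rel_tol)$value,
    error = function(e) {
      stop(sprintf("g-hyperprior quadrature failed (r = %g): %s",
                   r, conditionMessage(e)), call. = FALSE)
    }
  )
  s + log(val)
}

#' JZS one-way ANOVA Bayes factor
#'
#' Integrates [conditional_bf10()] over the scaled inverse-chi-squared
#' hyperprior on `g` (1 degree of freedom, scale `r^2`) by adaptive
#' quadrature in the representation `g = r^2 / z^2` with `z` half-normal,
#' computed in log space with relative tolerance `1e-8`.
#'
#' @inheritParams conditional_bf10
#' @param prior A [jzs_prior()], a preset name, or a positive scale `r`.
#' @return A single positive number, the Bayes factor for the effect against
#'   the null of equal group means.
#' @examples
#' d <- anova_data(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' jzs_bf10(d, "medium")
#' @export
jzs_bf10 <- function(data, prior = jzs_prior("medium")) {
  prior <- as_jzs_prior(prior)
  exp(log_jzs_bf10_stats(anova_bf_stats(data), prior$r))
}

#' Generator settings for prior-predictive ANOVA data
#'
#' Describes the study design and generation-side parameters used by
#' [simulate_anova_h1()] and [simulate_anova_h0()]. Defaults mirror a
#' three-arm study with 50 participants per group, error variance 0.5, and a
#' medium (`r = 1/2`) effect-prior scale.
#'
#' @param J Number of groups (>= 2).
#' @param per_group_n Observations per group (>= 2).
#' @param sigma2 Error variance used for generation (> 0).
#' @param alpha0 Generation intercept; every computed Bayes factor is
#'   invariant to it.
#' @param r_gen Scale of the g hyperprior that the effects are drawn from.
#' @param scale_effects_by_sigma2 If `TRUE` (default) effects are drawn with
#'   variance `g * sigma2`, matching the analysis prior exactly so that the
#'   Turing identity holds; `FALSE` draws them with variance `g`.
#' @return An object of class `anova_gen_config`.
#' @export
anova_gen_config <- function(J = 3, per_group_n = 50, sigma2 = 0.5,
                             alpha0 = 0, r_gen = 0.5,
                             scale_effects_by_sigma2 = TRUE) {
  if (J < 2 || J != round(J)) stop("`J` must be an integer >= 2", call. = FALSE)
  if (per_group_n < 2 || per_group_n != round(per_group_n)) {
    stop("`per_group_n` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  if (!is.numeric(r_gen) || r_gen < 0) {
    stop("`r_gen` must be nonnegative", call. = FALSE)
  }
  structure(
    list(J = as.integer(J), per_group_n = as.integer(per_group_n),
         sigma2 = sigma2, alpha0 = alpha0, r_gen = r_gen,
         scale_effects_by_sigma2 = isTRUE(scale_effects_by_sigma2)),
    class = "anova_gen_config"
  )
}

simulate_anova_impl <- function(cfg, m, seed, null_effects) {
  if (!inherits(cfg, "anova_gen_config")) {
    stop("`cfg` must be an anova_gen_config", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  seed <- materialize_seed(seed)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  J <- cfg$J
  N <- J * cfg$per_group_n
  group <- factor(rep(seq_len(J), each = cfg$per_group_n))
  Q <- sum_to_zero_basis(J)
  # fixed draw order (g scale, effects, noise) so the null generator is the
  # exact r_gen -> 0 limit of the alternative generator under the same seed
  z <- stats::rnorm(m)
  beta_raw <- matrix(stats::rnorm(m * (J - 1)), nrow = J - 1)
  eps <- matrix(stats::rnorm(N * m, sd = sqrt(cfg$sigma2)), nrow = N)

  g <- cfg$r_gen^2 / z^2
  if (cfg$r_gen == 0) g[] <- 0
  eff_var <- if (cfg$scale_effects_by_sigma2) g * cfg$sigma2 else g
  if (null_effects) eff_var[] <- 0

  out <- vector("list", m)
  for (i in seq_len(m)) {
    beta <- beta_raw[, i] * sqrt(eff_var[i])
    means <- cfg$alpha0 + drop(Q %*% beta)
    out[[i]] <- structure(list(y = means[as.integer(group)] + eps[, i],
                               group = group),
                          class = "anova_data")
  }
  attr(out, "seed") <- seed
  out
}

#' Prior-predictive ANOVA datasets under the alternative
#'
#' For each replicate, draws `g` from its scaled inverse-chi-squared
#' hyperprior (`g = r_gen^2 / z^2`), draws sum-to-zero effects from the
#' zero-mean normal effect prior, and adds Gaussian noise. This is the
#' prior-predictive distribution that the analysis prior of [jzs_bf10()]
#' assumes, so the Turing identity `E[BF01] = 1` applies to Bayes factors
#' computed with the matched scale.
#'
#' @param cfg An [anova_gen_config()].
#' @param m Number of replicate datasets.
#' @param seed Integer seed; drawn and recorded if `NULL`.
#' @return A list of `m` [anova_data()] objects with attribute `seed`.
#' @export
simulate_anova_h1 <- function(cfg, m, seed = NULL) {
  simulate_anova_impl(cfg, m, seed, null_effects = FALSE)
}

#' Prior-predictive ANOVA datasets under the null
#'
#' As [simulate_anova_h1()] but with all group effects fixed at zero. The
#' random-number stream is shared with the alternative generator, so with
#' `r_gen = 0` the two produce identical datasets under the same seed.
#'
#' @inheritParams simulate_anova_h1
#' @return A list of `m` [anova_data()] objects with attribute `seed`.
#' @export
simulate_anova_h0 <- function(cfg, m, seed = NULL) {
  simulate_anova_impl(cfg, m, seed, null_effects = TRUE)
}
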