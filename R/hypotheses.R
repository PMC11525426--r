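#' Point hypothesis for a binomial success probability
#'
#' Defines the simple hypothesis that the success probability equals a fixed
#' value `theta0`, e.g. the classic null `theta = 1/2` for a fair coin.
#'
#' @param theta0 Success probability, in `[0, 1]`.
#' @param label Short name used in reports (default `"H0"`).
#' @return An object of class `c("binom_point_hypothesis", "binom_hypothesis")`.
#' @examples
#' h0 <- point_hypothesis(1 / 2)
#' binom_marginal(h0, n = 2, k = 1) # 1/2
#' @seealso [beta_hypothesis()], [binom_marginal()]
#' @export
point_hypothesis <- function(theta0, label = "H0") {
  if (!is.numeric(theta0) || length(theta0) != 1L || is.na(theta0) ||
      theta0 < 0 || theta0 > 1) {
    stop("`theta0` must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = as.character(label)[1L], theta0 = theta0),
    class = c("binom_point_hypothesis", "binom_hypothesis")
  )
}

#' Beta or truncated-beta hypothesis for a binomial success probability
#'
#' Defines a composite hypothesis `theta ~ Beta(a, b)` restricted to
#' `[lower, upper]`. With the defaults `lower = 0, upper = 1` this is the
#' untruncated beta prior; `beta_hypothesis(1, 1)` is the uniform alternative
#' and `beta_hypothesis(1, 1, lower = 0.5)` is the directional hypothesis
#' `theta > 1/2` expressed as Uniform(0.5, 1).
#'
#' @param a,b Positive beta shape parameters.
#' @param lower,upper Truncation bounds with `0 <= lower < upper <= 1`.
#' @param label Short name used in reports (default `"H1"`).
#' @return An object of class `c("binom_beta_hypothesis", "binom_hypothesis")`.
#' @examples
#' h1 <- beta_hypothesis(1, 1)
#' hr <- beta_hypothesis(1, 1, lower = 0.5, label = "Hr")
#' binom_marginal(hr, n = 1, k = 1) # 0.75
#' @export
beta_hypothesis <- function(a, b, lower = 0, upper = 1, label = "H1") {
  for (nm in c("a", "b", "lower", "upper")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("`%s` must be a single non-missing number", nm), call. = FALSE)
    }
  }
  if (a <= 0 || b <= 0) {
    stop("beta shapes `a` and `b` must be positive", call. = FALSE)
  }
  if (lower < 0 || upper > 1 || lower >= upper) {
    stop("truncation bounds must satisfy 0 <= lower < upper <= 1", call. = FALSE)
  }
  mass <- stats::pbeta(upper, a, b) - stats::pbeta(lower, a, b)
  if (mass <= 0) {
    stop("truncation interval carries zero prior mass", call. = FALSE)
  }
  structure(
    list(label = as.character(label)[1L], a = a, b = b,
         lower = lower, upper = upper),
    class = c("binom_beta_hypothesis", "binom_hypothesis")
  )
}

is_truncated <- function(hyp) {
  inherits(hyp, "binom_beta_hypothesis") && (hyp$lower > 0 || hyp$upper < 1)
}

#' @export
print.binom_point_hypothesis <- function(x, ...) {
  cat(sprintf("%s: theta = %g (point hypothesis)\n", x$label, x$theta0))
  invisible(x)
}

#' @export
print.binom_beta_hypothesis <- function(x, ...) {
  if (is_truncated(x)) {
    cat(sprintf("%s: theta ~ Beta(%g, %g) truncated to [%g, %g]\n",
                x$label, x$a, x$b, x$lower, x$upper))
  } else {
    cat(sprintf("%s: theta ~ Beta(%g, %g)\n", x$label, x$a, x$b))
  }
  invisible(x)
}

check_outcome <- function(n, k) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop("`n` must be a single nonnegative integer", call. = FALSE)
  }
  if (!is.numeric(k) || anyNA(k) || any(k < 0) || any(k > n) ||
      any(k != round(k))) {
    stop("`k` must contain integers with 0 <= k <= n", call. = FALSE)
  }
  invisible(TRUE)
}
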