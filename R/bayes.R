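#' Specification of a Bayesian sequential satisfaction test
#'
#' The test decides between `H0: rho >= theta0` and `H1: rho < theta0`,
#' where `rho` is the unknown probability that a sampled trace satisfies
#' the property. `rho` carries a Beta prior; the running Bayes factor is
#' the ratio of the posterior mass above `theta0` to the mass below it,
#' and sampling stops when the (fairness-adjusted) Bayes factor leaves
#' `(1/T, T)`.
#'
#' @param theta0 Probability threshold in (0, 1).
#' @param prior Length-2 vector `c(alpha, beta)` of Beta prior parameters
#'   (> 0). The default `c(1, 1)` is the uniform (non-informative) prior.
#' @param bayes_threshold Decision threshold `T` (> 1): accept H0 when the
#'   adjusted Bayes factor exceeds `T`, accept H1 when it falls below `1/T`.
#' @param eta Asserted fairness bound (>= 1) on the geometric mean of the
#'   implied Radon-Nikodym derivatives of the sampling measures; `eta = 1`
#'   is i.i.d. sampling and applies no correction.
#' @param concentration_b Optional posterior-concentration rate constant
#'   `b` (> 0). When supplied, the spec is checked for eventual fairness
#'   (`eta^4 < exp(b)`) at construction and a warning is issued otherwise.
#' @param max_samples Sampling budget; the test returns `undecided` if the
#'   budget is exhausted.
#' @return An object of class `test_spec`.
#' @examples
#' test_spec(theta0 = 0.01, bayes_threshold = 100)
#' @export
test_spec <- function(theta0, prior = c(1, 1), bayes_threshold = 100,
                      eta = 1, concentration_b = NULL, max_samples = 1e6) {
  theta0 <- as.numeric(theta0)[1]
  if (!is.finite(theta0) || theta0 <= 0 || theta0 >= 1) {
    abort("`theta0` must lie strictly between 0 and 1.")
  }
  prior <- as.numeric(prior)
  if (length(prior) != 2L || any(!is.finite(prior)) || any(prior <= 0)) {
    abort("`prior` must be two positive Beta parameters c(alpha, beta).")
  }
  if (!is.finite(bayes_threshold) || bayes_threshold <= 1) {
    abort("`bayes_threshold` must be > 1.")
  }
  if (!is.finite(eta) || eta < 1) {
    abort("`eta` must be >= 1 (1 = i.i.d. sampling).")
  }
  if (!is.null(concentration_b)) {
    if (!is.finite(concentration_b) || concentration_b <= 0) {
      abort("`concentration_b` must be > 0 when supplied.")
    }
    if (!eventually_fair(eta, concentration_b)) {
      warn(sprintf(
        "eta^4 = %g is not < exp(b) = %g: the test is not eventually fair and may never terminate.",
        eta^4, exp(concentration_b)
      ))
    }
  }
  max_samples <- as.numeric(max_samples)[1]
  if (is.na(max_samples) || max_samples < 0) {
    abort("`max_samples` must be a non-negative integer.")
  }
  structure(
    list(
      theta0 = theta0, prior_alpha = prior[[1]], prior_beta = prior[[2]],
      bayes_threshold = bayes_threshold, eta = eta,
      concentration_b = concentration_b, max_samples = max_samples
    ),
    class = "test_spec"
  )
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf(
    "<test_spec> H0: rho >= %g vs H1: rho < %g\n  prior Beta(%g, %g), T = %g, eta = %g, max %g samples\n",
    x$theta0, x$theta0, x$prior_alpha, x$prior_beta, x$bayes_threshold,
    x$eta, x$max_samples
  ))
  invisible(x)
}

#' Bayes factor for the composite satisfaction hypotheses
#'
#' For `x` satisfying outcomes in `n` Bernoulli samples with Beta prior
#' `g`, the Bayes factor of `H0: rho >= theta0` against `H1: rho < theta0`
#' is the ratio of prior-weighted likelihood integrals
#' `B = Int_theta0^1 u^x (1-u)^(n-x) g(u) du / Int_0^theta0 ...`, which in
#' closed form is `(1 - I) / I` with `I` the regularised incomplete beta
#' function at `theta0` with parameters `(alpha + x, beta + n - x)`.
#' `log_bayes_factor` evaluates both tails on the log scale and so is
#' stable for `n` in the thousands; when `I` underflows to 0 or 1 the
#' result is the `+Inf`/`-Inf` sentinel rather than an error.
#'
#' @param x Number of satisfying samples (0 <= x <= n).
#' @param n Number of samples.
#' @param spec A [test_spec()].
#' @return The Bayes factor (`bayes_factor`) or its natural logarithm
#'   (`log_bayes_factor`).
#' @examples
#' sp <- test_spec(theta0 = 0.5)
#' bayes_factor(0, 0, sp) # prior mass splits evenly: 1
#' bayes_factor(1, 1, sp) # 3
#' @export
bayes_factor <- function(x, n, spec) {
  exp(log_bayes_factor(x, n, spec))
}

#' @rdname bayes_factor
#' @export
log_bayes_factor <- function(x, n, spec) {
  stopifnot(inherits(spec, "test_spec"))
  if (any(x < 0) || any(x > n)) abort("need 0 <= x <= n.")
  a <- spec$prior_alpha + x
  b <- spec$prior_beta + n - x
  log_upper <- pbeta(spec$theta0, a, b, lower.tail = FALSE, log.p = TRUE)
  log_lower <- pbeta(spec$theta0, a, b, lower.tail = TRUE, log.p = TRUE)
  log_upper - log_lower
}

#' Posterior probability that the satisfaction probability is below theta0
#'
#' `P(rho < theta0 | x, n)` under the Beta prior: the regularised
#' incomplete beta function at `theta0` with parameters
#' `(alpha + x, beta + n - x)`. Related to the Bayes factor by
#' `P = 1 / (1 + B)`.
#'
#' @inheritParams bayes_factor
#' @param theta0 Optional threshold overriding `spec$theta0`.
#' @return A probability.
#' @examples
#' sp <- test_spec(theta0 = 0.5)
#' posterior_prob_below(1, 1, sp) # Beta(2,1) cdf at 0.5: 0.25
#' @export
posterior_prob_below <- function(x, n, spec, theta0 = spec$theta0) {
  stopifnot(inherits(spec, "test_spec"))
  if (any(x < 0) || any(x > n)) abort("need 0 <= x <= n.")
  pbeta(theta0, spec$prior_alpha + x, spec$prior_beta + n - x)
}

#' Conservative fairness adjustment of the Bayes factor
#'
#' Non-i.i.d. sampling under an eta-fair strategy can distort the Bayes
#' factor by at most `eta^(2n)` after `n` samples. The adjustment therefore
#' shrinks the log Bayes factor towards 0 by `2 n log(eta)`: divided by
#' `eta^(2n)` when `B > 1`, multiplied by `eta^(2n)` when `B < 1`. The
#' correction never crosses zero: if it would flip the sign of `log B` the
#' result is clamped at 0 (maximally non-committal), so the correction
#' itself can never force a decision.
#'
#' @param log_bf Raw log Bayes factor (may be `+-Inf`).
#' @param eta Fairness bound (>= 1).
#' @param n Number of samples so far.
#' @return The adjusted log Bayes factor, with `|adjusted| <= |raw|`.
#' @examples
#' adjust_log_bf(log(100), eta = 1.1, n = 2) # log(100 / 1.1^4)
#' adjust_log_bf(log(100), eta = 1, n = 5) # unchanged
#' @export
adjust_log_bf <- function(log_bf, eta, n) {
  if (!is.finite(eta) || eta < 1) abort("`eta` must be >= 1.")
  if (n < 0) abort("`n` must be >= 0.")
  shrink <- 2 * n * log(eta)
  ifelse(log_bf > 0, pmax(log_bf - shrink, 0), pmin(log_bf + shrink, 0))
}

#' Check eta-fairness of an explicit sampling history
#'
#' A sampling strategy is eta-fair when the geometric mean of the implied
#' Radon-Nikodym derivatives of its per-sample measures lies in
#' `[1/eta, eta]`. The derivatives are only computable when the measures
#' are explicit (e.g. the discrete [toy_fixture()]); for SDE sampling the
#' symmetric perturbation policy is relied on instead and `eta` is a
#' user-asserted bound.
#'
#' @param factors Positive per-sample bias factors (Radon-Nikodym
#'   derivatives evaluated at the observed outcomes).
#' @param eta Fairness bound (>= 1).
#' @return `TRUE` iff the geometric mean lies within `[1/eta, eta]`.
#'   Vacuously `TRUE` (with a warning) on an empty history.
#' @examples
#' check_fairness(c(2, 0.5), eta = 1) # geometric mean 1
#' check_fairness(c(2, 2), eta = 1.5) # FALSE
#' @export
check_fairness <- function(factors, eta) {
  if (!is.finite(eta) || eta < 1) abort("`eta` must be >= 1.")
  if (length(factors) == 0L) {
    warn("empty sampling history: fairness holds vacuously.")
    return(TRUE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("bias factors must be positive and finite.")
  }
  gm_log <- mean(log(factors))
  gm_log >= -log(eta) - 1e-12 && gm_log <= log(eta) + 1e-12
}

#' Is an eta-fair test eventually fair?
#'
#' An eta-fair test terminates (the posterior concentration outweighs the
#' worst-case measure distortion) iff `1 <= eta^4 < exp(b)`, where `b` is
#' the exponential posterior-concentration rate constant. `b` is not
#' computed by this package; it is supplied by the user.
#'
#' @param eta Fairness bound (>= 1).
#' @param concentration_b Concentration rate constant (> 0).
#' @return `TRUE` or `FALSE` (strict inequality at the boundary).
#' @examples
#' eventually_fair(1.1, 1) # 1.4641 < e
#' eventually_fair(2, log(16)) # boundary: FALSE
#' @export
eventually_fair <- function(eta, concentration_b) {
  if (!is.finite(eta) || eta < 1) abort("`eta` must be >= 1.")
  if (!is.finite(concentration_b) || concentration_b <= 0) {
    abort("`concentration_b` must be > 0.")
  }
  4 * log(eta) < concentration_b
}
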