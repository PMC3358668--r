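#' Discrete two-outcome fixture with explicit change of measure
#'
#' A finite probability space with one rare, satisfying outcome: the
#' natural measure puts mass `p_rare` on it, the biased measure inflates
#' that mass to `min(c * p_rare, 1/2)`. Because both measures are explicit,
#' the Radon-Nikodym derivatives (mass ratios) are known exactly, so this
#' fixture is where fairness accounting ([check_fairness()]) and the
#' posterior distortion bounds ([biased_posterior_below()]) can be
#' validated — unlike for SDE sampling, where the implied change of measure
#' is not computable.
#'
#' @param c_bound Declared distortion bound `c` (>= 1).
#' @param p_rare Natural probability of the rare outcome (0 < p < 1/2).
#' @return An object of class `toy_measure_pair` with fields `p_natural`,
#'   `p_biased` (length-2 vectors: rare then common outcome), `satisfying`
#'   (logical mask), `ratio` (per-outcome derivatives) and `c_bound`.
#' @examples
#' toy_fixture(10, 1e-3) # rare mass 1e-3 -> 1e-2, ratio exactly 10
#' @export
toy_fixture <- function(c_bound, p_rare) {
  if (!is.finite(c_bound) || c_bound < 1) abort("`c_bound` must be >= 1.")
  if (!is.finite(p_rare) || p_rare <= 0 || p_rare >= 0.5) {
    abort("`p_rare` must lie in (0, 1/2).")
  }
  p_nat <- c(p_rare, 1 - p_rare)
  q_rare <- min(c_bound * p_rare, 0.5)
  p_bia <- c(q_rare, 1 - q_rare)
  ratio <- p_bia / p_nat
  if (any(ratio > c_bound + 1e-12) || any(ratio < 1 / c_bound - 1e-12)) {
    abort(sprintf(
      "the biased measure distorts an outcome by more than the declared bound c = %g; choose a smaller p_rare or c.",
      c_bound
    ))
  }
  structure(
    list(
      p_natural = p_nat, p_biased = p_bia,
      satisfying = c(TRUE, FALSE), ratio = ratio, c_bound = c_bound
    ),
    class = "toy_measure_pair"
  )
}

#' @export
print.toy_measure_pair <- function(x, ...) {
  cat(sprintf(
    "<toy_measure_pair> rare mass %g -> %g (ratio %g), c = %g\n",
    x$p_natural[1], x$p_biased[1], x$ratio[1], x$c_bound
  ))
  invisible(x)
}

#' Outcome sampler over the discrete toy fixture
#'
#' Draws satisfaction outcomes from the fixture under the natural measure,
#' the biased measure, or a symmetric policy that flips a fair coin per
#' sample between the biased measure and its mirror image (rare mass
#' divided by the same factor), so that the measure is biased for the rare
#' outcome as often as against it. Every sample reports its exact
#' Radon-Nikodym `bias_factor`, making the stream's fairness auditable
#' with [check_fairness()].
#'
#' @param fixture A [toy_fixture()].
#' @param mode `"natural"`, `"biased"` or `"symmetric"`.
#' @param seed Integer root seed.
#' @return A sampler function for [sequential_verify()].
#' @examples
#' s <- toy_sampler(toy_fixture(10, 1e-3), "biased", seed = 1)
#' s(1)
#' @export
toy_sampler <- function(fixture, mode = c("natural", "biased", "symmetric"),
                        seed) {
  stopifnot(inherits(fixture, "toy_measure_pair"))
  mode <- match.arg(mode)
  p_nat <- fixture$p_natural[1]
  # mirror measure: rare mass shrunk by the factor the biased one grew
  grow <- fixture$p_biased[1] / p_nat
  p_dn <- p_nat / grow
  function(i) {
    p_use <- switch(mode,
      natural = p_nat,
      biased = fixture$p_biased[1],
      symmetric = {
        up <- with_seed(rng_substream(seed, i, purpose = 2L), runif(1)) < 0.5
        if (up) fixture$p_biased[1] else p_dn
      }
    )
    u <- with_seed(rng_substream(seed, i, purpose = 0L), runif(1))
    outcome <- u < p_use
    bias_factor <- if (outcome) p_use / p_nat else (1 - p_use) / (1 - p_nat)
    list(outcome = outcome, bias_factor = bias_factor)
  }
}

#' Bernoulli stream with an odds-multiplier change of measure
#'
#' A biased Bernoulli sampler whose implied Radon-Nikodym derivative is
#' bounded by construction: multiplying the odds of success by `c` maps
#' the success probability `p` to `h = c p / (1 + (c - 1) p)`, and the
#' per-outcome derivative (`h/p` on success, `(1-h)/(1-p)` on failure)
#' lies in `[1/c, c]` for every `p`. In symmetric mode each sample flips a
#' fair coin between multiplying and dividing the odds by `c`.
#'
#' @param p Natural success probability.
#' @param c_bias Odds multiplier (>= 1).
#' @param seed Integer root seed.
#' @param symmetric Flip the bias direction per sample (`TRUE`, the
#'   fairness-preserving policy) or always bias upwards (`FALSE`).
#' @return A sampler function for [sequential_verify()].
#' @examples
#' s <- biased_bernoulli_sampler(0.01, c_bias = 10, seed = 1)
#' s(1)
#' @export
biased_bernoulli_sampler <- function(p, c_bias, seed, symmetric = TRUE) {
  stopifnot(p > 0, p < 1, c_bias >= 1)
  odds <- p / (1 - p)
  function(i) {
    cc <- c_bias
    if (symmetric) {
      up <- with_seed(rng_substream(seed, i, purpose = 2L), runif(1)) < 0.5
      if (!up) cc <- 1 / c_bias
    }
    h <- cc * odds / (1 + cc * odds)
    u <- with_seed(rng_substream(seed, i, purpose = 0L), runif(1))
    outcome <- u < h
    list(
      outcome = outcome,
      bias_factor = if (outcome) h / p else (1 - h) / (1 - p)
    )
  }
}

#' Posterior under an explicitly biased likelihood
#'
#' The biased analogue of [posterior_prob_below()]: the probability
#' `Q(rho < theta0 | X)` computed with the biased per-sample likelihoods
#' `h_i(u)` instead of `u`, where `h_i(u) = c_i u / (1 + (c_i - 1) u)` is
#' the odds-multiplier bias map with per-sample factor
#' `c_i = c_bound^(direction_i)`. The implied Radon-Nikodym derivative of
#' this map lies in `[1/c, c]` uniformly in `u`, so `Q` must lie within
#' `[c^(-2n) P, c^(2n) P]` of the unbiased posterior `P` — the distortion
#' bound that justifies the `eta^(2n)` Bayes-factor correction. Computed
#' by adaptive quadrature.
#'
#' @param outcomes Logical (or 0/1) vector of observed outcomes.
#' @param theta0 Probability threshold.
#' @param c_bound Odds-multiplier bound `c` (>= 1).
#' @param prior Beta prior parameters `c(alpha, beta)`.
#' @param directions Per-sample bias directions (+1 = towards
#'   satisfaction, -1 = away); defaults to all +1.
#' @return The posterior probability `Q(rho < theta0 | X)`.
#' @examples
#' biased_posterior_below(c(TRUE, FALSE, FALSE), 0.5, c_bound = 2)
#' @export
biased_posterior_below <- function(outcomes, theta0, c_bound,
                                   prior = c(1, 1), directions = NULL) {
  outcomes <- as.logical(outcomes)
  n <- length(outcomes)
  if (is.null(directions)) directions <- rep(1, n)
  stopifnot(length(directions) == n, c_bound >= 1, theta0 > 0, theta0 < 1)
  cc <- c_bound^directions
  integrand <- function(u) {
    out <- vapply(u, function(ui) {
      h <- cc * ui / (1 + (cc - 1) * ui)
      ll <- sum(ifelse(outcomes, log(h), log1p(-h)))
      exp(ll)
    }, numeric(1))
    out * stats::dbeta(u, prior[1], prior[2])
  }
  lower <- integrate(integrand, 0, theta0, rel.tol = 1e-10)$value
  upper <- integrate(integrand, theta0, 1, rel.tol = 1e-10)$value
  lower / (lower + upper)
}
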