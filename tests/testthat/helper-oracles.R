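# Shared fixtures and independent oracles.

# Standard Brownian motion dX = dW, X0 = 0.
brownian_model <- function() {
  sde_model(
    drift = function(t, x) 0 * x,
    diffusion = function(t, x) 0 * x + 1,
    initial_state = 0,
    variable_names = "x"
  )
}

# Direct quadrature of the Bayes-factor ratio of prior-weighted likelihood
# integrals (independent of the incomplete-beta closed form). Integrates in
# u = sin^2(phi), which removes the integrable endpoint singularities of
# priors with alpha or beta < 1.
quad_bayes_factor <- function(x, n, theta0, prior) {
  # u^(x+a-1) (1-u)^(n-x+b-1) / B(a,b) with u = sin^2(phi), du = sin(2 phi):
  # the trigonometric form never evaluates the density at the endpoints
  g <- function(phi) {
    2 * sin(phi)^(2 * (x + prior[1]) - 1) *
      cos(phi)^(2 * (n - x + prior[2]) - 1) / beta(prior[1], prior[2])
  }
  phi0 <- asin(sqrt(theta0))
  # a piece whose integrand underflows double precision over (almost) the
  # whole interval makes integrate() error out; report it as underflowed
  piece <- function(lo, hi) {
    tryCatch(
      stats::integrate(g, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value,
      error = function(e) 0
    )
  }
  upper <- piece(phi0, pi / 2)
  lower <- piece(0, phi0)
  list(bf = upper / lower, upper = upper, lower = lower)
}

# Random formula AST (uses the session RNG; callers set the seed).
random_formula <- function(depth, vars) {
  kinds <- if (depth <= 0) {
    "atom"
  } else {
    c("atom", "not", "and", "or", "until", "until")
  }
  kind <- sample(kinds, 1)
  switch(kind,
    atom = sdemc:::bltl_node(
      "atom",
      var = sample(vars, 1),
      rel = sample(c("<", ">", "="), 1),
      value = round(stats::runif(1, -2, 2), 1)
    ),
    not = sdemc:::bltl_node("not", child = random_formula(depth - 1, vars)),
    and = sdemc:::bltl_node(
      "and",
      left = random_formula(depth - 1, vars),
      right = random_formula(depth - 1, vars)
    ),
    or = sdemc:::bltl_node(
      "or",
      left = random_formula(depth - 1, vars),
      right = random_formula(depth - 1, vars)
    ),
    until = sdemc:::bltl_node(
      "until",
      left = random_formula(depth - 1, vars),
      right = random_formula(depth - 1, vars),
      bound = round(stats::runif(1, 0, 3), 2)
    )
  )
}

# Random finite timed trace; states rounded so equality atoms sometimes hit.
random_trace <- function(max_states, vars) {
  n <- sample(seq_len(max_states), 1)
  states <- matrix(
    round(stats::runif(n * length(vars), -2, 2), 1),
    n, length(vars)
  )
  durations <- round(stats::runif(n, 0, 1), 2)
  bltl_trace(states, durations, vars)
}
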