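#' Define a stochastic differential equation model
#'
#' Constructs a system of Ito stochastic differential equations
#' `dX = b(t, X) dt + v(t, X) dW` with one independent Brownian motion per
#' state variable. The diffusion is per-equation (diagonal): equation `i` is
#' driven by its own `dW_i`, with a coefficient that may depend on the whole
#' state. Both bundled tumor models, and every benchmark shipped with the
#' package, have exactly this form.
#'
#' Coefficient functions must be *vectorised across trajectories*: they
#' receive the time `t` (scalar) and a numeric matrix `x` with one row per
#' trajectory and one column per state variable, and must return a matrix of
#' the same shape (drift rates, respectively diffusion coefficients). Plain
#' arithmetic on columns of `x` satisfies this automatically.
#'
#' @param drift Function `(t, x)` returning the drift matrix.
#' @param diffusion Function `(t, x)` returning the per-equation diffusion
#'   coefficient matrix.
#' @param initial_state Numeric vector of initial values, one per variable.
#' @param variable_names Character vector naming the state variables; these
#'   are the identifiers BLTL atoms refer to. Defaults to `x1, x2, ...` (or
#'   `x` for a one-dimensional model).
#' @param positive If `TRUE`, states are clamped at 0 after every
#'   Euler-Maruyama step (population models); clamping events are counted on
#'   the returned trajectory.
#' @return An object of class `sde_model`.
#' @examples
#' # standard Brownian motion
#' bm <- sde_model(
#'   drift = function(t, x) 0 * x,
#'   diffusion = function(t, x) 0 * x + 1,
#'   initial_state = 0, variable_names = "x"
#' )
#' @seealso [sde_simulate()], [lefever_garay()], [immunogenic()]
#' @export
sde_model <- function(drift, diffusion, initial_state, variable_names = NULL,
                      positive = FALSE) {
  stopifnot(is.function(drift), is.function(diffusion))
  initial_state <- as.numeric(initial_state)
  d <- length(initial_state)
  if (d < 1L || anyNA(initial_state) || any(!is.finite(initial_state))) {
    abort("`initial_state` must be a finite numeric vector of length >= 1.")
  }
  if (is.null(variable_names)) {
    variable_names <- if (d == 1L) "x" else paste0("x", seq_len(d))
  }
  variable_names <- as.character(variable_names)
  if (length(variable_names) != d || anyDuplicated(variable_names)) {
    abort("`variable_names` must contain one unique name per state variable.")
  }
  m <- structure(
    list(
      dim_state = d,
      dim_noise = d,
      drift = drift,
      diffusion = diffusion,
      initial_state = initial_state,
      variable_names = variable_names,
      positive = isTRUE(positive)
    ),
    class = "sde_model"
  )
  # cheap shape check at the initial state
  x0 <- matrix(initial_state, nrow = 2L, ncol = d, byrow = TRUE)
  for (fn in c("drift", "diffusion")) {
    out <- m[[fn]](0, x0)
    if (!is.numeric(out) || length(out) != length(x0)) {
      abort(sprintf(
        "`%s` must return a numeric matrix of the same shape as its state argument (got length %d, expected %d).",
        fn, length(out), length(x0)
      ))
    }
  }
  m
}

#' @export
print.sde_model <- function(x, ...) {
  cat(sprintf(
    "<sde_model> %d state variable(s): %s\n  initial state: %s%s\n",
    x$dim_state, paste(x$variable_names, collapse = ", "),
    paste(signif(x$initial_state, 6), collapse = ", "),
    if (x$positive) "  (non-negative, clamped at 0)" else ""
  ))
  invisible(x)
}

#' Fixed-step simulation grid
#'
#' The Euler-Maruyama partition of `[0, t_end]` into steps of size `dt`.
#' The number of steps is `ceiling(t_end / dt)`, so the grid always covers
#' the full horizon.
#'
#' @param t_end Time horizon (> 0), in model time units.
#' @param dt Step size (> 0, `<= t_end`).
#' @return An object of class `sim_grid` with fields `t_end`, `dt`,
#'   `n_steps`.
#' @examples
#' sim_grid(10, 0.01)
#' @export
sim_grid <- function(t_end, dt) {
  t_end <- as.numeric(t_end)[1]
  dt <- as.numeric(dt)[1]
  if (!is.finite(t_end) || t_end <= 0) abort("`t_end` must be positive.")
  if (!is.finite(dt) || dt <= 0 || dt > t_end) {
    abort("`dt` must be positive and no larger than `t_end`.")
  }
  structure(
    list(t_end = t_end, dt = dt, n_steps = as.integer(ceiling(t_end / dt))),
    class = "sim_grid"
  )
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf(
    "<sim_grid> t_end = %g, dt = %g (%d steps)\n", x$t_end, x$dt, x$n_steps
  ))
  invisible(x)
}

#' Constant Girsanov drift perturbation
#'
#' A constant drift shift `theta` applied to each Brownian component for the
#' whole of one trajectory. Under the perturbed measure the Brownian
#' increments gain mean `theta * dt`; the exponential-martingale weight of
#' the resulting path is available in closed form (see
#' [girsanov_log_weight()]). `theta = 0` is the natural measure.
#'
#' @param theta Numeric vector of drift shifts, one per Brownian component
#'   (recycled to the model dimension by the simulator if scalar).
#' @param theta_max Declared bound on `max(abs(theta))` (>= 0). Used for
#'   validation and provenance; the perturbation policy draws fresh `theta`
#'   uniformly from `[-theta_max, theta_max]` for each sample.
#' @return An object of class `sde_perturbation`.
#' @examples
#' perturbation(0)            # natural measure
#' perturbation(c(0.5, -0.5), theta_max = 1)
#' @export
perturbation <- function(theta = 0, theta_max = max(abs(theta))) {
  theta <- as.numeric(theta)
  theta_max <- as.numeric(theta_max)[1]
  if (anyNA(theta) || any(!is.finite(theta))) abort("`theta` must be finite.")
  if (!is.finite(theta_max) || theta_max < 0) abort("`theta_max` must be >= 0.")
  if (length(theta) && max(abs(theta)) > theta_max + 1e-12) {
    abort("`max(abs(theta))` exceeds the declared `theta_max`.")
  }
  structure(
    list(theta = theta, theta_max = theta_max),
    class = "sde_perturbation"
  )
}

#' @export
print.sde_perturbation <- function(x, ...) {
  cat(sprintf(
    "<sde_perturbation> theta = (%s), theta_max = %g\n",
    paste(signif(x$theta, 6), collapse = ", "), x$theta_max
  ))
  invisible(x)
}

#' Perturbation policy for biased sampling
#'
#' Describes how the sequential sampler perturbs the probability measure
#' before each sample. Mode `"off"` always uses the natural measure; mode
#' `"symmetric_uniform"` draws a fresh constant shift
#' `theta ~ Uniform[-theta_max, theta_max]` (independently per Brownian
#' component) for every trajectory. Symmetry of the draw is the package's
#' constructive approximation of long-run fairness: over many samples the
#' measure is biased for an outcome as often as against it.
#'
#' @param theta_max Bound on the uniform draw (>= 0). Ignored when
#'   `mode = "off"`.
#' @param mode `"off"` (i.i.d. sampling) or `"symmetric_uniform"`.
#' @return An object of class `perturb_policy`.
#' @examples
#' perturb_policy(0, "off")
#' perturb_policy(6, "symmetric_uniform")
#' @export
perturb_policy <- function(theta_max = 0, mode = c("off", "symmetric_uniform")) {
  if (isFALSE(mode)) mode <- "off" # bare `off` in YAML is parsed as a boolean
  mode <- match.arg(mode)
  theta_max <- as.numeric(theta_max)[1]
  if (!is.finite(theta_max) || theta_max < 0) abort("`theta_max` must be >= 0.")
  if (mode == "off") theta_max <- 0
  structure(list(theta_max = theta_max, mode = mode), class = "perturb_policy")
}

# Draw one perturbation under a policy, from a dedicated substream.
draw_perturbation <- function(policy, dim_noise, root_seed, index) {
  if (policy$mode == "off" || policy$theta_max == 0) {
    return(perturbation(rep(0, dim_noise), theta_max = policy$theta_max))
  }
  theta <- with_seed(
    rng_substream(root_seed, index, purpose = 1L),
    runif(dim_noise, -policy$theta_max, policy$theta_max)
  )
  perturbation(theta, theta_max = policy$theta_max)
}
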