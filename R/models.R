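#' Stochastic tumor growth under immune surveillance and chemotherapy
#'
#' One-dimensional Ito SDE for a tumor cell population `x` subject to
#' logistic growth, saturating immune-mediated kill, periodic chemotherapy
#' forcing, and multiplicative environmental noise:
#' `dx = [r0 x (1 - x/K) - beta x^2 / (1 + x^2) + x (1 - x/K) A0 cos(omega t)] dt
#'  + x (1 - x/K) dW`.
#' State 0 is absorbing (every term carries a factor `x`) and the noise
#' vanishes at the carrying capacity `K`.
#'
#' The original literature parameterisation is not redistributed here; the
#' defaults below are *placeholder values chosen by this package* to give
#' bistable desk-scale dynamics: for the defaults, stable equilibria near
#' x = 0.46 and x = 5.84 separated by an unstable threshold near x = 3.69.
#' Override every parameter for quantitative work.
#'
#' @param r0 Linear per-capita birth rate.
#' @param K Carrying capacity (> 0).
#' @param beta Strength of the immune-mediated kill term (>= 0).
#' @param A0 Amplitude of the periodic chemotherapy forcing (>= 0).
#' @param omega Angular frequency of the chemotherapy forcing.
#' @param x0 Initial tumor burden (>= 0, cells).
#' @return An [sde_model()] with variable `"x"`, clamped at 0.
#' @examples
#' m <- lefever_garay()
#' path <- sde_simulate(m, sim_grid(10, 0.01), seed = 1)
#' @export
lefever_garay <- function(r0 = 0.6, K = 10, beta = 1.5, A0 = 0.2,
                          omega = 1, x0 = 1) {
  stopifnot(K > 0, beta >= 0, A0 >= 0, x0 >= 0)
  drift <- function(t, x) {
    r0 * x * (1 - x / K) - beta * x^2 / (1 + x^2) +
      x * (1 - x / K) * A0 * cos(omega * t)
  }
  diffusion <- function(t, x) x * (1 - x / K)
  m <- sde_model(drift, diffusion, x0, "x", positive = TRUE)
  m$params <- list(r0 = r0, K = K, beta = beta, A0 = A0, omega = omega,
                   x0 = x0)
  m$name <- "lefever_garay"
  m
}

#' Immunogenic tumor model
#'
#' Coupled Ito SDEs for immune effector cells `x` and tumor cells `y`:
#' `dx = (a1 - a2 x + a3 x y) dt + (b11 (x - x1) + b12 (y - y1)) dW1`,
#' `dy = (b1 y (1 - b2 y) - x y) dt + (b21 (x - x1) + b22 (y - y1)) dW2`.
#' `(x1, y1)` is the stochastic equilibrium point: the noise amplitude
#' grows with the distance from it and vanishes exactly there. Tumor
#' extinction (`y = 0`) is absorbing in `y`.
#'
#' As for [lefever_garay()], the defaults are placeholder values chosen by
#' this package (they put an interior equilibrium at `(1.5, 1)`), not the
#' original literature values; override them for quantitative work.
#'
#' @param a1,a2,a3 Immune-cell kinetics: constant influx, per-capita decay,
#'   tumor-stimulated proliferation.
#' @param b1,b2 Tumor logistic kinetics: growth rate and inverse carrying
#'   capacity.
#' @param b11,b12,b21,b22 Noise couplings to the displacement from the
#'   equilibrium point.
#' @param x1_eq,y1_eq The stochastic equilibrium point.
#' @param x0,y0 Initial immune and tumor amounts (>= 0, units).
#' @return An [sde_model()] with variables `"x"`, `"y"`, clamped at 0.
#' @examples
#' m <- immunogenic()
#' path <- sde_simulate(m, sim_grid(10, 0.01), seed = 1)
#' @export
immunogenic <- function(a1 = 0.3, a2 = 0.5, a3 = 0.3, b1 = 2, b2 = 0.25,
                        b11 = 0.1, b12 = 0.05, b21 = 0.05, b22 = 0.1,
                        x1_eq = 1.5, y1_eq = 1, x0 = 0.1, y0 = 0.1) {
  stopifnot(is.finite(x1_eq), is.finite(y1_eq), x0 >= 0, y0 >= 0)
  drift <- function(t, x) {
    cbind(
      a1 - a2 * x[, 1] + a3 * x[, 1] * x[, 2],
      b1 * x[, 2] * (1 - b2 * x[, 2]) - x[, 1] * x[, 2]
    )
  }
  diffusion <- function(t, x) {
    cbind(
      b11 * (x[, 1] - x1_eq) + b12 * (x[, 2] - y1_eq),
      b21 * (x[, 1] - x1_eq) + b22 * (x[, 2] - y1_eq)
    )
  }
  m <- sde_model(drift, diffusion, c(x0, y0), c("x", "y"), positive = TRUE)
  m$params <- list(a1 = a1, a2 = a2, a3 = a3, b1 = b1, b2 = b2,
                   b11 = b11, b12 = b12, b21 = b21, b22 = b22,
                   x1_eq = x1_eq, y1_eq = y1_eq, x0 = x0, y0 = y0)
  m$name <- "immunogenic"
  m
}

#' Brownian barrier-crossing benchmark
#'
#' Standard Brownian motion `dX = dW`, `X0 = 0`, with the property
#' `F[t](x > a)` ("the barrier `a` is crossed within time `t`"). By the
#' reflection principle the exact satisfaction probability is
#' `2 (1 - Phi(a / sqrt(t)))`, so this benchmark validates the whole
#' pipeline against an analytic ground truth. With `a = 3`, `t = 1` the
#' crossing is a rare event (~0.0027). Discrete-time monitoring only sees
#' the grid points, so Monte-Carlo estimates undercount crossings by
#' O(sqrt(dt)).
#'
#' @param a Barrier height (> 0).
#' @param horizon Time bound `t` (> 0).
#' @return A list with elements `model` (an [sde_model()]), `formula`
#'   (parsed `F[horizon](x > a)`) and `prob` (the reflection-principle
#'   probability).
#' @examples
#' bb <- brownian_barrier(1, 1)
#' bb$prob # 2 * (1 - pnorm(1)) ~ 0.3173
#' @export
brownian_barrier <- function(a, horizon) {
  stopifnot(a > 0, horizon > 0)
  model <- sde_model(
    drift = function(t, x) 0 * x,
    diffusion = function(t, x) 0 * x + 1,
    initial_state = 0,
    variable_names = "x"
  )
  model$name <- "brownian_barrier"
  model$params <- list(a = a, horizon = horizon)
  list(
    model = model,
    formula = parse_formula(sprintf("F[%.17g](x > %.17g)", horizon, a)),
    prob = 2 * (1 - pnorm(a / sqrt(horizon)))
  )
}

# --- preset registry ------------------------------------------------------

preset_registry <- function() {
  list(
    lefever_rare = list(
      description = "Tumor escape: >= 1% chance the burden reaches 1e11 cells within 10 time units, from 1e9 cells (placeholder kinetics at cell-count scale).",
      model = function(r0 = 0.6, K = 1e12, beta = 1.2e9, A0 = 0.12,
                       omega = 1, x0 = 1e9) {
        lefever_garay(r0 = r0, K = K, beta = beta, A0 = A0, omega = omega,
                      x0 = x0)
      },
      formula = "F[10](x > 1e11)",
      theta0 = 0.01,
      grid = list(t_end = 10, dt = 0.01)
    ),
    immuno_rare = list(
      description = "Immunogenic model: >= 1% chance variable x exceeds 3.3 units within 10 time units, from 0.1 units each. The headline property is printed over x although the tumor population is y; set `target = \"y\"` in the formula yourself to monitor the tumor instead.",
      model = function(a1 = 0.3, a2 = 0.5, a3 = 0.3, b1 = 2, b2 = 0.25,
                       b11 = 0.1, b12 = 0.05, b21 = 0.05, b22 = 0.1,
                       x1_eq = 1.5, y1_eq = 1, x0 = 0.1, y0 = 0.1) {
        immunogenic(a1, a2, a3, b1, b2, b11, b12, b21, b22,
                    x1_eq, y1_eq, x0, y0)
      },
      formula = "F[10](x > 3.3)",
      theta0 = 0.01,
      grid = list(t_end = 10, dt = 0.01)
    ),
    brownian_barrier = list(
      description = "Analytic benchmark: Brownian motion crossing barrier a within horizon t (defaults a = 1, t = 1; crossing probability 2 * (1 - pnorm(a / sqrt(t)))).",
      model = function(a = 1, horizon = 1) brownian_barrier(a, horizon)$model,
      formula = "F[1](x > 1)",
      theta0 = 0.1,
      grid = list(t_end = 1, dt = 0.001)
    )
  )
}

#' List bundled model presets
#'
#' @return A tibble with preset names, default formulas and descriptions.
#' @examples
#' list_presets()
#' @export
list_presets <- function() {
  reg <- preset_registry()
  tibble::tibble(
    preset = names(reg),
    formula = vapply(reg, `[[`, character(1), "formula"),
    theta0 = vapply(reg, `[[`, numeric(1), "theta0"),
    description = vapply(reg, `[[`, character(1), "description")
  )
}

#' Retrieve a bundled preset
#'
#' @param name Preset name (see [list_presets()]).
#' @param overrides Named list of model parameter overrides passed to the
#'   preset's model constructor.
#' @return A list with `model`, `formula` (string), `theta0` and `grid`.
#' @examples
#' p <- get_preset("brownian_barrier")
#' p$model
#' @export
get_preset <- function(name, overrides = list()) {
  reg <- preset_registry()
  if (!name %in% names(reg)) {
    abort(sprintf(
      "unknown preset '%s'; available: %s.", name,
      paste(names(reg), collapse = ", ")
    ))
  }
  p <- reg[[name]]
  ctor <- p$model
  ok <- intersect(names(overrides), names(formals(ctor)))
  bad <- setdiff(names(overrides), names(formals(ctor)))
  if (length(bad)) {
    abort(sprintf(
      "unknown parameter(s) for preset '%s': %s.", name,
      paste(bad, collapse = ", ")
    ))
  }
  model <- do.call(ctor, overrides[ok])
  list(model = model, formula = p$formula, theta0 = p$theta0, grid = p$grid)
}
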