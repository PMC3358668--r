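# Outcome samplers for sequential_verify(). Each factory returns a closure
# of the 1-based sample index; all randomness is derived from the factory's
# seed via rng_substream(), so outcomes are reproducible independently of
# evaluation order or batching.

#' Bernoulli outcome stream
#'
#' I.i.d. Bernoulli(`p`) satisfaction outcomes; sample `i` is a
#' deterministic function of `(seed, i)`.
#'
#' @param p Success probability.
#' @param seed Integer root seed.
#' @return A sampler function for [sequential_verify()].
#' @examples
#' s <- bernoulli_sampler(0.3, seed = 7)
#' s(1)$outcome
#' @export
bernoulli_sampler <- function(p, seed) {
  stopifnot(p >= 0, p <= 1)
  function(i) {
    u <- with_seed(rng_substream(seed, i, purpose = 0L), runif(1))
    list(outcome = u < p, bias_factor = 1)
  }
}

#' Constant outcome stream
#'
#' Always-satisfying or never-satisfying streams; useful as analytic
#' fixtures (the stopping time then follows the closed-form Beta tail).
#'
#' @param outcome `TRUE` or `FALSE`.
#' @return A sampler function for [sequential_verify()].
#' @export
constant_sampler <- function(outcome) {
  force(outcome)
  function(i) list(outcome = outcome, bias_factor = 1)
}

#' SDE trajectory satisfaction sampler
#'
#' Draws sample `i` by (1) drawing a perturbation under `policy` from
#' substream `(seed, i, purpose = 1)`; (2) simulating one Euler-Maruyama
#' trajectory whose Brownian increments come from substream
#' `(seed, i, purpose = 0)`; (3) monitoring the trace against `formula`.
#' With `policy` mode `"off"` this is i.i.d. sampling under the natural
#' measure; with `"symmetric_uniform"` each trajectory gets an independent
#' constant Girsanov drift shift drawn uniformly from
#' `[-theta_max, theta_max]` per Brownian component.
#'
#' Trajectories are simulated in blocks of `block_size` for speed; because
#' every trajectory is tied to its own substream, the outcomes are
#' identical to one-at-a-time simulation.
#'
#' @param model An [sde_model()].
#' @param formula A `bltl_formula` or formula string.
#' @param grid A [sim_grid()].
#' @param policy A [perturb_policy()].
#' @param seed Integer root seed.
#' @param block_size Number of trajectories simulated per batch.
#' @return A sampler function for [sequential_verify()]; each call returns
#'   `list(outcome, theta, log_weight)`.
#' @examples
#' bm <- sde_model(function(t, x) 0 * x, function(t, x) 0 * x + 1, 0, "x")
#' s <- sde_sampler(bm, "F[1](x > 1)", sim_grid(1, 0.02), seed = 1)
#' s(1)$outcome
#' @export
sde_sampler <- function(model, formula, grid, policy = perturb_policy(),
                        seed, block_size = 64L) {
  stopifnot(inherits(model, "sde_model"), inherits(grid, "sim_grid"),
            inherits(policy, "perturb_policy"))
  if (is.character(formula)) formula <- parse_formula(formula)
  unknown <- setdiff(formula_variables(formula), model$variable_names)
  if (length(unknown)) {
    abort(sprintf(
      "formula refers to variable(s) %s not present in the model (%s).",
      paste0("'", unknown, "'", collapse = ", "),
      paste(model$variable_names, collapse = ", ")
    ))
  }
  if (formula_horizon(formula) > grid$t_end) {
    warn(sprintf(
      "formula time bound (%g) exceeds the simulated horizon (%g): verdicts may be artifacts of the truncation.",
      formula_horizon(formula), grid$t_end
    ))
  }
  block_size <- max(1L, as.integer(block_size))
  durations <- c(rep(grid$dt, grid$n_steps), 0)
  cache <- new.env(parent = emptyenv())
  cache$start <- 0L # indices start+1 .. start+k are cached
  cache$samples <- list()

  function(i) {
    k <- i - cache$start
    if (k < 1L || k > length(cache$samples)) {
      idx <- seq.int(i, i + block_size - 1L)
      perts <- lapply(idx, function(j) {
        draw_perturbation(policy, model$dim_noise, seed, j)
      })
      thetas <- do.call(rbind, lapply(perts, `[[`, "theta"))
      seeds <- lapply(idx, function(j) rng_substream(seed, j, purpose = 0L))
      blk <- simulate_block(model, grid, thetas, seeds)
      cache$start <- i - 1L
      cache$samples <- lapply(seq_along(idx), function(r) {
        st <- blk$states[r, , ]
        dim(st) <- c(grid$n_steps + 1L, model$dim_state)
        tr <- structure(
          list(
            states = st,
            durations = durations,
            variable_names = model$variable_names
          ),
          class = "bltl_trace"
        )
        list(
          outcome = as.logical(bltl_eval_all(formula, tr)[[1L]]),
          theta = perts[[r]]$theta,
          log_weight = blk$log_weights[[r]]
        )
      })
      k <- 1L
    }
    cache$samples[[k]]
  }
}
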