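#' Monte-Carlo estimate of a satisfaction probability
#'
#' Plain i.i.d. estimation of `Pr(sigma |= formula)` under the natural
#' measure: simulates `n_paths` independent Euler-Maruyama trajectories,
#' monitors each against the formula, and returns the empirical
#' satisfaction frequency with its binomial standard error. Path `i` uses
#' substream `(seed, i)`, so estimates are reproducible and independent of
#' `block_size`.
#'
#' @inheritParams sde_sampler
#' @param n_paths Number of trajectories.
#' @param block_size Trajectories simulated per batch (memory/speed
#'   trade-off; does not affect the result).
#' @return A one-row tibble: `estimate`, `se`, `n_satisfied`, `n_paths`.
#' @examples
#' bb <- brownian_barrier(1, 1)
#' estimate_probability(bb$model, bb$formula, sim_grid(1, 0.01),
#'                      n_paths = 200, seed = 1)
#' @export
estimate_probability <- function(model, formula, grid, n_paths, seed,
                                 block_size = 2000L) {
  stopifnot(inherits(model, "sde_model"), inherits(grid, "sim_grid"))
  if (is.character(formula)) formula <- parse_formula(formula)
  unknown <- setdiff(formula_variables(formula), model$variable_names)
  if (length(unknown)) {
    abort(sprintf(
      "formula refers to variable(s) %s not present in the model.",
      paste0("'", unknown, "'", collapse = ", ")
    ))
  }
  n_paths <- as.integer(n_paths)
  block_size <- max(1L, as.integer(block_size))
  durations <- c(rep(grid$dt, grid$n_steps), 0)
  d <- model$dim_state
  n_sat <- 0L
  done <- 0L
  zero_theta <- rep(0, d)
  while (done < n_paths) {
    nb <- min(block_size, n_paths - done)
    idx <- done + seq_len(nb)
    seeds <- lapply(idx, function(j) rng_substream(seed, j, purpose = 0L))
    blk <- simulate_block(
      model, grid, matrix(zero_theta, nb, d, byrow = TRUE), seeds
    )
    for (r in seq_len(nb)) {
      st <- blk$states[r, , ]
      dim(st) <- c(grid$n_steps + 1L, d)
      tr <- structure(
        list(
          states = st,
          durations = durations,
          variable_names = model$variable_names
        ),
        class = "bltl_trace"
      )
      n_sat <- n_sat + as.integer(bltl_eval_all(formula, tr)[[1L]])
    }
    done <- done + nb
  }
  est <- n_sat / n_paths
  tibble::tibble(
    estimate = est,
    se = sqrt(est * (1 - est) / n_paths),
    n_satisfied = n_sat,
    n_paths = n_paths
  )
}
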