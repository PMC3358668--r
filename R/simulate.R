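# Core Euler-Maruyama engine, vectorised across a block of trajectories.
#
# Each path i draws its Brownian increments from its own substream seed, so
# block simulation is bit-identical to simulating paths one at a time. Raw
# draws are Normal(0, dt) increments of the *natural* Brownian motion; the
# perturbed increments actually fed to the scheme are dW + theta * dt.
#
# Returns: list(times, states [n_paths x (n_steps+1) x d], increments_hat
# [n_paths x n_steps x d], log_weights, clamp_counts, thetas [n_paths x d]).
simulate_block <- function(model, grid, thetas, seeds) {
  d <- model$dim_state
  n_steps <- grid$n_steps
  dt <- grid$dt
  n_paths <- length(seeds)
  if (is.null(dim(thetas))) thetas <- matrix(thetas, n_paths, d, byrow = TRUE)
  if (ncol(thetas) != d || nrow(thetas) != n_paths) {
    abort("perturbation dimension does not match the model's noise dimension.")
  }

  sd_dt <- sqrt(dt)
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  if (d == 1L) {
    return(simulate_block_1d(model, grid, thetas, seeds, times, sd_dt))
  }
  dW <- array(NA_real_, c(n_paths, n_steps, d))
  for (i in seq_len(n_paths)) {
    dW[i, , ] <- with_seed(seeds[[i]], rnorm(n_steps * d, sd = sd_dt))
  }
  states <- array(NA_real_, c(n_paths, n_steps + 1L, d))
  X <- matrix(model$initial_state, n_paths, d, byrow = TRUE)
  states[, 1L, ] <- X
  clamp_counts <- integer(n_paths)
  theta_dt <- thetas * dt

  for (k in seq_len(n_steps)) {
    tk <- times[[k]]
    B <- model$drift(tk, X)
    V <- model$diffusion(tk, X)
    dWhat_k <- matrix(dW[, k, ], n_paths, d) + theta_dt
    X <- X + B * dt + V * dWhat_k
    if (anyNA(X) || !all(is.finite(X))) {
      bad <- which(!apply(is.finite(X), 1L, all))[1]
      abort(sprintf(
        "non-finite state at step %d (t = %g) in trajectory %d; reduce `dt` or check the model coefficients.",
        k, times[[k + 1L]], bad
      ))
    }
    if (model$positive) {
      neg <- X < 0
      if (any(neg)) {
        clamp_counts <- clamp_counts + as.integer(rowSums(neg))
        X[neg] <- 0
      }
    }
    states[, k + 1L, ] <- X
  }

  # log Z_T = -sum_k theta . dW_k - |theta|^2 T / 2, on the natural increments
  t_total <- n_steps * dt
  W_sum <- vapply(
    seq_len(d),
    function(j) rowSums(matrix(dW[, , j], n_paths, n_steps)),
    numeric(n_paths)
  )
  W_sum <- matrix(W_sum, n_paths, d)
  log_weights <- -rowSums(W_sum * thetas) - rowSums(thetas^2) * t_total / 2

  increments_hat <- dW
  for (j in seq_len(d)) {
    increments_hat[, , j] <- increments_hat[, , j] + thetas[, j] * dt
  }

  list(
    times = times, states = states, increments_hat = increments_hat,
    log_weights = log_weights, clamp_counts = clamp_counts, thetas = thetas
  )
}

# One-dimensional specialisation: identical draws and arithmetic, but flat
# matrices instead of 3-d arrays (avoids a per-step copy).
simulate_block_1d <- function(model, grid, thetas, seeds, times, sd_dt) {
  n_steps <- grid$n_steps
  dt <- grid$dt
  n_paths <- length(seeds)
  theta <- thetas[, 1L]

  dW <- matrix(NA_real_, n_paths, n_steps)
  for (i in seq_len(n_paths)) {
    dW[i, ] <- with_seed(seeds[[i]], rnorm(n_steps, sd = sd_dt))
  }

  states <- matrix(NA_real_, n_paths, n_steps + 1L)
  X <- matrix(model$initial_state, n_paths, 1L)
  states[, 1L] <- X
  clamp_counts <- integer(n_paths)
  theta_dt <- theta * dt
  positive <- model$positive

  for (k in seq_len(n_steps)) {
    tk <- times[[k]]
    B <- model$drift(tk, X)
    V <- model$diffusion(tk, X)
    X <- X + B * dt + V * (dW[, k] + theta_dt)
    if (anyNA(X) || !all(is.finite(X))) {
      bad <- which(!is.finite(X))[1]
      abort(sprintf(
        "non-finite state at step %d (t = %g) in trajectory %d; reduce `dt` or check the model coefficients.",
        k, times[[k + 1L]], bad
      ))
    }
    if (positive) {
      neg <- X < 0
      if (any(neg)) {
        clamp_counts <- clamp_counts + as.integer(neg)
        X[neg] <- 0
      }
    }
    states[, k + 1L] <- X
  }

  t_total <- n_steps * dt
  log_weights <- -(rowSums(dW) * theta) - theta^2 * t_total / 2
  increments_hat <- dW + theta_dt
  dim(states) <- c(n_paths, n_steps + 1L, 1L)
  dim(increments_hat) <- c(n_paths, n_steps, 1L)

  list(
    times = times, states = states, increments_hat = increments_hat,
    log_weights = log_weights, clamp_counts = clamp_counts, thetas = thetas
  )
}

#' Simulate one SDE trajectory
#'
#' Integrates the model with the fixed-step Euler-Maruyama scheme
#' `X[k+1] = X[k] + b(t_k, X_k) dt + v(t_k, X_k) dW_hat_k`, where under a
#' perturbation the increments `dW_hat_k = dW_k + theta * dt` carry the
#' Girsanov drift shift. The log change-of-measure weight
#' `log Z_T = -sum_k theta . dW_k - |theta|^2 T / 2` of the sampled path
#' (with respect to the natural measure) is attached to the result.
#'
#' The trajectory is a deterministic function of
#' `(model, grid, perturbation, seed)`.
#'
#' @param model An [sde_model()].
#' @param grid A [sim_grid()].
#' @param perturbation A [perturbation()] or `NULL` for the natural measure.
#' @param seed Integer seed for this trajectory's Brownian increments.
#' @return A tibble of class `sde_trajectory` with a `time` column and one
#'   column per state variable, plus attributes `log_weight`,
#'   `brownian_increments` (the perturbed increments actually used),
#'   `perturbation`, `clamp_count` and `seed`.
#' @examples
#' bm <- sde_model(function(t, x) 0 * x, function(t, x) 0 * x + 1, 0, "x")
#' path <- sde_simulate(bm, sim_grid(1, 0.01), seed = 1)
#' attr(path, "log_weight") # 0 under the natural measure
#' @export
sde_simulate <- function(model, grid, perturbation = NULL, seed) {
  stopifnot(inherits(model, "sde_model"), inherits(grid, "sim_grid"))
  if (is.null(perturbation)) perturbation <- perturbation(rep(0, model$dim_noise))
  theta <- perturbation$theta
  if (length(theta) == 1L) theta <- rep(theta, model$dim_noise)
  if (length(theta) != model$dim_noise) {
    abort(sprintf(
      "perturbation has %d component(s) but the model has %d Brownian motion(s).",
      length(theta), model$dim_noise
    ))
  }
  blk <- simulate_block(model, grid, matrix(theta, 1L), list(seed))
  d <- model$dim_state
  out <- tibble::as_tibble(
    c(
      list(time = blk$times),
      stats::setNames(
        lapply(seq_len(d), function(j) blk$states[1L, , j]),
        model$variable_names
      )
    )
  )
  structure(
    out,
    log_weight = blk$log_weights[[1L]],
    brownian_increments = matrix(blk$increments_hat[1L, , ], grid$n_steps, d),
    perturbation = perturbation,
    clamp_count = blk$clamp_counts[[1L]],
    seed = seed,
    class = c("sde_trajectory", class(out))
  )
}

#' Girsanov exponential-martingale log weight
#'
#' For a constant drift shift `theta`, the Radon-Nikodym derivative of the
#' perturbed measure with respect to the natural one along a path is the
#' exponential martingale `Z_T = exp(-sum_k theta . dW_k - |theta|^2 T / 2)`,
#' where `dW_k` are the *natural*-measure Brownian increments (recovered
#' from the perturbed ones as `dW_hat_k - theta * dt`). Under the natural
#' measure `E[Z_T] = 1`.
#'
#' @param perturbation A [perturbation()].
#' @param brownian_increments Numeric matrix (`n_steps` x `dim_noise`) of
#'   natural-measure increments; a vector is treated as one column.
#' @param dt Step size used to generate the increments (> 0).
#' @return The scalar `log Z_T`; exactly 0 when `theta = 0`.
#' @examples
#' p <- perturbation(1)
#' # increments summing to W_T = 0 over T = 1: log Z = -0.5
#' girsanov_log_weight(p, matrix(c(0.5, -0.5), 2, 1), dt = 0.5)
#' @export
girsanov_log_weight <- function(perturbation, brownian_increments, dt) {
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be positive.")
  if (is.null(dim(brownian_increments))) {
    brownian_increments <- matrix(brownian_increments, ncol = 1L)
  }
  theta <- perturbation$theta
  if (length(theta) == 1L && ncol(brownian_increments) > 1L) {
    theta <- rep(theta, ncol(brownian_increments))
  }
  if (length(theta) != ncol(brownian_increments)) {
    abort("perturbation and increment dimensions do not match.")
  }
  if (all(theta == 0)) return(0)
  t_total <- nrow(brownian_increments) * dt
  -sum(colSums(brownian_increments) * theta) - sum(theta^2) * t_total / 2
}

#' Finite timed trace
#'
#' The object consumed by the BLTL monitor: a finite alternating sequence of
#' states and durations `(s_0, delta_0), (s_1, delta_1), ...`. The duration
#' of a state is the time spent in it before the next state is reached.
#'
#' @param states Numeric matrix with one row per state, or a vector for a
#'   one-variable trace.
#' @param durations Non-negative numeric vector, one duration per state.
#' @param variable_names Names of the state variables (columns).
#' @return An object of class `bltl_trace`.
#' @examples
#' bltl_trace(c(0, 0, 20), c(4, 1, 0), "x")
#' @export
bltl_trace <- function(states, durations, variable_names = NULL) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1L)
  states <- as.matrix(states)
  durations <- as.numeric(durations)
  if (is.null(variable_names)) {
    variable_names <- colnames(states) %||%
      (if (ncol(states) == 1L) "x" else paste0("x", seq_len(ncol(states))))
  }
  if (nrow(states) < 1L || length(durations) != nrow(states)) {
    abort("need one duration per state and at least one state.")
  }
  if (anyNA(durations) || any(durations < 0) || any(!is.finite(durations))) {
    abort("durations must be finite and >= 0.")
  }
  colnames(states) <- variable_names
  structure(
    list(states = states, durations = durations,
         variable_names = as.character(variable_names)),
    class = "bltl_trace"
  )
}

#' @export
print.bltl_trace <- function(x, ...) {
  cat(sprintf(
    "<bltl_trace> %d states of (%s), total duration %g\n",
    nrow(x$states), paste(x$variable_names, collapse = ", "),
    sum(x$durations)
  ))
  invisible(x)
}

#' Convert a simulated trajectory to a monitorable trace
#'
#' Every state carries the integration step `dt` as its duration except the
#' last, which carries 0 (nothing is observed beyond the horizon).
#'
#' @param x Object to convert (an `sde_trajectory`, or anything with a
#'   `time` column and variable columns).
#' @param ... Passed to methods.
#' @return A [bltl_trace()].
#' @export
as_trace <- function(x, ...) UseMethod("as_trace")

#' @export
as_trace.bltl_trace <- function(x, ...) x

#' @rdname as_trace
#' @export
as_trace.data.frame <- function(x, ...) {
  if (!"time" %in% names(x)) abort("expected a `time` column.")
  vars <- setdiff(names(x), "time")
  times <- x$time
  n <- nrow(x)
  durations <- c(diff(times), 0)
  bltl_trace(as.matrix(x[vars]), durations, vars)
}

#' Write a trajectory to CSV
#'
#' Columns are `time`, one per state variable, then `log_weight`, which is
#' populated on the final row only (it is a per-path, end-of-horizon
#' quantity).
#'
#' @param trajectory An `sde_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sde_trajectory"))
  df <- as.data.frame(trajectory)
  lw <- rep("", nrow(df))
  lw[nrow(df)] <- format(attr(trajectory, "log_weight"), digits = 17)
  df$log_weight <- lw
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a simulated trajectory
#'
#' One line per state variable against time.
#'
#' @param object An `sde_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sde_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"time",
    names_to = "variable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (model units)", y = "state") +
    ggplot2::theme_minimal()
}
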