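test_that("degenerate coefficients reproduce exact Euler sums", {
  # zero drift, zero noise: constant at the initial state, weight 0
  zero <- sde_model(function(t, x) 0 * x, function(t, x) 0 * x, 2.5, "x")
  path <- sde_simulate(zero, sim_grid(1, 0.1), seed = 1)
  expect_true(all(path$x == 2.5))
  expect_identical(attr(path, "log_weight"), 0)

  # pure unit drift: final state is initial + t_end exactly
  drift1 <- sde_model(function(t, x) 0 * x + 1, function(t, x) 0 * x, 0, "x")
  path <- sde_simulate(drift1, sim_grid(1, 0.1), seed = 99)
  expect_equal(tail(path$x, 1), 1, tolerance = 1e-12)
})

test_that("simulation is bit-identical given (model, grid, perturbation, seed)", {
  m <- lefever_garay()
  g <- sim_grid(2, 0.01)
  p <- perturbation(0.3, theta_max = 1)
  a <- sde_simulate(m, g, p, seed = 7)
  b <- sde_simulate(m, g, p, seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(attr(a, "log_weight"), attr(b, "log_weight"))
  expect_identical(attr(a, "brownian_increments"), attr(b, "brownian_increments"))
})

test_that("block simulation matches one-at-a-time simulation exactly", {
  m <- immunogenic()
  g <- sim_grid(1, 0.05)
  seeds <- lapply(1:5, function(i) rng_substream(3, i))
  thetas <- matrix(seq(-0.5, 0.5, length.out = 10), 5, 2)
  blk <- sdemc:::simulate_block(m, g, thetas, seeds)
  for (i in 1:5) {
    single <- sde_simulate(m, g, perturbation(thetas[i, ], theta_max = 1),
                           seed = seeds[[i]])
    expect_equal(blk$states[i, , 1], single$x, tolerance = 0)
    expect_equal(blk$states[i, , 2], single$y, tolerance = 0)
    expect_identical(blk$log_weights[[i]], attr(single, "log_weight"))
  }
})

test_that("girsanov weight follows the closed form", {
  expect_identical(girsanov_log_weight(perturbation(0), rnorm(50), 0.1), 0)
  # theta = 1, increments summing to W_T = 0 over T = 1: -theta*W - theta^2*T/2
  w <- girsanov_log_weight(perturbation(1), matrix(c(0.5, -0.5), 2, 1), 0.5)
  expect_equal(w, -0.5, tolerance = 1e-15)
  # generic increments: explicit formula, multi-component
  dw <- matrix(c(0.1, -0.2, 0.3, 0.05, 0, -0.1), 3, 2)
  th <- c(0.5, -1)
  expect_equal(
    girsanov_log_weight(perturbation(th, theta_max = 1), dw, 0.2),
    -sum(colSums(dw) * th) - sum(th^2) * 0.6 / 2,
    tolerance = 1e-14
  )
  expect_error(girsanov_log_weight(perturbation(1), dw[, 1], 0), "positive")
})

test_that("exp(log weight) is a martingale with mean 1 under the natural measure", {
  m <- brownian_model()
  g <- sim_grid(1, 0.01)
  seeds <- lapply(1:20000, function(i) rng_substream(11, i))
  blk <- sdemc:::simulate_block(m, g, matrix(0.8, 20000, 1), seeds)
  z <- exp(blk$log_weights)
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - 1), 4 * se)
})

test_that("a constant drift shift produces Normal(theta*T, T) terminal states", {
  m <- brownian_model()
  g <- sim_grid(1, 0.01)
  theta <- 0.7
  seeds <- lapply(1:10000, function(i) rng_substream(13, i))
  blk <- sdemc:::simulate_block(m, g, matrix(theta, 10000, 1), seeds)
  xT <- blk$states[, g$n_steps + 1, 1]
  ks <- suppressWarnings(stats::ks.test(xT, "pnorm", mean = theta, sd = 1))
  expect_gt(ks$p.value, 0.001)
})

test_that("theta = 0 and a zero-width symmetric policy give identical streams", {
  m <- brownian_model()
  g <- sim_grid(1, 0.05)
  f <- parse_formula("F[1](x > 0.5)")
  s_off <- sde_sampler(m, f, g, perturb_policy(0, "off"), seed = 21)
  s_sym <- sde_sampler(m, f, g, perturb_policy(0, "symmetric_uniform"), seed = 21)
  out_off <- vapply(1:50, function(i) s_off(i)$outcome, logical(1))
  out_sym <- vapply(1:50, function(i) s_sym(i)$outcome, logical(1))
  expect_identical(out_off, out_sym)
})

test_that("divergent states abort with the failing step index", {
  explode <- sde_model(function(t, x) x^3, function(t, x) 0 * x, 10, "x")
  expect_error(
    sde_simulate(explode, sim_grid(1, 0.1), seed = 1),
    "non-finite state at step"
  )
})

test_that("dimension mismatches are configuration errors", {
  m <- immunogenic()
  expect_error(
    sde_simulate(m, sim_grid(1, 0.1), perturbation(c(1, 1, 1), theta_max = 1),
                 seed = 1),
    "Brownian motion"
  )
  expect_error(sim_grid(1, 2), "dt")
  expect_error(sim_grid(-1, 0.1), "positive")
})

test_that("trajectories convert to traces with step durations and 0 at the end", {
  m <- brownian_model()
  path <- sde_simulate(m, sim_grid(0.3, 0.1), seed = 2)
  tr <- as_trace(path)
  expect_equal(nrow(tr$states), 4)
  expect_equal(tr$durations, c(0.1, 0.1, 0.1, 0))
  expect_identical(tr$states[, 1], path$x)

  m2 <- immunogenic()
  path2 <- sde_simulate(m2, sim_grid(0.2, 0.1), seed = 2)
  tr2 <- as_trace(path2)
  expect_identical(tr2$states[[2, 2]], path2$y[[2]])
  expect_error(bltl_satisfies(tr2, "z > 0"), "variable 'z'")
})

test_that("trajectory CSV carries the weight on the final row only", {
  m <- brownian_model()
  path <- sde_simulate(m, sim_grid(0.3, 0.1), perturbation(0.5, 1), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(path, f)
  lines <- readLines(f)
  expect_identical(lines[1], "time,x,log_weight")
  body <- read.csv(f, colClasses = c("numeric", "numeric", "character"))
  expect_identical(body$log_weight[1:3], rep("", 3))
  expect_equal(as.numeric(body$log_weight[4]), attr(path, "log_weight"))
})
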