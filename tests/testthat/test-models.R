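test_that("tumor extinction is absorbing and noise vanishes where it should", {
  lg <- lefever_garay()
  x0 <- matrix(0, 3, 1)
  xK <- matrix(lg$params$K, 3, 1)
  for (t in c(0, 1.3, 10)) {
    expect_true(all(lg$drift(t, x0) == 0))
    expect_true(all(lg$diffusion(t, x0) == 0))
    expect_true(all(lg$diffusion(t, xK) == 0))
  }

  im <- immunogenic()
  eq <- matrix(c(im$params$x1_eq, im$params$y1_eq), 1, 2)
  expect_true(all(im$diffusion(0, eq) == 0))
  # y = 0 is absorbing in y for any x
  st <- cbind(c(0, 0.5, 3), 0)
  expect_true(all(im$drift(0, st)[, 2] == 0))
})

test_that("the noise-free tumor model follows the logistic closed form", {
  lg <- lefever_garay(r0 = 1, K = 1, beta = 0, A0 = 0, x0 = 0.01)
  noiseless <- sde_model(lg$drift, function(t, x) 0 * x, 0.01, "x")
  path <- sde_simulate(noiseless, sim_grid(10, 1e-3), seed = 1)
  logistic <- function(t) 1 * 0.01 * exp(t) / (1 + 0.01 * (exp(t) - 1))
  expect_lt(max(abs(path$x - logistic(path$time))), 5e-3)
})

test_that("the deterministic immunogenic system settles on the y-nullcline", {
  im <- immunogenic(b11 = 0, b12 = 0, b21 = 0, b22 = 0, x0 = 1.2, y0 = 0.8)
  path <- sde_simulate(im, sim_grid(200, 1e-2), seed = 1)
  xf <- tail(path$x, 1)
  yf <- tail(path$y, 1)
  expect_gt(yf, 0) # interior fixed point, not extinction
  # y-nullcline: b1 (1 - b2 y) = x at any interior fixed point
  expect_equal(im$params$b1 * (1 - im$params$b2 * yf), xf, tolerance = 1e-3)
})

test_that("clamped tumor simulations stay non-negative and finite", {
  g <- sim_grid(5, 1e-3)
  for (m in list(lefever_garay(), immunogenic())) {
    seeds <- lapply(1:2000, function(i) rng_substream(77, i))
    blk <- sdemc:::simulate_block(
      m, g, matrix(0, 2000, m$dim_noise), seeds
    )
    expect_true(all(is.finite(blk$states)))
    expect_true(all(blk$states >= 0))
  }
})

test_that("the barrier benchmark returns the reflection-principle probability", {
  bb <- brownian_barrier(1, 1)
  expect_equal(bb$prob, 2 * (1 - pnorm(1)), tolerance = 1e-15)
  expect_equal(bb$prob, 0.3173105, tolerance = 1e-6)
  expect_equal(brownian_barrier(3, 1)$prob, 0.0026998, tolerance = 1e-4)
  expect_lt(brownian_barrier(40, 1)$prob, 1e-100)
  expect_identical(format(bb$formula), "F[1](x > 1)")
})

test_that("presets are registered and overridable", {
  ps <- list_presets()
  expect_setequal(
    ps$preset, c("lefever_rare", "immuno_rare", "brownian_barrier")
  )
  lef <- get_preset("lefever_rare")
  expect_identical(lef$formula, "F[10](x > 1e11)")
  expect_identical(lef$theta0, 0.01)
  expect_equal(lef$model$initial_state, 1e9)
  imm <- get_preset("immuno_rare", overrides = list(y0 = 0.5))
  expect_identical(imm$formula, "F[10](x > 3.3)")
  expect_equal(imm$model$initial_state, c(0.1, 0.5))
  expect_error(get_preset("nope"), "unknown preset")
  expect_error(get_preset("immuno_rare", list(zz = 1)), "unknown parameter")
})

test_that("the toy measure pair exposes exact Radon-Nikodym ratios", {
  same <- toy_fixture(1, 0.1)
  expect_identical(same$p_natural, same$p_biased)
  tf <- toy_fixture(10, 1e-3)
  expect_equal(tf$p_biased[1], 1e-2, tolerance = 1e-15)
  expect_equal(tf$ratio[1], 10, tolerance = 1e-12)
  expect_equal(sum(tf$p_natural), 1)
  expect_equal(sum(tf$p_biased), 1)
  # cap at 1/2 keeps the measures proper
  capped <- toy_fixture(10, 0.2)
  expect_equal(capped$p_biased[1], 0.5)
  expect_error(toy_fixture(0.5, 0.1), ">= 1")
  expect_error(toy_fixture(2, 0.7), "p_rare")
})

test_that("empirical toy frequencies converge to the declared ratios", {
  tf <- toy_fixture(4, 0.05)
  nat <- toy_sampler(tf, "natural", seed = 1)
  bia <- toy_sampler(tf, "biased", seed = 2)
  n <- 2e4
  hits_nat <- mean(vapply(1:n, function(i) nat(i)$outcome, logical(1)))
  hits_bia <- mean(vapply(1:n, function(i) bia(i)$outcome, logical(1)))
  # natural ~ 0.05, biased ~ 0.20; ratio ~ declared 4
  expect_lt(abs(hits_nat - 0.05), 4 * sqrt(0.05 * 0.95 / n))
  expect_lt(abs(hits_bia - 0.20), 4 * sqrt(0.2 * 0.8 / n))
  # reported bias factors are the exact per-outcome ratios
  s <- bia(1)
  expect_equal(s$bias_factor,
               if (s$outcome) tf$ratio[1] else tf$ratio[2],
               tolerance = 1e-12)
})

test_that("symmetric toy sampling keeps the realised bias factors eta-bounded", {
  # The realised geometric mean concentrates near exp of the sampling-measure
  # average of KL(mu_i || mu), which is > 1 even for a direction-symmetric
  # policy; eta must absorb that offset (~1.03 for c = 2, p = 0.1).
  tf <- toy_fixture(2, 0.1)
  sym <- toy_sampler(tf, "symmetric", seed = 3)
  draws <- lapply(1:4000, sym)
  factors <- vapply(draws, `[[`, numeric(1), "bias_factor")
  expect_true(check_fairness(factors, eta = 1.1))
  # while the one-sided biased stream is grossly unfair at the same eta
  bia <- toy_sampler(toy_fixture(4, 0.05), "biased", seed = 4)
  f2 <- vapply(lapply(1:4000, bia), `[[`, numeric(1), "bias_factor")
  expect_false(check_fairness(f2, eta = 1.1))
})
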