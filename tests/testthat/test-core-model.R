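test_that("parameter and noise constructors enforce their invariants", {
  expect_error(pe_params(lambda = 0), "lambda")
  expect_error(pe_params(lambda = 1.2))
  expect_error(pe_params(alpha = 1.5))
  expect_error(pe_params(sigma = -1))
  expect_error(pe_params(mu_low = 10, mu_high = -10))
  expect_error(pe_noise(sigma_g = -1))
  p <- pe_params()
  expect_equal(p$sigma, 0.2868 * 360 / (2 * pi))
})

test_that("Gaussian tuning peaks at the preferred PE and is symmetric", {
  p <- pe_params(n_primitives = 25)
  pop <- pe_population(p)
  i <- 13
  expect_equal(tuning_activities(pop, pop$mu[i])[i], 1)
  expect_equal(tuning_activities(pop, pop$mu[i] + p$sigma)[i], exp(-1 / 2))
  for (d in c(3, 11.5, 40)) {
    expect_equal(tuning_activities(pop, pop$mu[i] + d)[i],
                 tuning_activities(pop, pop$mu[i] - d)[i])
  }
  expect_error(tuning_activities(pop, NaN), "finite")
  expect_error(tuning_activities(pop, Inf), "finite")
})

test_that("tuning and readout are invariant to primitive ordering", {
  p <- pe_params(n_primitives = 40)
  pop <- pe_population(p)
  perm <- sample(40)
  pop2 <- pop
  pop2$mu <- pop$mu[perm]
  a1 <- tuning_activities(pop, 12.3)
  a2 <- tuning_activities(pop2, 12.3)
  expect_equal(a2, a1[perm])
  w <- rnorm(40)
  expect_equal(motor_command(w[perm], a2), motor_command(w, a1))
})

test_that("motor command is the weighted activity sum", {
  expect_equal(motor_command(numeric(5), runif(5)), 0)
  expect_equal(motor_command(2, 0.5), 1)
  w <- rnorm(8); a <- runif(8)
  expect_equal(motor_command(3 * w, a), 3 * motor_command(w, a))
  expect_error(motor_command(1:3, 1:4), "length")
})

test_that("movement error follows the trial mode", {
  expect_equal(movement_error(30, 30, "normal"), 0)
  expect_equal(movement_error(17, 99, "error_clamp"), 0)
  # channel trials: the command is forcibly 0, so the error is the rotation
  expect_equal(movement_error(30, 10, "channel"), 30)
  expect_error(movement_error(0, 0, "jump"), "unknown trial mode")
})

test_that("the PE update moves a fraction alpha towards the error", {
  expect_equal(update_pe(0, 30, 0.8), 24)
  expect_equal(update_pe(5, 42, 1), 42)
  expect_equal(update_pe(5, 42, 0), 5)
  expect_error(update_pe(0, 0, 1.5))
})

test_that("weight update combines forgetting and error-scaled activity", {
  w <- rnorm(6); a <- runif(6)
  expect_equal(update_weights(w, 10, a, 1, 0), w)
  expect_equal(update_weights(w, 0, a, 0.9, 2), 0.9 * w)
  expect_equal(update_weights(0, 30, 1, 0.9586, 2.3913), 71.739)
  expect_error(update_weights(1:3, 1, 1:2, 1, 1), "length")
})

test_that("step_trial is a fixed point at zero and unrolls by hand", {
  p <- ref_params()
  pop <- pe_population(p)
  st <- pe_state(length(pop$mu))

  s0 <- step_trial(st, 0, "normal", p, pop)
  expect_equal(s0$record$x, 0)
  expect_equal(s0$record$e, 0)
  expect_equal(s0$state$weights, st$weights)
  expect_equal(s0$state$pe_hat, 0)

  # one step: e = 30, PE -> alpha * 30, weights = eta * 30 * A(0) / norm
  s1 <- step_trial(st, 30, "normal", p, pop)
  expect_equal(s1$record$e, 30)
  expect_equal(s1$state$pe_hat, p$alpha * 30)
  expect_equal(s1$state$weights,
               p$eta * 30 * tuning_activities(pop, 0, normalized = TRUE))

  # two steps against an independent scalar unroll: the second command is
  # eta * 30 * c0 * exp(-(alpha*30)^2 / (4 sigma^2)) in the large-N limit
  s2 <- step_trial(s1$state, 30, "normal", p, pop)
  x2_oracle <- p$eta * 30 * pop_c0(p) *
    exp(-(p$alpha * 30)^2 / (4 * p$sigma^2))
  expect_equal(s2$record$x, x2_oracle, tolerance = 1e-6)
})

test_that("population inner product matches its Gaussian closed form", {
  p <- pe_params(sigma = 16.434, n_primitives = 4096,
                 mu_low = -1080, mu_high = 1080)
  pop <- pe_population(p)
  # shape: ratio to delta = 0 value is exp(-delta^2 / (4 sigma^2))
  ip0 <- inner_product(pop, 0, 0)
  expect_equal(inner_product(pop, 0, 2 * p$sigma) / ip0, exp(-1),
               tolerance = 1e-3)
  for (d in c(-90, -45, -10, 0, 25, 60, 90)) {
    expect_equal(
      inner_product(pop, 0, d) /
        inner_product_closed_form(d, p$sigma, pop$density),
      1, tolerance = 0.01
    )
  }
  # the closed form is maximal at zero PE change
  expect_true(all(inner_product_closed_form(c(-20, -5, 5, 20), 16, 1) <
                    inner_product_closed_form(0, 16, 1)))
})

test_that("the PE update rate equals the random-walk Kalman gain", {
  expect_lt(pe_kalman_gain(0, 1), 1e-12)
  expect_equal(pe_kalman_gain(1e6, 1), 1, tolerance = 1e-5)
  # with alpha at the steady-state gain, the linear PE update tracks the
  # full time-varying Kalman predictor after burn-in
  sz <- 3; sx <- 6
  a_star <- pe_kalman_gain(sz, sx)
  set.seed(9)
  g <- cumsum(rnorm(200, 0, sz))
  e <- g + rnorm(200, 0, sx)
  P <- 100; ghat <- 0
  pred_k <- pred_a <- numeric(200)
  peh <- 0
  for (t in 1:200) {
    pred_k[t] <- ghat
    Pm <- P + sz^2
    K <- Pm / (Pm + sx^2)
    ghat <- ghat + K * (e[t] - ghat)
    P <- (1 - K) * Pm
    pred_a[t] <- peh
    peh <- update_pe(peh, e[t], a_star)
  }
  expect_lt(max(abs(pred_k[50:200] - pred_a[50:200])), 1e-8)
})

test_that("uniform preferred-PE sampling stays in range and matches the grid ensemble", {
  p <- pe_params(n_primitives = 2000)
  set.seed(15)
  pop_u <- pe_population(p, sampling = "uniform")
  expect_true(all(pop_u$mu >= p$mu_low & pop_u$mu <= p$mu_high))
  # large-N: a randomly placed population behaves like the grid
  sched <- constant_schedule(30, 30)
  xu <- run_schedule(p, sched, pop = pop_u)$x
  xg <- run_schedule(p, sched)$x
  expect_lt(max(abs(xu - xg)), 0.05 * max(xg))
})

test_that("simulated dynamics are insensitive to the primitive count", {
  sched <- concat_phases(
    constant_schedule(30, 40, phase = "initial"),
    constant_schedule(-30, 5, phase = "opposite"),
    constant_schedule(0, 20, "error_clamp", phase = "clamp")
  )
  x1 <- run_schedule(pe_params(n_primitives = 1000), sched)$x
  x4 <- run_schedule(pe_params(n_primitives = 4000), sched)$x
  expect_lt(max(abs(x1 - x4)) / max(abs(x1)), 0.02)
})
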