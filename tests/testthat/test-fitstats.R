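test_that("exponential fit recovers exact-model data and flags degeneracy", {
  t <- 0:29
  y <- 30 * exp(-0.3 * t)
  f <- exp_fit(y)
  expect_equal(f$b, 0.3, tolerance = 1e-6)
  expect_equal(f$a, 30, tolerance = 1e-5)
  expect_equal(f$c, 0, tolerance = 1e-5)
  f2 <- exp_fit(12 - 8 * exp(-0.07 * t))
  expect_equal(f2$b, 0.07, tolerance = 1e-6)
  expect_equal(f2$a, -8, tolerance = 1e-4)
  const <- exp_fit(rep(5, 20))
  expect_true(const$flagged)
  expect_lt(abs(const$a), 1e-6)
})

test_that("exponential fit recovers the learning speed from noisy group averages", {
  b_true <- 0.3
  clean <- 30 * exp(-b_true * (0:29))
  errs <- vapply(1:30, function(s) {
    set.seed(s)
    curves <- t(replicate(12, clean + rnorm(30, 0, 5)))
    exp_fit(colMeans(curves))$b / b_true - 1
  }, numeric(1))
  expect_gt(mean(abs(errs) <= 0.10), 0.8)     # within 10% in most replicates
  expect_lt(abs(mean(errs)), 0.05)            # essentially unbiased
})

test_that("state-space fit identifies retention and adaptation exactly", {
  x <- numeric(40); e <- numeric(40)
  for (t in 1:39) {
    e[t] <- 30 - x[t]
    x[t + 1] <- 0.95 * x[t] + 0.2 * e[t]
  }
  e[40] <- 30 - x[40]
  f <- state_space_fit(x, e)
  expect_equal(f$A, 0.95, tolerance = 1e-10)
  expect_equal(f$B, 0.2, tolerance = 1e-10)

  f0 <- state_space_fit(0.9^(0:20) * 10, numeric(21))
  expect_true(f0$flagged)
  expect_true(is.na(f0$B))
  expect_equal(f0$A, 0.9, tolerance = 1e-10)
  expect_error(state_space_fit(1:10, 2 * (1:10)), "singular")

  run <- run_schedule(ref_params(), constant_schedule(30, 50))
  fr <- state_space_fit(run$x, 30 - run$x)
  expect_true(fr$A > 0 && fr$A <= 1)
  expect_true(fr$B > 0 && fr$B < 1)
})

test_that("affine scaling fit is exact and degrades monotonically with noise", {
  m <- sin(1:40)
  f <- affine_fit(m, 2 * m + 3)
  expect_equal(f$m, 2)
  expect_equal(f$n, 3)
  expect_equal(f$r_squared, 1)
  fc <- affine_fit(m, rep(7, 40))
  expect_true(fc$flagged)
  expect_equal(fc$m, 0)
  expect_equal(fc$r_squared, 0)
  p <- ref_params()
  model <- error_correction(seq(-45, 45, by = 5), p)
  r2 <- vapply(c(0, 2, 5, 10), function(sd_noise) {
    mean(vapply(1:10, function(s) {
      set.seed(100 * s + sd_noise)
      affine_fit(model, model + rnorm(length(model), 0, sd_noise * 0.05))$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("probe-design channel data identify the sigma/alpha ratio", {
  p <- ref_params()
  gen0 <- gen_config(motor_noise_sd = 0, force_noise_sd = 0)
  set.seed(21)
  tab <- do.call(rbind, lapply(1:6, function(i) {
    generate_probe_subject(gen0, n_cycles = 20, subject_id = paste0("s", i))
  }))
  fit <- fit_model_params(tab, "correction")
  expect_true(fit$pe_quiescent)
  expect_equal(fit$ratio, p$sigma / p$alpha, tolerance = 0.05)
})

test_that("stage-2 search returns the generating parameters on noiseless data", {
  p <- ref_params()
  y <- run_schedule(p, constant_schedule(30, 30, phase = "test"))$x
  fit <- fit_learning_curve(y, ratio = p$sigma / p$alpha)
  expect_equal(fit$params$alpha, 0.8)
  expect_equal(fit$params$lambda, p$lambda, tolerance = 1e-3)
  expect_equal(fit$params$eta, p$eta, tolerance = 1e-2)
  expect_equal(fit$params$sigma, p$sigma, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-3)
  # the generating grid point is the unique objective minimum
  expect_equal(fit$alpha_grid[which.min(fit$grid_rss)], 0.8)
})

test_that("bootstrap learning speeds behave at the degenerate margins", {
  clean <- 30 * exp(-0.25 * (0:24))
  curves <- t(replicate(6, clean))
  set.seed(5)
  bs <- bootstrap_learning_speed(curves, n_boot = 25)
  expect_equal(sd(bs$b), 0)             # identical subjects: no variability
  expect_equal(bs$mean_b, 0.25, tolerance = 1e-6)
  one <- bootstrap_learning_speed(curves, n_boot = 1)
  expect_length(one$b, 1)
})

test_that("randomization test is calibrated, label-symmetric and floor-bounded", {
  set.seed(11)
  a <- rnorm(10)
  expect_equal(randomization_test(a, a, n_perm = 99), 1)
  # perfectly separated groups hit the add-one resolution floor
  expect_equal(randomization_test(1:10 + 100, 1:10, n_perm = 199),
               1 / 200, tolerance = 1e-12)
  b <- rnorm(10, 1)
  set.seed(3); p_ab <- randomization_test(a, b, n_perm = 299)
  set.seed(3); p_ba <- randomization_test(b, a, n_perm = 299)
  expect_equal(p_ab, p_ba)
  # null p-values are uniform (two-sided statistic)
  set.seed(77)
  pvals <- replicate(200, randomization_test(rnorm(12), rnorm(12),
                                             n_perm = 199))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean + 3 SD screening removes exactly the documented outlier", {
  expect_length(exclude_outliers(rep(3, 10))$removed, 0)
  vals <- c(rep(0, 30), 100)
  scr <- exclude_outliers(vals)
  expect_equal(scr$removed, 100)
  # worked case: value 62.8017 against mean 27.6944 and sd 11.6704
  fix <- moments_fixture(27.6944, 11.6704, 62.8017)
  scr2 <- exclude_outliers(fix)
  expect_equal(scr2$removed, 62.8017)
  expect_length(scr2$kept, 11)
  # the screening threshold itself: mu + 3 sigma just below the outlier
  expect_gt(62.8017, scr2$mean + 3 * scr2$sd)
})

test_that("trailing moving average has uniform weights and end alignment", {
  expect_equal(moving_average(rep(4, 30), 16), rep(4, 15))
  expect_equal(moving_average(rep(c(1, -1), 16), 16), rep(0, 17))
  r <- moving_average(1:32, 16)
  expect_equal(r[1], 8.5)
  expect_length(r, 17)
  expect_equal(r, seq(8.5, 24.5, by = 1))
  expect_error(moving_average(1:10, 16), "shorter")
})
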