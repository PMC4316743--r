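test_that("structured training accelerates subsequent learning in group order", {
  p <- ref_params()
  reports <- lapply(1:3, structural_learning, params = p, n_runs = 30,
                    master_seed = 3)
  b <- vapply(reports, function(r) r$metrics$learning_speed_b, numeric(1))
  expect_lt(b[1], b[2])
  expect_lte(b[2], b[3])
  # block training leaves positive memory at the test PE, random training none
  expect_gt(reports[[3]]$metrics$memory_at_test_pe, 5)
  expect_lt(abs(reports[[1]]$metrics$memory_at_test_pe), 3)
})

test_that("training without perturbations leaves test learning naive", {
  p <- ref_params()
  rep0 <- structural_learning(p, 3, n_runs = 2, value_set = 0,
                              master_seed = 1)
  naive <- run_schedule(p, constant_schedule(30, 30))$x
  expect_equal(rep0$curves$test_x, naive, tolerance = 1e-10)
})

test_that("feedback blur lowers the fitted adaptation rate", {
  p <- ref_params()
  rep <- uncertainty_effect(p, sigma_g_list = c(0, 30, 60), n_runs = 40,
                            master_seed = 2)
  B <- rep$metrics$rates$B
  expect_true(all(diff(B) < 0))
  expect_true(all(rep$metrics$rates$A > 0 & rep$metrics$rates$A <= 1))
  expect_true(all(B > 0 & B < 1))
  # overwhelming blur: the error signal is pure noise, so the command is a
  # zero-mean noise-driven walk and the ensemble mean stays at baseline
  huge <- run_ensemble(p, constant_schedule(30, 50), 60,
                       noise = pe_noise(sigma_g = 1e4), master_seed = 2)
  final_x <- huge$x[, 50]
  expect_lt(abs(mean(final_x)), 4 * sd(final_x) / sqrt(length(final_x)))
  # no systematic adaptation towards the rotation
  expect_lt(mean(final_x), 10)
})

test_that("savings: relearning beats initial learning over the first five trials", {
  p <- ref_params()
  s <- savings(p, n_runs = 5, master_seed = 1)
  expect_gt(s$metrics$savings, 0)
  # without the opposite phase the relearning curve continues from the
  # asymptote, so the advantage is even larger
  s0 <- savings(p, opposite_n = 0, n_runs = 5, master_seed = 1)
  expect_gt(s0$metrics$savings, s$metrics$savings)
  # vanishing learning rate: no learning anywhere, metric collapses to zero
  tiny <- pe_params(eta = 1e-12)
  expect_lt(abs(savings(tiny, n_runs = 2, master_seed = 1)$metrics$savings),
            1e-8)
})

test_that("savings persistence across washout is ordered by the forgetting rate", {
  p <- ref_params()
  sw <- savings_washout_sweep(p, washout_lengths = c(0, 20, 50, 100))
  sweep <- sw$metrics$sweep
  for (lam in unique(sweep$lambda)) {
    d <- sweep[sweep$lambda == lam, ]
    expect_equal(d$savings_norm[1], 1)           # shortest washout is maximal
    expect_true(all(diff(d$savings_norm) < 0))   # decays with washout
  }
  # at the longest washout, slower forgetting preserves more savings
  long <- sweep[sweep$washout == 100, ]
  expect_true(all(diff(long$savings_norm[order(long$lambda)]) > 0))
  # geometric weight decay: long washout with lambda < 1 kills savings
  far <- savings_washout_sweep(p, lambda_list = 0.9586,
                               washout_lengths = c(0, 400))$metrics$sweep
  expect_lt(far$savings_norm[2], 1e-4)
})

test_that("anterograde interference slows opposite learning, more after longer training", {
  p <- ref_params()
  rep <- anterograde_interference(p, initial_lengths = c(25, 50, 100),
                                  opposite_n = 50, n_runs = 3,
                                  master_seed = 1)
  naive <- rep$curves$initial_naive
  for (curve in rep$curves$opposite) {
    expect_lt(curve[5], naive[5])   # slower than naive learning
    expect_lt(curve[10], naive[10])
  }
  # longer initial phase, slower opposite adaptation at matched trials
  at5 <- vapply(rep$curves$opposite, `[`, numeric(1), 5)
  expect_true(all(diff(at5) < 0))
  expect_true(all(diff(rep$metrics$index$half_rise_trials) >= 0))
})

test_that("spontaneous recovery re-expresses the initial memory during clamp", {
  p <- ref_params()
  rep <- spontaneous_recovery(p, n_runs = 3, master_seed = 1)
  expect_gt(rep$metrics$recovery, 0)
  expect_lt(rep$metrics$end_opposite_x, 5)  # output near/below baseline
  clamp_x <- rep$curves$mean$x[rep$curves$mean$phase == "clamp"]
  expect_gt(max(clamp_x), rep$metrics$end_opposite_x)
  # matching opposite length overwrites the memory at all visited PEs: the
  # clamped output decays towards baseline but never rebounds above it,
  # unlike the brief-opposite case
  full <- spontaneous_recovery(p, initial_n = 50, opposite_n = 50,
                               n_runs = 3, master_seed = 1)
  expect_lt(full$metrics$max_clamp_x, 1)
  expect_gt(rep$metrics$max_clamp_x, 2)
})

test_that("PE recruitment beats perturbation-prediction recruitment under clamp", {
  p <- ref_params()
  r0 <- perturbation_prediction(p, clamp_phat = 0, n_runs = 2,
                                master_seed = 1)
  rm30 <- perturbation_prediction(p, clamp_phat = -30, n_runs = 2,
                                  master_seed = 1)
  clamp0 <- r0$curves$mean$x[r0$curves$mean$phase == "clamp"]
  clamp30 <- rm30$curves$mean$x[rm30$curves$mean$phase == "clamp"]
  expect_gt(max(abs(clamp0 - clamp30)), 1)  # the assumed clamp p_hat matters
  expect_gt(rm30$metrics$pe_recovery, rm30$metrics$recovery)
  expect_gt(rm30$metrics$recovery_advantage, 0)
})

test_that("predicted perturbation and PE follow the same update on channel trials", {
  # on channel trials e = p, so the PE trajectory driven by e coincides with
  # a perturbation prediction driven by p
  p <- ref_params()
  set.seed(4)
  sched <- block_random_schedule(rotation_set(), 2, 40, mode = "channel")
  run <- run_schedule(p, sched)
  phat <- 0
  for (t in seq_len(nrow(sched))) {
    expect_equal(run$pe_hat[t], phat)
    phat <- phat + p$alpha * (sched$p[t] - phat)
  }
})

test_that("phenomenon reports are bit-reproducible given the seed", {
  p <- ref_params()
  a <- structural_learning(p, 2, n_runs = 5, master_seed = 9)
  b <- structural_learning(p, 2, n_runs = 5, master_seed = 9)
  expect_identical(a$curves$mean$x, b$curves$mean$x)
  expect_identical(a$metrics$learning_speed_b, b$metrics$learning_speed_b)
})
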