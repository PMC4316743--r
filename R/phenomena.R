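new_phenomenon <- function(name, curves, metrics, params, master_seed) {
  structure(list(name = name, curves = curves, metrics = metrics,
                 params = params, master_seed = master_seed),
            class = "pe_phenomenon")
}

#' @export
print.pe_phenomenon <- function(x, ...) {
  cat(sprintf("Phenomenon: %s\n", x$name))
  scalars <- Filter(function(v) is.numeric(v) && length(v) == 1, x$metrics)
  for (nm in names(scalars)) cat(sprintf("  %s = %.4g\n", nm, scalars[[nm]]))
  invisible(x)
}

#' The behavioural rotation set
#'
#' The seven rotations sampled during structured training.
#' @return `c(-45, -30, -15, 0, 15, 30, 45)` degrees.
#' @export
rotation_set <- function() c(-45, -30, -15, 0, 15, 30, 45)

#' Structural learning: faster adaptation after structured random training
#'
#' Training imposes block-random rotations (blocks of `group_k` identical
#' trials drawn from the rotation set), followed by washout and a constant
#' test rotation. With `group_k >= 2` consecutive identical perturbations
#' make the upcoming error predictable, so primitives tuned to the matching
#' prospective error accumulate memory that is re-activated in the test
#' phase, raising the fitted learning speed relative to `group_k = 1`.
#'
#' @param params A [pe_params()].
#' @param group_k Block length (1, 2 or 3 in the behavioural groups).
#' @param n_runs Ensemble size (100 in the reference simulations).
#' @param n_training,n_washout,n_test Phase lengths in trials.
#' @param test_p Test rotation, degrees.
#' @param training_mode `"channel"` (force-channel training, the behavioural
#'   setting: the command is forcibly 0 during training) or `"normal"`.
#' @param value_set Training rotation set.
#' @param noise A [pe_noise()].
#' @param master_seed Integer seed for the per-run schedules.
#' @return A `pe_phenomenon` with the mean trajectory (`curves$mean`), the
#'   mean test-phase curve (`curves$test_x`), and metrics `learning_speed_b`
#'   (exponential fit to the mean test curve) and `memory_at_test_pe` (mean
#'   end-of-training motor command probed at a PE of `test_p`).
#' @export
structural_learning <- function(params, group_k, n_runs = 100,
                                n_training = 210, n_washout = 10, n_test = 30,
                                test_p = 30, training_mode = "channel",
                                value_set = rotation_set(),
                                noise = pe_noise(), master_seed = 1) {
  stopifnot(group_k >= 1)
  pop <- pe_population(params)
  seeds <- derive_seeds(master_seed, n_runs)
  n_total <- n_training + n_washout + n_test
  xs <- matrix(0, n_runs, n_total)
  memory <- numeric(n_runs)
  probe <- tuning_activities(pop, test_p, normalized = TRUE)
  sched_rest <- concat_phases(
    constant_schedule(0, n_washout, phase = "washout"),
    constant_schedule(test_p, n_test, phase = "test")
  )
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    tr_sched <- block_random_schedule(value_set, group_k, n_training,
                                      mode = training_mode, phase = "training")
    tr <- run_schedule(params, tr_sched, noise, pop = pop)
    st <- attr(tr, "final_state")
    memory[i] <- motor_command(st$weights, probe)
    rest <- run_schedule(params, sched_rest, noise, pop = pop,
                         state = st, reset = FALSE)
    xs[i, ] <- c(tr$x, rest$x)
  }
  mean_x <- colMeans(xs)
  test_idx <- (n_training + n_washout + 1):n_total
  fit <- exp_fit(mean_x[test_idx])
  curves <- list(
    mean = data.frame(trial = seq_len(n_total),
                      phase = rep(c("training", "washout", "test"),
                                  c(n_training, n_washout, n_test)),
                      x = mean_x),
    test_x = mean_x[test_idx]
  )
  new_phenomenon(
    sprintf("structural learning (group %d)", group_k), curves,
    list(learning_speed_b = fit$b, exp_fit = fit,
         memory_at_test_pe = mean(memory), group_k = group_k,
         n_runs = n_runs),
    params, master_seed
  )
}

#' Effect of feedback uncertainty on the adaptation rate
#'
#' Adaptation to a constant rotation with Gaussian feedback blur of s.d.
#' `sigma_g`; for each blur level the across-run mean command is fit with the
#' linear state-space model of [state_space_fit()]. Greater blur makes the
#' prospective error jump between trials, de-correlating consecutive
#' recruitment patterns and lowering the fitted adaptation rate `B`.
#'
#' @param params A [pe_params()].
#' @param sigma_g_list Blur levels, degrees.
#' @param n_trials Trials of adaptation per level.
#' @param p Rotation, degrees.
#' @param n_runs Ensemble size per level.
#' @param master_seed Integer seed.
#' @return A `pe_phenomenon`; `metrics$rates` is a data frame with columns
#'   `sigma_g`, `A` (retention) and `B` (adaptation rate).
#' @export
uncertainty_effect <- function(params, sigma_g_list = c(0, 18, 30, 36, 60),
                               n_trials = 50, p = 30, n_runs = 100,
                               master_seed = 1) {
  sched <- constant_schedule(p, n_trials, phase = "test")
  curves <- list()
  rates <- data.frame(sigma_g = sigma_g_list, A = NA_real_, B = NA_real_)
  for (i in seq_along(sigma_g_list)) {
    # same master seed at every level: paired (common-random-number) noise
    # draws across blur levels sharpen the level-to-level comparison
    ens <- run_ensemble(params, sched, n_runs,
                        noise = pe_noise(sigma_g = sigma_g_list[i]),
                        master_seed = master_seed)
    mx <- ens$mean$x
    fit <- state_space_fit(mx, p - mx)
    rates$A[i] <- fit$A
    rates$B[i] <- fit$B
    curves[[paste0("sigma_g_", sigma_g_list[i])]] <- mx
  }
  new_phenomenon("uncertainty effect", curves,
                 list(rates = rates, n_runs = n_runs), params, master_seed)
}

savings_metric <- function(x_initial, x_relearn, n_first = 5) {
  sum(x_relearn[seq_len(n_first)] - x_initial[seq_len(n_first)])
}

#' Savings: faster relearning after brief opposite learning
#'
#' Initial learning of a rotation, brief opposite rotation that returns the
#' output towards baseline, then relearning. The savings metric is the summed
#' difference of the command over the first five trials (relearning minus
#' initial); it is positive because primitives recruited early in initial
#' learning (at large positive PEs) keep their memory through the opposite
#' phase, whose PEs lie elsewhere.
#'
#' @param params A [pe_params()].
#' @param initial_n,opposite_n,relearn_n Phase lengths in trials.
#' @param p Rotation, degrees (opposite phase uses `-p`).
#' @param n_runs Ensemble size.
#' @param noise A [pe_noise()].
#' @param master_seed Integer seed.
#' @return A `pe_phenomenon` with metric `savings` (degrees, summed over the
#'   first five trials).
#' @export
savings <- function(params, initial_n = 30, opposite_n = 5, relearn_n = 30,
                    p = 30, n_runs = 10, noise = pe_noise(),
                    master_seed = 1) {
  stopifnot(initial_n >= 5, relearn_n >= 5, opposite_n >= 0)
  phases <- list(constant_schedule(p, initial_n, phase = "initial"))
  if (opposite_n > 0) {
    phases <- c(phases, list(constant_schedule(-p, opposite_n,
                                               phase = "opposite")))
  }
  phases <- c(phases, list(constant_schedule(p, relearn_n,
                                             phase = "relearn")))
  sched <- do.call(concat_phases, phases)
  ens <- run_ensemble(params, sched, n_runs, noise = noise,
                      master_seed = master_seed)
  mx <- ens$mean$x
  x_init <- mx[ens$mean$phase == "initial"]
  x_rel <- mx[ens$mean$phase == "relearn"]
  new_phenomenon("savings", list(mean = ens$mean),
                 list(savings = savings_metric(x_init, x_rel),
                      n_runs = n_runs),
                 params, master_seed)
}

#' Persistence of savings across washout length and forgetting rate
#'
#' Initial learning, a washout of varying length, then relearning; the
#' savings metric is computed per washout length for each forgetting rate and
#' normalized so each rate's maximum is 1. Because every weight decays by
#' `lambda` on every trial, stored memory shrinks geometrically during
#' washout; a forgetting rate close to 1 preserves savings across long
#' washouts. Noiseless and deterministic, so a single run per condition.
#'
#' @param params Baseline [pe_params()] (rates other than `lambda` reused).
#' @param lambda_list Forgetting rates to compare.
#' @param washout_lengths Washout lengths in trials (0 allowed).
#' @param initial_n,relearn_n Phase lengths.
#' @param p Rotation, degrees.
#' @return A `pe_phenomenon`; `metrics$sweep` has columns `lambda`,
#'   `washout`, `savings`, `savings_norm`.
#' @export
savings_washout_sweep <- function(params,
                                  lambda_list = c(0.9586, 0.9786, 0.9986),
                                  washout_lengths = c(0, 10, 20, 50, 100, 200),
                                  initial_n = 60, relearn_n = 20, p = 30) {
  stopifnot(all(lambda_list > 0), all(lambda_list <= 1))
  rows <- list()
  for (lam in lambda_list) {
    prm <- pe_params(lambda = lam, eta = params$eta, alpha = params$alpha,
                     sigma = params$sigma,
                     n_primitives = params$n_primitives,
                     mu_low = params$mu_low, mu_high = params$mu_high)
    sav <- vapply(washout_lengths, function(w) {
      phases <- list(constant_schedule(p, initial_n, phase = "initial"))
      if (w > 0) {
        phases <- c(phases, list(constant_schedule(0, w, phase = "washout")))
      }
      phases <- c(phases, list(constant_schedule(p, relearn_n,
                                                 phase = "relearn")))
      sched <- do.call(concat_phases, phases)
      run <- run_schedule(prm, sched)
      savings_metric(run$x[run$phase == "initial"],
                     run$x[run$phase == "relearn"])
    }, numeric(1))
    rows[[as.character(lam)]] <- data.frame(
      lambda = lam, washout = washout_lengths, savings = sav,
      savings_norm = sav / max(sav)
    )
  }
  sweep <- do.call(rbind, rows)
  rownames(sweep) <- NULL
  new_phenomenon("savings washout sweep", list(),
                 list(sweep = sweep), params, NA_integer_)
}

#' Anterograde interference: prior learning slows opposite learning
#'
#' Initial learning of `p` for a configurable number of trials, then opposite
#' learning of `-p`. Late in initial learning the active primitives sit near
#' zero PE; their memory must be reversed during opposite learning, so
#' adaptation there is slower, the more so the longer the initial phase.
#'
#' @param params A [pe_params()].
#' @param initial_lengths Initial-phase lengths to compare, trials.
#' @param opposite_n Opposite-phase length, trials.
#' @param p Rotation, degrees.
#' @param n_runs Ensemble size.
#' @param noise A [pe_noise()].
#' @param master_seed Integer seed.
#' @return A `pe_phenomenon`. `curves$opposite` holds, per initial length,
#'   the opposite-phase adaptation `-x` by trial; `metrics$index` gives the
#'   interference index (trials for the opposite-phase adaptation to reach
#'   half its final level) per initial length, and `curves$initial_naive` the
#'   naive initial-learning curve for comparison.
#' @export
anterograde_interference <- function(params, initial_lengths = c(25, 50, 100),
                                     opposite_n = 50, p = 30, n_runs = 10,
                                     noise = pe_noise(), master_seed = 1) {
  stopifnot(all(initial_lengths >= 1), opposite_n >= 3)
  naive <- run_ensemble(params, constant_schedule(p, opposite_n,
                                                  phase = "initial"),
                        n_runs, noise = noise,
                        master_seed = master_seed)$mean$x
  opp <- list()
  index <- data.frame(initial_n = initial_lengths, half_rise_trials = NA_real_)
  for (i in seq_along(initial_lengths)) {
    L <- initial_lengths[i]
    sched <- concat_phases(
      constant_schedule(p, L, phase = "initial"),
      constant_schedule(-p, opposite_n, phase = "opposite")
    )
    ens <- run_ensemble(params, sched, n_runs, noise = noise,
                        master_seed = master_seed)
    adapt <- -ens$mean$x[ens$mean$phase == "opposite"]
    opp[[as.character(L)]] <- adapt
    asymptote <- mean(utils::tail(adapt, 5))
    index$half_rise_trials[i] <- which(adapt >= asymptote / 2)[1]
  }
  new_phenomenon("anterograde interference",
                 list(opposite = opp, initial_naive = naive),
                 list(index = index, n_runs = n_runs), params, master_seed)
}

#' Spontaneous recovery of a trained memory during error clamp
#'
#' Long initial learning, brief opposite learning that apparently abolishes
#' the output, then error-clamp trials (observed error forced to 0). During
#' the clamp the PE decays geometrically to 0 at rate `1 - alpha`,
#' re-activating the near-zero-PE primitives that stored the initial memory,
#' so the command rises back above its end-of-opposite level.
#'
#' @param params A [pe_params()].
#' @param initial_n,opposite_n,clamp_n Phase lengths in trials.
#' @param p Rotation, degrees.
#' @param n_runs Ensemble size.
#' @param noise A [pe_noise()].
#' @param master_seed Integer seed.
#' @return A `pe_phenomenon` with metric `recovery` (max clamp-phase command
#'   minus the command on the last opposite-phase trial, degrees).
#' @export
spontaneous_recovery <- function(params, initial_n = 50, opposite_n = 5,
                                 clamp_n = 50, p = 30, n_runs = 10,
                                 noise = pe_noise(), master_seed = 1) {
  sched <- concat_phases(
    constant_schedule(p, initial_n, phase = "initial"),
    constant_schedule(-p, opposite_n, phase = "opposite"),
    constant_schedule(0, clamp_n, "error_clamp", phase = "clamp")
  )
  ens <- run_ensemble(params, sched, n_runs, noise = noise,
                      master_seed = master_seed)
  mx <- ens$mean$x
  end_opp <- mx[sum(ens$mean$phase %in% c("initial", "opposite"))]
  clamp_x <- mx[ens$mean$phase == "clamp"]
  new_phenomenon("spontaneous recovery", list(mean = ens$mean),
                 list(recovery = max(clamp_x) - end_opp,
                      max_clamp_x = max(clamp_x),
                      end_opposite_x = end_opp, n_runs = n_runs),
                 params, master_seed)
}

#' Rival model: recruitment by predicted perturbation
#'
#' Variant in which the primitives are recruited by a predicted perturbation
#' instead of the prospective error: `p_hat` follows the same linear update
#' on the (noiseless) perturbation, `p_hat <- p_hat + alpha * (p - p_hat)`,
#' and is forcibly set to `clamp_phat` during error-clamp trials (during a
#' clamp the perturbation is undefined for the learner). Run on the
#' spontaneous-recovery protocol for side-by-side comparison with the
#' prospective-error model under matched phases; the PE model recovers,
#' whereas the rival's recovery depends on the assumed clamp-phase `p_hat`.
#'
#' @param params A [pe_params()] (the update rate `alpha` is reused for
#'   `p_hat`).
#' @param clamp_phat `p_hat` imposed during the clamp, degrees (0 or the last
#'   pre-clamp perturbation, -30, in the reference comparison).
#' @param initial_n,opposite_n,clamp_n Phase lengths in trials.
#' @param p Rotation, degrees.
#' @param n_runs Ensemble size (the noiseless protocol is deterministic).
#' @param master_seed Integer seed (kept for matched-seed comparisons).
#' @return A `pe_phenomenon` with the rival trajectory (`curves$mean`), the
#'   matched PE-model trajectory (`curves$pe_model`), and metrics `recovery`
#'   (rival), `pe_recovery` and `recovery_advantage` (PE minus rival).
#' @export
perturbation_prediction <- function(params, clamp_phat = -30,
                                    initial_n = 50, opposite_n = 5,
                                    clamp_n = 50, p = 30, n_runs = 10,
                                    master_seed = 1) {
  sched <- concat_phases(
    constant_schedule(p, initial_n, phase = "initial"),
    constant_schedule(-p, opposite_n, phase = "opposite"),
    constant_schedule(0, clamp_n, "error_clamp", phase = "clamp")
  )
  pop <- pe_population(params)
  n <- nrow(sched)
  W <- numeric(length(pop$mu))
  phat <- 0
  x <- e <- ph <- numeric(n)
  for (t in seq_len(n)) {
    phat_used <- if (sched$mode[t] == "error_clamp") clamp_phat else phat
    a <- tuning_activities(pop, phat_used, normalized = TRUE)
    x[t] <- if (sched$mode[t] == "channel") 0 else motor_command(W, a)
    e[t] <- movement_error(sched$p[t], x[t], sched$mode[t])
    W <- update_weights(W, e[t], a, params$lambda, params$eta)
    ph[t] <- phat_used
    if (sched$mode[t] != "error_clamp") {
      phat <- phat + params$alpha * (sched$p[t] - phat)
    }
  }
  rival <- data.frame(trial = seq_len(n), phase = sched$phase,
                      mode = sched$mode, p = sched$p, x = x, e = e,
                      p_hat = ph, stringsAsFactors = FALSE)
  end_opp_idx <- initial_n + opposite_n
  rival_recovery <- max(x[rival$phase == "clamp"]) - x[end_opp_idx]
  pe <- spontaneous_recovery(params, initial_n, opposite_n, clamp_n, p,
                             n_runs = n_runs, master_seed = master_seed)
  new_phenomenon(
    sprintf("perturbation-prediction model (clamp p_hat = %g)", clamp_phat),
    list(mean = rival, pe_model = pe$curves$mean),
    list(recovery = rival_recovery,
         pe_recovery = pe$metrics$recovery,
         recovery_advantage = pe$metrics$recovery - rival_recovery,
         clamp_phat = clamp_phat),
    params, master_seed
  )
}
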