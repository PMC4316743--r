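#' Simulate a schedule with the prospective-error model
#'
#' Iterates [step_trial()] over a schedule, starting from the zero initial
#' state (`W = 0`, `pe_hat = 0`) unless a continuing state is supplied.
#'
#' @param params A [pe_params()].
#' @param schedule A `pe_schedule` (see [constant_schedule()],
#'   [block_random_schedule()], [concat_phases()]).
#' @param noise A [pe_noise()].
#' @param pop Optional [pe_population()]; built from `params` if missing.
#' @param state Optional starting [pe_state()] (continues a previous run when
#'   `reset = FALSE`).
#' @param reset If `TRUE` (default) start from the zero state.
#' @param pe_fixed Optional fixed PE at which activities are evaluated on
#'   every trial (see [step_trial()]).
#' @return A data frame with one row per trial (`trial`, `phase`, `mode`,
#'   `p`, `x`, `x_plan`, `e`, `pe_hat`) and attributes `final_state` and
#'   `population`.
#' @export
run_schedule <- function(params, schedule, noise = pe_noise(), pop = NULL,
                         state = NULL, reset = TRUE, pe_fixed = NULL) {
  stopifnot(inherits(params, "pe_params"), inherits(schedule, "pe_schedule"))
  if (is.null(pop)) pop <- pe_population(params)
  if (reset || is.null(state)) state <- pe_state(length(pop$mu))
  n <- nrow(schedule)
  x <- xp <- e <- peh <- numeric(n)
  # inlined trial loop (same update as step_trial, without per-trial
  # record allocation)
  W <- state$weights
  pe_hat <- state$pe_hat
  mu <- pop$mu
  two_s2 <- 2 * pop$sigma^2
  norm <- pop$norm
  lambda <- params$lambda; eta <- params$eta; alpha <- params$alpha
  sg <- noise$sigma_g
  xi <- if (sg > 0) stats::rnorm(n, 0, sg) else numeric(n)
  p_vec <- schedule$p
  mode_vec <- schedule$mode
  for (t in seq_len(n)) {
    pe_used <- if (is.null(pe_fixed)) pe_hat else pe_fixed
    a <- exp(-(pe_used - mu)^2 / two_s2) / norm
    x_plan <- sum(W * a)
    mode_t <- mode_vec[t]
    if (mode_t == "normal") {
      x[t] <- x_plan
      e[t] <- p_vec[t] - x_plan + xi[t]
    } else if (mode_t == "channel") {
      x[t] <- 0
      e[t] <- p_vec[t] + xi[t]
    } else {
      x[t] <- x_plan
      e[t] <- 0
    }
    xp[t] <- x_plan
    peh[t] <- pe_hat
    W <- lambda * W + (eta * e[t]) * a
    pe_hat <- pe_hat + alpha * (e[t] - pe_hat)
  }
  state <- structure(list(weights = W, pe_hat = pe_hat,
                          trial_index = state$trial_index + n),
                     class = "pe_state")
  out <- data.frame(trial = seq_len(n), phase = schedule$phase,
                    mode = schedule$mode, p = schedule$p,
                    x = x, x_plan = xp, e = e, pe_hat = peh,
                    stringsAsFactors = FALSE)
  attr(out, "final_state") <- state
  attr(out, "population") <- pop
  out
}

# Per-run seeds derived from a master seed. The first k seeds are identical
# for any n_runs >= k, so enlarging an ensemble never reshuffles earlier runs.
derive_seeds <- function(master_seed, n_runs) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_runs)
}

#' Run an ensemble of independent simulations
#'
#' Repeats [run_schedule()] `n_runs` times with per-run seeds derived from
#' `master_seed` and returns per-run trajectories plus across-run means.
#' Re-running with the same `master_seed` is bit-identical.
#'
#' @param params A [pe_params()].
#' @param schedule Either a `pe_schedule` used for every run, or a function
#'   `function(run)` returning the (possibly random, per-run) schedule; the
#'   function is called after the run's seed is set.
#' @param n_runs Number of runs (>= 1).
#' @param noise A [pe_noise()].
#' @param master_seed Integer master seed.
#' @param pop Optional shared [pe_population()].
#' @param pe_fixed Passed to [run_schedule()].
#' @return An object of class `pe_ensemble`: matrices `x`, `e`, `pe_hat`
#'   (`n_runs` x `n_trials`), the across-run `mean` data frame, the per-run
#'   `final_states`, and the first run's schedule.
#' @export
run_ensemble <- function(params, schedule, n_runs, noise = pe_noise(),
                         master_seed = 1, pop = NULL, pe_fixed = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(pop)) pop <- pe_population(params)
  seeds <- derive_seeds(master_seed, n_runs)
  runs <- vector("list", n_runs)
  sched1 <- NULL
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    sched <- if (is.function(schedule)) schedule(i) else schedule
    if (i == 1L) sched1 <- sched
    runs[[i]] <- run_schedule(params, sched, noise, pop = pop,
                              pe_fixed = pe_fixed)
  }
  n_trials <- nrow(runs[[1]])
  stopifnot(all(vapply(runs, nrow, integer(1)) == n_trials))
  xm <- do.call(rbind, lapply(runs, `[[`, "x"))
  em <- do.call(rbind, lapply(runs, `[[`, "e"))
  pm <- do.call(rbind, lapply(runs, `[[`, "pe_hat"))
  mean_df <- data.frame(trial = seq_len(n_trials), phase = sched1$phase,
                        mode = sched1$mode, p = sched1$p,
                        x = colMeans(xm), e = colMeans(em),
                        pe_hat = colMeans(pm), stringsAsFactors = FALSE)
  structure(
    list(x = xm, e = em, pe_hat = pm, mean = mean_df,
         final_states = lapply(runs, attr, "final_state"),
         schedule = sched1, n_runs = n_runs, master_seed = master_seed,
         params = params),
    class = "pe_ensemble"
  )
}

#' @export
print.pe_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d runs x %d trials (phases: %s)\n",
              x$n_runs, ncol(x$x), paste(unique(x$mean$phase), collapse = ", ")))
  invisible(x)
}
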