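#' Exponential learning-curve fit
#'
#' Least-squares fit of `y_t = a * exp(-b * t) + c` with `t = 0, 1, ...`
#' over the series; `b` is the learning speed. For fixed `b` the model is
#' linear in `(a, c)`, so the fit profiles the residual sum of squares over a
#' coarse grid of `b` values and refines the best bracket with 1-D
#' optimization; this reaches the global least-squares solution without
#' nonlinear-solver convergence failures.
#'
#' @param y Per-trial values (length >= 4).
#' @param b_max Upper bound of the learning-speed search (per trial).
#' @return An object of class `pe_exp_fit`: `a`, `b`, `c`, `rss`, and
#'   `flagged = TRUE` when `b` is unidentifiable (essentially constant data or
#'   a vanishing amplitude `a`).
#' @examples
#' y <- 30 * exp(-0.3 * (0:29))
#' exp_fit(y)$b
#' @export
exp_fit <- function(y, b_max = 3) {
  stopifnot(is.numeric(y), length(y) >= 4, all(is.finite(y)))
  t <- seq_along(y) - 1
  rss_b <- function(b) {
    z <- exp(-b * t)
    fit <- stats::lm.fit(cbind(z, 1), y)
    sum(fit$residuals^2)
  }
  grid <- c(seq(0.005, 0.1, by = 0.005), seq(0.12, 1, by = 0.02),
            seq(1.1, b_max, by = 0.1))
  rss <- vapply(grid, rss_b, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss_b, c(lo, hi), tol = 1e-10)
  b <- opt$minimum
  z <- exp(-b * t)
  coefs <- stats::lm.fit(cbind(z, 1), y)$coefficients
  flagged <- stats::sd(y) < 1e-12 || abs(coefs[1]) < 1e-8 * max(1, stats::sd(y))
  structure(list(a = unname(coefs[1]), b = b, c = unname(coefs[2]),
                 rss = opt$objective, flagged = flagged),
            class = "pe_exp_fit")
}

#' @export
print.pe_exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit: a = %.4g, b = %.4g (learning speed), c = %.4g%s\n",
              x$a, x$b, x$c, if (x$flagged) " [flagged: b unidentifiable]" else ""))
  invisible(x)
}

#' Linear state-space fit of a learning curve
#'
#' Ordinary least squares on `x[t+1] = A * x[t] + B * e[t]`, where `A` is the
#' retention (forgetting) factor and `B` the adaptation rate. With the error
#' convention `e = p - x` used throughout this package, `B > 0` means
#' adaptation (the command moves towards the perturbation); under the
#' opposite error-sign convention the same model is written `x[t+1] =
#' A x[t] - B e[t]`, and the fitted `B` here is the negative of that
#' regression slope.
#'
#' @param x_series Motor-command series.
#' @param e_series Aligned error series (`e = p - x` convention).
#' @return An object of class `pe_state_space_fit`: `A`, `B`, `rss`,
#'   `flagged` (`TRUE`, with `B = NA`, when the error series is all zero so
#'   `B` is unidentifiable).
#' @export
state_space_fit <- function(x_series, e_series) {
  stopifnot(length(x_series) == length(e_series), length(x_series) >= 3,
            all(is.finite(x_series)), all(is.finite(e_series)))
  n <- length(x_series)
  y <- x_series[-1]
  x0 <- x_series[-n]
  e0 <- e_series[-n]
  if (all(abs(e0) < 1e-12)) {
    fit <- stats::lm.fit(cbind(x0), y)
    return(structure(list(A = unname(fit$coefficients[1]), B = NA_real_,
                          rss = sum(fit$residuals^2), flagged = TRUE),
                     class = "pe_state_space_fit"))
  }
  X <- cbind(x0, e0)
  if (qr(X)$rank < 2) stop("singular design: x and e series are collinear")
  fit <- stats::lm.fit(X, y)
  structure(list(A = unname(fit$coefficients[1]),
                 B = unname(fit$coefficients[2]),
                 rss = sum(fit$residuals^2), flagged = FALSE),
            class = "pe_state_space_fit")
}

#' @export
print.pe_state_space_fit <- function(x, ...) {
  cat(sprintf("State-space fit: retention A = %.4f, adaptation B = %.4f%s\n",
              x$A, x$B, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Affine scaling of a model curve onto data
#'
#' Closed-form least squares for `data = m * model + n`, used to map model
#' output (degrees of movement direction) onto measured quantities in other
#' units such as channel forces.
#'
#' @param model_curve Model predictions.
#' @param data_curve Observed values, same length.
#' @return An object of class `pe_affine_fit`: gain `m`, offset `n`,
#'   `r_squared` (`0` and `flagged = TRUE` for zero-variance data, where the
#'   fit is degenerate).
#' @export
affine_fit <- function(model_curve, data_curve) {
  stopifnot(length(model_curve) == length(data_curve), length(model_curve) >= 2)
  sst <- sum((data_curve - mean(data_curve))^2)
  if (sst < 1e-24) {
    return(structure(list(m = 0, n = mean(data_curve), r_squared = 0,
                          flagged = TRUE),
                     class = "pe_affine_fit"))
  }
  fit <- stats::lm.fit(cbind(model_curve, 1), data_curve)
  sse <- sum(fit$residuals^2)
  structure(list(m = unname(fit$coefficients[1]),
                 n = unname(fit$coefficients[2]),
                 r_squared = 1 - sse / sst, flagged = FALSE),
            class = "pe_affine_fit")
}

#' Fit the tuning-width-to-update-rate ratio from error corrections
#'
#' Stage-1 fit: with weights and PE at zero, the next-trial correction after
#' observing an error `e` is proportional to `e * exp(-e^2 / (4 r^2))` with
#' `r = sigma / alpha`; only this ratio is identified. The observed
#' corrections are fit as `m * g(e; r) + n` (affine scale absorbing force
#' units), minimizing the residual sum of squares over `r`.
#'
#' @param e Observed channel-trial errors, degrees.
#' @param f_next Correction measured on the following trial (any units).
#' @param interval Search interval for `r`, degrees.
#' @return An object of class `pe_stage1_fit`: `ratio` (`sigma/alpha`,
#'   degrees), affine `m`, `n`, and `r_squared`.
#' @export
fit_correction_ratio <- function(e, f_next, interval = c(2, 200)) {
  stopifnot(length(e) == length(f_next), length(e) >= 4)
  rss_r <- function(r) {
    g <- e * exp(-e^2 / (4 * r^2))
    sum(stats::lm.fit(cbind(g, 1), f_next)$residuals^2)
  }
  opt <- stats::optimize(rss_r, interval, tol = 1e-8)
  r <- opt$minimum
  g <- e * exp(-e^2 / (4 * r^2))
  af <- affine_fit(g, f_next)
  structure(list(ratio = r, m = af$m, n = af$n, r_squared = af$r_squared),
            class = "pe_stage1_fit")
}

#' Fit the full model parameters to a test-phase learning curve
#'
#' Stage-2 fit: given the stage-1 ratio `sigma / alpha`, searches the PE
#' update rate on the grid `alpha = 0.1, 0.2, ..., 1.0` (with the ratio tie,
#' `alpha = 0` would force a zero tuning width and is infeasible), sets
#' `sigma = ratio * alpha`, and for each grid point estimates `(lambda, eta)`
#' by least squares between the observed curve and the model's noiseless
#' adaptation curve to a constant perturbation.
#'
#' With the ratio tie the learning-rate modulation depends on `e - pe_hat`
#' only through the ratio, so `alpha` is identified by how fast the PE tracks
#' abrupt error changes: on a smooth constant-rotation curve the grid
#' objective is nearly flat across neighbouring `alpha` values, whereas
#' protocols containing reversals and error-clamp segments (where the PE
#' relaxes at rate `1 - alpha`) separate them sharply. Supply such a protocol
#' via `schedule` when recovering `alpha` from noisy data (see
#' [alpha_probe_schedule()]).
#'
#' @param y Observed per-trial movement angle (test phase, or the richer
#'   `schedule` protocol).
#' @param ratio Stage-1 `sigma / alpha` ratio, degrees.
#' @param p Test perturbation, degrees (ignored when `schedule` is given).
#' @param alpha_grid Candidate update rates.
#' @param schedule Optional `pe_schedule` that generated `y`; defaults to
#'   `length(y)` constant-rotation trials.
#' @param n_primitives Population size used in the fitting simulations
#'   (results are N-invariant; a moderate size keeps the search fast).
#' @return An object of class `pe_stage2_fit`: best-fit [pe_params()] in
#'   `params`, the per-grid-point objective values, and `rss`.
#' @export
fit_learning_curve <- function(y, ratio, p = 30,
                               alpha_grid = seq(0.1, 1, by = 0.1),
                               schedule = NULL, n_primitives = 200) {
  stopifnot(length(y) >= 4, ratio > 0)
  n <- length(y)
  sched <- if (is.null(schedule)) {
    constant_schedule(p, n, mode = "normal", phase = "test")
  } else {
    stopifnot(nrow(schedule) == n)
    schedule
  }
  objective <- function(theta, alpha) {
    lambda <- theta[1]; eta <- theta[2]
    if (lambda <= 0 || lambda > 1 || eta <= 0) return(1e12)
    prm <- pe_params(lambda = lambda, eta = eta, alpha = alpha,
                     sigma = ratio * alpha, n_primitives = n_primitives)
    sim <- run_schedule(prm, sched)
    sum((sim$x - y)^2)
  }
  best <- NULL
  grid_rss <- numeric(length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    a <- alpha_grid[i]
    opt <- stats::optim(c(0.95, 2), objective, alpha = a,
                        method = "L-BFGS-B",
                        lower = c(0.5, 0.05), upper = c(1, 10))
    grid_rss[i] <- opt$value
    if (is.null(best) || opt$value < best$value) {
      best <- list(value = opt$value, par = opt$par, alpha = a)
    }
  }
  params <- pe_params(lambda = best$par[1], eta = best$par[2],
                      alpha = best$alpha, sigma = ratio * best$alpha)
  structure(list(params = params, alpha_grid = alpha_grid,
                 grid_rss = grid_rss, rss = best$value),
            class = "pe_stage2_fit")
}

#' Fit model parameters from a trial table
#'
#' Dispatches the two-stage fitting procedure on a trial table (see
#' [read_trial_table()] for the schema). Stage `"correction"` pairs each
#' channel-trial error with the force measured on the immediately following
#' channel trial (within subject) and fits the `sigma / alpha` ratio with
#' [fit_correction_ratio()]. Stage `"learning-curve"` averages the
#' (non-excluded) test-phase movement angles across subjects and fits the
#' remaining parameters with [fit_learning_curve()].
#'
#' The stage-1 function assumes a near-zero prospective error when the error
#' is observed; during continuous random training this holds only after a
#' quiet stretch of small errors, so pairs are screened on the preceding
#' error history (`lag1_tol`, `lag2_tol`) before fitting. If too few pairs
#' survive the screen, all consecutive pairs are used and the result is
#' flagged.
#'
#' @param table A trial-table data frame.
#' @param stage `"correction"` or `"learning-curve"`.
#' @param ratio For `"learning-curve"`: the stage-1 ratio (degrees).
#' @param lag1_tol,lag2_tol For `"correction"`: maximal absolute error on the
#'   one- and two-back trials for a pair to count as PE-quiescent, degrees.
#' @param ... Passed to the underlying fitter.
#' @return The stage-1 or stage-2 fit object.
#' @export
fit_model_params <- function(table, stage = c("correction", "learning-curve"),
                             ratio = NULL, lag1_tol = 1, lag2_tol = 15, ...) {
  stage <- match.arg(stage)
  if (stage == "correction") {
    ch <- table[table$mode == "channel", , drop = FALSE]
    if (nrow(ch) < 5) stop("trial table has no channel-phase trials to fit")
    pair_up <- function(d, screen) {
      d <- d[order(d$trial), ]
      n <- nrow(d)
      idx <- seq_len(n - 1)
      keep <- diff(d$trial) == 1
      if (screen) {
        lag1 <- c(Inf, abs(d$e_deg[seq_len(n - 2)]))
        lag2 <- c(Inf, Inf, abs(d$e_deg[seq_len(max(0, n - 3))]))
        keep <- keep & lag1 <= lag1_tol & lag2 <= lag2_tol
      }
      data.frame(e = d$e_deg[idx][keep], f = d$force_au[idx + 1][keep])
    }
    pairs <- do.call(rbind, lapply(split(ch, ch$subject_id), pair_up,
                                   screen = TRUE))
    screened <- TRUE
    if (nrow(pairs) < 10) {
      pairs <- do.call(rbind, lapply(split(ch, ch$subject_id), pair_up,
                                     screen = FALSE))
      screened <- FALSE
    }
    fit <- fit_correction_ratio(pairs$e, pairs$f, ...)
    fit$n_pairs <- nrow(pairs)
    fit$pe_quiescent <- screened
    return(fit)
  }
  if (is.null(ratio)) stop("stage 'learning-curve' needs the stage-1 `ratio`")
  te <- table[table$phase == "test" & !table$excluded, , drop = FALSE]
  if (nrow(te) == 0) stop("trial table has no test-phase trials to fit")
  curve <- tapply(te$angle_deg, te$trial, mean)
  p <- abs(te$p_deg[1])
  fit_learning_curve(as.numeric(curve), ratio = ratio, p = p, ...)
}

#' Protocol for identifying the PE update rate
#'
#' Initial adaptation followed by repeated reversal / error-clamp /
#' relearning cycles (three by default). The abrupt transitions and clamp segments (PE relaxing at rate
#' `1 - alpha`) make the `alpha` grid of [fit_learning_curve()] well
#' separated at behavioural noise levels, where a plain constant-rotation
#' curve leaves neighbouring grid points indistinguishable.
#'
#' @param p Rotation magnitude, degrees.
#' @param initial_n,reversal_n,clamp_n,relearn_n Segment lengths, trials.
#' @param n_cycles Number of reversal cycles.
#' @return A `pe_schedule`.
#' @export
alpha_probe_schedule <- function(p = 30, initial_n = 30, reversal_n = 5,
                                 clamp_n = 15, relearn_n = 15, n_cycles = 3) {
  phases <- list(constant_schedule(p, initial_n, phase = "test"))
  for (i in seq_len(n_cycles)) {
    phases <- c(phases, list(
      constant_schedule(-p, reversal_n, phase = sprintf("reversal%d", i)),
      constant_schedule(0, clamp_n, "error_clamp",
                        phase = sprintf("clamp%d", i)),
      constant_schedule(p, relearn_n, phase = sprintf("relearn%d", i))
    ))
  }
  do.call(concat_phases, phases)
}

#' Bootstrap distribution of the learning speed
#'
#' Resamples subjects with replacement, averages their curves, and fits the
#' learning speed `b` of [exp_fit()] to each resampled average.
#'
#' @param subject_curves Matrix of per-subject learning curves (subjects in
#'   rows, trials in columns); at least 2 subjects.
#' @param n_boot Number of bootstrap resamples (3000 in the standard
#'   analysis).
#' @return An object of class `pe_bootstrap`: the vector `b` of resampled
#'   learning speeds and their `mean_b`.
#' @export
bootstrap_learning_speed <- function(subject_curves, n_boot = 3000) {
  stopifnot(is.matrix(subject_curves), nrow(subject_curves) >= 2, n_boot >= 1)
  ns <- nrow(subject_curves)
  b <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(ns, ns, replace = TRUE)
    exp_fit(colMeans(subject_curves[idx, , drop = FALSE]))$b
  }, numeric(1))
  structure(list(b = b, mean_b = mean(b), n_boot = n_boot),
            class = "pe_bootstrap")
}

#' Randomization (permutation) test for a difference in means
#'
#' The two samples are intermingled and randomly re-divided `n_perm` times;
#' the p-value is the add-one-corrected fraction of random splits whose mean
#' difference is at least as extreme as the observed one. The default
#' two-sided statistic `|mean(a) - mean(b)|` makes the p-value invariant to
#' swapping the group labels and uniformly distributed under the null.
#'
#' @param a,b Numeric samples (non-empty).
#' @param n_perm Number of random splits.
#' @param alternative `"two.sided"` (default), `"greater"` (mean(a) >
#'   mean(b)) or `"less"`.
#' @return The permutation p-value, in (0, 1].
#' @export
randomization_test <- function(a, b, n_perm = 10000,
                               alternative = c("two.sided", "greater", "less")) {
  stopifnot(length(a) >= 1, length(b) >= 1, n_perm >= 1)
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  obs <- mean(a) - mean(b)
  d <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  extreme <- switch(alternative,
    two.sided = sum(abs(d) >= abs(obs)),
    greater = sum(d >= obs),
    less = sum(d <= obs)
  )
  (1 + extreme) / (1 + n_perm)
}

#' Screen values with the mean + 3 SD rule
#'
#' One pass: the mean and standard deviation are computed on the full set and
#' values outside `mean +/- n_sd * sd` are removed.
#'
#' @param values Numeric vector (length >= 3).
#' @param n_sd Multiplier (3 in the standard screen).
#' @return A list with `kept`, `removed`, `removed_idx`, and the screening
#'   `mean` and `sd`.
#' @export
exclude_outliers <- function(values, n_sd = 3) {
  stopifnot(length(values) >= 3, all(is.finite(values)))
  m <- mean(values)
  s <- stats::sd(values)
  out <- abs(values - m) > n_sd * s
  list(kept = values[!out], removed = values[out],
       removed_idx = which(out), mean = m, sd = s)
}

#' Uniform trailing moving average
#'
#' `ma[t] = mean(x[(t - window + 1):t])`, reported from the first full
#' window; a window of 16 averages out target-to-target generalization
#' structure in multi-target designs.
#'
#' @param x Numeric series (length >= `window`).
#' @param window Window size.
#' @return Numeric vector of length `length(x) - window + 1`, aligned to the
#'   window end.
#' @export
moving_average <- function(x, window = 16) {
  stopifnot(window >= 1)
  if (length(x) < window) stop("series shorter than the window")
  out <- stats::filter(x, rep(1 / window, window), sides = 1)
  as.numeric(out[window:length(x)])
}
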