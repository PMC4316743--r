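#' Initial model state
#'
#' Learning starts from zero weights and a zero prospective error.
#'
#' @param n_primitives Number of primitives (match the population).
#' @return An object of class `pe_state` with fields `weights`, `pe_hat`,
#'   `trial_index`.
#' @export
pe_state <- function(n_primitives) {
  structure(list(weights = numeric(n_primitives), pe_hat = 0,
                 trial_index = 0L),
            class = "pe_state")
}

#' Observed movement error for one trial
#'
#' On a `normal` trial the cursor error is `p - x` plus feedback blur. On a
#' force-`channel` trial the executed movement is constrained straight, so the
#' command is forcibly 0 and the error equals the perturbation (plus blur). On
#' an `error_clamp` trial the feedback is manipulated so the observed error is
#' exactly 0.
#'
#' @param p Perturbation, degrees.
#' @param x Motor command, degrees (ignored in channel/clamp modes).
#' @param mode One of `"normal"`, `"channel"`, `"error_clamp"`.
#' @param noise A [pe_noise()]; `sigma_g` is the feedback-blur s.d.
#' @return Observed error `e`, degrees. Uses the R random number generator
#'   when `sigma_g > 0`; seed it with [set.seed()] for reproducibility.
#' @export
movement_error <- function(p, x, mode, noise = pe_noise()) {
  if (!mode %in% c("normal", "channel", "error_clamp")) {
    stop("unknown trial mode: ", mode)
  }
  if (mode == "error_clamp") return(0)
  xi <- if (noise$sigma_g > 0) stats::rnorm(1, 0, noise$sigma_g) else 0
  if (mode == "channel") p + xi else p - x + xi
}

#' Update the prospective error from an observed error
#'
#' `pe_new = pe_hat + alpha * (e - pe_hat)`: the predicted error for the next
#' trial moves a fraction `alpha` towards the error just observed. With
#' `alpha` equal to the steady-state gain of the random-walk Kalman filter
#' (see [pe_kalman_gain()]) this is the optimal one-step predictor.
#'
#' @param pe_hat Current prospective error, degrees.
#' @param e Observed movement error, degrees.
#' @param alpha Update rate in [0, 1].
#' @return Updated prospective error, degrees.
#' @export
update_pe <- function(pe_hat, e, alpha) {
  stopifnot(alpha >= 0, alpha <= 1, is.finite(pe_hat), is.finite(e))
  pe_hat + alpha * (e - pe_hat)
}

#' Error-driven weight update with forgetting
#'
#' `W_new[i] = lambda * W[i] + eta * e * A[i]`: the more active a primitive,
#' the more its weight is pushed to cancel the observed error; inactive
#' primitives keep their memory, eroded only by the forgetting factor.
#'
#' @param weights Current weight vector.
#' @param e Observed movement error, degrees.
#' @param activities Activity vector (same length as `weights`).
#' @param lambda Forgetting rate in (0, 1].
#' @param eta Learning rate (> 0).
#' @return Updated weight vector.
#' @export
update_weights <- function(weights, e, activities, lambda, eta) {
  if (length(weights) != length(activities)) {
    stop("`weights` and `activities` must have the same length")
  }
  lambda * weights + eta * e * activities
}

#' Simulate one trial of the prospective-error model
#'
#' The four-step loop: (1) activities from the current PE; (2) motor command
#' `x = W %*% A` (forced to 0 on channel trials); (3) observed error by trial
#' mode; (4) weight update and PE update. Weights and PE update on every trial
#' mode, including channel and error-clamp trials. Activities are population
#' normalized (see [pe_population()]) so the dynamics do not depend on the
#' number of primitives.
#'
#' @param state A [pe_state()].
#' @param p Perturbation, degrees.
#' @param mode Trial mode, see [movement_error()].
#' @param params A [pe_params()].
#' @param pop A [pe_population()] built from `params`.
#' @param noise A [pe_noise()].
#' @param pe_fixed If non-`NULL`, activities are evaluated at this fixed PE
#'   instead of the running estimate (decouples recruitment from the
#'   perturbation; used for ensemble memory-nulling analyses). The PE itself
#'   still updates.
#' @return `list(state = <new pe_state>, record = <one-row data.frame>)`; the
#'   record carries `p`, `x`, `e`, `pe_hat` (the PE used this trial), `mode`,
#'   and `x_plan`, the command the population would have produced (equal to
#'   `x` except on channel trials, where the executed command is 0 but
#'   `x_plan` is the corrective force expressed against the channel).
#' @export
step_trial <- function(state, p, mode, params, pop, noise = pe_noise(),
                       pe_fixed = NULL) {
  stopifnot(inherits(state, "pe_state"), inherits(params, "pe_params"),
            inherits(pop, "pe_population"))
  pe_used <- if (is.null(pe_fixed)) state$pe_hat else pe_fixed
  a <- tuning_activities(pop, pe_used, normalized = TRUE)
  x_plan <- motor_command(state$weights, a)
  x <- if (mode == "channel") 0 else x_plan
  e <- movement_error(p, x, mode, noise)
  new_state <- structure(
    list(weights = update_weights(state$weights, e, a,
                                  params$lambda, params$eta),
         pe_hat = update_pe(state$pe_hat, e, params$alpha),
         trial_index = state$trial_index + 1L),
    class = "pe_state"
  )
  record <- data.frame(trial = new_state$trial_index, p = p, x = x,
                       x_plan = x_plan, e = e, pe_hat = state$pe_hat,
                       mode = mode, stringsAsFactors = FALSE)
  list(state = new_state, record = record)
}

#' Steady-state Kalman gain of the random-walk error model
#'
#' For the generative model `g[t+1] = g[t] + zeta`, `e[t] = g[t] + xi`, the
#' steady-state gain of the scalar Kalman predictor is
#' `K = (-phi + sqrt(phi^2 + 4 phi)) / 2` with `phi = sigma_zeta^2 /
#' sigma_xi^2`. Setting the PE update rate `alpha` to this value makes
#' [update_pe()] the steady-state optimal one-step error predictor.
#'
#' @param sigma_zeta Drift s.d. of the true error, degrees (>= 0).
#' @param sigma_xi Observation-noise s.d., degrees (> 0).
#' @return The steady-state gain in [0, 1).
#' @export
pe_kalman_gain <- function(sigma_zeta, sigma_xi) {
  stopifnot(sigma_xi > 0, sigma_zeta >= 0)
  phi <- sigma_zeta^2 / sigma_xi^2
  (-phi + sqrt(phi^2 + 4 * phi)) / 2
}
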