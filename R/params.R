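#' Model parameters for the prospective-error primitive model
#'
#' Bundles the four learning parameters together with the primitive population
#' layout. Defaults are the best-fit values for adaptation to a 30 degree
#' visuomotor rotation: forgetting rate `lambda = 0.9586`, learning rate
#' `eta = 2.3913`, prospective-error update rate `alpha = 0.8` and tuning
#' width `sigma = 0.2868 * (360 / (2 * pi))` (about 16.43 degrees).
#'
#' @param lambda Forgetting rate, in (0, 1]. Every weight decays by this factor
#'   on every trial, whether or not its primitive was active.
#' @param eta Learning rate (> 0). Scales the error-driven weight increment;
#'   with the population normalization used by [step_trial()] it equals the
#'   effective single-trial error-to-command gain at zero prospective-error
#'   change (up to the fixed population constant, see [pe_population()]).
#' @param alpha Prospective-error update rate, in [0, 1]. The PE moves this
#'   fraction of the way towards the just-observed error each trial.
#' @param sigma Tuning width of the Gaussian primitives, degrees (> 0).
#' @param n_primitives Number of primitives (>= 1). Results are insensitive to
#'   this in the large-N regime because activities are density-normalized.
#' @param mu_low,mu_high Bounds of the preferred-PE range, degrees.
#'
#' @return An object of class `pe_params`.
#' @examples
#' p <- pe_params()
#' p$sigma / p$alpha # identified ratio from single-trial error corrections
#' @export
pe_params <- function(lambda = 0.9586, eta = 2.3913, alpha = 0.8,
                      sigma = 0.2868 * (360 / (2 * pi)),
                      n_primitives = 1000, mu_low = -180, mu_high = 180) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, lambda > 0, lambda <= 1,
    is.numeric(eta), length(eta) == 1L, eta > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
    is.numeric(sigma), length(sigma) == 1L, sigma > 0,
    is.numeric(n_primitives), length(n_primitives) == 1L, n_primitives >= 1,
    is.numeric(mu_low), is.numeric(mu_high), mu_low < mu_high
  )
  structure(
    list(lambda = lambda, eta = eta, alpha = alpha, sigma = sigma,
         n_primitives = as.integer(n_primitives),
         mu_low = mu_low, mu_high = mu_high),
    class = "pe_params"
  )
}

#' @export
print.pe_params <- function(x, ...) {
  cat("Prospective-error model parameters\n")
  cat(sprintf("  lambda = %.4f, eta = %.4f, alpha = %.2f, sigma = %.3f deg\n",
              x$lambda, x$eta, x$alpha, x$sigma))
  cat(sprintf("  %d primitives, preferred PE in (%g, %g) deg\n",
              x$n_primitives, x$mu_low, x$mu_high))
  invisible(x)
}

#' Noise model for simulated trials
#'
#' @param sigma_g Feedback-blur standard deviation, degrees (>= 0). Added to
#'   the observed movement error on normal and channel trials, emulating
#'   experimentally blurred endpoint feedback.
#' @param sigma_xi Observation-noise s.d., degrees (>= 0). Sensory noise in the
#'   generative model of the error used by [pe_kalman_gain()].
#' @param sigma_zeta Drift s.d. of the true error random walk, degrees (>= 0);
#'   used by [pe_kalman_gain()].
#'
#' @return An object of class `pe_noise`.
#' @export
pe_noise <- function(sigma_g = 0, sigma_xi = 0, sigma_zeta = 0) {
  stopifnot(sigma_g >= 0, sigma_xi >= 0, sigma_zeta >= 0)
  structure(list(sigma_g = sigma_g, sigma_xi = sigma_xi,
                 sigma_zeta = sigma_zeta),
            class = "pe_noise")
}

#' @export
print.pe_noise <- function(x, ...) {
  cat(sprintf("Trial noise: sigma_g = %g, sigma_xi = %g, sigma_zeta = %g deg\n",
              x$sigma_g, x$sigma_xi, x$sigma_zeta))
  invisible(x)
}
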