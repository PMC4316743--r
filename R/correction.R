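#' Single-trial error-correction function
#'
#' Starting from zero weights and zero PE, the corrective command produced on
#' the trial after observing an error `e` in a force-channel trial is
#' `f(e) = eta * c0 * e * exp(-(alpha * e)^2 / (4 * sigma^2))`, where `c0 =
#' 1 / (2 * sqrt(pi) * sigma * rho0)` is the fixed population-normalization
#' constant. The correction is odd in `e` and non-monotonic: it peaks at
#' `e = sqrt(2) * sigma / alpha` and falls off for larger errors, because a
#' large error drives the prospective error far from the primitives that
#' experienced it.
#'
#' @param e Observed movement error(s), degrees (vectorized).
#' @param params A [pe_params()].
#' @return Predicted correction in degrees (up to the affine scaling applied
#'   when fitting force data, see [affine_fit()]).
#' @export
error_correction <- function(e, params) {
  stopifnot(inherits(params, "pe_params"))
  c0 <- 1 / (2 * sqrt(pi) * params$sigma * PE_REF_DENSITY)
  k <- params$alpha^2 / (4 * params$sigma^2)
  params$eta * c0 * e * exp(-k * e^2)
}

#' Error size at which the single-trial correction peaks
#'
#' @param params A [pe_params()].
#' @return `sqrt(2) * sigma / alpha`, degrees.
#' @export
error_correction_peak <- function(params) {
  stopifnot(inherits(params, "pe_params"), params$alpha > 0)
  sqrt(2) * params$sigma / params$alpha
}

#' Error correction averaged over feedback blur
#'
#' When the observed error is blurred by Gaussian noise `xi ~ N(0, sigma_g^2)`
#' the expected correction `E[f(e + xi)]` has the closed Gaussian-integral
#' form `eta * c0 * e * (1 + 2 k sigma_g^2)^(-3/2) *
#' exp(-k e^2 / (1 + 2 k sigma_g^2))` with `k = alpha^2 / (4 sigma^2)`:
#' blur both shrinks and flattens the correction, which is how feedback
#' uncertainty lowers the apparent learning rate.
#'
#' @param e True movement error(s), degrees (vectorized).
#' @param sigma_g Feedback-blur s.d., degrees (>= 0).
#' @param params A [pe_params()].
#' @param method `"closed"` (default) or `"quadrature"` (numeric integration
#'   over the blur; used as an independent check of the closed form).
#' @return Expected correction, degrees.
#' @export
uncertainty_averaged_correction <- function(e, sigma_g, params,
                                            method = c("closed", "quadrature")) {
  stopifnot(inherits(params, "pe_params"))
  if (sigma_g < 0) stop("`sigma_g` must be >= 0")
  method <- match.arg(method)
  if (sigma_g == 0) return(error_correction(e, params))
  k <- params$alpha^2 / (4 * params$sigma^2)
  if (method == "closed") {
    c0 <- 1 / (2 * sqrt(pi) * params$sigma * PE_REF_DENSITY)
    s <- 1 + 2 * k * sigma_g^2
    return(params$eta * c0 * e * s^(-3 / 2) * exp(-k * e^2 / s))
  }
  vapply(e, function(ei) {
    stats::integrate(
      function(xi) error_correction(ei + xi, params) *
        stats::dnorm(xi, 0, sigma_g),
      lower = -8 * sigma_g, upper = 8 * sigma_g,
      rel.tol = 1e-10, abs.tol = 0
    )$value
  }, numeric(1))
}
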