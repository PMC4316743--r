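# Reference primitive density (primitives per degree) anchoring the activity
# normalization: 100 primitives over the full 360-degree PE range. Dividing
# activities by the large-N population norm at this density makes every
# simulated quantity independent of n_primitives while keeping the effective
# single-trial gain equal to eta * exp(-dPE^2 / (4 sigma^2)) / (2 sqrt(pi) *
# sigma * rho0), i.e. classic sum-normalized Gaussian population coding.
PE_REF_DENSITY <- 100 / 360

#' Build a population of Gaussian-tuned motor primitives
#'
#' Each primitive carries a preferred prospective error `mu[i]` and a shared
#' tuning width `sigma`. Preferred PEs are placed on a deterministic even grid
#' over `(mu_low, mu_high)` by default; uniform random sampling is available
#' and gives the same ensemble-averaged behaviour at large N.
#'
#' @param params A [pe_params()] object.
#' @param sampling `"grid"` (default) or `"uniform"` random placement.
#' @return An object of class `pe_population` with fields `mu`, `sigma` and
#'   the normalization constant `norm` applied to activities in simulation.
#' @examples
#' pop <- pe_population(pe_params(n_primitives = 8))
#' pop$mu
#' @export
pe_population <- function(params, sampling = c("grid", "uniform")) {
  stopifnot(inherits(params, "pe_params"))
  sampling <- match.arg(sampling)
  n <- params$n_primitives
  span <- params$mu_high - params$mu_low
  mu <- switch(sampling,
    grid = params$mu_low + span * (seq_len(n) - 0.5) / n,
    uniform = stats::runif(n, params$mu_low, params$mu_high)
  )
  density <- n / span
  structure(
    list(mu = mu, sigma = params$sigma, density = density,
         norm = params$sigma * sqrt(2 * pi * density * PE_REF_DENSITY),
         sampling = sampling),
    class = "pe_population"
  )
}

#' @export
print.pe_population <- function(x, ...) {
  cat(sprintf("Primitive population: %d units (%s), sigma = %.3f deg\n",
              length(x$mu), x$sampling, x$sigma))
  invisible(x)
}

#' Gaussian tuning activities of the primitive population
#'
#' The i-th primitive responds with `exp(-(pe_hat - mu[i])^2 / (2 sigma^2))`:
#' maximal (1) when the prospective error equals its preferred PE, and at one
#' tuning width away it falls to `exp(-1/2)`.
#'
#' @param pop A [pe_population()].
#' @param pe_hat Current prospective error, degrees (finite scalar).
#' @param normalized If `TRUE`, divide by the population norm `pop$norm`
#'   (the form used inside [step_trial()]); the default returns raw
#'   activities in [0, 1].
#' @return Numeric vector of length `length(pop$mu)`.
#' @export
tuning_activities <- function(pop, pe_hat, normalized = FALSE) {
  stopifnot(inherits(pop, "pe_population"))
  if (!is.numeric(pe_hat) || length(pe_hat) != 1L || !is.finite(pe_hat)) {
    stop("`pe_hat` must be a finite numeric scalar")
  }
  a <- exp(-(pe_hat - pop$mu)^2 / (2 * pop$sigma^2))
  if (normalized) a / pop$norm else a
}

#' Motor command as a weighted sum of primitive activities
#'
#' `x = sum(weights * activities)`, the population readout of the model.
#'
#' @param weights Weight vector (degrees of command per unit activity).
#' @param activities Activity vector, same length.
#' @return The motor command in degrees.
#' @export
motor_command <- function(weights, activities) {
  if (length(weights) != length(activities)) {
    stop("`weights` and `activities` must have the same length")
  }
  sum(weights * activities)
}

#' Population inner product between two prospective errors
#'
#' `sum_i A_i(pe_a) * A_i(pe_b)` over raw Gaussian activities. In the
#' large-N limit with unbounded uniform preferred PEs this sum approaches
#' `density * sigma * sqrt(pi) * exp(-(pe_b - pe_a)^2 / (4 sigma^2))`
#' (see [inner_product_closed_form()]): the learning rate of the reduced
#' recursion is modulated by this factor, maximal when the PE does not change
#' between trials.
#'
#' @param pop A [pe_population()].
#' @param pe_a,pe_b Prospective errors, degrees.
#' @return Unitless scalar.
#' @export
inner_product <- function(pop, pe_a, pe_b) {
  stopifnot(inherits(pop, "pe_population"))
  sum(tuning_activities(pop, pe_a) * tuning_activities(pop, pe_b))
}

#' Closed form of the population inner product
#'
#' @param delta PE difference `pe_b - pe_a`, degrees.
#' @param sigma Tuning width, degrees.
#' @param density Primitives per degree.
#' @return `density * sigma * sqrt(pi) * exp(-delta^2 / (4 * sigma^2))`.
#' @export
inner_product_closed_form <- function(delta, sigma, density) {
  density * sigma * sqrt(pi) * exp(-delta^2 / (4 * sigma^2))
}
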