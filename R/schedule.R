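new_schedule <- function(p, mode, phase) {
  stopifnot(length(p) == length(mode), length(p) == length(phase),
            all(is.finite(p)),
            all(mode %in% c("normal", "channel", "error_clamp")))
  structure(data.frame(trial = seq_along(p), p = p, mode = mode,
                       phase = phase, stringsAsFactors = FALSE),
            class = c("pe_schedule", "data.frame"))
}

#' Constant-perturbation schedule
#'
#' @param p Perturbation, degrees (e.g. 30 for the test rotation, 0 for
#'   washout).
#' @param n_trials Number of trials (>= 1).
#' @param mode Trial mode for every trial.
#' @param phase Phase label.
#' @return A `pe_schedule` data frame with columns `trial`, `p`, `mode`,
#'   `phase`.
#' @examples
#' constant_schedule(30, 5)               # a brief test phase
#' constant_schedule(0, 5, "error_clamp") # an error-clamp phase
#' @export
constant_schedule <- function(p, n_trials, mode = "normal",
                              phase = "training") {
  stopifnot(n_trials >= 1)
  new_schedule(rep(p, n_trials), rep(mode, n_trials), rep(phase, n_trials))
}

#' Block-random perturbation schedule
#'
#' The perturbation is constant within consecutive blocks of `block_len`
#' trials; each block's value is drawn uniformly (i.i.d.) from `value_set`.
#' `block_len = 1` gives a fully random sequence; 2 and 3 give the structured
#' environments in which consecutive identical perturbations make the
#' upcoming error predictable. The final block may be partial. Uses the R
#' random number generator; seed with [set.seed()].
#'
#' @param value_set Candidate perturbations, degrees. The behavioural rotation
#'   set is `c(-45, -30, -15, 0, 15, 30, 45)`.
#' @param block_len Block length `k` (>= 1).
#' @param n_trials Total number of trials.
#' @param mode Trial mode (the behavioural training phase uses
#'   `"channel"`).
#' @param phase Phase label.
#' @return A `pe_schedule`.
#' @export
block_random_schedule <- function(value_set, block_len, n_trials,
                                  mode = "channel", phase = "training") {
  if (block_len < 1) stop("`block_len` must be >= 1")
  stopifnot(length(value_set) >= 1, n_trials >= 1)
  n_blocks <- ceiling(n_trials / block_len)
  draws <- sample(value_set, n_blocks, replace = TRUE)
  p <- rep(draws, each = block_len)[seq_len(n_trials)]
  new_schedule(p, rep(mode, n_trials), rep(phase, n_trials))
}

#' Concatenate labelled schedule phases
#'
#' @param ... One or more `pe_schedule` objects, in order.
#' @return A single `pe_schedule` with trial indices renumbered and phase
#'   labels preserved.
#' @examples
#' sched <- concat_phases(
#'   constant_schedule(30, 50, phase = "initial"),
#'   constant_schedule(-30, 5, phase = "opposite"),
#'   constant_schedule(0, 50, "error_clamp", phase = "clamp")
#' )
#' table(sched$phase)
#' @export
concat_phases <- function(...) {
  phases <- list(...)
  if (length(phases) == 0) stop("at least one phase is required")
  stopifnot(all(vapply(phases, inherits, logical(1), "pe_schedule")))
  out <- do.call(rbind, lapply(phases, as.data.frame))
  new_schedule(out$p, out$mode, out$phase)
}
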