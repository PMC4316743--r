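#' Configuration of the synthetic behavioural-data generator
#'
#' @param params Generating [pe_params()].
#' @param motor_noise_sd Trial-to-trial motor noise added to recorded test and
#'   washout movement angles, degrees.
#' @param force_gain,force_offset Affine map from the model's corrective
#'   command (degrees) to recorded channel force (arbitrary units), emulating
#'   the unit mismatch between force and movement direction.
#' @param force_noise_sd Noise s.d. on recorded forces, in force units;
#'   defaults to 10 percent of the peak single-trial corrective force.
#' @param n_training,n_washout,n_test Phase lengths in trials.
#' @param value_set Training rotation set.
#' @param test_p Magnitude of the test rotation, degrees.
#' @return An object of class `pe_gen_config`.
#' @export
gen_config <- function(params = pe_params(), motor_noise_sd = 5,
                       force_gain = 1, force_offset = 0,
                       force_noise_sd = NULL,
                       n_training = 84, n_washout = 10, n_test = 30,
                       value_set = rotation_set(), test_p = 30) {
  stopifnot(inherits(params, "pe_params"), motor_noise_sd >= 0)
  if (is.null(force_noise_sd)) {
    peak <- error_correction(error_correction_peak(params), params)
    force_noise_sd <- 0.1 * abs(force_gain) * peak
  }
  stopifnot(force_noise_sd >= 0)
  structure(
    list(params = params, motor_noise_sd = motor_noise_sd,
         force_gain = force_gain, force_offset = force_offset,
         force_noise_sd = force_noise_sd,
         n_training = n_training, n_washout = n_washout, n_test = n_test,
         value_set = value_set, test_p = test_p),
    class = "pe_gen_config"
  )
}

#' Generate one synthetic subject
#'
#' Simulates the behavioural protocol through the prospective-error model:
#' force-channel training with block-random rotations (block length
#' `group_k`), washout, then a constant test rotation of `+30` (CCW) or `-30`
#' (CW) degrees. Channel rows record the corrective force (affine-scaled
#' would-be command plus force noise); washout and test rows record the
#' movement angle (command plus motor noise). Uses the R random number
#' generator; seed with [set.seed()].
#'
#' @param group_k Group (block length 1, 2 or 3).
#' @param sign `"ccw"` (+30 test rotation) or `"cw"` (-30).
#' @param gen A [gen_config()].
#' @param subject_id Identifier stored in the table.
#' @return A trial-table data frame (see [read_trial_table()] for the
#'   schema).
#' @export
generate_subject <- function(group_k, sign = c("ccw", "cw"),
                             gen = gen_config(), subject_id = "s1") {
  sign <- match.arg(sign)
  stopifnot(inherits(gen, "pe_gen_config"), group_k >= 1)
  test_p <- if (sign == "ccw") gen$test_p else -gen$test_p
  sched <- concat_phases(
    block_random_schedule(gen$value_set, group_k, gen$n_training,
                          mode = "channel", phase = "training"),
    constant_schedule(0, gen$n_washout, phase = "washout"),
    constant_schedule(test_p, gen$n_test, phase = "test")
  )
  run <- run_schedule(gen$params, sched)
  n <- nrow(run)
  is_channel <- run$mode == "channel"
  angle <- ifelse(is_channel, NA_real_,
                  run$x + stats::rnorm(n, 0, gen$motor_noise_sd))
  force <- ifelse(is_channel,
                  gen$force_gain * run$x_plan + gen$force_offset +
                    stats::rnorm(n, 0, gen$force_noise_sd),
                  NA_real_)
  data.frame(
    subject_id = subject_id, group = as.integer(group_k),
    rotation_sign = sign, phase = run$phase, trial = run$trial,
    mode = run$mode, p_deg = run$p, x_deg = run$x, e_deg = run$e,
    pe_hat_deg = run$pe_hat, angle_deg = angle, force_au = force,
    excluded = FALSE, stringsAsFactors = FALSE
  )
}

#' Generate a probe-design subject for single-trial correction measurement
#'
#' A channel-trial protocol purpose-built to measure the single-trial
#' error-correction function under its stated zero-weight, zero-PE context:
#' each cycle is a quiet run of zero-perturbation channel trials (weights
#' decay geometrically, the PE relaxes to 0), one isolated probe rotation
#' drawn from `value_set`, and a read-out channel trial whose force expresses
#' the fresh correction. Uses the R random number generator.
#'
#' @param gen A [gen_config()].
#' @param n_cycles Number of probe cycles.
#' @param quiet_len Zero-perturbation trials per cycle before the probe.
#' @param subject_id Identifier stored in the table.
#' @return A trial-table data frame (all channel mode, `phase = "training"`).
#' @export
generate_probe_subject <- function(gen = gen_config(), n_cycles = 30,
                                   quiet_len = 40, subject_id = "s1") {
  stopifnot(inherits(gen, "pe_gen_config"), n_cycles >= 1, quiet_len >= 2)
  probes <- sample(gen$value_set, n_cycles, replace = TRUE)
  p <- unlist(lapply(probes, function(v) c(rep(0, quiet_len), v, 0)))
  sched <- new_schedule(p, rep("channel", length(p)),
                        rep("training", length(p)))
  run <- run_schedule(gen$params, sched)
  n <- nrow(run)
  force <- gen$force_gain * run$x_plan + gen$force_offset +
    stats::rnorm(n, 0, gen$force_noise_sd)
  data.frame(
    subject_id = subject_id, group = NA_integer_, rotation_sign = "ccw",
    phase = run$phase, trial = run$trial, mode = run$mode, p_deg = run$p,
    x_deg = run$x, e_deg = run$e, pe_hat_deg = run$pe_hat,
    angle_deg = NA_real_, force_au = force, excluded = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic group
#'
#' Twelve subjects by default, half assigned to the +30 (CCW) and half to the
#' -30 (CW) test rotation, with per-subject seeds derived from the master
#' seed.
#'
#' @param group_k Group (block length).
#' @param n_subjects Number of subjects (even).
#' @param gen A [gen_config()].
#' @param master_seed Integer master seed.
#' @return A trial-table data frame stacking all subjects.
#' @export
generate_group <- function(group_k, n_subjects = 12, gen = gen_config(),
                           master_seed = 1) {
  stopifnot(n_subjects >= 2, n_subjects %% 2 == 0)
  seeds <- derive_seeds(master_seed, n_subjects)
  signs <- rep(c("ccw", "cw"), each = n_subjects / 2)
  tabs <- lapply(seq_len(n_subjects), function(i) {
    set.seed(seeds[i])
    generate_subject(group_k, signs[i], gen,
                     subject_id = sprintf("g%d_s%02d", group_k, i))
  })
  do.call(rbind, tabs)
}

#' Fold CW subjects onto the CCW convention
#'
#' Negates the signed columns (`p_deg`, `x_deg`, `e_deg`, `pe_hat_deg`,
#' `angle_deg`, `force_au`) of rows belonging to CW subjects and relabels
#' them CCW, so the two rotation directions can be pooled; idempotent.
#'
#' @param table A trial-table data frame.
#' @return The normalized table.
#' @export
normalize_sign <- function(table) {
  stopifnot(is.data.frame(table), "rotation_sign" %in% names(table))
  cw <- table$rotation_sign == "cw"
  for (col in c("p_deg", "x_deg", "e_deg", "pe_hat_deg", "angle_deg",
                "force_au")) {
    table[[col]][cw] <- -table[[col]][cw]
  }
  table$rotation_sign[cw] <- "ccw"
  table
}

#' Inject one outlying test-phase angle
#'
#' Replaces a single subject's movement angle at one test trial by
#' `mean + multiplier * sd` of that trial's angles across subjects,
#' exercising the mean + 3 SD screening rule downstream. All other rows are
#' untouched.
#'
#' @param table A multi-subject trial-table data frame.
#' @param multiplier SD multiplier (> 0), relative to the column's moments
#'   before injection. Note the masking effect of one-pass screening: the
#'   screening mean and SD are recomputed including the outlier, so at a
#'   group size of 12 an injected value needs roughly 10 pre-injection SDs
#'   to exceed the mean + 3 SD threshold; smaller multipliers survive
#'   (the within-sample z-score is bounded by `(n - 1) / sqrt(n)`, about
#'   3.18 at n = 12, so the fence can only just be crossed).
#' @param trial Test trial to corrupt (default: drawn at random).
#' @param subject Subject to corrupt (default: drawn at random).
#' @return The table with one modified `angle_deg` and an attribute
#'   `outlier` locating it.
#' @export
inject_outlier <- function(table, multiplier = 4, trial = NULL,
                           subject = NULL) {
  stopifnot(multiplier > 0)
  te <- table$phase == "test"
  trials <- unique(table$trial[te])
  subjects <- unique(table$subject_id)
  if (is.null(trial)) trial <- sample(trials, 1)
  if (is.null(subject)) subject <- sample(subjects, 1)
  col <- te & table$trial == trial
  m <- mean(table$angle_deg[col])
  s <- stats::sd(table$angle_deg[col])
  row <- which(col & table$subject_id == subject)
  stopifnot(length(row) == 1)
  table$angle_deg[row] <- m + multiplier * s
  attr(table, "outlier") <- list(subject = subject, trial = trial,
                                 value = table$angle_deg[row])
  table
}
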