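TRIAL_TABLE_COLS <- c("subject_id", "group", "rotation_sign", "phase",
                      "trial", "mode", "p_deg", "x_deg", "e_deg",
                      "pe_hat_deg", "angle_deg", "force_au", "excluded")
TRIAL_MODES <- c("normal", "channel", "error_clamp")

#' Convert simulation records to the trial-table schema
#'
#' @param run A data frame from [run_schedule()].
#' @param subject_id,group,rotation_sign Identifiers to stamp on every row.
#' @return A trial-table data frame (angles/forces unset, for pure model
#'   runs).
#' @export
as_trial_table <- function(run, subject_id = "run1", group = NA_integer_,
                           rotation_sign = "ccw") {
  data.frame(
    subject_id = subject_id, group = as.integer(group),
    rotation_sign = rotation_sign, phase = run$phase, trial = run$trial,
    mode = run$mode, p_deg = run$p, x_deg = run$x, e_deg = run$e,
    pe_hat_deg = run$pe_hat, angle_deg = NA_real_, force_au = NA_real_,
    excluded = FALSE, stringsAsFactors = FALSE
  )
}

#' Write a trial table to CSV
#'
#' UTF-8, `.` decimal, full numeric precision (round-trips to at least
#' 1e-12).
#'
#' @param table A trial-table data frame (schema of [read_trial_table()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  missing <- setdiff(TRIAL_TABLE_COLS, names(table))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!table$mode %in% TRIAL_MODES)
  if (length(bad) > 0) {
    stop("invalid trial mode in row(s) ", paste(bad, collapse = ", "))
  }
  tab <- table[, TRIAL_TABLE_COLS]
  for (col in c("p_deg", "x_deg", "e_deg", "pe_hat_deg", "angle_deg",
                "force_au")) {
    tab[[col]] <- sprintf("%.15g", tab[[col]])
    tab[[col]][tab[[col]] == "NA"] <- ""
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' The schema is one row per trial with columns `subject_id`, `group`,
#' `rotation_sign`, `phase`, `trial`, `mode` (`normal` / `channel` /
#' `error_clamp`), `p_deg`, `x_deg`, `e_deg`, `pe_hat_deg`, `angle_deg`
#' (test/washout rows), `force_au` (channel rows) and `excluded`. Angles are
#' degrees, counter-clockwise positive.
#'
#' @param path CSV file written by [write_trial_table()].
#' @return A trial-table data frame.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(TRIAL_TABLE_COLS, names(tab))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!tab$mode %in% TRIAL_MODES)
  if (length(bad) > 0) {
    stop("unknown trial mode at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  tab$excluded <- as.logical(tab$excluded)
  tab
}

config_schema <- function() {
  list(
    params = c("lambda", "eta", "alpha", "sigma", "n_primitives",
               "mu_low", "mu_high"),
    noise = c("sigma_g", "sigma_xi", "sigma_zeta"),
    phase = c("phase", "type", "p", "n", "mode", "values", "block_len")
  )
}

#' Validate a run configuration
#'
#' Checks the structure of a configuration list: required keys, no unknown
#' keys, and parameter invariants (e.g. `alpha` in [0, 1]).
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly, or an error naming the offending keys.
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  top <- c("params", "noise", "phases", "n_runs", "master_seed")
  unknown <- setdiff(names(cfg), top)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in c("params", "phases", "n_runs", "master_seed")) {
    if (is.null(cfg[[k]])) stop("missing required config key: ", k)
  }
  unknown <- setdiff(names(cfg$params), schema$params)
  if (length(unknown) > 0) {
    stop("unknown params keys: ", paste(unknown, collapse = ", "))
  }
  # delegate numeric invariants to the constructors
  do.call(pe_params, cfg$params)
  if (!is.null(cfg$noise)) {
    unknown <- setdiff(names(cfg$noise), schema$noise)
    if (length(unknown) > 0) {
      stop("unknown noise keys: ", paste(unknown, collapse = ", "))
    }
    do.call(pe_noise, cfg$noise)
  }
  for (ph in cfg$phases) {
    unknown <- setdiff(names(ph), schema$phase)
    if (length(unknown) > 0) {
      stop("unknown phase keys: ", paste(unknown, collapse = ", "))
    }
    if (is.null(ph$type) || !ph$type %in% c("constant", "block_random")) {
      stop("phase `type` must be 'constant' or 'block_random'")
    }
    if (is.null(ph$n) || ph$n < 1) stop("phase `n` must be >= 1")
  }
  stopifnot(cfg$n_runs >= 1)
  invisible(cfg)
}

#' Read / write run configurations (YAML)
#'
#' @param path YAML file.
#' @return `read_config()` returns the validated configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg A configuration list (validated before writing).
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build the schedule described by a configuration
#'
#' @param cfg A validated configuration list.
#' @return A `pe_schedule` if all phases are deterministic, otherwise a
#'   function `function(run)` drawing a fresh schedule per run (for
#'   [run_ensemble()]).
#' @export
schedule_from_config <- function(cfg) {
  build <- function() {
    phases <- lapply(cfg$phases, function(ph) {
      mode <- if (is.null(ph$mode)) "normal" else ph$mode
      label <- if (is.null(ph$phase)) "phase" else ph$phase
      if (ph$type == "constant") {
        constant_schedule(ph$p, ph$n, mode = mode, phase = label)
      } else {
        block_random_schedule(unlist(ph$values), ph$block_len, ph$n,
                              mode = mode, phase = label)
      }
    })
    do.call(concat_phases, phases)
  }
  random <- any(vapply(cfg$phases, function(ph) ph$type == "block_random",
                       logical(1)))
  if (random) function(run) build() else build()
}

#' Run the simulation described by a configuration
#'
#' @param cfg A configuration list (or a YAML path).
#' @return A `pe_ensemble`.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  params <- do.call(pe_params, cfg$params)
  noise <- if (is.null(cfg$noise)) pe_noise() else do.call(pe_noise, cfg$noise)
  run_ensemble(params, schedule_from_config(cfg), cfg$n_runs,
               noise = noise, master_seed = cfg$master_seed)
}
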