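# Experiment definition files: fixed features in JSON, optional
# trial-specific features in CSV. Both are plain text so that experiment
# variants can be versioned and shared without touching code.

REQUIRED_TRIAL_COLS <- c("trial_number", "phase", "condition")
KNOWN_TRIAL_COLS <- c(REQUIRED_TRIAL_COLS, "reinforced", "iti_s",
                      "cs_duration_s", "us_onset_s",
                      "wall_color_r", "wall_color_g", "wall_color_b",
                      "start_x", "start_z")

#' Load an experiment definition
#'
#' Reads a JSON fixed-features file (room, US, stimuli, phases, search task,
#' tracker rate; all lengths in meters and times in seconds) and optionally a
#' trial-features CSV fixing the per-trial list. Missing optional keys are
#' filled with the package defaults; unknown keys are reported as warnings;
#' a missing `phases` key is an error.
#'
#' @param json_path Path to the JSON file.
#' @param trial_csv_path Optional path to a per-trial features CSV (columns
#'   `trial_number, phase, condition` required; `reinforced, iti_s,
#'   cs_duration_s, us_onset_s, wall_color_r/g/b, start_x, start_z`
#'   recognised). When given, [build_experiment()] on the returned spec
#'   reproduces this fixed trial list instead of randomising.
#' @return An [experiment_spec()]; any fixed trial table is attached as the
#'   `trial_table` element.
#' @export
load_experiment_config <- function(json_path, trial_csv_path = NULL) {
  if (!file.exists(json_path))
    stop(sprintf("config file not found: %s", json_path), call. = FALSE)
  cfg <- jsonlite::fromJSON(json_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  known <- c("name", "room", "us", "stimuli", "phases", "pedestal_position",
             "search_task", "tracker_rate_hz")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(cfg$phases) || length(cfg$phases) == 0L)
    stop("config validation failed: required field 'phases' is missing or empty",
         call. = FALSE)

  room <- do.call(room_spec, filter_args(cfg$room, names(formals(room_spec))))
  us <- do.call(us_field, filter_args(cfg$us, names(formals(us_field))))
  stimuli <- if (is.null(cfg$stimuli)) default_stimuli() else
    lapply(cfg$stimuli, function(s)
      do.call(stimulus_spec, filter_args(s, names(formals(stimulus_spec)))))
  search <- do.call(search_task_spec,
                    filter_args(cfg$search_task,
                                names(formals(search_task_spec))))
  phases <- lapply(cfg$phases, function(p) {
    if (is.null(p$phase_kind))
      stop("config validation failed: a phase entry is missing 'phase_kind'",
           call. = FALSE)
    kind <- p$phase_kind
    over <- filter_args(p[setdiff(names(p), "phase_kind")],
                        names(formals(phase_spec)))
    do.call(phase_defaults, c(list(phase_kind = kind), over))
  })
  spec <- experiment_spec(
    name = if (is.null(cfg$name)) tools::file_path_sans_ext(basename(json_path)) else cfg$name,
    phases = phases, room = room, us = us, stimuli = stimuli,
    pedestal_position = if (is.null(cfg$pedestal_position)) c(0, 1.1, 2.5) else as.numeric(cfg$pedestal_position),
    search_task = search,
    tracker_rate = if (is.null(cfg$tracker_rate_hz)) 90 else cfg$tracker_rate_hz)
  if (!is.null(trial_csv_path))
    spec$trial_table <- read_trial_features(trial_csv_path)
  spec
}

filter_args <- function(x, allowed) {
  if (is.null(x)) return(list())
  x <- x[!vapply(x, is.null, logical(1))]
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    warning(sprintf("ignoring unknown config keys: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  x[intersect(names(x), allowed)]
}

#' Write an experiment definition to JSON
#'
#' Inverse of [load_experiment_config()]: `load_experiment_config(
#' write_experiment_config(spec, path))` reproduces the spec.
#'
#' @param spec An [experiment_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(spec, path) {
  stopifnot(inherits(spec, "experiment_spec"))
  cfg <- list(
    name = spec$name,
    room = unclass(spec$room),
    us = unclass(spec$us),
    stimuli = lapply(spec$stimuli, unclass),
    pedestal_position = spec$pedestal_position,
    phases = lapply(spec$phases, unclass),
    search_task = unclass(spec$search_task),
    tracker_rate_hz = spec$tracker_rate
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read and validate a per-trial features CSV
#'
#' @param path CSV path (UTF-8, comma-separated, header row required).
#' @return A validated data frame, one row per trial.
#' @export
read_trial_features <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trial features file not found: %s", path), call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop(sprintf("trial features file %s contains no trials", path),
         call. = FALSE)
  missing <- setdiff(REQUIRED_TRIAL_COLS, names(tab))
  if (length(missing))
    stop(sprintf("trial features file %s is missing required columns: %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(tab), KNOWN_TRIAL_COLS)
  if (length(unknown))
    warning(sprintf("ignoring unknown trial feature columns: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$condition %in% c("CS+", "CS-", "none"))
      stop(sprintf("row %d: condition '%s' is not one of CS+, CS-, none",
                   i, row$condition), call. = FALSE)
    if (!is.null(tab$reinforced) && isTRUE(as.logical(row$reinforced)) &&
        row$condition == "CS-")
      stop(sprintf("row %d: a CS- trial cannot be reinforced", i),
           call. = FALSE)
    if (!is.null(tab$iti_s) && (is.na(row$iti_s) || row$iti_s < 0))
      stop(sprintf("row %d: iti_s must be a non-negative number", i),
           call. = FALSE)
  }
  tab
}

#' Packaged experiment templates
#'
#' Five validated experiment designs are shipped as JSON data files:
#'
#' * `exp1` — Pavlovian acquisition (16), avoidance learning (16),
#'   transfer (4), instructed extinction (16), transfer (4); no visible US
#'   source cue.
#' * `exp2` — as `exp1`, with the US source visibly cued.
#' * `exp3` — avoidance learning without preceding Pavlovian acquisition.
#' * `exp4` — as `exp2` plus a reinstatement phase (1 unsignalled US + 16
#'   trials).
#' * `exp5` — as `exp3` plus extinction recall (4), a second transfer, and
#'   reinstatement (1 unsignalled US + 6 trials), with a perceptually more
#'   distinct CS pair (blue cube vs. yellow cylinder).
#'
#' All templates start with a 40-s free-movement practice period that is
#' excluded from analyses.
#'
#' @param name One of `"exp1"` ... `"exp5"`, or a path to a JSON config.
#' @return An [experiment_spec()].
#' @export
experiment_template <- function(name) {
  if (file.exists(name)) return(load_experiment_config(name))
  path <- system.file("extdata", "templates", paste0(name, ".json"),
                      package = "avoidsim")
  if (path == "")
    stop(sprintf("unknown experiment template '%s' (expected exp1..exp5 or a config path)",
                 name), call. = FALSE)
  load_experiment_config(path)
}
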