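# Session persistence in the one-row-per-trial + one-movement-CSV-per-
# tracker-per-trial layout used by Unity Experiment Framework style loggers.
#
# Layout: <dir>/trial_results.csv          one row per trial
#         <dir>/trackers/<tracker>_T<k>.csv  per-trial movement samples
#         <dir>/events.csv                 event markers (session time)
#         <dir>/spec.json                  experiment definition snapshot
#
# Tracker files hold trial-relative time (0 = CS onset) so per-trial
# kinematics are self-contained; session-relative onsets live in
# trial_results.csv.

TRACKER_COLS <- c("time_s", "pos_x", "pos_y", "pos_z", "yaw_deg")

# Common aliases seen in third-party exports of this layout.
TRACKER_ALIASES <- c(time = "time_s", t = "time_s",
                     x = "pos_x", y = "pos_y", z = "pos_z",
                     yaw = "yaw_deg", heading = "yaw_deg")

#' Write a session to disk
#'
#' @param session A [run_session()] `session_log`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, a manifest data frame listing every file written with
#'   its row count.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "session_log"))
  dir.create(file.path(directory, "trackers"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create session directory %s", directory),
         call. = FALSE)

  trials <- session$trials
  trials$head_file <- ifelse(
    vapply(session$traces, is.null, logical(1)), NA_character_,
    file.path("trackers", sprintf("head_T%03d.csv", trials$trial_num)))

  manifest <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- session$traces[[i]]
    if (is.null(tr)) next
    f <- file.path(directory, trials$head_file[i])
    df <- as.data.frame(tr[, TRACKER_COLS, drop = FALSE])
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(file = trials$head_file[i], rows = nrow(df),
                 stringsAsFactors = FALSE)
  }

  write.csv(trials, file.path(directory, "trial_results.csv"),
            row.names = FALSE, na = "")
  write.csv(session$events, file.path(directory, "events.csv"),
            row.names = FALSE, na = "")
  write_experiment_config(session$spec, file.path(directory, "spec.json"))
  meta <- list(participant_id = session$participant_id,
               experiment = session$experiment)
  if (!is.null(session$cs_assignment))
    meta$cs_plus_stimulus <- session$cs_assignment[["CS+"]]$shape
  jsonlite::write_json(meta, file.path(directory, "session.json"),
                       auto_unbox = TRUE)

  manifest[[length(manifest) + 1L]] <-
    data.frame(file = "trial_results.csv", rows = nrow(trials),
               stringsAsFactors = FALSE)
  manifest[[length(manifest) + 1L]] <-
    data.frame(file = "events.csv", rows = nrow(session$events),
               stringsAsFactors = FALSE)
  manifest[[length(manifest) + 1L]] <-
    data.frame(file = "spec.json", rows = NA_integer_,
               stringsAsFactors = FALSE)
  invisible(do.call(rbind, manifest))
}

#' Read a session directory
#'
#' Inverse of [write_session()] up to serialisation precision. Tracker files
#' with aliased column names (`time`, `x`, `yaw`, ...) are accepted with a
#' warning; missing tracker files referenced by the trial table, and
#' non-monotone timestamps, are errors that name the offending trial/file.
#'
#' @param directory Session directory.
#' @return A `session_log`.
#' @export
read_session <- function(directory) {
  res_file <- file.path(directory, "trial_results.csv")
  if (!file.exists(res_file))
    stop(sprintf("%s is not a session directory (no trial_results.csv)",
                 directory), call. = FALSE)
  trials <- read.csv(res_file, stringsAsFactors = FALSE)
  spec <- load_experiment_config(file.path(directory, "spec.json"))
  events_file <- file.path(directory, "events.csv")
  events <- if (file.exists(events_file))
    read.csv(events_file, stringsAsFactors = FALSE) else NULL
  meta_file <- file.path(directory, "session.json")
  meta <- if (file.exists(meta_file)) jsonlite::fromJSON(meta_file) else list()

  traces <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    f <- trials$head_file[i]
    if (is.na(f) || !nzchar(f)) next
    path <- file.path(directory, f)
    if (!file.exists(path))
      stop(sprintf("trial %d references missing tracker file %s",
                   trials$trial_num[i], f), call. = FALSE)
    traces[[i]] <- read_tracker_file(path, spec$tracker_rate)
  }
  structure(list(
    participant_id = if (!is.null(meta$participant_id)) meta$participant_id
      else trials$ppid[1],
    experiment = if (!is.null(meta$experiment)) meta$experiment else spec$name,
    trials = trials, traces = traces, events = events, spec = spec,
    agent_state = NULL, cs_assignment = NULL),
    class = "session_log")
}

read_tracker_file <- function(path, rate = NA_real_) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("cannot parse tracker file %s: %s",
                                path, conditionMessage(e)), call. = FALSE))
  hit <- names(df) %in% names(TRACKER_ALIASES)
  if (any(hit)) {
    warning(sprintf("tracker file %s uses aliased column names (%s); mapping to the standard vocabulary",
                    basename(path), paste(names(df)[hit], collapse = ", ")),
            call. = FALSE)
    names(df)[hit] <- TRACKER_ALIASES[names(df)[hit]]
  }
  missing <- setdiff(setdiff(TRACKER_COLS, "yaw_deg"), names(df))
  if (length(missing))
    stop(sprintf("tracker file %s is missing columns: %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  if (!"yaw_deg" %in% names(df)) df$yaw_deg <- NA_real_
  for (cc in TRACKER_COLS) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  bad <- which(!complete.cases(df[, c("time_s", "pos_x", "pos_y", "pos_z")]))
  if (length(bad))
    stop(sprintf("tracker file %s: malformed sample at row %d",
                 path, bad[1] + 1L), call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    row <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(sprintf("tracker file %s: timestamps not strictly increasing at row %d",
                 path, row + 1L), call. = FALSE)
  }
  m <- as.matrix(df[, TRACKER_COLS])
  attr(m, "tracker_id") <- "head"
  attr(m, "nominal_rate") <- rate
  attr(m, "handedness") <- "left_y_up"
  m
}

#' Convert a trace between left- and right-handed y-up frames
#'
#' Negates the z axis and re-expresses yaw consistently
#' (`yaw' = 180 - yaw`, modulo 360), so that headings keep pointing at the
#' same physical landmarks; applying the conversion twice is the identity,
#' and all distances and relative angles are invariant when the CS position
#' is co-converted.
#'
#' @param trace A tracker sample matrix (columns `time_s, pos_x, pos_y,
#'   pos_z, yaw_deg`).
#' @param target `"left_y_up"` or `"right_y_up"`.
#' @return The converted trace, with its `handedness` attribute updated.
#' @export
convert_handedness <- function(trace, target = c("left_y_up", "right_y_up")) {
  target <- match.arg(target)
  current <- attr(trace, "handedness")
  if (is.null(current)) current <- "left_y_up"
  if (current == target) return(trace)
  out <- trace
  out[, "pos_z"] <- -trace[, "pos_z"]
  out[, "yaw_deg"] <- (180 - trace[, "yaw_deg"]) %% 360
  attr(out, "handedness") <- target
  out
}
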