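# Seven trial-level kinematic summary statistics from a head-tracker trace,
# computed over the CS-onset -> US-onset analysis window:
#   mean / maximum / minimum distance to the CS location, total distance
#   travelled (path length), maximum speed, mean head direction relative to
#   the CS, and reaction time of the first move away from the CS-onset
#   position (0.7 m displacement criterion).
#
# All distance-based quantities use the horizontal (x, z) projection by
# default: locomotor avoidance is horizontal and the pedestal height is
# constant. A 3-D mode is available for paradigms where height matters.

#' Restrict a trace to an analysis window
#'
#' Keeps samples with `t0 <= time_s < t1`, preserving order.
#'
#' @param trace Tracker sample matrix.
#' @param window `c(t0, t1)` in trial time (seconds; CS onset = 0).
#' @return The windowed trace.
#' @export
extract_window <- function(trace, window = c(0, 8)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- trace[, "time_s"] >= window[1] & trace[, "time_s"] < window[2]
  if (!any(keep))
    stop(sprintf("no samples in analysis window [%g, %g)",
                 window[1], window[2]), call. = FALSE)
  out <- trace[keep, , drop = FALSE]
  for (a in c("tracker_id", "nominal_rate", "handedness"))
    attr(out, a) <- attr(trace, a)
  out
}

#' Distance from head to CS location
#'
#' @param x,y,z Head position (vectorised), meters.
#' @param cs_position 3-D CS location.
#' @param mode `"2d"` (horizontal x-z plane, default) or `"3d"`.
#' @return Distance(s) in meters.
#' @export
distance_to_cs <- function(x, y, z, cs_position, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (mode == "2d")
    sqrt((x - cs_position[1])^2 + (z - cs_position[3])^2)
  else
    sqrt((x - cs_position[1])^2 + (y - cs_position[2])^2 +
         (z - cs_position[3])^2)
}

#' Head direction relative to the CS
#'
#' Absolute angle in `[0, 180]` degrees between the horizontal heading
#' vector (from yaw) and the horizontal bearing from head to CS; 0 means
#' facing the CS, 180 facing directly away.
#'
#' @param x,z Head position (vectorised).
#' @param yaw_deg Heading in degrees (0 = +z, increasing toward +x).
#' @param cs_position 3-D CS location.
#' @return Angle(s) in degrees; `NA` where yaw is missing or the head is at
#'   the CS ground point (undefined bearing).
#' @export
head_angle <- function(x, z, yaw_deg, cs_position) {
  bearing <- atan2(cs_position[1] - x, cs_position[3] - z) * 180 / pi
  d <- sqrt((x - cs_position[1])^2 + (z - cs_position[3])^2)
  ang <- abs(((yaw_deg - bearing + 180) %% 360) - 180)
  ang[d < 1e-12] <- NA_real_
  ang
}

#' Reaction time of the first move away
#'
#' Earliest sample time at which the horizontal displacement from the
#' window's first sample reaches `threshold` meters. Displacement from the
#' CS-onset position counts regardless of direction, i.e. a move that
#' decreases the distance to the CS still triggers the criterion.
#'
#' @param trace Tracker sample matrix.
#' @param window Analysis window, passed to [extract_window()].
#' @param threshold Displacement criterion in meters (default 0.7).
#' @return Time in seconds, or `NA` (censored) if the criterion is never
#'   met within the window.
#' @export
reaction_time <- function(trace, window = c(0, 8), threshold = 0.7) {
  stopifnot(threshold > 0)
  w <- extract_window(trace, window)
  disp <- sqrt((w[, "pos_x"] - w[1, "pos_x"])^2 +
               (w[, "pos_z"] - w[1, "pos_z"])^2)
  idx <- which(disp >= threshold)
  if (!length(idx)) return(NA_real_)
  unname(w[idx[1], "time_s"])
}

#' Seven trial-level kinematic summaries
#'
#' @param trace Tracker sample matrix for one trial (trial time, 0 = CS
#'   onset).
#' @param cs_position 3-D CS location.
#' @param window Analysis window `c(t0, t1)`; default CS onset to US onset,
#'   `c(0, 8)`.
#' @param distance_mode `"2d"` or `"3d"`, see [distance_to_cs()].
#' @param rt_threshold Reaction-time displacement criterion, meters.
#' @param smooth_window Odd number of samples for a centered moving-average
#'   position smoother applied before all computations; 0 (default)
#'   disables it. Raw finite-difference path lengths and speeds are
#'   noise-inflated on jittery hardware traces; the smoother trades a
#'   little temporal resolution for robustness.
#' @return An object of class `kinematic_summary`: a named list with
#'   `mean_dist_m`, `max_dist_m`, `min_dist_m`, `path_len_m`,
#'   `max_speed_mps`, `head_angle_deg` (mean; `NA` if yaw missing), `rt_s`
#'   (`NA` = censored), and `n_samples`.
#' @export
summarize_trial <- function(trace, cs_position, window = c(0, 8),
                            distance_mode = c("2d", "3d"),
                            rt_threshold = 0.7, smooth_window = 0L) {
  distance_mode <- match.arg(distance_mode)
  if (smooth_window > 1L) trace <- smooth_trace(trace, smooth_window)
  w <- extract_window(trace, window)
  if (nrow(w) < 2L)
    stop("need at least 2 samples in the analysis window", call. = FALSE)
  d <- distance_to_cs(w[, "pos_x"], w[, "pos_y"], w[, "pos_z"],
                      cs_position, distance_mode)
  dx <- diff(w[, "pos_x"])
  dz <- diff(w[, "pos_z"])
  step <- if (distance_mode == "2d") sqrt(dx^2 + dz^2) else
    sqrt(dx^2 + diff(w[, "pos_y"])^2 + dz^2)
  dt <- diff(w[, "time_s"])
  ang <- if (all(is.na(w[, "yaw_deg"]))) NA_real_ else
    mean(head_angle(w[, "pos_x"], w[, "pos_z"], w[, "yaw_deg"],
                    cs_position), na.rm = TRUE)
  structure(list(
    mean_dist_m = mean(d),
    max_dist_m = max(d),
    min_dist_m = min(d),
    path_len_m = sum(step),
    max_speed_mps = max(step / dt),
    head_angle_deg = ang,
    rt_s = reaction_time(trace, window, rt_threshold),
    n_samples = nrow(w)), class = "kinematic_summary")
}

# Centered moving average of the position columns (window k, odd); the ends
# use shrunken symmetric windows so the trace length is preserved.
smooth_trace <- function(trace, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("smooth_window must be odd", call. = FALSE)
  h <- k %/% 2L
  n <- nrow(trace)
  out <- trace
  for (col in c("pos_x", "pos_y", "pos_z")) {
    v <- trace[, col]
    cs <- cumsum(c(0, v))
    i <- seq_len(n)
    lo <- pmax(1L, i - h)
    hi <- pmin(n, i + h)
    out[, col] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf(
    "<kinematic_summary> dist mean/min/max %.3f/%.3f/%.3f m, path %.3f m, max speed %.3f m/s, head angle %.1f deg, RT %s (%d samples)\n",
    x$mean_dist_m, x$min_dist_m, x$max_dist_m, x$path_len_m,
    x$max_speed_mps, x$head_angle_deg,
    if (is.na(x$rt_s)) "censored" else sprintf("%.3f s", x$rt_s),
    x$n_samples))
  invisible(x)
}

# Analysis window for one trial record: CS onset to the scheduled US onset
# (8 s for 9-s conditioning trials, including unreinforced ones); transfer
# and practice trials, which schedule no US, default to the full CS period.
trial_window <- function(cs_duration_s, scheduled_us_onset_s,
                         transfer_window = c("full", "nominal"),
                         nominal = 8) {
  transfer_window <- match.arg(transfer_window)
  t1 <- if (!is.na(scheduled_us_onset_s)) scheduled_us_onset_s
        else if (transfer_window == "nominal") min(nominal, cs_duration_s)
        else cs_duration_s
  c(0, t1)
}

#' Kinematic summaries for every trial of a session
#'
#' Appends the seven summary columns (`mean_dist_m`, `max_dist_m`,
#' `min_dist_m`, `path_len_m`, `max_speed_mps`, `head_angle_deg`, `rt_s`)
#' to the session's trial table. Trials without a CS period (practice,
#' unsignalled US) get `NA` summaries. The analysis window runs from CS
#' onset to the scheduled US onset; trials that schedule no US (transfer)
#' use the full CS period by default.
#'
#' @param session A `session_log` (from [run_session()] or
#'   [read_session()]).
#' @param distance_mode,rt_threshold Passed to [summarize_trial()].
#' @param transfer_window `"full"` (default) or `"nominal"` (cut transfer
#'   trials at the conditioning phases' 8-s US onset).
#' @return The trial table with summary columns appended.
#' @export
summarize_session <- function(session, distance_mode = c("2d", "3d"),
                              rt_threshold = 0.7,
                              transfer_window = c("full", "nominal")) {
  stopifnot(inherits(session, "session_log"))
  distance_mode <- match.arg(distance_mode)
  transfer_window <- match.arg(transfer_window)
  trials <- session$trials
  cs <- session$spec$pedestal_position
  cols <- c("mean_dist_m", "max_dist_m", "min_dist_m", "path_len_m",
            "max_speed_mps", "head_angle_deg", "rt_s")
  for (cc in cols) trials[[cc]] <- NA_real_
  for (i in seq_len(nrow(trials))) {
    tr <- session$traces[[i]]
    if (is.null(tr) || !trials$condition[i] %in% c("CS+", "CS-")) next
    win <- trial_window(trials$cs_duration_s[i],
                        trials$scheduled_us_onset_s[i], transfer_window)
    s <- summarize_trial(tr, cs, win, distance_mode, rt_threshold)
    for (cc in cols) trials[[cc]][i] <- s[[cc]]
  }
  trials
}

#' Augment a stored session with kinematic summaries
#'
#' Batch entry point: reads a session directory, computes the seven
#' summaries per trial, and rewrites `trial_results.csv` with the summary
#' columns appended.
#'
#' @param directory Session directory (layout of [write_session()]).
#' @param ... Passed to [summarize_session()].
#' @return The augmented trial table, invisibly.
#' @export
augment_session_dir <- function(directory, ...) {
  session <- read_session(directory)
  trials <- summarize_session(session, ...)
  write.csv(trials, file.path(directory, "trial_results.csv"),
            row.names = FALSE, na = "")
  invisible(trials)
}
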