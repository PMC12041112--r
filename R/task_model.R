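# Declarative task model: room, US sound field, CS, phases, trial schedules.
#
# Geometry convention (matches the Unity-style logs this package reads and
# writes): left-handed, y-up, distances in meters. The room is centered on
# the origin in the horizontal (x, z) plane with the floor at y = 0. The CS
# pedestal sits at `pedestal_position`; phase starting points lie on the -z
# side of the pedestal at the phase's start distance.

PHASE_KINDS <- c(
  "practice", "pavlovian_acquisition", "avoidance_learning", "transfer",
  "instructed_extinction", "extinction_recall", "reinstatement"
)

#' Virtual room description
#'
#' @param width,depth,height Room extents in meters. Default 8 x 8 x 3.
#' @param wall_color Integer RGB triple (0-255), settable per trial to
#'   implement simple context manipulations.
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(width = 8, depth = 8, height = 3,
                      wall_color = c(128L, 128L, 128L)) {
  stopifnot(width > 0, depth > 0, height > 0)
  wall_color <- as.integer(wall_color)
  if (length(wall_color) != 3L || any(wall_color < 0L) || any(wall_color > 255L))
    stop("wall_color must be an RGB triple in 0-255", call. = FALSE)
  structure(list(width = width, depth = depth, height = height,
                 wall_color = wall_color), class = "room_spec")
}

#' Unconditioned-stimulus sound field
#'
#' The US is a short loud sound whose intensity decays linearly with distance
#' from its source, so that there is a sharp radius beyond which it is
#' inaudible (`1 / decay_per_m` meters).
#'
#' @param intensity_db Sound level at zero distance from the source, in dB.
#'   Default 80.
#' @param decay_per_m Fraction of the source intensity lost per meter.
#'   Default 0.25 (inaudible at 4 m).
#' @param duration_s US duration in seconds. Default 1.
#' @param source_position 3-D source location in meters (defaults to under
#'   the CS pedestal).
#' @param vibration_cue Logical; if `TRUE` the source is visibly marked when
#'   the US plays, so a simulated agent perceives US occurrence regardless of
#'   distance. If `FALSE` the US goes unnoticed beyond the audible radius.
#' @return An object of class `us_field`.
#' @export
us_field <- function(intensity_db = 80, decay_per_m = 0.25, duration_s = 1,
                     source_position = c(0, 1.1, 2.5), vibration_cue = FALSE) {
  stopifnot(intensity_db >= 0, duration_s > 0, length(source_position) == 3L)
  if (!(decay_per_m > 0 && decay_per_m <= 1))
    stop("decay_per_m must be in (0, 1]", call. = FALSE)
  structure(list(intensity_db = intensity_db, decay_per_m = decay_per_m,
                 duration_s = duration_s,
                 source_position = as.numeric(source_position),
                 vibration_cue = isTRUE(vibration_cue)),
            class = "us_field")
}

#' US intensity at a distance
#'
#' Linear decay: `intensity_db * max(0, 1 - decay_per_m * distance)`. The
#' result is never negative; beyond `1 / decay_per_m` meters the US is
#' inaudible (0 dB).
#'
#' @param field A [us_field()].
#' @param distance Distance from the source in meters (vectorised), `>= 0`.
#' @return Intensity in dB, same length as `distance`.
#' @examples
#' f <- us_field()
#' us_intensity(f, c(0, 2, 4, 10)) # 80 40 0 0
#' @export
us_intensity <- function(field, distance) {
  stopifnot(inherits(field, "us_field"))
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  field$intensity_db * pmax(0, 1 - field$decay_per_m * distance)
}

#' Sample inter-trial intervals
#'
#' ITIs are drawn from a uniform distribution on `[lo, hi]` seconds
#' (default 9-15 s, mean 12 s).
#'
#' @param n Number of draws.
#' @param lo,hi Interval bounds in seconds, `lo <= hi`.
#' @return Numeric vector of length `n`.
#' @export
sample_iti <- function(n = 1, lo = 9, hi = 15) {
  if (lo > hi) stop("iti range invalid: lo > hi", call. = FALSE)
  runif(n, lo, hi)
}

#' Conditioned-stimulus description
#'
#' @param cs_label `"CS+"` or `"CS-"` (the default role; counterbalancing may
#'   swap roles across participants).
#' @param shape Shape identifier, e.g. `"cube"`.
#' @param color Integer RGB triple (0-255).
#' @param size 3-D extents in meters.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(cs_label, shape = "cube",
                          color = c(128L, 128L, 128L),
                          size = c(0.2, 0.2, 0.2)) {
  cs_label <- match.arg(cs_label, c("CS+", "CS-"))
  structure(list(cs_label = cs_label, shape = shape,
                 color = as.integer(color), size = as.numeric(size)),
            class = "stimulus_spec")
}

#' Incidental search (coin-collection) task settings
#'
#' During transfer trials, coins appear one at a time inside a horizontal
#' ellipse in front of the starting point and must be touched by the hand to
#' be collected.
#'
#' @param coin_lifetime Seconds each coin stays up. Default 1.
#' @param spawn_ellipse_width,spawn_ellipse_depth Ellipse extents in meters.
#'   Default 2 x 2.
#' @param spawn_height Coin height above the floor, meters. Default 1.
#' @param ellipse_center_offset Distance of the ellipse center in front of
#'   the starting point (toward the pedestal), meters. Default 1.
#' @param collection_radius Hand-to-coin distance that counts as a
#'   collection, meters. Default 0.15.
#' @return An object of class `search_task_spec`.
#' @export
search_task_spec <- function(coin_lifetime = 1, spawn_ellipse_width = 2,
                             spawn_ellipse_depth = 2, spawn_height = 1,
                             ellipse_center_offset = 1,
                             collection_radius = 0.15) {
  stopifnot(coin_lifetime > 0, spawn_ellipse_width > 0,
            spawn_ellipse_depth > 0, collection_radius > 0)
  structure(list(coin_lifetime = coin_lifetime,
                 spawn_ellipse_width = spawn_ellipse_width,
                 spawn_ellipse_depth = spawn_ellipse_depth,
                 spawn_height = spawn_height,
                 ellipse_center_offset = ellipse_center_offset,
                 collection_radius = collection_radius),
            class = "search_task_spec")
}

#' Experimental phase description
#'
#' @param phase_kind One of `r paste0('"', PHASE_KINDS, '"', collapse = ", ")`.
#' @param n_trials_per_condition Trials per condition (CS+ and CS-). The
#'   practice phase ignores this and consists of a single free-movement
#'   period without CS.
#' @param reinforcement_rate Fraction of CS+ trials on which the US is
#'   delivered. Must produce an integer count of reinforced trials.
#' @param cs_duration CS presentation time, seconds (9 for conditioning
#'   phases, 21 for transfer).
#' @param us_onset Scheduled US onset in seconds after CS onset (`NA` for
#'   phases that never schedule a US and have no nominal analysis cut, i.e.
#'   practice and transfer). For reinforced trials the US co-terminates with
#'   the CS, so `us_onset + us_duration` must equal `cs_duration`.
#' @param start_distance Starting-point distance from the CS pedestal,
#'   meters.
#' @param iti_range Two-element `c(lo, hi)` uniform ITI bounds, seconds.
#' @param movement_allowed Logical; `FALSE` for the seated Pavlovian
#'   acquisition phase.
#' @param instructed_approach Logical; `TRUE` when a prompt instructs
#'   participants to approach the CS (instructed extinction).
#' @param search_task Logical; `TRUE` when the coin task runs (transfer).
#' @param pre_phase_us Count of unsignalled US deliveries before the first
#'   trial of the phase (reinstatement).
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(phase_kind, n_trials_per_condition = 8,
                       reinforcement_rate = 0, cs_duration = 9, us_onset = 8,
                       start_distance = 1, iti_range = c(9, 15),
                       movement_allowed = TRUE, instructed_approach = FALSE,
                       search_task = FALSE, pre_phase_us = 0L) {
  phase_kind <- match.arg(phase_kind, PHASE_KINDS)
  if (reinforcement_rate < 0 || reinforcement_rate > 1)
    stop("reinforcement_rate must be in [0, 1]", call. = FALSE)
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2])
    stop("iti_range must be c(lo, hi) with lo <= hi", call. = FALSE)
  stopifnot(n_trials_per_condition >= 0, cs_duration > 0, start_distance >= 0,
            pre_phase_us >= 0)
  n_reinf <- reinforcement_rate * n_trials_per_condition
  if (abs(n_reinf - round(n_reinf)) > 1e-9)
    stop(sprintf(
      "reinforcement_rate %.4g x %d CS+ trials is not an integer count; refusing to round",
      reinforcement_rate, as.integer(n_trials_per_condition)), call. = FALSE)
  structure(list(phase_kind = phase_kind,
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 reinforcement_rate = reinforcement_rate,
                 cs_duration = cs_duration, us_onset = us_onset,
                 start_distance = start_distance,
                 iti_range = as.numeric(iti_range),
                 movement_allowed = isTRUE(movement_allowed),
                 instructed_approach = isTRUE(instructed_approach),
                 search_task = isTRUE(search_task),
                 pre_phase_us = as.integer(pre_phase_us)),
            class = "phase_spec")
}

#' Canonical phase settings
#'
#' Returns a [phase_spec()] with the validated defaults of each phase kind:
#' 9-s CS with US onset at 8 s and 75% partial reinforcement for Pavlovian
#' acquisition (seated, 2 m) and avoidance learning (free movement, 1 m
#' start); 21-s unreinforced CS with the coin task for transfer (2.5 m
#' start); unreinforced 9-s CS with an approach instruction from 4 m for
#' instructed extinction; 4-trial uninstructed extinction recall from 1 m;
#' reinstatement preceded by one unsignalled US.
#'
#' @param phase_kind Phase kind string.
#' @param ... Overrides passed on to [phase_spec()].
#' @return A `phase_spec`.
#' @export
phase_defaults <- function(phase_kind, ...) {
  phase_kind <- match.arg(phase_kind, PHASE_KINDS)
  base <- switch(phase_kind,
    practice = list(n_trials_per_condition = 0L, reinforcement_rate = 0,
                    cs_duration = 40, us_onset = NA_real_, start_distance = 2,
                    movement_allowed = TRUE),
    pavlovian_acquisition = list(n_trials_per_condition = 8L,
                                 reinforcement_rate = 0.75, cs_duration = 9,
                                 us_onset = 8, start_distance = 2,
                                 movement_allowed = FALSE),
    avoidance_learning = list(n_trials_per_condition = 8L,
                              reinforcement_rate = 0.75, cs_duration = 9,
                              us_onset = 8, start_distance = 1),
    transfer = list(n_trials_per_condition = 2L, reinforcement_rate = 0,
                    cs_duration = 21, us_onset = NA_real_,
                    start_distance = 2.5, search_task = TRUE),
    instructed_extinction = list(n_trials_per_condition = 8L,
                                 reinforcement_rate = 0, cs_duration = 9,
                                 us_onset = 8, start_distance = 4,
                                 instructed_approach = TRUE),
    extinction_recall = list(n_trials_per_condition = 2L,
                             reinforcement_rate = 0, cs_duration = 9,
                             us_onset = 8, start_distance = 1),
    reinstatement = list(n_trials_per_condition = 8L, reinforcement_rate = 0,
                         cs_duration = 9, us_onset = 8, start_distance = 1,
                         pre_phase_us = 1L)
  )
  args <- modifyList(c(list(phase_kind = phase_kind), base), list(...))
  do.call(phase_spec, args)
}

#' Full experiment description
#'
#' @param name Experiment name (used in logs and manifests).
#' @param phases List of [phase_spec()] objects, in presentation order.
#' @param room A [room_spec()].
#' @param us A [us_field()].
#' @param stimuli List of two [stimulus_spec()]s (default CS+ and CS- roles).
#' @param pedestal_position 3-D CS pedestal location, meters.
#' @param search_task A [search_task_spec()].
#' @param tracker_rate Head-tracker sampling rate in Hz (80-120 for parity
#'   with headset hardware; default 90).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, phases, room = room_spec(),
                            us = us_field(),
                            stimuli = default_stimuli(),
                            pedestal_position = c(0, 1.1, 2.5),
                            search_task = search_task_spec(),
                            tracker_rate = 90) {
  if (length(phases) == 0L) stop("phases must be nonempty", call. = FALSE)
  stopifnot(all(vapply(phases, inherits, logical(1), "phase_spec")),
            inherits(room, "room_spec"), inherits(us, "us_field"),
            length(stimuli) %in% c(1L, 2L),
            all(vapply(stimuli, inherits, logical(1), "stimulus_spec")),
            inherits(search_task, "search_task_spec"),
            tracker_rate > 0)
  for (ph in phases) {
    if (ph$reinforcement_rate > 0 &&
        abs(ph$us_onset + us$duration_s - ph$cs_duration) > 1e-9)
      stop(sprintf(
        "phase '%s': us_onset (%g) + us duration (%g) must equal cs_duration (%g) so the US co-terminates with the CS",
        ph$phase_kind, ph$us_onset, us$duration_s, ph$cs_duration),
        call. = FALSE)
  }
  structure(list(name = name, phases = phases, room = room, us = us,
                 stimuli = stimuli,
                 pedestal_position = as.numeric(pedestal_position),
                 search_task = search_task, tracker_rate = tracker_rate),
            class = "experiment_spec")
}

#' Default CS pair
#'
#' A blue cube and a dark green cube, 0.2 m each, with the blue cube in the
#' CS+ role before counterbalancing.
#' @return List of two [stimulus_spec()]s.
#' @export
default_stimuli <- function() {
  list(stimulus_spec("CS+", "cube", c(46L, 61L, 124L), c(0.2, 0.2, 0.2)),
       stimulus_spec("CS-", "cube", c(5L, 31L, 32L), c(0.2, 0.2, 0.2)))
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %s\n", x$name))
  cat(sprintf("  room %g x %g x %g m; pedestal at (%g, %g, %g); tracker %g Hz\n",
              x$room$width, x$room$depth, x$room$height,
              x$pedestal_position[1], x$pedestal_position[2],
              x$pedestal_position[3], x$tracker_rate))
  cat(sprintf("  US: %g dB, %g%%/m decay (inaudible beyond %g m), %g s%s\n",
              x$us$intensity_db, 100 * x$us$decay_per_m,
              1 / x$us$decay_per_m, x$us$duration_s,
              if (x$us$vibration_cue) ", source visibly cued" else ""))
  for (i in seq_along(x$phases)) {
    ph <- x$phases[[i]]
    cat(sprintf(
      "  %d. %-22s %2d/cond, reinf %.0f%%, CS %g s, start %g m%s\n",
      i, ph$phase_kind, ph$n_trials_per_condition,
      100 * ph$reinforcement_rate, ph$cs_duration, ph$start_distance,
      if (ph$pre_phase_us > 0)
        sprintf(", %d unsignalled US", ph$pre_phase_us) else ""))
  }
  invisible(x)
}

# Starting point: on the -z side of the pedestal at the given distance.
start_position <- function(spec, distance) {
  c(spec$pedestal_position[1], spec$pedestal_position[3] - distance)
}

#' Generate the trial list for one phase
#'
#' Conditions are interleaved by a uniform random permutation; exactly
#' `round(reinforcement_rate * n_trials_per_condition)` CS+ trials are
#' flagged reinforced, chosen uniformly at random; CS- trials are never
#' reinforced. Each trial carries an ITI drawn from the phase's uniform
#' range. An optional maximum run length supports pseudo-randomised orders.
#'
#' @param phase A [phase_spec()].
#' @param max_run Maximum tolerated run of identical conditions; `Inf`
#'   (default) means unconstrained uniform permutation.
#' @return A data frame with one row per trial: `trial_number` (1-based,
#'   across conditions; unsignalled pre-phase US rows have `trial_number` 0
#'   and condition `"none"`), `condition`, `reinforced`, `iti_s`,
#'   `cs_duration_s`, `us_onset_s` (`NA` unless reinforced),
#'   `scheduled_us_onset_s` (the phase's nominal US onset, for analysis
#'   windows).
#' @export
build_phase_schedule <- function(phase, max_run = Inf) {
  stopifnot(inherits(phase, "phase_spec"))
  pre <- if (phase$pre_phase_us > 0L) {
    data.frame(trial_number = 0L, condition = "none", reinforced = TRUE,
               iti_s = sample_iti(phase$pre_phase_us, phase$iti_range[1],
                                  phase$iti_range[2]),
               cs_duration_s = 0, us_onset_s = 0,
               scheduled_us_onset_s = NA_real_,
               stringsAsFactors = FALSE)
  } else NULL

  n <- phase$n_trials_per_condition
  if (phase$phase_kind == "practice") {
    body <- data.frame(trial_number = 1L, condition = "none",
                       reinforced = FALSE,
                       iti_s = sample_iti(1, phase$iti_range[1],
                                          phase$iti_range[2]),
                       cs_duration_s = phase$cs_duration,
                       us_onset_s = NA_real_,
                       scheduled_us_onset_s = NA_real_,
                       stringsAsFactors = FALSE)
  } else if (n == 0L) {
    body <- NULL
  } else {
    cond <- rep(c("CS+", "CS-"), each = n)
    repeat {
      cond <- sample(cond)
      runs <- rle(cond)$lengths
      if (max(runs) <= max_run) break
    }
    n_reinf <- as.integer(round(phase$reinforcement_rate * n))
    reinforced <- rep(FALSE, 2L * n)
    if (n_reinf > 0L) {
      plus_idx <- which(cond == "CS+")
      reinforced[sample(plus_idx, n_reinf)] <- TRUE
    }
    body <- data.frame(
      trial_number = seq_len(2L * n), condition = cond,
      reinforced = reinforced,
      iti_s = sample_iti(2L * n, phase$iti_range[1], phase$iti_range[2]),
      cs_duration_s = phase$cs_duration,
      us_onset_s = ifelse(reinforced, phase$us_onset, NA_real_),
      scheduled_us_onset_s = phase$us_onset,
      stringsAsFactors = FALSE)
  }
  out <- rbind(pre, body)
  if (is.null(out)) {
    out <- data.frame(trial_number = integer(), condition = character(),
                      reinforced = logical(), iti_s = numeric(),
                      cs_duration_s = numeric(), us_onset_s = numeric(),
                      scheduled_us_onset_s = numeric(),
                      phase = character(), stringsAsFactors = FALSE)
  } else {
    out$phase <- phase$phase_kind
  }
  rownames(out) <- NULL
  out
}

#' Generate a full per-participant session schedule
#'
#' Concatenates the phase schedules in order and applies CS-identity
#' counterbalancing: for odd participant indices the first configured
#' stimulus plays the CS+ role, for even indices the roles are swapped
#' (deterministic, so cohorts are balanced by construction).
#'
#' @param spec An [experiment_spec()].
#' @param participant_index 1-based participant number.
#' @param max_run Passed to [build_phase_schedule()].
#' @return A data frame of trials with phase bookkeeping columns
#'   (`phase`, `phase_index`, `start_x`, `start_z`, `movement_allowed`,
#'   `instructed_approach`, `search_task`) in addition to the per-phase
#'   columns; the CS-role assignment is in `attr(, "cs_assignment")`.
#' @export
build_experiment <- function(spec, participant_index = 1L, max_run = Inf) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (participant_index < 1L)
    stop("participant_index must be >= 1", call. = FALSE)
  parts <- vector("list", length(spec$phases))
  for (i in seq_along(spec$phases)) {
    ph <- spec$phases[[i]]
    sch <- build_phase_schedule(ph, max_run = max_run)
    if (nrow(sch)) {
      sch$phase_index <- i
      st <- start_position(spec, ph$start_distance)
      sch$start_x <- st[1]
      sch$start_z <- st[2]
      sch$movement_allowed <- ph$movement_allowed
      sch$instructed_approach <- ph$instructed_approach
      sch$search_task <- ph$search_task
    }
    parts[[i]] <- sch
  }
  out <- do.call(rbind, parts[vapply(parts, nrow, integer(1)) > 0])
  rownames(out) <- NULL
  first <- spec$stimuli[[1]]
  second <- if (length(spec$stimuli) > 1L) spec$stimuli[[2]] else NULL
  odd <- participant_index %% 2L == 1L
  assignment <- list(
    `CS+` = if (odd) first else second,
    `CS-` = if (odd) second else first
  )
  attr(out, "cs_assignment") <- assignment
  attr(out, "participant_index") <- as.integer(participant_index)
  out
}
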