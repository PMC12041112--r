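# Headless session simulation: delta-rule learning agents with a
# distance-regulating movement policy stand in for human participants.
#
# Learning model. Each agent keeps, per condition, an excitatory association
# V (delta-rule toward 1 whenever a US is perceived) and an inhibitory
# association I (delta-rule toward the current V when an expected US is
# omitted, if extinction learning is enabled). The behaviourally effective
# association is max(0, V - I): extinction builds inhibition on top of a
# preserved excitatory trace, and an unsignalled US resets the inhibition,
# which is what lets the simulated cohorts show return of avoidance after
# reinstatement while a plain single-trace delta rule cannot.

HEAD_HEIGHT_STANDING <- 1.7
HEAD_HEIGHT_SEATED <- 1.2
APPROACH_STOP_DISTANCE <- 0.3
HAND_FORWARD_OFFSET <- 0.4
ROOM_WALL_MARGIN <- 0.1

#' Simulated-agent parameters
#'
#' @param learning_rate Delta-rule learning rate per trial, in `[0, 1]`.
#' @param avoidance_threshold Effective association above which the agent
#'   retreats from the CS when free to move.
#' @param preferred_safe_distance Distance (m) the retreating agent
#'   regulates to; the default equals the US field's audible radius (4 m).
#' @param walk_speed Walking speed, m/s.
#' @param heading_noise_sd Heading jitter per sample, degrees.
#' @param position_noise_sd Postural sway: Brownian position noise with this
#'   displacement sd (m) per axis over one second.
#' @param extinction_learning Logical; whether US omission builds inhibition
#'   (turn off to freeze associations during unreinforced phases).
#' @param approach_compliance Probability (per trial) of obeying an
#'   instructed-approach prompt.
#' @param generalisation_weight Fraction of the effective CS+ association
#'   that spills over to the CS-.
#' @param reinstatement_reset Fraction of accumulated inhibition wiped by an
#'   unsignalled US (1 = full reset).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(learning_rate = 0.3, avoidance_threshold = 0.4,
                         preferred_safe_distance = 4, walk_speed = 1,
                         heading_noise_sd = 5, position_noise_sd = 0.05,
                         extinction_learning = TRUE,
                         approach_compliance = 1,
                         generalisation_weight = 0.2,
                         reinstatement_reset = 1) {
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must be in [0, 1]", call. = FALSE)
  if (generalisation_weight < 0 || generalisation_weight > 1)
    stop("generalisation_weight must be in [0, 1]", call. = FALSE)
  stopifnot(walk_speed >= 0, avoidance_threshold >= 0,
            preferred_safe_distance >= 0, heading_noise_sd >= 0,
            position_noise_sd >= 0,
            approach_compliance >= 0, approach_compliance <= 1,
            reinstatement_reset >= 0, reinstatement_reset <= 1)
  structure(list(learning_rate = learning_rate,
                 avoidance_threshold = avoidance_threshold,
                 preferred_safe_distance = preferred_safe_distance,
                 walk_speed = walk_speed,
                 heading_noise_sd = heading_noise_sd,
                 position_noise_sd = position_noise_sd,
                 extinction_learning = isTRUE(extinction_learning),
                 approach_compliance = approach_compliance,
                 generalisation_weight = generalisation_weight,
                 reinstatement_reset = reinstatement_reset),
            class = "agent_params")
}

#' Heterogeneous agent population
#'
#' Returns a parameter-drawing function for [run_cohort()]: each simulated
#' participant gets independently drawn learning rates, avoidance
#' thresholds, preferred distances, walking speeds, noise levels,
#' instruction compliance and CS+ -> CS- generalisation, so cohort-level
#' effect sizes reflect between-participant variability instead of the
#' degenerate homogeneous case. Draws use the participant's own RNG stream,
#' so cohorts remain reproducible and stable under resizing.
#'
#' @param ... Fixed overrides applied to every participant after the draws
#'   (passed to [agent_params()]).
#' @return A `function(i)` suitable as the `params` argument of
#'   [run_cohort()].
#' @export
agent_population <- function(...) {
  overrides <- list(...)
  function(i) {
    draws <- list(
      learning_rate = runif(1, 0.15, 0.45),
      avoidance_threshold = runif(1, 0.3, 0.6),
      preferred_safe_distance = runif(1, 3, 4.5),
      walk_speed = runif(1, 0.6, 1.4),
      heading_noise_sd = runif(1, 3, 8),
      position_noise_sd = runif(1, 0.03, 0.08),
      approach_compliance = runif(1, 0.8, 1),
      generalisation_weight = runif(1, 0, 0.4))
    do.call(agent_params, modifyList(draws, overrides))
  }
}

#' Non-learning (null) agent
#'
#' An agent with zero learning rate: it never acquires a CS-US association
#' and therefore only sways around the starting point. Used for type-I-error
#' calibration of the statistical layer.
#' @param ... Overrides passed to [agent_params()].
#' @return An `agent_params` object with `learning_rate = 0`.
#' @export
null_agent <- function(...) agent_params(learning_rate = 0, ...)

#' Fresh agent state
#'
#' @param position Horizontal `c(x, z)` position, meters.
#' @return An object of class `agent_state` with zero associations.
#' @export
agent_state <- function(position = c(0, 0)) {
  structure(list(position = as.numeric(position), yaw = 0,
                 V = c("CS+" = 0, "CS-" = 0),
                 I = c("CS+" = 0, "CS-" = 0)),
            class = "agent_state")
}

#' Delta-rule association update
#'
#' `V' = V + alpha * (outcome - V)`. With binary outcomes the long-run fixed
#' point of the expected update equals the reinforcement rate.
#'
#' @param v Current association strength in `[0, 1]`.
#' @param outcome Observed outcome (update target) in `[0, 1]`; 1 = US
#'   perceived, 0 = no US.
#' @param alpha Learning rate in `[0, 1]`.
#' @return Updated association strength, guaranteed to stay in `[0, 1]`.
#' @examples
#' update_association(0, 1, 0.5) # 0.5
#' @export
update_association <- function(v, outcome, alpha) {
  if (alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]", call. = FALSE)
  if (any(v < 0) || any(v > 1) || any(outcome < 0) || any(outcome > 1))
    stop("v and outcome must be in [0, 1]", call. = FALSE)
  v + alpha * (outcome - v)
}

# Behaviourally effective association, with CS+ -> CS- generalisation.
effective_association <- function(state, condition, params) {
  eff <- state$V - state$I
  eff[eff < 0] <- 0
  if (condition == "CS-")
    min(1, eff[["CS-"]] + params$generalisation_weight * eff[["CS+"]])
  else eff[[condition]]
}

# Movement drive for one trial: 0 drift, 1 retreat, 2 approach.
drive_mode <- function(state, params, condition, movement_allowed,
                       instructed_approach, compliant) {
  if (!movement_allowed) return(0L)
  if (instructed_approach && compliant) return(2L)
  v <- effective_association(state, condition, params)
  if (v > params$avoidance_threshold) return(1L)
  0L
}

#' Advance the agent by one time step
#'
#' Single-step view of the movement policy used by [run_trial()]: an agent
#' whose effective association exceeds the avoidance threshold retreats from
#' the CS at walking speed until the preferred safe distance; under an
#' instructed-approach prompt (and compliant) it walks toward the CS; with
#' no drive it only sways. Heading follows the movement direction (or the
#' CS bearing when stationary) plus noise; positions are clipped to the
#' room.
#'
#' @param state An [agent_state()].
#' @param params An [agent_params()].
#' @param spec The [experiment_spec()] (room geometry and CS position).
#' @param condition `"CS+"`, `"CS-"` or `"none"`.
#' @param dt Time step, seconds (`> 0`).
#' @param movement_allowed,instructed_approach,compliant Trial context.
#' @return The updated `agent_state`.
#' @export
agent_policy_step <- function(state, params, spec, condition = "none",
                              dt = 1 / 90, movement_allowed = TRUE,
                              instructed_approach = FALSE,
                              compliant = TRUE) {
  stopifnot(dt > 0)
  mode <- if (condition == "none") 0L else
    drive_mode(state, params, condition, movement_allowed,
               instructed_approach, compliant)
  m <- sim_steps_trial(state$position, spec, mode, params, dt, 1L)
  state$position <- c(m[2L, 2L], m[2L, 3L])
  state$yaw <- m[2L, 4L]
  state
}

sim_steps_trial <- function(position, spec, mode, params, dt, n) {
  cs <- spec$pedestal_position
  hx <- spec$room$width / 2 - ROOM_WALL_MARGIN
  hz <- spec$room$depth / 2 - ROOM_WALL_MARGIN
  sim_steps_cpp(position[1], position[2], cs[1], cs[3], mode,
                params$walk_speed, params$preferred_safe_distance,
                APPROACH_STOP_DISTANCE, params$heading_noise_sd,
                params$position_noise_sd, dt, as.integer(n),
                -hx, hx, -hz, hz)
}

new_trace <- function(time, x, y, z, yaw, rate) {
  m <- cbind(time_s = time, pos_x = x, pos_y = y, pos_z = z, yaw_deg = yaw)
  attr(m, "tracker_id") <- "head"
  attr(m, "nominal_rate") <- rate
  attr(m, "handedness") <- "left_y_up"
  m
}

#' Simulate one trial
#'
#' Places the agent at the trial's starting point, integrates the movement
#' policy over the CS period at the tracker rate (trial time 0 = CS onset),
#' emits event markers (`cs_on`, `us_on`/`us_off` for reinforced trials,
#' `cs_off`, coin events during search-task trials), and applies one
#' association update with the *perceived* outcome: a delivered US goes
#' unnoticed when the agent is outside the audible radius at US onset,
#' unless the US source is visibly cued (`vibration_cue`).
#'
#' @param trial One schedule row (list or single-row data frame) from
#'   [build_experiment()].
#' @param spec The [experiment_spec()].
#' @param state An [agent_state()]; its associations carry across trials.
#' @param params An [agent_params()].
#' @return A list with elements `trace` (sample matrix, `NULL` for
#'   unsignalled-US rows), `events` (data frame with trial-relative times),
#'   `state` (updated), and `outcome` (the perceived US outcome).
#' @export
run_trial <- function(trial, spec, state, params) {
  trial <- as.list(trial)
  rate <- spec$tracker_rate
  dt <- 1 / rate
  cs <- spec$pedestal_position
  ev <- list()

  if (trial$condition == "none" && trial$cs_duration_s == 0) {
    # unsignalled US (reinstatement): no CS, no trace
    d <- sqrt(sum((state$position - cs[c(1, 3)])^2))
    perceived <- spec$us$vibration_cue || us_intensity(spec$us, d) > 0
    if (perceived && params$reinstatement_reset > 0)
      state$I <- state$I * (1 - params$reinstatement_reset)
    events <- data.frame(
      time_s = c(0, 0, spec$us$duration_s),
      event = c("trial_start", "us_on", "us_off"),
      payload = c("", "condition=none", ""),
      stringsAsFactors = FALSE)
    return(list(trace = NULL, events = events, state = state, outcome = 1))
  }

  state$position <- c(trial$start_x, trial$start_z)
  movement <- isTRUE(trial$movement_allowed)
  approach <- isTRUE(trial$instructed_approach)
  compliant <- runif(1) < params$approach_compliance
  mode <- if (trial$condition == "none") 0L else
    drive_mode(state, params, trial$condition, movement, approach, compliant)

  n <- as.integer(round(trial$cs_duration_s * rate))
  m <- sim_steps_trial(state$position, spec, mode, params, dt, n)
  samp <- m[seq_len(n), , drop = FALSE]
  head_y <- if (movement) HEAD_HEIGHT_STANDING else HEAD_HEIGHT_SEATED
  trace <- new_trace(samp[, 1], samp[, 2], rep(head_y, n), samp[, 3],
                     samp[, 4], rate)
  state$position <- c(m[n + 1L, 2L], m[n + 1L, 3L])
  state$yaw <- m[n + 1L, 4L]

  ev[[length(ev) + 1L]] <- c(0, "trial_start", "")
  ev[[length(ev) + 1L]] <- c(0, "cs_on",
                             sprintf("condition=%s", trial$condition))

  outcome <- 0
  if (isTRUE(trial$reinforced)) {
    onset_idx <- min(n, as.integer(floor(trial$us_onset_s * rate)) + 1L)
    d_onset <- sqrt((samp[onset_idx, 2] - cs[1])^2 +
                    (samp[onset_idx, 3] - cs[3])^2)
    outcome <- as.numeric(spec$us$vibration_cue ||
                            us_intensity(spec$us, d_onset) > 0)
    ev[[length(ev) + 1L]] <- c(trial$us_onset_s, "us_on",
                               sprintf("intensity_db=%.3f",
                                       us_intensity(spec$us, d_onset)))
    ev[[length(ev) + 1L]] <- c(trial$us_onset_s + spec$us$duration_s,
                               "us_off", "")
  }

  if (isTRUE(trial$search_task)) {
    ce <- simulate_coins(trace, trial, spec)
    for (k in seq_len(nrow(ce)))
      ev[[length(ev) + 1L]] <- c(ce$time_s[k], ce$event[k], ce$payload[k])
  }

  ev[[length(ev) + 1L]] <- c(trial$cs_duration_s, "cs_off", "")

  # one association update per trial (trial-level learning)
  if (trial$condition %in% c("CS+", "CS-")) {
    a <- params$learning_rate
    cond <- trial$condition
    if (outcome == 1) {
      state$V[[cond]] <- update_association(state$V[[cond]], 1, a)
      state$I[[cond]] <- update_association(state$I[[cond]], 0, a)
    } else if (params$extinction_learning) {
      state$I[[cond]] <- update_association(state$I[[cond]],
                                            state$V[[cond]], a)
    }
  }

  events <- as.data.frame(do.call(rbind, ev), stringsAsFactors = FALSE)
  names(events) <- c("time_s", "event", "payload")
  events$time_s <- as.numeric(events$time_s)
  events <- events[order(events$time_s, method = "radix"), , drop = FALSE]
  rownames(events) <- NULL
  list(trace = trace, events = events, state = state, outcome = outcome)
}

# Coin task: coins appear one at a time inside an ellipse centered 1 m in
# front of the starting point (toward the pedestal); the hand is modeled as
# the head position offset forward along the heading.
simulate_coins <- function(trace, trial, spec, st = spec$search_task) {
  cs <- spec$pedestal_position
  start <- c(trial$start_x, trial$start_z)
  to_cs <- cs[c(1, 3)] - start
  nrm <- sqrt(sum(to_cs^2))
  dir <- if (nrm > 1e-9) to_cs / nrm else c(0, 1)
  center <- start + dir * st$ellipse_center_offset

  spawn_times <- seq(0, trial$cs_duration_s - st$coin_lifetime,
                     by = st$coin_lifetime)
  yaw_rad <- trace[, "yaw_deg"] * pi / 180
  hand_x <- trace[, "pos_x"] + HAND_FORWARD_OFFSET * sin(yaw_rad)
  hand_z <- trace[, "pos_z"] + HAND_FORWARD_OFFSET * cos(yaw_rad)
  hand_y <- trace[, "pos_y"] - 0.5

  out <- list()
  for (ts in spawn_times) {
    r <- sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    cx <- center[1] + (st$spawn_ellipse_width / 2) * r * cos(th)
    cz <- center[2] + (st$spawn_ellipse_depth / 2) * r * sin(th)
    out[[length(out) + 1L]] <- data.frame(
      time_s = ts, event = "coin_spawn",
      payload = sprintf("x=%.4f;y=%.4f;z=%.4f", cx, st$spawn_height, cz),
      stringsAsFactors = FALSE)
    live <- trace[, "time_s"] >= ts &
      trace[, "time_s"] < ts + st$coin_lifetime
    if (any(live)) {
      dd <- sqrt((hand_x[live] - cx)^2 + (hand_y[live] - st$spawn_height)^2 +
                 (hand_z[live] - cz)^2)
      hit <- which(dd <= st$collection_radius)
      if (length(hit)) {
        t_hit <- trace[live, "time_s"][hit[1]]
        out[[length(out) + 1L]] <- data.frame(
          time_s = t_hit, event = "coin_collect", payload = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Simulate a full session
#'
#' Runs every trial of a schedule in order. Between trials the agent is
#' repositioned at the upcoming trial's starting point (return walks during
#' the inter-trial interval are not instrumented). Event times are reported
#' from session start; tracker traces use trial-relative time with 0 = CS
#' onset.
#'
#' @param spec An [experiment_spec()].
#' @param params An [agent_params()].
#' @param participant_index 1-based index, used for counterbalancing.
#' @param participant_id Participant label; defaults to `"P<index>"`.
#' @param schedule Optional pre-built schedule from [build_experiment()];
#'   built from `spec` (or its fixed `trial_table`) when omitted.
#' @return An object of class `session_log`: a list with `participant_id`,
#'   `experiment`, `trials` (one row per trial), `traces` (list of sample
#'   matrices, `NULL` where no CS period exists), `events`, `spec`, and the
#'   final `agent_state`.
#' @export
run_session <- function(spec, params = agent_params(),
                        participant_index = 1L,
                        participant_id = sprintf("P%03d", participant_index),
                        schedule = NULL) {
  stopifnot(inherits(spec, "experiment_spec"), inherits(params, "agent_params"))
  if (is.null(schedule)) {
    schedule <- if (!is.null(spec$trial_table))
      fixed_schedule(spec) else build_experiment(spec, participant_index)
  }
  state <- agent_state(c(schedule$start_x[1], schedule$start_z[1]))
  n <- nrow(schedule)
  traces <- vector("list", n)
  all_events <- vector("list", n)
  rec <- schedule
  rec$ppid <- participant_id
  rec$trial_num <- seq_len(n)
  rec$cs_on_s <- NA_real_
  rec$us_on_s <- NA_real_
  rec$outcome <- NA_real_

  clock <- 0
  for (i in seq_len(n)) {
    tr <- run_trial(schedule[i, ], spec, state, params)
    state <- tr$state
    clock <- clock + schedule$iti_s[i]
    ev <- tr$events
    ev$time_s <- ev$time_s + clock
    ev$trial_num <- i
    all_events[[i]] <- ev
    traces[[i]] <- tr$trace
    rec$cs_on_s[i] <- if (schedule$cs_duration_s[i] > 0) clock else NA_real_
    rec$us_on_s[i] <- if (isTRUE(schedule$reinforced[i]))
      clock + ifelse(is.na(schedule$us_onset_s[i]), 0,
                     schedule$us_onset_s[i]) else NA_real_
    rec$outcome[i] <- tr$outcome
    clock <- clock + schedule$cs_duration_s[i]
  }
  events <- do.call(rbind, all_events)
  rownames(events) <- NULL
  structure(list(participant_id = participant_id,
                 experiment = spec$name,
                 trials = rec, traces = traces, events = events,
                 spec = spec, agent_state = state,
                 cs_assignment = attr(schedule, "cs_assignment")),
            class = "session_log")
}

# Expand a fixed trial-features table into a runnable schedule.
fixed_schedule <- function(spec) {
  tab <- spec$trial_table
  kinds <- vapply(spec$phases, function(p) p$phase_kind, character(1))
  out <- tab
  if (is.null(out$reinforced)) out$reinforced <- FALSE
  if (is.null(out$iti_s))
    out$iti_s <- sample_iti(nrow(out))
  if (is.null(out$cs_duration_s) || is.null(out$us_onset_s) ||
      is.null(out$start_x) || is.null(out$start_z)) {
    for (i in seq_len(nrow(out))) {
      idx <- match(out$phase[i], kinds)
      if (is.na(idx))
        stop(sprintf("row %d: phase '%s' not defined in the experiment spec",
                     i, out$phase[i]), call. = FALSE)
      ph <- spec$phases[[idx]]
      if (is.null(tab$cs_duration_s)) out$cs_duration_s[i] <- ph$cs_duration
      if (is.null(tab$us_onset_s))
        out$us_onset_s[i] <- if (isTRUE(out$reinforced[i])) ph$us_onset else NA_real_
      st <- start_position(spec, ph$start_distance)
      if (is.null(tab$start_x)) out$start_x[i] <- st[1]
      if (is.null(tab$start_z)) out$start_z[i] <- st[2]
      out$scheduled_us_onset_s[i] <- ph$us_onset
      out$movement_allowed[i] <- ph$movement_allowed
      out$instructed_approach[i] <- ph$instructed_approach
      out$search_task[i] <- ph$search_task
      out$phase_index[i] <- idx
    }
  }
  out$reinforced <- as.logical(out$reinforced)
  out
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s, experiment %s: %d trials, %d events\n",
              x$participant_id, x$experiment, nrow(x$trials),
              nrow(x$events)))
  tb <- table(x$trials$phase, x$trials$condition)
  print(tb)
  invisible(x)
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483647)
}

#' Simulate a cohort of participants
#'
#' Per-participant seeds are derived from the master seed and the
#' participant index, so a cohort is reproducible and its first `k` members
#' do not change when `n_participants` grows. CS-identity counterbalancing
#' alternates with participant parity.
#'
#' @param spec An [experiment_spec()].
#' @param n_participants Number of participants (`>= 1`).
#' @param seed Master seed (integer).
#' @param params Either a single [agent_params()] used for everyone, or a
#'   `function(i)` returning the parameters for participant `i` (drawn
#'   inside that participant's RNG stream).
#' @return A list of [run_session()] `session_log`s.
#' @export
run_cohort <- function(spec, n_participants, seed = 1L,
                       params = agent_params()) {
  if (n_participants < 1L) stop("n_participants must be >= 1", call. = FALSE)
  lapply(seq_len(n_participants), function(i) {
    set.seed(derive_seed(seed, i))
    p <- if (is.function(params)) params(i) else params
    run_session(spec, params = p, participant_index = i)
  })
}
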