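# Independent brute-force oracle for the seven kinematic summaries.
# Deliberately written as per-sample loops with its own geometry (unit
# vectors + acos instead of modular yaw arithmetic) so it shares no code
# path with the package implementation.

oracle_summary <- function(trace, cs, window = c(0, 8), mode = "2d",
                           rt_threshold = 0.7) {
  keep <- integer(0)
  for (i in seq_len(nrow(trace))) {
    ti <- trace[i, "time_s"]
    if (ti >= window[1] && ti < window[2]) keep <- c(keep, i)
  }
  stopifnot(length(keep) >= 2)
  w <- trace[keep, , drop = FALSE]
  n <- nrow(w)

  dists <- numeric(n)
  angles <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dx <- w[i, "pos_x"] - cs[1]
    dy <- w[i, "pos_y"] - cs[2]
    dz <- w[i, "pos_z"] - cs[3]
    dists[i] <- if (mode == "2d") sqrt(dx^2 + dz^2) else
      sqrt(dx^2 + dy^2 + dz^2)
    yaw <- w[i, "yaw_deg"]
    hd <- sqrt(dx^2 + dz^2)
    if (!is.na(yaw) && hd > 1e-12) {
      head_vec <- c(sin(yaw * pi / 180), cos(yaw * pi / 180))
      bear_vec <- c(-dx, -dz) / hd
      dot <- sum(head_vec * bear_vec)
      dot <- max(-1, min(1, dot))
      angles[i] <- acos(dot) * 180 / pi
    }
  }

  path <- 0
  max_speed <- -Inf
  for (i in 2:n) {
    dx <- w[i, "pos_x"] - w[i - 1, "pos_x"]
    dy <- w[i, "pos_y"] - w[i - 1, "pos_y"]
    dz <- w[i, "pos_z"] - w[i - 1, "pos_z"]
    step <- if (mode == "2d") sqrt(dx^2 + dz^2) else sqrt(dx^2 + dy^2 + dz^2)
    path <- path + step
    sp <- step / (w[i, "time_s"] - w[i - 1, "time_s"])
    if (sp > max_speed) max_speed <- sp
  }

  rt <- NA_real_
  for (i in seq_len(n)) {
    dx <- w[i, "pos_x"] - w[1, "pos_x"]
    dz <- w[i, "pos_z"] - w[1, "pos_z"]
    if (sqrt(dx^2 + dz^2) >= rt_threshold) {
      rt <- w[i, "time_s"]
      break
    }
  }

  list(mean_dist_m = sum(dists) / n,
       max_dist_m = max(dists),
       min_dist_m = min(dists),
       path_len_m = path,
       max_speed_mps = max_speed,
       head_angle_deg = if (all(is.na(angles))) NA_real_ else
         mean(angles[!is.na(angles)]),
       rt_s = rt)
}

# Random piecewise-smooth test trace: slightly jittered sample clock,
# random-walk positions, random headings; optionally no yaw column.
random_trace <- function(n = 300, with_yaw = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- runif(n, 0.008, 0.014)
  time <- cumsum(dt) - dt[1]
  x <- cumsum(rnorm(n, 0, 0.02))
  y <- 1.7 + cumsum(rnorm(n, 0, 0.002))
  z <- cumsum(rnorm(n, 0, 0.02))
  yaw <- if (with_yaw) runif(n, 0, 360) else rep(NA_real_, n)
  m <- cbind(time_s = time, pos_x = x, pos_y = y, pos_z = z, yaw_deg = yaw)
  attr(m, "tracker_id") <- "head"
  attr(m, "nominal_rate") <- 90
  attr(m, "handedness") <- "left_y_up"
  m
}

expect_summary_matches_oracle <- function(trace, cs, window,
                                          tol = 1e-9, mode = "2d") {
  got <- summarize_trial(trace, cs, window, distance_mode = mode)
  want <- oracle_summary(trace, cs, window, mode = mode)
  for (f in names(want)) {
    if (is.na(want[[f]])) {
      expect_true(is.na(got[[f]]), label = sprintf("%s is NA", f))
    } else {
      expect_equal(unname(got[[f]]), unname(want[[f]]), tolerance = tol,
                   label = sprintf("field %s", f))
    }
  }
}
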