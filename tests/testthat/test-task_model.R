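# Task model: US field, ITIs, schedules, templates, config round-trips.

test_that("US intensity decays linearly and clips at the audible radius", {
  f <- us_field(intensity_db = 80, decay_per_m = 0.25)
  expect_equal(us_intensity(f, 0), 80)
  expect_equal(us_intensity(f, 2), 40)
  expect_equal(us_intensity(f, 4), 0)
  expect_equal(us_intensity(f, 10), 0)
  expect_error(us_intensity(f, -1), "non-negative")

  # non-increasing in distance, exactly 0 beyond 1/decay
  d <- seq(0, 8, by = 0.05)
  v <- us_intensity(f, d)
  expect_true(all(diff(v) <= 1e-12))
  expect_true(all(v[d >= 1 / f$decay_per_m] == 0))
  expect_true(all(v >= 0))
})

test_that("ITI sampling covers [9, 15] with mean 12", {
  set.seed(42)
  x <- sample_iti(10000)
  expect_true(all(x >= 9 & x <= 15))
  expect_equal(mean(x), 12, tolerance = 0.1 / 12)
  expect_equal(sample_iti(1, lo = 9, hi = 9), 9)
  expect_error(sample_iti(1, lo = 10, hi = 9), "lo > hi")
})

test_that("phase schedules have exact condition and reinforcement counts", {
  set.seed(7)
  ph <- phase_defaults("pavlovian_acquisition")
  sch <- build_phase_schedule(ph)
  expect_equal(nrow(sch), 16L)
  expect_equal(sum(sch$condition == "CS+"), 8L)
  expect_equal(sum(sch$condition == "CS-"), 8L)
  expect_equal(sum(sch$reinforced), 6L) # 75% of 8
  expect_true(all(!sch$reinforced[sch$condition == "CS-"]))
  expect_true(all(sch$iti_s >= 9 & sch$iti_s <= 15))
  expect_true(all(is.na(sch$us_onset_s[!sch$reinforced])))
  expect_true(all(sch$us_onset_s[sch$reinforced] == 8))

  tr <- build_phase_schedule(phase_defaults("transfer"))
  expect_equal(nrow(tr), 4L)
  expect_equal(sum(tr$condition == "CS+"), 2L)
  expect_equal(sum(tr$reinforced), 0L)
  expect_true(all(tr$cs_duration_s == 21))

  empty <- build_phase_schedule(phase_defaults("avoidance_learning",
                                               n_trials_per_condition = 0))
  expect_equal(nrow(empty), 0L)
})

test_that("non-integer reinforced counts are rejected, naming the rate", {
  expect_error(phase_spec("avoidance_learning", n_trials_per_condition = 8,
                          reinforcement_rate = 0.7),
               "0.7")
})

test_that("US co-termination is enforced at the experiment level", {
  bad <- phase_defaults("avoidance_learning", us_onset = 7.5)
  expect_error(experiment_spec("bad", list(bad)), "co-terminates")
})

test_that("CS+ positions are uniform over the trial order (chi-square)", {
  set.seed(11)
  ph <- phase_defaults("pavlovian_acquisition")
  counts <- numeric(16)
  for (r in 1:1000) {
    sch <- build_phase_schedule(ph)
    counts <- counts + (sch$condition == "CS+")
  }
  # each of the 16 slots holds a CS+ trial in half of the schedules
  p <- chisq.test(counts, p = rep(1 / 16, 16))$p.value
  expect_gt(p, 0.01)
})

test_that("max_run constrains pseudo-random orders", {
  set.seed(3)
  ph <- phase_defaults("pavlovian_acquisition")
  for (r in 1:20) {
    sch <- build_phase_schedule(ph, max_run = 3)
    expect_lte(max(rle(sch$condition)$lengths), 3)
  }
})

test_that("experiment templates reproduce the validated phase structure", {
  counts <- function(name) {
    spec <- experiment_template(name)
    sapply(spec$phases, function(p)
      if (p$phase_kind == "practice") 0L else 2L * p$n_trials_per_condition)
  }
  kinds <- function(name)
    sapply(experiment_template(name)$phases, `[[`, "phase_kind")

  expect_equal(unname(counts("exp1")),
               c(0L, 16L, 16L, 4L, 16L, 4L))
  expect_equal(unname(kinds("exp1")),
               c("practice", "pavlovian_acquisition", "avoidance_learning",
                 "transfer", "instructed_extinction", "transfer"))
  expect_equal(unname(counts("exp2")), c(0L, 16L, 16L, 4L, 16L, 4L))
  expect_equal(unname(kinds("exp3")),
               c("practice", "avoidance_learning", "transfer",
                 "instructed_extinction", "transfer"))
  expect_equal(unname(counts("exp3")), c(0L, 16L, 4L, 16L, 4L))
  expect_equal(unname(kinds("exp4")),
               c("practice", "pavlovian_acquisition", "avoidance_learning",
                 "transfer", "instructed_extinction", "transfer",
                 "reinstatement"))
  expect_equal(unname(counts("exp4")), c(0L, 16L, 16L, 4L, 16L, 4L, 16L))
  expect_equal(unname(kinds("exp5")),
               c("practice", "avoidance_learning", "transfer",
                 "instructed_extinction", "extinction_recall", "transfer",
                 "reinstatement"))
  expect_equal(unname(counts("exp5")), c(0L, 16L, 4L, 16L, 4L, 4L, 6L))

  # reinstatement phases are preceded by exactly one unsignalled US
  e4 <- experiment_template("exp4")
  expect_equal(e4$phases[[7]]$pre_phase_us, 1L)
  e5 <- experiment_template("exp5")
  expect_equal(e5$phases[[7]]$pre_phase_us, 1L)
  expect_equal(e5$phases[[7]]$n_trials_per_condition, 3L)

  # starting distances: avoidance 1 m, transfer 2.5 m, extinction 4 m
  sd4 <- sapply(e4$phases, `[[`, "start_distance")
  expect_equal(unname(sd4[3:5]), c(1, 2.5, 4))
})

test_that("full schedules concatenate phases and counterbalance by parity", {
  set.seed(5)
  spec <- experiment_template("exp4")
  sch <- build_experiment(spec, participant_index = 1)
  tbl <- table(sch$phase)
  expect_equal(unname(tbl[["pavlovian_acquisition"]]), 16L)
  expect_equal(unname(tbl[["reinstatement"]]), 17L) # 1 unsignalled US + 16
  expect_equal(sum(sch$condition == "none" & sch$cs_duration_s == 0), 1L)

  a1 <- attr(build_experiment(spec, 1), "cs_assignment")
  a2 <- attr(build_experiment(spec, 2), "cs_assignment")
  expect_equal(a1[["CS+"]]$color, a2[["CS-"]]$color)
  expect_equal(a1[["CS-"]]$color, a2[["CS+"]]$color)
  expect_error(build_experiment(spec, 0), ">= 1")
})

test_that("config files round-trip and are validated", {
  spec <- experiment_template("exp5")
  tmp <- tempfile(fileext = ".json")
  write_experiment_config(spec, tmp)
  back <- load_experiment_config(tmp)
  expect_equal(back$phases, spec$phases)
  expect_equal(back$us, spec$us)
  expect_equal(back$stimuli, spec$stimuli)
  expect_equal(back$tracker_rate, spec$tracker_rate)

  # missing phases is an error naming the field; unknown keys warn
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "x", room = list(width = 8)), bad,
                       auto_unbox = TRUE)
  expect_error(load_experiment_config(bad), "phases")
  odd <- tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "x", frobnicate = 1,
                            phases = list(list(phase_kind = "avoidance_learning"))),
                       odd, auto_unbox = TRUE)
  expect_warning(load_experiment_config(odd), "frobnicate")
})

test_that("trial feature CSVs are validated row by row", {
  empty <- tempfile(fileext = ".csv")
  writeLines("trial_number,phase,condition", empty)
  expect_error(read_trial_features(empty), "no trials")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("trial_number,phase,condition,reinforced",
               "1,avoidance_learning,CS+,TRUE",
               "2,avoidance_learning,CS-,TRUE"), bad)
  expect_error(read_trial_features(bad), "row 2")

  ok <- tempfile(fileext = ".csv")
  writeLines(c("trial_number,phase,condition,reinforced",
               "1,avoidance_learning,CS+,TRUE",
               "2,avoidance_learning,CS-,FALSE"), ok)
  tab <- read_trial_features(ok)
  expect_equal(nrow(tab), 2L)
})
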