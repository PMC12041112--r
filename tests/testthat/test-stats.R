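# Effect sizes, mixed-model contrasts, sensitivity power analysis.

test_that("condition aggregation produces per-participant pairs", {
  tab <- data.frame(
    ppid = rep(c("a", "b"), each = 4),
    phase = "avoidance_learning",
    condition = rep(c("CS+", "CS+", "CS-", "CS-"), 2),
    trial_number = rep(1:4, 2),
    mean_dist_m = c(3, 4, 1, 2, 2, 2, 1, 3))
  pairs <- aggregate_by_condition(tab, "mean_dist_m", "avoidance_learning")
  expect_equal(pairs$cs_plus, c(3.5, 2))
  expect_equal(pairs$cs_minus, c(1.5, 2))
  expect_equal(pairs$n_plus, c(2L, 2L))

  # all-missing condition values drop the participant with a warning
  tab$rt_s <- c(NA, NA, 1, 1, 0.5, 0.6, 0.7, 0.8)
  expect_warning(p2 <- aggregate_by_condition(tab, "rt_s",
                                              "avoidance_learning"),
                 "dropping 1")
  expect_equal(p2$ppid, "b")
  expect_error(aggregate_by_condition(tab, "mean_dist_m", "no_such_phase"),
               "no usable")
})

test_that("paired d and g match hand calculations", {
  # differences (1, 2, 3): d = 2, g = 2 * (1 - 3/7) = 8/7
  es <- paired_effect_size(c(2, 3, 4), c(1, 1, 1))
  expect_equal(es$cohens_d, 2)
  expect_equal(es$hedges_g, 2 * (1 - 3 / 7))
  expect_equal(es$n_pairs, 3L)
  expect_true(es$ci_low <= es$hedges_g && es$hedges_g <= es$ci_high)
  expect_lt(abs(es$hedges_g), abs(es$cohens_d))

  # identical condition vectors: defined as a zero effect
  es0 <- paired_effect_size(c(1, 2, 3), c(1, 2, 3))
  expect_equal(es0$cohens_d, 0)
  expect_equal(es0$hedges_g, 0)
  expect_true(es0$ci_low <= 0 && es0$ci_high >= 0)

  # constant nonzero differences: undefined standardized effect
  expect_error(paired_effect_size(c(2, 3, 4), c(1, 2, 3)), "undefined")
  expect_error(paired_effect_size(1, 2), "at least 2")
})

test_that("paired effect sizes equal a brute-force recomputation", {
  set.seed(51)
  for (r in 1:1000) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 1, 2)
    y <- rnorm(n, 0.5, 1.5)
    es <- paired_effect_size(x, y)
    d_raw <- mean(x - y) / sqrt(sum((x - y - mean(x - y))^2) / (n - 1))
    expect_equal(es$cohens_d, d_raw, tolerance = 1e-12)
    expect_equal(es$hedges_g, d_raw * (1 - 3 / (4 * (n - 1) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("the correction vanishes and the nct CI covers as n grows", {
  set.seed(52)
  x <- rnorm(5000, 0.5, 1)
  y <- rnorm(5000, 0, 1)
  es <- paired_effect_size(x, y)
  expect_equal(es$hedges_g, es$cohens_d, tolerance = 1e-3)

  # nct CI equals the t-interval back-transformed at the boundaries:
  # check via the p-value duality on a hand case
  es3 <- paired_effect_size(c(2, 3, 4), c(1, 1, 1))
  t_obs <- es3$cohens_d * sqrt(3)
  J <- 1 - 3 / 7
  expect_equal(pt(t_obs, df = 2, ncp = es3$ci_low / J * sqrt(3)), 0.975,
               tolerance = 1e-6)
  expect_equal(pt(t_obs, df = 2, ncp = es3$ci_high / J * sqrt(3)), 0.025,
               tolerance = 1e-6)

  # bootstrap alternative is in the same ballpark
  set.seed(53)
  x <- rnorm(40, 1); y <- rnorm(40, 0.4)
  a <- paired_effect_size(x, y)
  b <- paired_effect_size(x, y, ci_method = "bootstrap")
  expect_lt(abs(a$ci_low - b$ci_low), 0.35)
  expect_lt(abs(a$ci_high - b$ci_high), 0.35)
})

test_that("within-phase LMM recovers a known CS effect", {
  # generative model: dv = 1.0 * CS+ + participant intercept + noise
  gen_table <- function(n_ppid = 24, n_trials = 32, cs_effect = 1,
                        sd_ppid = 0.5, sd_res = 0.5) {
    ppid <- rep(seq_len(n_ppid), each = n_trials)
    cond <- rep(rep(c("CS+", "CS-"), n_trials / 2), n_ppid)
    trial <- rep(rep(seq_len(n_trials / 2), each = 2), n_ppid)
    b <- rnorm(n_ppid, 0, sd_ppid)
    data.frame(ppid = ppid, phase = "avoidance_learning", condition = cond,
               trial_number = trial,
               dv = b[ppid] + cs_effect * (cond == "CS+") +
                 rnorm(length(ppid), 0, sd_res))
  }
  set.seed(54)
  ests <- ses <- numeric(30)
  for (r in seq_along(ests)) {
    fit <- fit_within_phase_model(gen_table(), "dv")
    co <- fixed_effect(fit, "conditionCS+")
    ests[r] <- co["estimate"]
    ses[r] <- co["se"]
  }
  expect_lt(abs(mean(ests) - 1), 2 * sd(ests) / sqrt(length(ests)))
  expect_lt(abs(mean(ests) - 1), 0.1)

  # single participant: the random intercept is unidentifiable
  one <- gen_table(n_ppid = 2)
  expect_error(fit_within_phase_model(one[one$ppid == 1, ], "dv"),
               "2 participants")
})

test_that("cross-phase interactions behave under relabeling and symmetry", {
  gen2 <- function(effect_a, effect_b, seed) {
    set.seed(seed)
    out <- list()
    for (ph in c("A", "B")) {
      eff <- if (ph == "A") effect_a else effect_b
      ppid <- rep(1:16, each = 16)
      cond <- rep(rep(c("CS+", "CS-"), 8), 16)
      trial <- rep(rep(1:8, each = 2), 16)
      out[[ph]] <- data.frame(
        ppid = ppid, phase = ph, condition = cond, trial_number = trial,
        dv = rnorm(16, 0, 0.5)[ppid] + eff * (cond == "CS+") +
          rnorm(length(ppid), 0, 0.5))
    }
    do.call(rbind, out)
  }
  tab <- gen2(1, 0, seed = 55)
  fit <- fit_cross_phase_model(tab, "dv", c("A", "B"))
  inter <- fixed_effect(fit, "conditionCS+:phaseB")
  expect_lt(abs(inter["estimate"] - (-1)), 2 * inter["se"])

  # swapping the phase order flips the interaction sign
  fit_sw <- fit_cross_phase_model(tab, "dv", c("B", "A"))
  inter_sw <- fixed_effect(fit_sw, "conditionCS+:phaseA")
  expect_lt(abs(inter_sw["estimate"] + inter["estimate"]),
            2 * inter["se"])

  # identical phases: interaction near zero
  tab_eq <- gen2(0.8, 0.8, seed = 56)
  fit_eq <- fit_cross_phase_model(tab_eq, "dv", c("A", "B"))
  inter_eq <- fixed_effect(fit_eq, "conditionCS+:phaseB")
  expect_lt(abs(inter_eq["estimate"]), 3 * inter_eq["se"])

  expect_error(fit_cross_phase_model(tab, "dv", c("A", "B", "C")),
               "exactly two")
})

test_that("sensitivity d is monotone, consistent, and near the normal approximation", {
  ns <- c(5, 10, 20, 23, 24, 30, 31, 32, 50, 100, 500)
  d <- vapply(ns, sensitivity_dz, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[length(d)], 0.12)

  # normal approximation (z_{1-alpha} + z_{power}) / sqrt(n) within 5%
  for (n in c(20, 23, 32, 50, 100)) {
    approx <- (qnorm(0.95) + qnorm(0.8)) / sqrt(n)
    expect_lt(abs(sensitivity_dz(n) - approx) / approx, 0.05)
  }

  # the solved d really delivers the requested power
  for (n in c(12, 23, 31)) {
    dmin <- sensitivity_dz(n)
    pow <- 1 - pt(qt(0.95, n - 1), n - 1, ncp = dmin * sqrt(n))
    expect_equal(pow, 0.8, tolerance = 1e-5)
  }
  # two-sided needs a larger effect than one-sided
  expect_gt(sensitivity_dz(24, tails = "two"), sensitivity_dz(24))
  expect_error(sensitivity_dz(24, power = 0.01), "power")
})

test_that("cohort effect sizes grow with graded avoidance strength", {
  # avoidance propensity graded through the response threshold: the lower
  # the threshold, the larger the fraction of a heterogeneous cohort whose
  # learned association drives retreat, and the more consistently it does
  # so — so the cohort-level g for mean distance must increase across
  # levels (the top threshold exceeds any attainable association: a null
  # level)
  spec <- avoidance_only_spec()
  thresholds <- c(1.2, 0.9, 0.7, 0.55, 0.4)
  g_mean <- numeric(length(thresholds))
  for (li in seq_along(thresholds)) {
    g <- numeric(8)
    for (k in seq_along(g)) {
      cohort <- run_cohort(
        spec, 12, seed = 6000 + 37 * li + k,
        params = agent_population(avoidance_threshold = thresholds[li]))
      g[k] <- paired_effect_size(cohort_pairs(cohort))$hedges_g
    }
    g_mean[li] <- mean(g)
  }
  strength <- -thresholds
  expect_gt(cor(strength, g_mean, method = "spearman"), 0.9)
})

test_that("agent populations draw valid, reproducible parameters", {
  set.seed(61)
  pop <- agent_population(walk_speed = 2)
  p1 <- pop(1)
  expect_s3_class(p1, "agent_params")
  expect_equal(p1$walk_speed, 2) # fixed override
  expect_true(p1$learning_rate >= 0.15 && p1$learning_rate <= 0.45)
  # per-participant streams make cohort draws reproducible
  spec <- avoidance_only_spec()
  c1 <- run_cohort(spec, 2, seed = 62, params = agent_population())
  c2 <- run_cohort(spec, 2, seed = 62, params = agent_population())
  expect_identical(c1[[2]]$trials, c2[[2]]$trials)
})

test_that("effect-size tables cover phases x DVs in tidy form", {
  spec <- avoidance_only_spec()
  cohort <- run_cohort(spec, 6, seed = 57)
  tab <- cohort_table(cohort)
  es <- effect_size_table(tab, dvs = c("mean_dist_m", "max_speed_mps"))
  expect_equal(nrow(es), 2L)
  expect_true(all(es$phase == "avoidance_learning"))
  expect_true(all(es$ci_low <= es$hedges_g & es$hedges_g <= es$ci_high))
  expect_gt(es$hedges_g[es$dv == "mean_dist_m"], 0)
})
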