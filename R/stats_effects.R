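# Paired effect sizes and sensitivity power analysis.
#
# The primary criterion for a CS+/CS- difference within a phase is the
# paired standardized mean difference: Cohen's d_z (mean of the
# participant-level condition differences over their SD) with the Hedges
# small-sample correction J = 1 - 3 / (4 * df - 1), df = n - 1, and a 95%
# confidence interval from the noncentral-t pivot of the paired t statistic.

#' Per-participant condition means
#'
#' Aggregates a long trial table to one (CS+ mean, CS- mean) pair per
#' participant for a given dependent variable and phase. Participants with
#' no usable trial in one of the conditions (e.g. all reaction times
#' censored) are dropped with a warning.
#'
#' @param table Long trial table: one row per trial with at least `ppid`,
#'   `phase`, `condition` and the DV column.
#' @param dv Name of the dependent-variable column.
#' @param phase Phase to aggregate (a value of `table$phase`), or `NULL`
#'   for all rows.
#' @return A data frame with columns `ppid`, `cs_plus`, `cs_minus`,
#'   `n_plus`, `n_minus` (trial counts entering each mean).
#' @export
aggregate_by_condition <- function(table, dv, phase = NULL) {
  stopifnot(dv %in% names(table))
  rows <- table$condition %in% c("CS+", "CS-")
  if (!is.null(phase)) rows <- rows & table$phase == phase
  sub <- table[rows & !is.na(table[[dv]]), , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no usable '%s' trials%s", dv,
                 if (is.null(phase)) "" else sprintf(" in phase '%s'", phase)),
         call. = FALSE)
  agg <- aggregate(sub[[dv]], by = list(ppid = sub$ppid,
                                        condition = sub$condition), mean)
  cnt <- aggregate(sub[[dv]], by = list(ppid = sub$ppid,
                                        condition = sub$condition), length)
  ids <- unique(sub$ppid)
  get <- function(df, id, cond) {
    v <- df$x[df$ppid == id & df$condition == cond]
    if (length(v)) v else NA_real_
  }
  out <- data.frame(
    ppid = ids,
    cs_plus = vapply(ids, get, numeric(1), df = agg, cond = "CS+"),
    cs_minus = vapply(ids, get, numeric(1), df = agg, cond = "CS-"),
    n_plus = vapply(ids, get, numeric(1), df = cnt, cond = "CS+"),
    n_minus = vapply(ids, get, numeric(1), df = cnt, cond = "CS-"),
    stringsAsFactors = FALSE)
  drop <- !complete.cases(out[, c("cs_plus", "cs_minus")])
  if (any(drop)) {
    warning(sprintf("dropping %d participant(s) missing a condition: %s",
                    sum(drop), paste(out$ppid[drop], collapse = ", ")),
            call. = FALSE)
    out <- out[!drop, , drop = FALSE]
  }
  out$n_plus <- as.integer(out$n_plus)
  out$n_minus <- as.integer(out$n_minus)
  rownames(out) <- NULL
  out
}

hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Paired effect size (Cohen's d, Hedges' g) with noncentral-t CI
#'
#' For paired condition means `x` (CS+) and `y` (CS-), the default variant
#' is `d_z = mean(x - y) / sd(x - y)`; `d_av` divides by the mean of the
#' two condition SDs instead. Hedges' `g = J * d` with
#' `J = 1 - 3 / (4 * (n - 1) - 1)`. The confidence interval inverts the
#' noncentral-t distribution of the paired t statistic
#' (`t = d_z * sqrt(n)`); a nonparametric bootstrap CI is available as an
#' alternative.
#'
#' If every difference is exactly zero the effect is defined as 0 with a
#' degenerate CI; a nonzero mean difference with zero variance is an error.
#'
#' @param x CS+ per-participant means, or a data frame from
#'   [aggregate_by_condition()] (columns `cs_plus`, `cs_minus`).
#' @param y CS- per-participant means (omit when `x` is a data frame).
#' @param variant `"dz"` (default) or `"dav"`.
#' @param ci_method `"nct"` (noncentral-t pivot, default) or
#'   `"bootstrap"` (percentile, 2000 resamples).
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `effect_size`: list with `cohens_d`,
#'   `hedges_g`, `ci_low`, `ci_high` (bounds on g), `n_pairs`, `variant`,
#'   `conf_level`.
#' @examples
#' paired_effect_size(c(2, 3, 4), c(1, 1, 1)) # d = 2, g = 8/7
#' @export
paired_effect_size <- function(x, y = NULL, variant = c("dz", "dav"),
                               ci_method = c("nct", "bootstrap"),
                               conf_level = 0.95) {
  variant <- match.arg(variant)
  ci_method <- match.arg(ci_method)
  if (is.data.frame(x)) {
    y <- x$cs_minus
    x <- x$cs_plus
  }
  stopifnot(length(x) == length(y), conf_level > 0, conf_level < 1)
  keep <- complete.cases(cbind(x, y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  diffs <- x - y
  df <- n - 1
  J <- hedges_j(df)

  if (all(diffs == 0)) {
    return(structure(list(cohens_d = 0, hedges_g = 0, ci_low = 0,
                          ci_high = 0, n_pairs = n, variant = variant,
                          conf_level = conf_level), class = "effect_size"))
  }
  sd_d <- sd(diffs)
  if (sd_d == 0)
    stop("zero-variance differences with nonzero mean: effect size undefined",
         call. = FALSE)
  denom <- switch(variant, dz = sd_d, dav = (sd(x) + sd(y)) / 2)
  d <- mean(diffs) / denom
  g <- J * d

  alpha <- 1 - conf_level
  if (ci_method == "nct") {
    # CI on the noncentrality of the paired t, mapped back to d units.
    t_obs <- mean(diffs) / (sd_d / sqrt(n))
    scale <- d / (t_obs / sqrt(n)) # 1 for dz; sd ratio for dav
    lo <- nct_ncp_bound(t_obs, df, 1 - alpha / 2)
    hi <- nct_ncp_bound(t_obs, df, alpha / 2)
    ci <- J * scale * c(lo, hi) / sqrt(n)
  } else {
    est <- function(idx) {
      dn <- switch(variant, dz = sd(diffs[idx]),
                   dav = (sd(x[idx]) + sd(y[idx])) / 2)
      if (dn == 0) return(NA_real_)
      J * mean(diffs[idx]) / dn
    }
    boot <- replicate(2000, est(sample.int(n, replace = TRUE)))
    ci <- quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                   names = FALSE)
  }
  structure(list(cohens_d = d, hedges_g = g, ci_low = ci[1], ci_high = ci[2],
                 n_pairs = n, variant = variant, conf_level = conf_level),
            class = "effect_size")
}

# Noncentrality parameter ncp such that pt(t_obs, df, ncp) = p.
nct_ncp_bound <- function(t_obs, df, p) {
  # pnt warns about its final-precision guarantee far inside the tails;
  # the uniroot tolerance below is much coarser than that
  f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - p
  span <- abs(t_obs) + 10
  lo <- -span; hi <- span
  while (f(lo) < 0) lo <- lo - span
  while (f(hi) > 0) hi <- hi + span
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf(
    "<effect_size> d%s = %.3f, Hedges' g = %.3f, %g%% CI [%.3f, %.3f], n = %d pairs\n",
    if (x$variant == "dz") "_z" else "_av", x$cohens_d, x$hedges_g,
    100 * x$conf_level, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

#' Sensitivity power analysis for the paired t test
#'
#' Smallest standardized paired effect `d` detectable with the requested
#' power at significance level `alpha`, for `n` pairs, using the exact
#' noncentral-t power function (solved numerically to 1e-6).
#'
#' @param n Number of pairs (`>= 2`).
#' @param power Target power, in `(alpha, 1)`. Default 0.80.
#' @param alpha Significance level. Default 0.05.
#' @param tails `"one"` (directional, default — e.g. CS+ > CS-) or
#'   `"two"`.
#' @return Minimal detectable Cohen's d.
#' @export
sensitivity_dz <- function(n, power = 0.8, alpha = 0.05,
                           tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  pow <- function(d) {
    ncp <- d * sqrt(n)
    if (tails == "one") {
      1 - suppressWarnings(pt(qt(1 - alpha, df), df, ncp))
    } else {
      tc <- qt(1 - alpha / 2, df)
      1 - suppressWarnings(pt(tc, df, ncp)) +
        suppressWarnings(pt(-tc, df, ncp))
    }
  }
  if (power <= pow(0) || power >= 1)
    stop(sprintf("power must be in (%.3f, 1) for these settings", pow(0)),
         call. = FALSE)
  uniroot(function(d) pow(d) - power, c(1e-8, 20), tol = 1e-6)$root
}

#' Effect sizes for several DVs and phases
#'
#' @param table Long trial table (e.g. rows of [summarize_session()] over a
#'   cohort).
#' @param dvs Character vector of DV columns; defaults to the seven
#'   kinematic summaries.
#' @param phases Phases to include; defaults to all analysed phases present.
#' @param ... Passed to [paired_effect_size()].
#' @return Tidy data frame: one row per phase x DV with d, g, CI bounds and
#'   pair/censoring counts.
#' @export
effect_size_table <- function(table,
                              dvs = c("mean_dist_m", "max_dist_m",
                                      "min_dist_m", "path_len_m",
                                      "max_speed_mps", "head_angle_deg",
                                      "rt_s"),
                              phases = NULL, ...) {
  if (is.null(phases))
    phases <- unique(table$phase[table$condition %in% c("CS+", "CS-")])
  out <- list()
  for (ph in phases) for (dv in dvs) {
    res <- tryCatch({
      pairs <- suppressWarnings(aggregate_by_condition(table, dv, ph))
      es <- paired_effect_size(pairs, ...)
      data.frame(phase = ph, dv = dv, n_pairs = es$n_pairs,
                 cohens_d = es$cohens_d, hedges_g = es$hedges_g,
                 ci_low = es$ci_low, ci_high = es$ci_high,
                 n_censored = sum(table$phase == ph &
                                    table$condition %in% c("CS+", "CS-") &
                                    is.na(table[[dv]])),
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' Cohort trial table
#'
#' Binds the augmented trial tables of a simulated cohort into one long
#' table for the statistics layer.
#'
#' @param cohort List of `session_log`s from [run_cohort()].
#' @param ... Passed to [summarize_session()].
#' @return Long trial table (one row per trial per participant).
#' @export
cohort_table <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, summarize_session, ...))
}

#' Condition means by DV, normalised for display
#'
#' Base-graphics companion plot: per-participant condition means of each DV
#' are rescaled to 0-1 and shown side by side for CS+ and CS-, one DV group
#' at a time.
#'
#' @param table Long trial table.
#' @param dvs DV columns to show.
#' @param phase Phase to plot.
#' @return Invisibly, the matrix of group means that was drawn.
#' @export
plot_condition_means <- function(table,
                                 dvs = c("mean_dist_m", "max_dist_m",
                                         "min_dist_m", "path_len_m",
                                         "max_speed_mps", "head_angle_deg",
                                         "rt_s"),
                                 phase = "avoidance_learning") {
  mm <- sapply(dvs, function(dv) {
    pairs <- tryCatch(aggregate_by_condition(table, dv, phase),
                      error = function(e) NULL,
                      warning = function(w) suppressWarnings(
                        aggregate_by_condition(table, dv, phase)))
    if (is.null(pairs)) return(c(`CS+` = NA_real_, `CS-` = NA_real_))
    vals <- c(pairs$cs_plus, pairs$cs_minus)
    rng <- range(vals, finite = TRUE)
    sc <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else vals * 0
    k <- length(pairs$cs_plus)
    c(`CS+` = mean(sc[seq_len(k)]), `CS-` = mean(sc[-seq_len(k)]))
  })
  graphics::barplot(mm, beside = TRUE, ylim = c(0, 1),
                    legend.text = rownames(mm),
                    ylab = "normalised condition mean", las = 2,
                    main = sprintf("phase: %s", phase))
  invisible(mm)
}
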