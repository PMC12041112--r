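# Linear mixed-effects contrasts.
#
# Within a phase:  DV ~ CS * Trial_num + (1 | ppid)
# Across phases:   DV ~ CS * Phase + Trial_num + (1 | ppid)
#
# CS is the condition factor (reference CS-, so the CS coefficient is the
# CS+ minus CS- difference), Trial_num the within-phase trial number across
# conditions entered as a linear numeric predictor, and ppid a random
# participant intercept. p values use Satterthwaite degrees of freedom. If
# the mixed model fails to converge, a repeated-measures ANOVA on the
# participant-by-condition means is reported as fallback.

prepare_lmm_data <- function(table, dv, phases = NULL) {
  stopifnot(dv %in% names(table))
  rows <- table$condition %in% c("CS+", "CS-") & !is.na(table[[dv]])
  if (!is.null(phases)) rows <- rows & table$phase %in% phases
  d <- table[rows, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable rows for the model", call. = FALSE)
  d$condition <- factor(d$condition, levels = c("CS-", "CS+"))
  if (!is.null(phases)) d$phase <- factor(d$phase, levels = phases)
  d$.dv <- d[[dv]]
  d
}

lmm_result <- function(fit, data, dv, formula_str, fallback = NULL) {
  if (is.null(fit)) {
    # repeated-measures fallback on participant-by-condition means
    agg <- aggregate(data$.dv,
                     by = list(ppid = data$ppid, condition = data$condition),
                     mean)
    rm_fit <- aov(x ~ condition + Error(factor(ppid) / condition),
                  data = agg)
    return(structure(list(converged = FALSE, fallback = "rm_anova",
                          coefficients = NULL, anova = summary(rm_fit),
                          dv = dv, formula = formula_str,
                          n_obs = nrow(data),
                          n_participants = length(unique(data$ppid))),
                     class = "lmm_result"))
  }
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(converged = TRUE, fallback = fallback,
                 coefficients = co,
                 ranef_var = vc$vcov[vc$grp == "ppid"],
                 resid_var = vc$vcov[vc$grp == "Residual"],
                 singular = lme4::isSingular(fit),
                 dv = dv, formula = formula_str, model = fit,
                 n_obs = nrow(data),
                 n_participants = length(unique(data$ppid))),
            class = "lmm_result")
}

fit_lmm <- function(formula, data) {
  fit <- tryCatch(
    lmerTest::lmer(formula, data = data,
                   control = lme4::lmerControl(check.conv.singular =
                                                 lme4::.makeCC("ignore", tol = 1e-4))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs)))
      fit <- NULL
  }
  fit
}

#' Within-phase mixed-effects contrast
#'
#' Fits `DV ~ CS * Trial_num + (1 | ppid)` on the trials of one phase: main
#' effects of condition (CS+ vs. CS-) and trial number (linear, 1 df),
#' their interaction, and a random participant intercept.
#'
#' @param table Long trial table.
#' @param dv Dependent-variable column name.
#' @param phase Phase to model (`NULL` = all rows).
#' @return An object of class `lmm_result` with the fixed-effect table
#'   (`estimate`, `se`, `df`, `t`, `p` rows named after the terms), the
#'   random-intercept and residual variances and a convergence flag; on
#'   non-convergence, a repeated-measures ANOVA fallback.
#' @export
fit_within_phase_model <- function(table, dv, phase = NULL) {
  d <- prepare_lmm_data(table, dv)
  if (!is.null(phase)) d <- d[d$phase == phase, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable rows for the model", call. = FALSE)
  if (length(unique(d$ppid)) < 2L)
    stop("need >= 2 participants: the random intercept is unidentifiable",
         call. = FALSE)
  if (nrow(d) < 4L) stop("need more trials than parameters", call. = FALSE)
  fit <- fit_lmm(.dv ~ condition * trial_number + (1 | ppid), d)
  lmm_result(fit, d, dv, "DV ~ CS * Trial_num + (1 | ppid)")
}

#' Across-phase mixed-effects contrast
#'
#' Fits `DV ~ CS * Phase + Trial_num + (1 | ppid)` over exactly two phases
#' (e.g. avoidance learning vs. instructed extinction, or extinction vs.
#' reinstatement). The CS x Phase interaction is the criterion for a change
#' of the CS+/CS- difference between phases; the first element of `phases`
#' is the reference level.
#'
#' @param table Long trial table.
#' @param dv Dependent-variable column name.
#' @param phases Character vector of exactly two phase labels.
#' @return An `lmm_result`; the interaction row is named
#'   `conditionCS+:phase<second phase>`.
#' @export
fit_cross_phase_model <- function(table, dv, phases) {
  if (length(phases) != 2L)
    stop("phases must name exactly two phases", call. = FALSE)
  d <- prepare_lmm_data(table, dv, phases)
  if (length(unique(d$ppid)) < 2L)
    stop("need >= 2 participants: the random intercept is unidentifiable",
         call. = FALSE)
  if (!all(phases %in% d$phase))
    stop("both phases must contribute usable rows", call. = FALSE)
  fit <- fit_lmm(.dv ~ condition * phase + trial_number + (1 | ppid), d)
  lmm_result(fit, d, dv, "DV ~ CS * Phase + Trial_num + (1 | ppid)")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s  [DV = %s; %d obs, %d participants]\n",
              x$formula, x$dv, x$n_obs, x$n_participants))
  if (!x$converged) {
    cat("  mixed model did not converge; repeated-measures ANOVA fallback:\n")
    print(x$anova)
    return(invisible(x))
  }
  printCoefmat(as.matrix(x$coefficients), digits = 3, Pvalue = TRUE,
               has.Pvalue = TRUE)
  cat(sprintf("  random intercept var %.4g, residual var %.4g%s\n",
              x$ranef_var, x$resid_var,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  invisible(x)
}

#' Fixed-effect summary row
#'
#' Convenience accessor: the estimate, SE and p value of one fixed-effect
#' term of an [fit_within_phase_model()] / [fit_cross_phase_model()] result.
#'
#' @param x An `lmm_result`.
#' @param term Row name, e.g. `"conditionCS+"`; partial matching on the
#'   interaction is supported via `grepl` when `fixed = FALSE`.
#' @param fixed Exact row-name match (default) or pattern match.
#' @return Named numeric vector `c(estimate, se, df, t, p)`.
#' @export
fixed_effect <- function(x, term, fixed = TRUE) {
  stopifnot(inherits(x, "lmm_result"), x$converged)
  rn <- rownames(x$coefficients)
  idx <- if (fixed) match(term, rn) else grep(term, rn, fixed = FALSE)[1]
  if (is.na(idx))
    stop(sprintf("term '%s' not found (have: %s)", term,
                 paste(rn, collapse = ", ")), call. = FALSE)
  unlist(x$coefficients[idx, ])
}
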