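#' Prepare a model frame for the trajectory models
#'
#' Restricts a preprocessed table to structured P1/P2/S trials with known
#' repetition number and NVAR code, and builds the model variables:
#' `log_rep = ln(repetition)`, `condition` as a factor with `S` as the
#' reference level, and factors for subject, picture and NVAR class.
#' Trials lacking an NVAR code (each run's first trial) are dropped.
#'
#' @param table A preprocessed response table (see [preprocess()]).
#' @param correct_only Keep correct trials only (the RT model's default).
#' @return A model-frame data frame.
#' @export
trajectory_frame <- function(table, correct_only = TRUE) {
  check_response_table(table, c("subject_id", "condition", "repetition",
                                "iti_ms", "correct", "rt_s"))
  if (!"nvar" %in% names(table)) table <- code_nvar(table)
  keep <- table$phase == "structured" &
    table$condition %in% c("P1", "P2", "S") &
    !is.na(table$repetition) & !is.na(table$nvar)
  if (correct_only) keep <- keep & table$correct
  d <- table[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable trials for the trajectory model")
  data.frame(
    rt_s = d$rt_s,
    correct = d$correct,
    log_rep = log(d$repetition),
    condition = factor(d$condition, levels = c("S", "P1", "P2")),
    iti_ms = d$iti_ms,
    subject = factor(paste(d$subject_id, d$session_id)),
    picture = factor(d$stimulus_id),
    nvar = factor(d$nvar),
    stringsAsFactors = FALSE)
}

lmer_converged <- function(model) {
  cc <- model@optinfo$conv
  ok_opt <- is.null(cc$opt) || cc$opt == 0L
  msgs <- unlist(cc$lme4$messages)
  ok_lme4 <- is.null(msgs) || all(grepl("boundary|singular", msgs,
                                        ignore.case = TRUE))
  ok_opt && ok_lme4
}

#' Mixed-effects learning-trajectory model for RT
#'
#' Fits, by REML, the linear mixed model
#' `rt_s ~ log_rep * condition + iti_ms + (1 + log_rep | subject) +
#' (1 | picture) + (1 | nvar)` to correct structured trials (first chunk
#' presentations are expected to have been removed by preprocessing).
#' Fixed effects are assessed with type-III F tests using Satterthwaite
#' degrees of freedom.  Estimated marginal means (EMMs) per condition are
#' computed at the mean of `log_rep` and ITI; EMM linear trends are the
#' condition-specific slopes of RT in `ln(repetition)`.  Pairwise EMM and
#' trend contrasts are asymptotic z tests with Tukey adjustment.
#'
#' On non-convergence the model is not silently accepted: with
#' `on_nonconvergence = "error"` (default) a structured error of class
#' `sl_convergence_error` advises dropping the random slope; `"reduce"`
#' refits without the random slope (the conventional model reduction) and
#' records this in the result.
#'
#' @param table A preprocessed response table, or a frame from
#'   [trajectory_frame()].
#' @param emm Compute EMMs and trend contrasts (skip for speed in power
#'   loops where only the ANOVA table is needed).
#' @param on_nonconvergence `"error"`, `"reduce"` or `"ignore"`.
#' @param random_slope Include the by-subject random slope on `log_rep`.
#' @return An object of class `sl_trajectory_fit` with elements `model`,
#'   `anova` (type-III table), `fixed` (coefficient table), `emm`,
#'   `trends`, `emm_contrasts`, `trend_contrasts`, `varcor`, `df_method`,
#'   `converged`, `reduced`.
#' @export
fit_rt_trajectory <- function(table, emm = TRUE,
                              on_nonconvergence = c("error", "reduce",
                                                    "ignore"),
                              random_slope = TRUE) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  d <- if (all(c("log_rep", "picture") %in% names(table))) {
    table
  } else {
    trajectory_frame(table, correct_only = TRUE)
  }
  # center covariates at their sample means so type-III main effects and
  # EMMs refer to the average repetition and ITI, not repetition 1
  centers <- c(log_rep = mean(d$log_rep), iti_ms = mean(d$iti_ms))
  d$log_rep <- d$log_rep - centers[["log_rep"]]
  d$iti_ms <- d$iti_ms - centers[["iti_ms"]]
  form <- if (random_slope) {
    rt_s ~ log_rep * condition + iti_ms + (1 + log_rep | subject) +
      (1 | picture) + (1 | nvar)
  } else {
    rt_s ~ log_rep * condition + iti_ms + (1 | subject) +
      (1 | picture) + (1 | nvar)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = d, REML = TRUE)))
  reduced <- FALSE
  if (!lmer_converged(fit) && random_slope) {
    if (on_nonconvergence == "error") {
      stop(structure(class = c("sl_convergence_error", "error",
                               "condition"),
                     list(message = paste0(
                       "trajectory model did not converge; consider ",
                       "refitting without the by-subject random slope ",
                       "(random_slope = FALSE or on_nonconvergence = ",
                       "\"reduce\")"), call = NULL)))
    }
    if (on_nonconvergence == "reduce") {
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(rt_s ~ log_rep * condition + iti_ms +
                         (1 | subject) + (1 | picture) + (1 | nvar),
                       data = d, REML = TRUE)))
      reduced <- TRUE
    }
  }
  av <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  res <- list(model = fit, anova = av,
              fixed = as.data.frame(summary(fit)$coefficients),
              varcor = as.data.frame(lme4::VarCorr(fit)),
              df_method = "Satterthwaite (type III); z (contrasts)",
              converged = lmer_converged(fit), reduced = reduced,
              centers = centers, n_obs = nrow(d))
  if (emm) {
    em <- suppressMessages(
      emmeans::emmeans(fit, ~condition, lmer.df = "asymptotic"))
    res$emm <- as.data.frame(em)
    res$emm_contrasts <- as.data.frame(
      emmeans::contrast(em, "pairwise", adjust = "tukey"))
    tr <- suppressMessages(
      emmeans::emtrends(fit, ~condition, var = "log_rep",
                        lmer.df = "asymptotic"))
    res$trends <- as.data.frame(tr)
    res$trend_contrasts <- as.data.frame(
      emmeans::contrast(tr, "pairwise", adjust = "tukey"))
  }
  class(res) <- "sl_trajectory_fit"
  res
}

#' @export
print.sl_trajectory_fit <- function(x, ...) {
  cat("<sl_trajectory_fit>", x$n_obs, "trials;",
      if (x$converged) "converged" else "NOT converged",
      if (x$reduced) "(random slope dropped)" else "", "\n")
  cat("type III fixed effects (", x$df_method, "):\n", sep = "")
  print(round(as.data.frame(x$anova), 4))
  if (!is.null(x$trends)) {
    cat("EMM trends (s per ln-repetition):\n")
    print(x$trends, digits = 4)
    cat("trend contrasts (Tukey-adjusted z):\n")
    print(x$trend_contrasts, digits = 4)
  }
  invisible(x)
}

#' Binomial mixed model for accuracy
#'
#' Fits `correct ~ log_rep * condition + iti_ms + (1 | subject) +
#' (1 | picture)` by Laplace-approximated ML with a binomial response and
#' tests the fixed effects with type-III Wald chi-squared tests.
#'
#' @param table A preprocessed response table (all retained trials, correct
#'   and incorrect), or a [trajectory_frame()] with `correct_only = FALSE`.
#' @return A list with `model` and `wald` (the type-III chi-squared table).
#' @export
fit_accuracy_glmm <- function(table) {
  d <- if (all(c("log_rep", "picture") %in% names(table))) {
    table
  } else {
    trajectory_frame(table, correct_only = FALSE)
  }
  if (all(d$correct) || !any(d$correct)) {
    stop("degenerate accuracy data: responses are all ",
         if (all(d$correct)) "correct" else "incorrect",
         "; a binomial model cannot be estimated")
  }
  d$log_rep <- d$log_rep - mean(d$log_rep)
  d$iti_ms <- d$iti_ms - mean(d$iti_ms)
  contrasts(d$condition) <- stats::contr.sum(nlevels(d$condition))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(correct ~ log_rep * condition + iti_ms + (1 | subject) +
                  (1 | picture),
                data = d, family = stats::binomial())))
  if (!lmer_converged(fit)) {
    stop(structure(class = c("sl_convergence_error", "error", "condition"),
                   list(message = "accuracy GLMM did not converge",
                        call = NULL)))
  }
  wald <- car::Anova(fit, type = "III")
  list(model = fit, wald = as.data.frame(wald))
}

#' Linear-versus-logarithmic encompassing comparison of the priming
#' trajectory
#'
#' Computes, per subject and repetition number, the mean correct-trial RT
#' difference between single (S) and second-pair-member (P2) trials, and
#' fits two ordinary regressions of that difference: model a, linear in
#' repetition, and model b, linear in ln(repetition).  Each is then tested
#' by an F test against the combined (encompassing) model containing both
#' predictors: a model is judged sufficient when adding the rival
#' predictor yields no significant improvement.  The verdict is `"log"`
#' when the linear model is rejected against the combined model and the
#' logarithmic one is not, `"linear"` in the mirror case, and
#' `"indeterminate"` otherwise.
#'
#' @param table A preprocessed response table.
#' @param alpha Significance level for the encompassing F tests.
#' @return An object of class `sl_sp2_comparison`: per-repetition
#'   differences, both fits, R-squared values, encompassing F statistics
#'   and p values, and the verdict.
#' @export
sp2_encompassing <- function(table, alpha = 0.05) {
  check_response_table(table, c("subject_id", "condition", "repetition",
                                "correct", "rt_s"))
  d <- table[table$phase == "structured" & table$correct &
               !is.na(table$repetition) &
               table$condition %in% c("S", "P2"), , drop = FALSE]
  key <- paste(d$subject_id, d$session_id, d$repetition, d$condition,
               sep = "\r")
  mu <- tapply(d$rt_s, key, mean)
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  cell <- data.frame(subject = paste(parts[, 1], parts[, 2]),
                     repetition = as.integer(parts[, 3]),
                     condition = parts[, 4], mean_rt = as.vector(mu),
                     stringsAsFactors = FALSE)
  wide_key <- paste(cell$subject, cell$repetition)
  s_rt <- cell$mean_rt[cell$condition == "S"]
  names(s_rt) <- wide_key[cell$condition == "S"]
  p2_rt <- cell$mean_rt[cell$condition == "P2"]
  names(p2_rt) <- wide_key[cell$condition == "P2"]
  common <- intersect(names(s_rt), names(p2_rt))
  if (length(common) == 0L) stop("no subject x repetition cell has both ",
                                 "S and P2 trials")
  diffs <- data.frame(
    subject = sub(" [0-9]+$", "", common),
    repetition = as.integer(sub("^.* ", "", common)),
    diff_s = as.vector(s_rt[common] - p2_rt[common]),
    stringsAsFactors = FALSE)
  if (length(unique(diffs$repetition)) < 3L) {
    stop("need at least 3 distinct repetition values for the model ",
         "comparison")
  }
  fit_a <- stats::lm(diff_s ~ repetition, data = diffs)
  fit_b <- stats::lm(diff_s ~ log(repetition), data = diffs)
  fit_ab <- stats::lm(diff_s ~ repetition + log(repetition), data = diffs)
  r2 <- function(m) summary(m)$r.squared
  r2a <- r2(fit_a); r2b <- r2(fit_b); r2ab <- r2(fit_ab)
  stopifnot(r2ab >= max(r2a, r2b) - 1e-12)   # encompassing consistency
  cmp_a <- stats::anova(fit_a, fit_ab)
  cmp_b <- stats::anova(fit_b, fit_ab)
  p_a <- cmp_a$`Pr(>F)`[2]; p_b <- cmp_b$`Pr(>F)`[2]
  verdict <- if (p_a < alpha && p_b >= alpha) {
    "log"
  } else if (p_b < alpha && p_a >= alpha) {
    "linear"
  } else {
    "indeterminate"
  }
  structure(list(
    differences = diffs, fit_linear = fit_a, fit_log = fit_b,
    fit_combined = fit_ab,
    r2_linear = r2a, r2_log = r2b, r2_combined = r2ab,
    f_linear = summary(fit_a)$fstatistic[["value"]],
    f_log = summary(fit_b)$fstatistic[["value"]],
    f_linear_vs_combined = cmp_a$F[2], p_linear_vs_combined = p_a,
    f_log_vs_combined = cmp_b$F[2], p_log_vs_combined = p_b,
    df_residual = stats::df.residual(fit_ab),
    alpha = alpha, verdict = verdict), class = "sl_sp2_comparison")
}

#' @export
print.sl_sp2_comparison <- function(x, ...) {
  cat("<sl_sp2_comparison>", nrow(x$differences),
      "subject x repetition differences\n")
  cat(sprintf("  linear:   R2 = %.4f\n  log:      R2 = %.4f\n",
              x$r2_linear, x$r2_log))
  cat(sprintf("  combined: R2 = %.4f\n", x$r2_combined))
  cat(sprintf("  linear vs combined: F = %.3f, p = %.4f\n",
              x$f_linear_vs_combined, x$p_linear_vs_combined))
  cat(sprintf("  log vs combined:    F = %.3f, p = %.4f\n",
              x$f_log_vs_combined, x$p_log_vs_combined))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Monte-Carlo power of the mixed-model interaction test
#'
#' Simulates cohorts, applies the exclusion cascade, fits the RT
#' trajectory model, and reports how often the type-III
#' log(repetition) x condition interaction test rejects at `alpha`.
#'
#' @inheritParams mc_power
#' @param filter An [filter_config()] object (the warm-up-design default
#'   uses a 2-SD slow trim).
#' @return A one-row data frame as in [mc_power()].
#' @export
lmm_power <- function(spec, params, n_subjects, n_iter = 1000L,
                      alpha = 0.05,
                      filter = filter_config(sd_multiplier = 2),
                      seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be at least 1")
  rej <- logical(n_iter)
  for (it in seq_len(n_iter)) {
    cohort <- make_cohort(spec, n_subjects, params,
                          seed = substream_seed(seed, "lmm_power", it))
    pre <- preprocess(cohort, filter)$data
    fit <- fit_rt_trajectory(pre, emm = FALSE,
                             on_nonconvergence = "reduce")
    av <- as.data.frame(fit$anova)
    rej[it] <- av["log_rep:condition", "Pr(>F)"] < alpha
  }
  k <- sum(rej)
  ci <- stats::binom.test(k, n_iter)$conf.int
  data.frame(statistic = "lmm_interaction", power = k / n_iter,
             ci_lo = ci[1], ci_hi = ci[2], n_iter = n_iter,
             n_subjects = n_subjects, alpha = alpha,
             stringsAsFactors = FALSE)
}
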