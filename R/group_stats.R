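#' Per-subject condition summaries
#'
#' Computes, for each subject and condition (P1/P2/S), the mean RT over
#' correct trials, the accuracy (proportion correct over all retained
#' trials), and trial counts.  Subjects with a condition cell containing
#' no correct trials cannot enter the paired tests and are dropped with a
#' warning.
#'
#' @param table A preprocessed response table.
#' @return A data frame with columns `subject_id`, `condition`,
#'   `mean_rt_s`, `accuracy`, `n_trials`, `n_correct`.
#' @export
summarize_conditions <- function(table) {
  check_response_table(table, c("subject_id", "condition", "correct",
                                "rt_s"))
  tab <- table[table$condition %in% c("P1", "P2", "S"), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no P1/P2/S trials in input")
  f_subj <- factor(tab$subject_id)
  f_cond <- factor(tab$condition, levels = c("P1", "P2", "S"))
  cell <- interaction(f_subj, f_cond, drop = FALSE)
  n_trials <- as.vector(table(cell))
  corr <- tab[tab$correct, , drop = FALSE]
  cell_c <- interaction(factor(corr$subject_id, levels = levels(f_subj)),
                        factor(corr$condition, levels = levels(f_cond)),
                        drop = FALSE)
  n_correct <- as.vector(table(cell_c))
  mean_rt <- as.vector(tapply(corr$rt_s, cell_c, mean))
  acc <- ifelse(n_trials > 0, n_correct / n_trials, NA_real_)
  out <- data.frame(
    subject_id = rep(levels(f_subj), times = 3L),
    condition = rep(c("P1", "P2", "S"), each = nlevels(f_subj)),
    mean_rt_s = mean_rt, accuracy = acc,
    n_trials = n_trials, n_correct = n_correct,
    stringsAsFactors = FALSE)
  empty <- unique(out$subject_id[out$n_correct == 0L])
  if (length(empty)) {
    warning("dropping subject(s) with an empty condition cell: ",
            paste(empty, collapse = ", "))
    out <- out[!(out$subject_id %in% empty), , drop = FALSE]
  }
  out <- out[order(out$subject_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

summary_matrix <- function(summaries, value = "mean_rt_s") {
  m <- tapply(summaries[[value]], list(summaries$subject_id,
                                       summaries$condition), identity)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("incomplete design: missing cell(s) ",
         paste(sprintf("%s:%s", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = ", "))
  }
  if (nrow(m) < 3L || ncol(m) < 2L) {
    stop("need at least 3 subjects and 2 conditions")
  }
  m
}

#' Repeated-measures ANOVA with Tukey-Kramer post hoc tests on RT
#'
#' One-way within-subject ANOVA of per-subject condition mean RTs
#' (df = (k-1), (k-1)(n-1); no sphericity correction by default), followed
#' by all pairwise comparisons using the studentized-range (Tukey-Kramer)
#' statistic on the ANOVA error term, `q = (m_i - m_j) / sqrt(MSE / n)`.
#' Pairwise Cohen's d is the mean difference over the pooled SD of the two
#' conditions' subject means.
#'
#' @param summaries Output of [summarize_conditions()].
#' @param gg Apply the Greenhouse-Geisser correction to the omnibus df
#'   (off by default).
#' @return An object of class `sl_contrast_set`: a list with `test` (the
#'   omnibus data frame row) and `pairwise` (one row per condition pair).
#' @export
rm_anova_rt <- function(summaries, gg = FALSE) {
  m <- summary_matrix(summaries, "mean_rt_s")
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(rownames(m), k)),
                   condition = factor(rep(colnames(m), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject/condition), data = df)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  fval <- tab["condition", "F value"]
  # exactly balanced condition means: report F = 0, not 0/0 noise
  if (tab["condition", "Sum Sq"] < 1e-12 * max(sum(tab[, "Sum Sq"]), 1)) {
    fval <- 0
    tab["condition", "Pr(>F)"] <- 1
  }
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  mse <- tab["Residuals", "Mean Sq"]
  pval <- tab["condition", "Pr(>F)"]
  eps <- 1
  if (gg) {
    # Greenhouse-Geisser epsilon from the double-centered covariance
    S <- stats::cov(m)
    Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    pval <- stats::pf(fval, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  test <- data.frame(statistic = "F", value = fval, df1 = df1 * eps,
                     df2 = df2 * eps, p = pval,
                     adjustment = if (gg) "Greenhouse-Geisser" else "none",
                     stringsAsFactors = FALSE)
  pairs <- utils::combn(colnames(m), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diffm <- mean(m[, a]) - mean(m[, b])
    q <- diffm / sqrt(mse / n)
    d <- diffm / sqrt((stats::var(m[, a]) + stats::var(m[, b])) / 2)
    data.frame(contrast = paste(a, b, sep = "-"), statistic = "q",
               value = q, df = df2,
               p = stats::ptukey(abs(q), k, df2, lower.tail = FALSE),
               effect_size = d, effect_size_type = "cohens_d",
               adjustment = "Tukey-Kramer", stringsAsFactors = FALSE)
  }))
  structure(list(test = test, pairwise = pw, n_subjects = n, mse = mse),
            class = "sl_contrast_set")
}

# Wilcoxon signed-rank z with tie correction (zeros dropped, as in the
# classic procedure); the rank-biserial-style effect size is |z| / sqrt(n).
signed_rank_z <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0L) {
    return(list(z = 0, p = 1, r = 0, n = length(x)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- nz * (nz + 1) / 4
  ties <- table(r)
  sig2 <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), r = abs(z) / sqrt(length(x)),
       n = length(x))
}

#' Friedman test with pairwise Wilcoxon signed-rank tests on accuracy
#'
#' Friedman chi-squared over the subject x condition accuracy matrix,
#' followed by pairwise Wilcoxon signed-rank tests reported as normal
#' approximation z values with the effect size `r = |z| / sqrt(n)`.
#'
#' @inheritParams rm_anova_rt
#' @return An `sl_contrast_set` (see [rm_anova_rt()]).
#' @export
friedman_accuracy <- function(summaries) {
  m <- summary_matrix(summaries, "accuracy")
  if (all(m == m[, 1])) {
    # no within-subject variation at all: the statistic is defined as 0
    chi2 <- 0; pval <- 1
  } else {
    ft <- stats::friedman.test(m)
    chi2 <- unname(ft$statistic); pval <- ft$p.value
  }
  test <- data.frame(statistic = "chi_squared", value = chi2,
                     df1 = ncol(m) - 1, df2 = NA_real_,
                     p = pval, adjustment = "none",
                     stringsAsFactors = FALSE)
  pairs <- utils::combn(colnames(m), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    w <- signed_rank_z(m[, a], m[, b])
    data.frame(contrast = paste(a, b, sep = "-"), statistic = "z",
               value = w$z, df = NA_real_, p = w$p, effect_size = w$r,
               effect_size_type = "rank_biserial_r",
               adjustment = "Wilcoxon", stringsAsFactors = FALSE)
  }))
  structure(list(test = test, pairwise = pw, n_subjects = nrow(m)),
            class = "sl_contrast_set")
}

#' @export
print.sl_contrast_set <- function(x, ...) {
  cat("<sl_contrast_set> n =", x$n_subjects, "subjects\n")
  print(x$test, row.names = FALSE)
  cat("pairwise:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Between-experiment contrasts of learning markers
#'
#' Compares per-subject condition difference scores (P1-P2, P2-S, P1-S)
#' between two independent cohorts: pooled-variance two-sample t tests for
#' mean-RT differences and Mann-Whitney U tests for accuracy differences,
#' each Holm-Bonferroni adjusted across the three contrasts of a measure.
#'
#' @param summaries_a,summaries_b [summarize_conditions()] outputs for the
#'   two cohorts.
#' @return A data frame with one row per measure x contrast.
#' @export
between_experiment_contrasts <- function(summaries_a, summaries_b) {
  ma_rt <- summary_matrix(summaries_a, "mean_rt_s")
  mb_rt <- summary_matrix(summaries_b, "mean_rt_s")
  ma_ac <- summary_matrix(summaries_a, "accuracy")
  mb_ac <- summary_matrix(summaries_b, "accuracy")
  if (nrow(ma_rt) < 2L || nrow(mb_rt) < 2L) {
    stop("each cohort needs at least 2 subjects")
  }
  contrasts <- list(`P1-P2` = c("P1", "P2"), `P2-S` = c("P2", "S"),
                    `P1-S` = c("P1", "S"))
  one_measure <- function(ma, mb, measure) {
    rows <- lapply(names(contrasts), function(cn) {
      cc <- contrasts[[cn]]
      da <- ma[, cc[1]] - ma[, cc[2]]
      db <- mb[, cc[1]] - mb[, cc[2]]
      if (measure == "mean_rt_s") {
        if (stats::var(da) + stats::var(db) == 0) {
          # zero-variance difference scores: identical means are a null
          # result, different means a maximal one
          eq <- mean(da) == mean(db)
          tt <- list(statistic = if (eq) 0 else Inf * sign(mean(da) -
                                                             mean(db)),
                     parameter = length(da) + length(db) - 2,
                     p.value = if (eq) 1 else 0)
        } else {
          tt <- stats::t.test(da, db, var.equal = TRUE)
        }
        data.frame(measure = "rt", contrast = cn, statistic = "t",
                   value = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   method = "two-sample t", stringsAsFactors = FALSE)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(da, db))
        data.frame(measure = "accuracy", contrast = cn, statistic = "U",
                   value = unname(wt$statistic), df = NA_real_,
                   p = wt$p.value, method = "Mann-Whitney U",
                   stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "holm")
    out$adjustment <- "Holm-Bonferroni"
    out
  }
  rbind(one_measure(ma_rt, mb_rt, "mean_rt_s"),
        one_measure(ma_ac, mb_ac, "accuracy"))
}

#' Monte-Carlo power of the group tests
#'
#' Simulates cohorts from an observer model, applies the exclusion
#' cascade, runs the named test(s), and reports the rejection fraction at
#' level `alpha` with an exact binomial confidence interval.
#'
#' @param spec An [design_spec()] object.
#' @param params An [observer_params()] object (its effect amplitudes
#'   define the simulated truth; the null observer gives the type-I rate).
#' @param n_subjects Cohort size per iteration.
#' @param n_iter Number of simulated cohorts.
#' @param statistic Character vector naming the tests to evaluate:
#'   `"anova"` (omnibus RM-ANOVA), `"tukey_p2_s"` (Tukey-Kramer P2 vs S),
#'   `"friedman"`, `"wilcoxon_p2_s"`.
#' @param alpha Significance level.
#' @param filter An [filter_config()] object.
#' @param drop_category_repeats Apply
#'   [drop_category_repeating_trials()] before testing (the motor-confound
#'   reanalysis).
#' @param seed Master seed.
#' @return A data frame with one row per statistic: rejection fraction
#'   `power`, binomial 95% CI, `n_iter`, `n_subjects`.
#' @export
mc_power <- function(spec, params, n_subjects, n_iter = 1000L,
                     statistic = "tukey_p2_s", alpha = 0.05,
                     filter = filter_config(),
                     drop_category_repeats = FALSE, seed = 1L) {
  if (n_iter < 1L) stop("n_iter must be at least 1")
  stats_names <- match.arg(statistic,
                           c("anova", "tukey_p2_s", "friedman",
                             "wilcoxon_p2_s"), several.ok = TRUE)
  rej <- matrix(FALSE, n_iter, length(stats_names),
                dimnames = list(NULL, stats_names))
  for (it in seq_len(n_iter)) {
    cohort <- make_cohort(spec, n_subjects, params,
                          seed = substream_seed(seed, "mc_power", it))
    pre <- preprocess(cohort, filter)$data
    if (drop_category_repeats) {
      pre <- drop_category_repeating_trials(pre)$data
    }
    summ <- suppressWarnings(summarize_conditions(pre))
    if (any(c("anova", "tukey_p2_s") %in% stats_names)) {
      a <- rm_anova_rt(summ)
      if ("anova" %in% stats_names) {
        rej[it, "anova"] <- a$test$p < alpha
      }
      if ("tukey_p2_s" %in% stats_names) {
        rej[it, "tukey_p2_s"] <-
          a$pairwise$p[a$pairwise$contrast == "P2-S"] < alpha
      }
    }
    if (any(c("friedman", "wilcoxon_p2_s") %in% stats_names)) {
      f <- friedman_accuracy(summ)
      if ("friedman" %in% stats_names) {
        rej[it, "friedman"] <- f$test$p < alpha
      }
      if ("wilcoxon_p2_s" %in% stats_names) {
        rej[it, "wilcoxon_p2_s"] <-
          f$pairwise$p[f$pairwise$contrast == "P2-S"] < alpha
      }
    }
  }
  do.call(rbind, lapply(stats_names, function(s) {
    k <- sum(rej[, s])
    ci <- stats::binom.test(k, n_iter)$conf.int
    data.frame(statistic = s, power = k / n_iter, ci_lo = ci[1],
               ci_hi = ci[2], n_iter = n_iter, n_subjects = n_subjects,
               alpha = alpha, stringsAsFactors = FALSE)
  }))
}
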