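test_that("condition summaries match hand arithmetic", {
  tab <- rbind(
    toy_response_table(c(0.4, 0.6, 0.5, 0.9), condition = "P1",
                       correct = c(TRUE, TRUE, FALSE, TRUE)),
    toy_response_table(c(0.3, 0.5), condition = "P2"),
    toy_response_table(c(0.7, 0.7, 0.7), condition = "S"))
  tab$trial <- seq_len(nrow(tab))
  s <- summarize_conditions(tab)
  expect_equal(s$mean_rt_s[s$condition == "P1"], mean(c(0.4, 0.6, 0.9)))
  expect_equal(s$mean_rt_s[s$condition == "P2"], 0.4)
  expect_equal(s$mean_rt_s[s$condition == "S"], 0.7)
  expect_equal(s$accuracy[s$condition == "P1"], 3 / 4)
  expect_equal(s$n_trials, c(4L, 2L, 3L))

  # all-constant RTs give constant means
  tab2 <- rbind(toy_response_table(rep(0.5, 3), condition = "P1"),
                toy_response_table(rep(0.5, 3), condition = "P2"),
                toy_response_table(rep(0.5, 3), condition = "S"))
  tab2$trial <- seq_len(nrow(tab2))
  expect_true(all(summarize_conditions(tab2)$mean_rt_s == 0.5))

  # a subject with an empty correct cell is dropped with a warning
  tab3 <- rbind(tab2,
                within(tab2, {subject_id <- "s2"
                              correct[condition == "P2"] <- FALSE}))
  expect_warning(s3 <- summarize_conditions(tab3), "s2")
  expect_false("s2" %in% s3$subject_id)
})

test_that("repeated-measures ANOVA and Tukey-Kramer match the sums-of-squares oracle", {
  set.seed(10)
  m <- matrix(round(stats::rnorm(15, 0.6, 0.05), 4), 5, 3)
  res <- rm_anova_rt(toy_summaries(m))
  orc <- oracle_rm_anova(m)
  expect_equal(res$test$value, orc$F, tolerance = 1e-10)
  expect_equal(res$test$df1, orc$df1)
  expect_equal(res$test$df2, orc$df2)
  expect_equal(res$test$p, orc$p, tolerance = 1e-10)
  # Tukey-Kramer q from the oracle error term
  q_orc <- (mean(m[, 1]) - mean(m[, 2])) / sqrt(orc$mse / nrow(m))
  expect_equal(res$pairwise$value[res$pairwise$contrast == "P1-P2"],
               q_orc, tolerance = 1e-10)
  expect_equal(res$pairwise$p[1],
               ptukey(abs(q_orc), 3, orc$df2, lower.tail = FALSE),
               tolerance = 1e-10)
  # effect size: mean difference over pooled condition SD
  d_orc <- (mean(m[, 1]) - mean(m[, 2])) /
    sqrt((var(m[, 1]) + var(m[, 2])) / 2)
  expect_equal(res$pairwise$effect_size[1], d_orc, tolerance = 1e-10)

  # exactly balanced condition means (latin-square rows) -> F = 0
  m0 <- rbind(c(0.5, 0.6, 0.7), c(0.6, 0.7, 0.5), c(0.7, 0.5, 0.6))
  expect_equal(rm_anova_rt(toy_summaries(m0))$test$value, 0)

  # incomplete designs are refused with the missing cell named
  s_bad <- toy_summaries(m)[-2, ]
  expect_error(rm_anova_rt(s_bad), "missing cell")
})

test_that("Friedman and signed-rank tests match the rank-arithmetic oracle", {
  set.seed(11)
  acc <- matrix(sample(seq(0.80, 0.99, 0.01), 12), 4, 3)  # no ties
  res <- friedman_accuracy(toy_summaries(matrix(0.5, 4, 3), acc = acc))
  orc <- oracle_friedman(acc)
  expect_equal(res$test$value, orc$chi2, tolerance = 1e-10)
  expect_equal(res$test$df1, orc$df)
  expect_equal(res$test$p, orc$p, tolerance = 1e-10)

  wz <- oracle_signed_rank(acc[, 1], acc[, 2])
  got <- res$pairwise[res$pairwise$contrast == "P1-P2", ]
  expect_equal(got$value, wz$z, tolerance = 1e-10)
  expect_equal(got$effect_size, abs(wz$z) / sqrt(4), tolerance = 1e-10)

  # identical accuracies everywhere -> chi-squared = 0
  res0 <- friedman_accuracy(toy_summaries(matrix(0.5, 4, 3),
                                          acc = matrix(0.9, 4, 3)))
  expect_equal(res0$test$value, 0)
})

test_that("between-experiment contrasts match t/U oracles and Holm adjustment", {
  m_a <- matrix(c(0.62, 0.64, 0.66, 0.58, 0.59, 0.60, 0.61, 0.62, 0.63),
                3, 3)  # P1, P2, S columns
  m_b <- matrix(c(0.60, 0.61, 0.62, 0.60, 0.605, 0.61, 0.60, 0.61, 0.62),
                3, 3)
  acc_a <- matrix(c(0.90, 0.91, 0.92, 0.95, 0.96, 0.94, 0.90, 0.89, 0.91),
                  3, 3)
  acc_b <- matrix(0.9, 3, 3)
  res <- between_experiment_contrasts(toy_summaries(m_a, acc_a),
                                      toy_summaries(m_b, acc_b))
  expect_equal(nrow(res), 6)
  # t statistic against a direct pooled-variance computation
  da <- m_a[, 1] - m_a[, 2]; db <- m_b[, 1] - m_b[, 2]
  sp <- sqrt((2 * var(da) + 2 * var(db)) / 4)
  t_orc <- (mean(da) - mean(db)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$value[res$measure == "rt" & res$contrast == "P1-P2"],
               t_orc, tolerance = 1e-10)
  expect_equal(res$df[res$measure == "rt"][1], 4)
  # U statistic against exhaustive pair enumeration
  ua <- acc_a[, 2] - acc_a[, 3]; ub <- acc_b[, 2] - acc_b[, 3]
  expect_equal(res$value[res$measure == "accuracy" &
                           res$contrast == "P2-S"],
               oracle_mann_whitney_u(ua, ub), tolerance = 1e-10)
  # Holm adjustment within measure
  prt <- res$p[res$measure == "rt"]
  expect_equal(res$p_adj[res$measure == "rt"],
               p.adjust(prt, method = "holm"))

  # identical cohorts: all adjusted RT p values are 1 up to ties
  same <- between_experiment_contrasts(toy_summaries(m_a, acc_a),
                                       toy_summaries(m_a, acc_a))
  expect_true(all(same$p_adj[same$measure == "rt"] == 1))
})

test_that("Monte-Carlo power behaves at the extremes and grows with n", {
  spec <- design_spec("exp1b", n_runs = 2)  # lighter cohorts for speed
  # strong effect saturates
  strong <- observer_params(prime_amp = 0.06, sigma_resid = 0.05)
  pw_hi <- mc_power(spec, strong, n_subjects = 8, n_iter = 20,
                    statistic = "tukey_p2_s", seed = 21)
  expect_gte(pw_hi$power, 0.9)
  # intermediate effect gains power with n
  mid <- observer_params(prime_amp = 0.012, sigma_resid = 0.12)
  pw_small <- mc_power(spec, mid, n_subjects = 6, n_iter = 40,
                       statistic = "tukey_p2_s", seed = 22)
  pw_big <- mc_power(spec, mid, n_subjects = 24, n_iter = 40,
                     statistic = "tukey_p2_s", seed = 22)
  expect_gt(pw_big$power, pw_small$power)
  expect_error(mc_power(spec, mid, 5, n_iter = 0), "n_iter")
})

test_that("condition-dependent lapses drive the accuracy tests", {
  spec <- design_spec("exp1b", n_runs = 2)
  p_eff <- observer_params(prime_amp = 0,
                           lapse_rate = 0.10,
                           lapse_delta = c(P1 = 0, P2 = -0.08, S = 0))
  pw <- mc_power(spec, p_eff, n_subjects = 12, n_iter = 25,
                 statistic = c("friedman", "wilcoxon_p2_s"), seed = 23)
  expect_gte(pw$power[pw$statistic == "friedman"], 0.6)
  expect_gte(pw$power[pw$statistic == "wilcoxon_p2_s"], 0.6)
})
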