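# Variability, correlation, baseline and statistical-test operations.

test_that("coefficient of variation uses the sample (n-1) SD", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(c(1.5, 2.5)), 100 * sqrt(0.5) / 2,
               tolerance = 1e-12) # ~35.36 under n-1; n would give 25
  expect_error(coefficient_of_variation(c(1)), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("cv_table recovers per-subject, per-pad dispersion", {
  # identical sessions: all-zero row
  ds <- dataset_from_curves(list(rep(1.5, 16), rep(1.5, 16)),
                            c("A", "A"), c("1", "2"))
  tab <- cv_table(ds)
  expect_equal(unname(tab$cv["A", ]), rep(0, 16))

  # a subject with one session is excluded with a warning
  ds2 <- dataset_from_curves(list(rep(1.5, 16), rep(2, 16), rep(1, 16)),
                             c("A", "A", "B"), c("1", "2", "1"))
  expect_warning(tab2 <- cv_table(ds2), "single session")
  expect_equal(rownames(tab2$cv), "A")

  # hand-checkable dispersion: sessions 1.5 and 2.5 on every pad
  ds3 <- dataset_from_curves(list(rep(1.5, 16), rep(2.5, 16)),
                             c("A", "A"), c("1", "2"))
  expect_equal(unname(cv_table(ds3)$cv["A", ]),
               rep(coefficient_of_variation(c(1.5, 2.5)), 16))
})

test_that("cv_row_summary reproduces the published row summaries", {
  fx <- study_cv_fixture()
  smry <- cv_row_summary(fx$cv)
  # largest and smallest average variance in the cohort
  expect_equal(round(max(smry$mean), 1), 26.6)
  expect_equal(smry$subject_id[which.max(smry$mean)], "5")
  expect_equal(round(min(smry$mean), 1), 13.1)
  expect_equal(smry$subject_id[which.min(smry$mean)], "8")
  # subject 1's printed SD discriminates the n-1 convention (2.99 vs 2.89)
  expect_equal(round(smry$sd[smry$subject_id == "1"], 1), 3.0)
  # every printed row mean matches at the printed precision; the printed
  # SDs were computed from unrounded per-pad CVs, so recomputation from
  # the printed integer cells can differ in the last digit (subject 7:
  # 4.97 recomputed vs 5.1 printed)
  expect_equal(round(smry$mean, 1), fx$printed$mean)
  expect_true(all(abs(smry$sd - fx$printed$sd) < 0.2))
})

test_that("mean and percentile curves follow the stated conventions", {
  ds <- dataset_from_curves(list(rep(1.0, 16), rep(2.0, 16)),
                            c("A", "B"), c("1", "1"))
  expect_equal(as.numeric(mean_curve(ds)), rep(1.5, 16))
  expect_error(mean_curve(dataset_from_curves(list(), character(), character())),
               "empty")

  one <- dataset_from_curves(list(rep(1.7, 16)), "A", "1")
  expect_equal(as.numeric(mean_curve(one)), rep(1.7, 16))

  ds3 <- dataset_from_curves(list(rep(1, 16), rep(2, 16), rep(3, 16)),
                             c("A", "B", "C"), c("1", "1", "1"))
  expect_equal(as.numeric(percentile_curve(ds3, 50)), rep(2, 16))
  expect_equal(as.numeric(percentile_curve(ds3, 0)), rep(1, 16))

  ds4 <- dataset_from_curves(list(rep(1, 16), rep(2, 16), rep(3, 16), rep(4, 16)),
                             c("A", "B", "C", "D"), rep("1", 4))
  # linear interpolation at rank (n-1)q/100 + 1: q=25 over 1..4 -> 1.75
  expect_equal(as.numeric(percentile_curve(ds4, 25)), rep(1.75, 16))

  # monotone non-decreasing in q, per pad
  withr::local_seed(5)
  ds5 <- random_grid_dataset(8)
  qs <- seq(0, 100, by = 10)
  curves <- sapply(qs, function(q) as.numeric(percentile_curve(ds5, q)))
  expect_true(all(apply(curves, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("total_distance is an L1 metric", {
  expect_equal(total_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(total_distance(c(1, 2, 3), c(1.5, 2.0, 2.5)), 1.0)
  expect_equal(total_distance(rep(1.9, 16), rep(1.0, 16)), 14.4)
  expect_error(total_distance(1:3, 1:4), "mismatch")
  # metric axioms on random curves
  withr::local_seed(8)
  for (i in 1:25) {
    a <- runif(16, 0.1, 5); b <- runif(16, 0.1, 5); c <- runif(16, 0.1, 5)
    expect_gte(total_distance(a, b), 0)
    expect_equal(total_distance(a, b), total_distance(b, a))
    expect_lte(total_distance(a, c),
               total_distance(a, b) + total_distance(b, c) + 1e-12)
  }
  expect_identical(total_distance(a, b) == 0, all(a == b))
})

test_that("optimal_constant is the exhaustive grid L1 minimizer", {
  ds <- dataset_from_curves(list(rep(1.8, 16), rep(1.8, 16)),
                            c("A", "B"), c("1", "1"))
  expect_equal(optimal_constant(ds), list(constant_mA = 1.8,
                                          total_distance_mA = 0))
  # ties break toward the smallest constant
  ds2 <- dataset_from_curves(list(c(1.0, 2.0), c(1.4, 1.6)),
                             c("A", "B"), c("1", "1"))
  oc <- optimal_constant(ds2)
  expect_equal(oc$constant_mA, 1.4)
  expect_equal(oc$total_distance_mA, 1.2)
})

test_that("optimal_constant equals the pooled median within one grid step", {
  withr::local_seed(101)
  for (i in 1:100) {
    ds <- random_grid_dataset(sample(2:8, 1), n_pads = sample(c(4, 8, 16), 1))
    oc <- optimal_constant(ds)
    vals <- ds$amplitude_mA
    orc <- oracle_optimal_constant(vals)
    expect_equal(oc$constant_mA, orc$constant_mA)
    expect_equal(oc$total_distance_mA, orc$total_distance_mA, tolerance = 1e-9)
    # within one grid step of the pooled median interval (any point in the
    # interval is an L1 minimizer; ties break toward the smallest)
    mi <- median_interval(vals)
    expect_gte(oc$constant_mA, mi[1] - 0.1 - 1e-9)
    expect_lte(oc$constant_mA, mi[2] + 0.1 + 1e-9)
    # the pooled-median distance lower-bounds every grid constant
    expect_lte(sum(abs(vals - median(vals))), oc$total_distance_mA + 1e-9)
  }
})

test_that("compare_baselines summarizes per-curve distances by strategy", {
  ds <- dataset_from_curves(list(rep(1.8, 16), rep(1.8, 16), rep(1.8, 16)),
                            c("A", "B", "C"), rep("1", 3))
  cmp <- compare_baselines(ds, list(baseline_strategy("mean_curve")))
  expect_equal(cmp$summary$mean, 0)
  expect_equal(cmp$summary$sd, 0)

  withr::local_seed(13)
  ds2 <- random_grid_dataset(10)
  cmp2 <- compare_baselines(ds2, list(
    baseline_strategy("constant", constant_mA = 1.0),
    baseline_strategy("optimal_constant")))
  s <- cmp2$summary
  expect_lte(s$mean[s$strategy == "optimal_constant"],
             s$mean[s$strategy == "constant_1.0_mA"])
  expect_equal(dim(cmp2$distances), c(10L, 2L))
})

test_that("check_baseline_constraint counts pads above a subject's range", {
  ds <- dataset_from_curves(list(rep(2.0, 16), rep(2.2, 16)),
                            c("A", "A"), c("1", "2"))
  # global per-pad minimum is never above any subject's maximum
  gm <- apply(curve_matrix(ds), 2, min)
  expect_equal(unname(check_baseline_constraint(gm, ds)), 0L)
  # baseline above the subject's max on pads 1-4 only
  b <- rep(1.5, 16); b[1:4] <- 2.5
  expect_equal(unname(check_baseline_constraint(b, ds)), 4L)
})

test_that("pearson_r validates and matches hand computation", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(a, rep(1, 4)), "constant")
  expect_error(pearson_r(a, 1:3), "mismatch")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("correlation_analysis matches a brute-force per-pair oracle", {
  withr::local_seed(30)
  # 3 subjects x 4 sessions with distinct patterns
  curves <- list(); subj <- c(); sess <- c()
  for (s in 1:3) {
    base <- 1.5 + 0.5 * s * sin(seq(0, pi, length.out = 8))^2 + 0.2 * s
    for (j in 1:4) {
      curves <- c(curves, list(to_grid(pmax(base + rnorm(8, 0, 0.2), 0.15), "floor")))
      subj <- c(subj, paste0("S", s)); sess <- c(sess, as.character(j))
    }
  }
  ds <- dataset_from_curves(curves, subj, sess)
  res <- correlation_analysis(ds)
  m <- curve_matrix(ds)
  overall <- colMeans(m)
  for (s in unique(subj)) {
    rows <- m[attr(m, "subject_id") == s, ]
    indiv <- colMeans(rows)
    rA <- apply(rows, 1, function(x) cor(x, overall))
    rB <- apply(rows, 1, function(x) cor(x, indiv))
    got <- res$by_subject[res$by_subject$subject_id == s, ]
    expect_equal(got$r_overall_mean, mean(rA))
    expect_equal(got$r_overall_sd, sd(rA))
    expect_equal(got$r_individual_mean, mean(rB))
    expect_equal(got$r_individual_sd, sd(rB))
  }
})

test_that("sessions equal to the subject mean give perfect individual correlation", {
  curves <- list(seq(1.0, 2.5, by = 0.1), seq(1.0, 2.5, by = 0.1),
                 seq(1.2, 4.2, by = 0.2), seq(1.2, 4.2, by = 0.2))
  ds <- dataset_from_curves(curves, c("A", "A", "B", "B"),
                            c("1", "2", "1", "2"))
  res <- correlation_analysis(ds)
  expect_equal(res$by_subject$r_individual_mean, c(1, 1))
  expect_equal(res$by_subject$r_individual_sd, c(0, 0))
})

test_that("correlation_analysis reproduces the published column summaries", {
  fx <- study_correlation_fixture()
  expect_equal(round(mean(fx$r_individual_mean), 2), 0.82)
  expect_equal(round(sd(fx$r_individual_mean), 2), 0.11)
  expect_equal(round(mean(fx$r_streamlined_baseline), 2), 0.63)
  expect_equal(round(sd(fx$r_streamlined_baseline), 2), 0.31)
})

test_that("paired_t_test matches the closed-form oracle", {
  fx <- study_correlation_fixture()
  res <- paired_t_test(fx$r_overall_mean, fx$r_individual_mean)
  orc <- oracle_paired_t(fx$r_overall_mean, fx$r_individual_mean)
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_equal(res$df, 8)
  expect_equal(res$p, orc$p, tolerance = 1e-12)

  # symmetric differences (-1, 0, 1) about zero
  sym <- paired_t_test(c(1, 2, 3), c(2, 2, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(paired_t_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_t_test(1:3, 1:4), "mismatch")

  withr::local_seed(17)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    res <- paired_t_test(x, y)
    orc <- oracle_paired_t(x, y)
    expect_equal(res$t, orc$t, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
})

test_that("rm_anova_gg matches a brute-force sums-of-squares oracle", {
  Y <- matrix(c(10.1, 11.2,  9.8,
                12.0, 13.5, 11.0,
                 9.5, 10.9,  9.9,
                11.1, 12.8, 10.5,
                10.7, 12.1, 10.2), nrow = 5, byrow = TRUE)
  res <- rm_anova_gg(Y)
  orc <- oracle_rm_anova(Y)
  expect_equal(res$F, orc$F, tolerance = 1e-8)
  expect_equal(res$epsilon, orc$epsilon, tolerance = 1e-8)
  expect_equal(res$df1, orc$epsilon * orc$df1, tolerance = 1e-8)
  expect_equal(res$df2, orc$epsilon * orc$df2, tolerance = 1e-8)
  expect_true(res$epsilon > 1 / (ncol(Y) - 1) - 1e-12 && res$epsilon <= 1)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_bonferroni <= 1))
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
})

test_that("rm_anova_gg degenerates correctly", {
  # equal condition means: F = 0, p = 1
  Y0 <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4) + c(0.5, -0.5, 0.5, -0.5),
              c(1, 2, 3, 4) + c(-0.5, 0.5, -0.5, 0.5))
  res0 <- rm_anova_gg(Y0)
  expect_equal(res0$F, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  expect_error(rm_anova_gg(matrix(1:4, 2, 2)), ">= 3 units")
  expect_error(rm_anova_gg(matrix(1:5, 5, 1)), ">= 2 conditions")
  Yna <- matrix(rnorm(12), 4, 3); Yna[2, 2] <- NA
  expect_error(rm_anova_gg(Yna), "missing")
})

test_that("with two conditions the RM-ANOVA reduces to the paired t-test", {
  withr::local_seed(23)
  for (i in 1:5) {
    Y <- matrix(rnorm(20, mean = rep(c(0, 0.8), each = 10)), ncol = 2)
    res <- rm_anova_gg(Y)
    tt <- paired_t_test(Y[, 1], Y[, 2])
    expect_equal(res$epsilon, 1)
    expect_equal(res$F, tt$t^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p, tolerance = 1e-10)
  }
})
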