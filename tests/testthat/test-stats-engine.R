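# Statistics engine: oracle equivalence, epsilon/Mauchly behaviour,
# post-hocs, assumption checks, correlations, difference scores.

test_that("mixed_anova matches the aov split-plot oracle on a balanced toy design", {
  d <- toy_mixed_data()
  tab <- mixed_anova(d, dv = "y", within = "cond", between = c("A", "B"),
                     subject = "participant")
  oracle <- aov_mixed_oracle(d, "y", "cond", c("A", "B"), "participant")
  key <- c(A = "A", B = "B", `A:B` = "A:B", cond = "cond",
           `A:cond` = "A:cond", `B:cond` = "B:cond", `A:B:cond` = "A:B:cond")
  for (eff in names(key)) {
    mine <- tab[tab$effect == eff, ]
    ref <- oracle[[key[[eff]]]]
    expect_equal(mine$ss, ref$ss, tolerance = 1e-8)
    expect_equal(mine$ss_error, ref$ss_error, tolerance = 1e-8)
    expect_equal(mine$df1, ref$df1)
    expect_equal(mine$df2, ref$df2)
    expect_equal(mine$F, ref$F, tolerance = 1e-8)
    expect_equal(mine$p, ref$p, tolerance = 1e-8)
    # partial eta^2 from the oracle's sums of squares
    expect_equal(mine$pes, ref$ss / (ref$ss + ref$ss_error), tolerance = 1e-8)
  }
})

test_that("single-group RM-ANOVA matches the frozen reference implementation", {
  d <- rm_fixture()
  ref <- rm_fixture_reference()
  tab <- mixed_anova(d, dv = "y", within = "cond", between = character(0),
                     subject = "participant")
  expect_equal(tab$ss, ref$ss, tolerance = 1e-8)
  expect_equal(tab$ss_error, ref$ss_error, tolerance = 1e-8)
  expect_equal(tab$F, ref$F, tolerance = 1e-8)
  expect_equal(tab$p, ref$p, tolerance = 1e-6)
  expect_equal(tab$p_gg, ref$p_gg, tolerance = 1e-6)
  expect_equal(tab$epsilon, ref$epsilon, tolerance = 1e-8)
  expect_equal(attr(tab, "mauchly")$W, ref$W, tolerance = 1e-8)
})

test_that("two within levels force epsilon 1 and uncorrected p", {
  d <- expand.grid(participant = paste0("S", 1:10), cond = c("c1", "c2"),
                   stringsAsFactors = FALSE)
  d$g <- rep(rep(c("a", "b"), each = 5), 2)
  d$y <- stressreg:::with_seed(2, rnorm(nrow(d)))
  tab <- mixed_anova(d, dv = "y", within = "cond", between = "g",
                     subject = "participant")
  w <- tab[tab$stratum == "within", ]
  expect_true(all(w$epsilon == 1))
  expect_equal(w$p_gg, w$p)
  expect_false(attr(tab, "mauchly")$applicable)
})

test_that("translation and positive scaling leave F, p, eta^2 and epsilon unchanged", {
  d <- toy_mixed_data()
  base <- mixed_anova(d, "y", "cond", c("A", "B"), "participant")
  d2 <- d; d2$y <- d2$y + 17.3
  shifted <- mixed_anova(d2, "y", "cond", c("A", "B"), "participant")
  d3 <- d; d3$y <- d3$y * 3.7
  scaled <- mixed_anova(d3, "y", "cond", c("A", "B"), "participant")
  for (other in list(shifted, scaled)) {
    expect_equal(other$F, base$F, tolerance = 1e-10)
    expect_equal(other$p, base$p, tolerance = 1e-10)
    expect_equal(other$pes, base$pes, tolerance = 1e-10)
    expect_equal(other$epsilon, base$epsilon, tolerance = 1e-10)
  }
})

test_that("gg_epsilon obeys its analytic anchors", {
  # k = 2: bounds force 1
  expect_equal(gg_epsilon(matrix(c(2, 0.5, 0.5, 1), 2)), 1)
  # compound symmetry: epsilon exactly 1 for any k
  for (k in 3:5) {
    cs <- matrix(0.3, k, k); diag(cs) <- 1
    expect_equal(gg_epsilon(cs), 1)
  }
  # maximal non-sphericity (rank-1 contrast covariance): lower bound 1/(k-1)
  v <- c(4, -1, -1, -1, -1)
  expect_equal(gg_epsilon(outer(v, v)), 0.25)
  # agrees with the orthonormal-contrast formulation on random covariances
  for (seed in 1:5) {
    S <- stressreg:::with_seed(seed, {
      A <- matrix(rnorm(25), 5)
      crossprod(A)
    })
    M <- stressreg:::orthonormal_contrasts(5)
    SS <- t(M) %*% S %*% M
    eps_contrast <- sum(diag(SS))^2 / (4 * sum(SS^2))
    expect_equal(gg_epsilon(S), min(max(eps_contrast, 0.25), 1),
                 tolerance = 1e-10)
  }
  expect_error(gg_epsilon(matrix(1, 2, 3)), "square")
})

test_that("mauchly_test behaves at its anchors and under the null", {
  # identity covariance is exactly spherical
  expect_equal(mauchly_test(diag(4), n = 20)$W, 1)
  expect_false(mauchly_test(diag(2), n = 20)$applicable)
  # W in (0, 1] for random covariances
  for (seed in 1:5) {
    S <- stressreg:::with_seed(seed, crossprod(matrix(rnorm(16), 4)))
    W <- mauchly_test(S, n = 12)$W
    expect_gt(W, 0)
    expect_lte(W, 1)
  }
  # under a spherical population the p-value is roughly uniform
  ps <- vapply(1:200, function(r) {
    Y <- stressreg:::with_seed(5000 + r, matrix(rnorm(25 * 4), 25, 4))
    mauchly_test(stats::cov(Y), n = 25)$p
  }, 0)
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  rej <- mean(ps < 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})

test_that("bonferroni_posthoc corrects by family size and matches t oracles", {
  cells <- stressreg:::with_seed(6, list(
    a = rnorm(12, 0, 1), b = rnorm(12, 0.8, 1.5), c = rnorm(12, 0.2, 1)
  ))
  fam <- list(list(label = "a vs b", a = "a", b = "b"),
              list(label = "a vs c (paired)", a = "a", b = "c", paired = TRUE))
  res <- bonferroni_posthoc(cells, fam)
  expect_equal(nrow(res), 2)
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p_raw))
  expect_equal(res$alpha_adjusted, rep(0.025, 2))
  # oracle equivalence with stats::t.test
  welch <- t.test(cells$a, cells$b)
  expect_equal(res$t[1], unname(welch$statistic), tolerance = 1e-12)
  expect_equal(res$df[1], unname(welch$parameter), tolerance = 1e-10)
  paired <- t.test(cells$a, cells$c, paired = TRUE)
  expect_equal(res$t[2], unname(paired$statistic), tolerance = 1e-12)
  expect_equal(res$p_raw[2], paired$p.value, tolerance = 1e-12)
  # family of 5 with p_raw = 0.004 -> 0.02 (check scaling directly)
  expect_equal(min(1, 5 * 0.004), 0.02)
  fam5 <- rep(list(list(a = "a", b = "b")), 5)
  res5 <- bonferroni_posthoc(cells, fam5)
  expect_equal(res5$p_bonferroni, pmin(1, 5 * res5$p_raw))
  # identical groups -> t = 0, corrected p = 1
  same <- list(x = rep(2, 5), y = rep(2, 5))
  res0 <- bonferroni_posthoc(same, list(list(a = "x", b = "y")))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_bonferroni, 1)
  expect_error(bonferroni_posthoc(cells, list()), "empty")
  expect_warning(
    bonferroni_posthoc(list(a = 1, b = c(1, 2, 3)),
                       list(list(a = "a", b = "b"))), "n < 2")
})

test_that("assumption checks calibrate on normal and flag lognormal data", {
  # standard-normal samples: ks_p exceeds 0.05 in at least 90% of replicates
  ks_ok <- vapply(1:20, function(r) {
    x <- stressreg:::with_seed(900 + r, rnorm(500))
    assumption_checks(x, n_mc = 400)$ks_p > 0.05
  }, TRUE)
  expect_gte(mean(ks_ok), 0.90)
  # lognormal samples: transform recommended in most replicates
  flags <- vapply(1:10, function(r) {
    x <- stressreg:::with_seed(300 + r, rlnorm(300, 0, 1))
    assumption_checks(x, n_mc = 400)$log_transform_recommended
  }, TRUE)
  expect_gt(mean(flags), 0.5)
  # non-positive data needing a transform flags the shift instead
  x <- stressreg:::with_seed(7, rlnorm(300) - 2)
  chk <- assumption_checks(x, n_mc = 400)
  expect_true(chk$shift_required)
  expect_false(chk$log_transform_recommended)
  # Levene: equal values in both cells -> statistic 0
  lev <- assumption_checks(c(rep(2, 10), rep(5, 10)),
                           groups = rep(c("a", "b"), each = 10), n_mc = 200)
  expect_equal(lev$levene_F, 0)
  expect_equal(lev$levene_p, 1)
  # Levene (centre = mean) matches a hand-run one-way ANOVA on |x - cell mean|
  set.seed(11)
  x2 <- c(rnorm(15, 0, 1), rnorm(15, 0, 3))
  g2 <- rep(c("a", "b"), each = 15)
  chk2 <- assumption_checks(x2, groups = g2, n_mc = 200)
  z <- abs(x2 - ave(x2, g2))
  oracle <- anova(lm(z ~ g2))
  expect_equal(chk2$levene_F, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(chk2$levene_p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("pearson_corr hits exact anchors and is consistent", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_corr(x, -x)$r, -1.0)
  set.seed(8)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  mine <- pearson_corr(a, b)
  oracle <- cor.test(a, b)
  expect_equal(mine$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-10)
  # estimator consistency: mean r-hat over replicates ~ rho = 0.3
  rs <- vapply(1:2000, function(r) {
    stressreg:::with_seed(40000 + r, {
      x <- rnorm(40)
      y <- 0.3 * x + sqrt(1 - 0.09) * rnorm(40)
      cor(x, y)
    })
  }, 0)
  expect_equal(mean(rs), 0.3, tolerance = 0.02)
  expect_error(pearson_corr(rep(1, 5), 1:5), "variance")
  expect_error(pearson_corr(1:2, 1:2), "3 complete pairs")
})

test_that("difference scores remove the reference and cancel participant offsets", {
  d <- data.frame(participant = rep(c("P1", "P2"), each = 5),
                  condition = rep(er_conditions(), 2),
                  v = c(3, 6, 7, 4, 5, 2, 5, 8, 3, 4))
  out <- difference_scores(d, dv = "v")
  expect_false("view_negative" %in% out$condition)
  expect_equal(nrow(out), 8)
  expect_equal(out$v[out$participant == "P1" & out$condition == "reappraisal"],
               4 - 6)
  # pure additive participant offsets cancel: group contrast is unchanged
  st <- simulate_study(study_config(n_per_cell = 10, seed = 21,
                                    include = "ratings"))
  cm <- condition_means(st$ratings, "arousal")
  offs <- setNames(seq_len(nrow(st$roster)) * 0.37, st$roster$id)
  cm_off <- cm
  cm_off$arousal <- cm_off$arousal + offs[cm_off$participant]
  c1 <- reappraisal_stress_contrast(difference_scores(cm, "arousal"),
                                    st$roster, "arousal")
  c2 <- reappraisal_stress_contrast(difference_scores(cm_off, "arousal"),
                                    st$roster, "arousal")
  expect_equal(c1$t, c2$t, tolerance = 1e-10)
  dd <- d[d$condition != "view_negative", ]
  expect_warning(difference_scores(rbind(d, data.frame(
    participant = "P3", condition = "reappraisal", v = 1)), dv = "v"),
    "without a reference")
})

test_that("power: a 0.8-point stressed-male reappraisal shift is usually detected", {
  hits <- vapply(1:40, function(r) {
    cfg <- study_config(n_per_cell = 20, seed = 7000 + r, include = "ratings")
    st <- simulate_study(cfg)
    cm <- condition_means(st$ratings, "arousal")
    ct <- reappraisal_stress_contrast(cm, st$roster, "arousal")
    ct$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})
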