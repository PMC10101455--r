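test_that("Welch t from printed cohort summaries reproduces the worked example", {
  # LC volumes, validation cohort: 8.0 +/- 0.6 (n=33) vs 5.2 +/- 0.6 (n=39)
  gc <- welch_t_from_summary(8.0, 0.6, 33, 5.2, 0.6, 39)
  expect_equal(gc$statistic, 2.8 / sqrt(0.72), tolerance = 1e-12)
  expect_lt(abs(gc$statistic - 3.306) / 3.306, 0.005)
  expect_lt(gc$p_value, 0.01)
  expect_gt(gc$df, min(33, 39) - 1)
  expect_lt(gc$df, 33 + 39 - 2)
})

test_that("Welch t and df agree with direct formula evaluation", {
  set.seed(42)
  for (rep in 1:20) {
    a <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welch_t(a, b)
    ora <- welch_formulas(a, b)
    expect_equal(got$statistic, ora$t, tolerance = 1e-10)
    expect_equal(got$df, ora$df, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
  }
})

test_that("Welch t degenerate and identity cases", {
  x <- c(1, 2, 3, 4)
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Shapiro-Wilk wrapper behaves under null, skew and degeneracy", {
  set.seed(1)
  p_norm <- replicate(100, shapiro_wilk(rnorm(200))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(50, shapiro_wilk(rexp(200))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  expect_error(shapiro_wilk(rep(3, 10)), "degenerate")
  expect_error(shapiro_wilk(c(1, 2)), "at least 3")
})

test_that("ANCOVA with no covariates reduces to one-way ANOVA (F = t^2)", {
  set.seed(7)
  d <- data.frame(group = rep(c("control", "pd"), c(10, 12)),
                  snc_volume = c(rnorm(10, 450, 40), rnorm(12, 350, 40)))
  got <- ancova_group_effect(d, "snc_volume", covariates = character(0))
  t_pooled <- t.test(snc_volume ~ group, data = d, var.equal = TRUE)
  expect_equal(got$statistic, unname(t_pooled$statistic)^2, tolerance = 1e-8)
  expect_equal(got$p_value, t_pooled$p.value, tolerance = 1e-8)
  # constant covariates carry no information and must give the same answer
  d$zero <- 0
  got0 <- suppressWarnings(ancova_group_effect(d, "snc_volume",
                                               covariates = "zero"))
  expect_equal(got0$statistic, got$statistic, tolerance = 1e-8)
})

test_that("ANCOVA matches explicit normal-equations least squares", {
  set.seed(12)
  n <- 12
  d <- data.frame(group = rep(c("control", "pd"), each = 6),
                  age = round(runif(n, 50, 80)),
                  education = round(runif(n, 10, 20)))
  d$lc_volume <- 8 - 2 * (d$group == "pd") - 0.03 * d$age + rnorm(n, 0, 0.8)
  got <- ancova_group_effect(d, "lc_volume", c("age", "education"))
  ora <- normal_equations_group_F(d$lc_volume,
                                  cbind(d$age, d$education),
                                  as.numeric(d$group == "pd"))
  expect_equal(got$statistic, ora$F, tolerance = 1e-8)
  expect_equal(got$df, ora$df)
  expect_equal(got$p_value, ora$p, tolerance = 1e-8)
  expect_named(got$covariate_p, c("age", "education"))
})

test_that("ANCOVA rejects a rank-deficient design", {
  d <- data.frame(group = rep(c("control", "pd"), each = 6),
                  snc_volume = rnorm(12, 400, 30))
  d$dup <- as.numeric(d$group == "pd")
  expect_error(ancova_group_effect(d, "snc_volume", "dup"), "rank")
})

test_that("partial correlation: identities, degeneracy, recovery", {
  set.seed(3)
  age <- rnorm(50, 65, 8)
  x <- rnorm(50)
  r1 <- partial_correlation(x, x, age)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(2 * age + 1, -age + 3, age), "degenerate")
  # known partial correlation 0.3 after removing a shared age effect
  n <- 5000
  age2 <- rnorm(n, 65, 8)
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  L <- chol(S)
  e <- matrix(rnorm(2 * n), n) %*% L
  xx <- 0.05 * age2 + e[, 1]
  yy <- -0.08 * age2 + e[, 2]
  est <- partial_correlation(xx, yy, age2)
  expect_lt(abs(est$r - 0.3), 0.04)
  expect_lt(est$p_value, 1e-10)
})

test_that("AUC equals the Mann-Whitney pair count on small instances", {
  set.seed(9)
  for (rep in 1:60) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    scores <- sample(0:5, n1 + n0, replace = TRUE)  # many ties on purpose
    labels <- rep(c("pd", "control"), c(n1, n0))
    got <- roc_auc(scores, labels, "pd")
    expect_equal(got$auc, pairwise_auc(scores, labels == "pd", pos_low = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separation, null, orientation and errors", {
  perf <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("pd", "control"), each = 3), "pd")
  expect_equal(perf$auc, 1)
  expect_equal(perf$ci95[2], 1)
  set.seed(5)
  null <- roc_auc(rnorm(4000), sample(c("pd", "control"), 4000, TRUE), "pd")
  expect_lt(abs(null$auc - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep("pd", 5), "pd"), "both classes")
  flip <- roc_auc(c(1, 2, 3, 10, 11, 12), rep(c("pd", "control"), each = 3),
                  "pd", higher_is_positive = TRUE)
  expect_equal(flip$auc, 0)
})

test_that("Hanley-McNeil and DeLong SEs agree with pROC on a fixture", {
  library(pROC)
  set.seed(21)
  vol <- c(rnorm(30, 8, 3), rnorm(35, 5.2, 3.5))
  grp <- rep(c("control", "pd"), c(30, 35))
  ours <- roc_auc(vol, grp, "pd", se_method = "delong")
  ref <- pROC::roc(response = grp, predictor = vol, levels = c("pd", "control"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(ours$se, sqrt(pROC::var(ref)), tolerance = 1e-8)
})

test_that("combined marker matches the single marker when one is constant", {
  set.seed(8)
  d <- data.frame(group = rep(c("control", "pd"), c(25, 25)),
                  snc_volume = c(rnorm(25, 430, 100), rnorm(25, 330, 100)),
                  lc_volume = 5)
  comb <- combine_markers(d)
  single <- roc_auc(d$snc_volume, d$group, "pd")
  expect_equal(comb$roc$auc, single$auc, tolerance = 1e-6)
})

test_that("combined marker approaches the analytic binormal optimum", {
  set.seed(14)
  n <- 5000
  S <- matrix(c(1, 0.3, 0.3, 1), 2) * 100^2
  L <- chol(S)
  delta <- c(-100, -60)
  ctrl <- matrix(rnorm(2 * n), n) %*% L + 430
  pd <- sweep(matrix(rnorm(2 * n), n) %*% L + 430, 2, -delta, "-")
  d <- data.frame(group = rep(c("control", "pd"), each = n),
                  snc_volume = c(ctrl[, 1], pd[, 1]),
                  lc_volume = c(ctrl[, 2], pd[, 2]))
  comb <- combine_markers(d)
  auc_analytic <- pnorm(sqrt(drop(t(delta) %*% solve(S) %*% delta)) / sqrt(2))
  expect_lt(abs(comb$roc$auc - auc_analytic), 0.01)
  # in-sample, the joint fit cannot lose much to either single marker
  a1 <- roc_auc(d$snc_volume, d$group, "pd")$auc
  a2 <- roc_auc(d$lc_volume, d$group, "pd")$auc
  expect_gte(comb$roc$auc, max(a1, a2) - 0.02)
})

test_that("perfect separation falls back to a penalized fit with a warning", {
  d <- data.frame(group = rep(c("control", "pd"), each = 10),
                  snc_volume = c(rnorm(10, 500, 10), rnorm(10, 200, 10)),
                  lc_volume = c(rnorm(10, 9, 0.5), rnorm(10, 3, 0.5)))
  expect_warning(comb <- combine_markers(d), "separation")
  expect_equal(comb$roc$auc, 1)
  expect_match(comb$method, "ridge")
})

test_that("group tests are invariant under rescaling volumes to cm^3", {
  set.seed(31)
  d <- data.frame(group = rep(c("control", "pd"), c(20, 22)),
                  age = rnorm(42, 64, 9),
                  education = rnorm(42, 17, 3),
                  snc_volume = c(rnorm(20, 429, 115), rnorm(22, 329, 106)))
  d2 <- d; d2$snc_volume <- d2$snc_volume / 1000
  w1 <- welch_t(d$snc_volume[d$group == "control"], d$snc_volume[d$group == "pd"])
  w2 <- welch_t(d2$snc_volume[d2$group == "control"], d2$snc_volume[d2$group == "pd"])
  expect_equal(w1$statistic, w2$statistic, tolerance = 1e-10)
  a1 <- ancova_group_effect(d, "snc_volume")
  a2 <- ancova_group_effect(d2, "snc_volume")
  expect_equal(a1$statistic, a2$statistic, tolerance = 1e-8)
  r1 <- roc_auc(d$snc_volume, d$group, "pd")
  r2 <- roc_auc(d2$snc_volume, d2$group, "pd")
  expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
})
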