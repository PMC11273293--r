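test_that("Anderson-Darling statistic and p-value match the frozen reference oracle", {
  # expected values computed once with an independent reference
  # implementation of the Scholz-Stephens midrank statistic
  a1 <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
          0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
          0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
          0.87845, -0.049926, -0.184862, -0.68093, 1.222541, -0.154529,
          -0.428328, -0.352134, 0.532309, 0.365444, 0.412733, 0.430821)
  b1 <- c(3.284142, -0.02834, -0.165916, -0.557905, 1.300773, 1.967664,
          0.351868, -0.592203, -0.571826, 1.345771, 1.46623, 1.206101,
          -0.365163, 0.80181, 0.651692, 0.784295, 1.632857, 0.790674,
          1.382588, 0.587853, 0.875855, 1.320675, -1.394303, 0.084427,
          -0.111484, -0.330541, 0.142315, 2.443424, -0.62558, 1.758762,
          -1.687731, 0.064649, 0.711579, 1.262089, 1.424595, 1.531351,
          0.046657, -0.101057, 1.615369, 0.251304)
  r <- ad_two_sample(a1, b1)
  expect_equal(r$statistic, 3.739110779701869, tolerance = 1e-10)
  expect_equal(r$p, 0.010120274858500098, tolerance = 1e-8)
  # tied data, no distributional difference
  r2 <- ad_two_sample(c(1, 1, 2, 3, 3, 3, 4, 5, 6, 7),
                      c(2, 2, 3, 4, 4, 5, 5, 6, 8, 9))
  expect_equal(r2$statistic, 0.15486713528010843, tolerance = 1e-10)
  expect_equal(r2$p, 0.25)
  # duplicated sample -> no difference, p at the upper clip
  x <- rnorm(20)
  expect_equal(ad_two_sample(x, x)$p, 0.25)
  expect_error(ad_two_sample(1:3, 1:10), "at least 5")
})

test_that("Anderson-Darling test has power and a usable permutation variant", {
  set.seed(71)
  a <- rnorm(100); b <- rnorm(100, 2)
  expect_equal(ad_two_sample(a, b)$p, 0.001)  # lower clip
  set.seed(72)
  pe <- ad_two_sample(rnorm(15), rnorm(15), exact = TRUE, n_perm = 300)$p
  expect_gt(pe, 0.05)
  pe2 <- ad_two_sample(rnorm(15), rnorm(15, 3), exact = TRUE, n_perm = 300)$p
  expect_lt(pe2, 0.02)
})

test_that("the feature-wise LRT reduces to a hand computation for one feature", {
  set.seed(80)
  n <- 50
  batch <- factor(rep(c("a", "b", "c"), length.out = n))
  x <- rnorm(n)
  y <- 0.5 * x + 0.4 * (batch == "b") + rnorm(n)
  res <- featurewise_batch_lrt(cbind(f = y), cbind(x = x), batch)
  rss1 <- sum(resid(lm(y ~ batch + x))^2)
  rss0 <- sum(resid(lm(y ~ x))^2)
  stat <- n * log(rss0 / rss1)
  expect_equal(res$batch$statistic, stat, tolerance = 1e-10)
  expect_equal(res$batch$p, pchisq(stat, 2, lower.tail = FALSE))
  # covariate t-test matches the standard regression summary
  sm <- summary(lm(y ~ 0 + batch + x))$coefficients
  expect_equal(unname(res$covariates["f", "x"]), sm["x", 4], tolerance = 1e-10)
})

test_that("LRT batch p-values are uniform under permuted labels and detect shifts", {
  set.seed(81)
  pvals <- unlist(lapply(1:30, function(r) {
    Y <- matrix(rnorm(120 * 10), 120, 10)
    batch <- factor(sample(rep(c("a", "b", "c"), 40)))
    featurewise_batch_lrt(Y, batch = batch)$batch$p
  }))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  d <- small_gaussian(n = 150, p = 5, seed = 82, shift = 1)
  expect_gt(min(featurewise_batch_lrt(d$Y, batch = d$batch)$batch$neglog10p), 3)
})

test_that("Pillai's trace matches an independent eigen oracle", {
  set.seed(90)
  batch <- factor(rep(c("a", "b", "c"), each = 10))
  y <- rnorm(30) + (batch == "b")
  # independent eigen oracle on a bivariate toy
  Y <- cbind(y, z = 0.3 * y + rnorm(30))
  grand <- colMeans(Y)
  H <- matrix(0, 2, 2); E <- matrix(0, 2, 2)
  for (g in levels(batch)) {
    Yg <- Y[batch == g, ]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    E <- E + crossprod(sweep(Yg, 2, mg))
  }
  V_oracle <- sum(diag(H %*% solve(H + E)))
  got <- manova_pillai(Y, batch = batch)
  expect_equal(got$pillai, V_oracle, tolerance = 1e-10)
  # duplicated rows across groups -> no mean differences -> V ~ 0
  Yd <- matrix(rnorm(20), 10, 2)
  dup <- rbind(Yd, Yd)
  vd <- manova_pillai(dup, batch = factor(rep(c("a", "b"), each = 10)))
  expect_lt(vd$pillai, 1e-10)
})

test_that("univariate Pillai equals the eta-squared of the ANOVA", {
  set.seed(91)
  batch <- factor(rep(c("a", "b"), each = 12))
  y <- rnorm(24) + 0.8 * (batch == "b")
  grand <- mean(y)
  H <- sum(tapply(y, batch, function(v) length(v) * (mean(v) - grand)^2))
  E <- sum(unlist(tapply(y, batch, function(v) (v - mean(v))^2)))
  got <- manova_pillai(cbind(f = y), batch = batch)
  expect_equal(got$pillai, H / (H + E), tolerance = 1e-10)
  expect_equal(got$p, anova(lm(y ~ batch))$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("kBET is calibrated on mixed data and rejects separated batches", {
  set.seed(100)
  Y <- matrix(rnorm(400 * 8), 400, 8)
  batch <- factor(rep(c("a", "b"), 200))
  kb <- kbet(Y, batch, n_repeats = 200, n_perm = 50)
  expect_gte(kb$observed, 0.02 - 1e-9)
  expect_lte(kb$observed, 0.10)
  expect_gt(kb$p, 0.01)
  # disjoint clusters aligned with batch
  Ys <- Y + 10 * (as.integer(batch) - 1)
  kb2 <- kbet(Ys, batch, n_repeats = 200, n_perm = 50)
  expect_gt(kb2$observed, 0.95)
  expect_lt(kb2$p, 0.05)
})

test_that("kBET is invariant to common positive rescaling of the features", {
  set.seed(101)
  Y <- matrix(rnorm(150 * 5), 150, 5)
  batch <- factor(rep(c("a", "b", "c"), 50))
  set.seed(7); k1 <- kbet(Y, batch, n_repeats = 50, n_perm = 20)
  set.seed(7); k2 <- kbet(Y * 37.5, batch, n_repeats = 50, n_perm = 20)
  expect_equal(k1$observed, k2$observed)
  expect_equal(k1$per_point_p, k2$per_point_p)
  expect_error(kbet(Y, factor(rep("a", 150))), "at least 2")
  expect_error(kbet(Y, batch, k0 = 200), "smaller")
})

test_that("batch prediction score sits at baseline under the null and detects strong effects", {
  set.seed(110)
  Y <- matrix(rnorm(200 * 6), 200, 6)
  batch <- factor(rep(c("a", "b"), each = 100))
  ps <- batch_prediction_score(Y, batch, repeats = 8)
  se <- sd(ps$per_repeat) / sqrt(length(ps$per_repeat))
  expect_lt(abs(ps$accuracy - ps$baseline), 4 * max(se, 0.01))
  Ys <- Y + 3 * (as.integer(batch) - 1)
  expect_gt(batch_prediction_score(Ys, batch, repeats = 3)$accuracy, 0.9)
  expect_error(batch_prediction_score(Y, batch, folds = 500), "folds")
})

test_that("the full report assembles every block", {
  d <- small_gaussian(n = 90, p = 6, seed = 120, shift = 0.5)
  set.seed(121)
  rep <- evaluate_harmonization(d$Y, batch = d$batch, kbet_repeats = 50,
                                kbet_perm = 20, prediction_repeats = 2)
  expect_s3_class(rep, "harmonization_report")
  expect_true(all(rep$ad$per_feature >= 0.001 & rep$ad$per_feature <= 0.25))
  expect_true(rep$kbet$observed >= 0 && rep$kbet$observed <= 1)
  expect_output(print(rep), "kBET")
})
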