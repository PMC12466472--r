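test_that("trait derivations reproduce the worked formulas", {
  ph <- data.frame(sample_id = c("a", "b"),
                   BW80 = c(20, 18), BW180 = c(45, 46.9),
                   feed_intake = c(162, 150), body_length = c(0.75, 0.8),
                   carcass_weight = c(22, 23), live_weight = c(45, 46.9),
                   tail_fat = c(1.1, 1.3))
  d <- derive_performance_traits(ph)
  expect_equal(d$MBW[1], (0.5 * (20 + 45))^0.75, tolerance = 1e-12)
  expect_equal(d$MBW[1], 13.6117, tolerance = 1e-4)
  expect_equal(d$BMI[2], 46.9 / 0.8^2, tolerance = 1e-12)
  expect_equal(d$BMI[2], 73.28, tolerance = 1e-2)
  expect_equal(d$ADG[1], 0.25)
  expect_equal(d$FCR[1], 1.62 / 0.25, tolerance = 1e-12)
  expect_equal(d$dressing_pct, c(22 / 45, 23 / 46.9))
  expect_equal(d$tail_fat_rel_carcass, c(1.1 / 22, 1.3 / 23))
  expect_equal(d$tail_fat_rel_live, c(1.1 / 45, 1.3 / 46.9))

  # ADG <= 0 flags FCR as missing
  ph$BW180[1] <- 19
  d2 <- derive_performance_traits(ph)
  expect_true(is.na(d2$FCR[1]) && d2$fcr_flagged[1])
})

test_that("RFI is an OLS residual with its standard properties", {
  set.seed(4)
  n <- 60
  d <- data.frame(MBW = runif(n, 10, 16), ADG = runif(n, 0.2, 0.35))
  d$ADFI <- 0.2 + 0.08 * d$MBW + 2 * d$ADG + rnorm(n, 0, 0.05)
  rfi <- compute_rfi(d)
  expect_lt(abs(sum(rfi)), 1e-10)
  # animal exactly on the fitted plane has RFI 0
  fit <- lm(ADFI ~ MBW + ADG, data = d)
  d2 <- rbind(d, data.frame(MBW = 13, ADG = 0.3,
                            ADFI = predict(fit, data.frame(MBW = 13, ADG = 0.3))))
  expect_lt(abs(compute_rfi(d2)[n + 1]), 0.02)
  # adding a constant to ADFI leaves RFI unchanged
  d3 <- d; d3$ADFI <- d3$ADFI + 5
  expect_equal(compute_rfi(d3), compute_rfi(d), tolerance = 1e-10)
  expect_error(compute_rfi(within(d, MBW <- 2 * ADG)), "collinear")
})

test_that("enterotype-trait association: null calibration, power, label flip", {
  set.seed(14)
  n <- 300
  et <- factor(rep(1:2, each = n / 2))
  bp <- factor(sample(1:3, n, TRUE))
  null_traits <- as.data.frame(matrix(rnorm(n * 500), n))
  res <- enterotype_trait_assoc(null_traits, et, bp)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 1e-4)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.025)

  # planted 1-SD shift at n = 500 is BH-significant
  set.seed(15)
  n2 <- 500
  et2 <- factor(rep(1:2, each = n2 / 2))
  y <- rnorm(n2) + (as.integer(et2) - 1)
  shifted <- data.frame(hit = y,
                        null1 = rnorm(n2), null2 = rnorm(n2))
  res2 <- enterotype_trait_assoc(shifted, et2, NULL)
  expect_lt(res2$q[res2$trait == "hit"], 0.05)

  # recoding labels flips the sign of the contrast only
  res3 <- enterotype_trait_assoc(shifted, factor(et2, levels = c("2", "1")), NULL)
  expect_equal(res3$estimate, -res2$estimate, tolerance = 1e-10)
  expect_equal(res3$p, res2$p, tolerance = 1e-10)

  # q monotone in p rank, bounded by 1
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q <= 1))
})

test_that("balanced-design group means are reproduced by the fit", {
  set.seed(16)
  et <- factor(rep(1:2, each = 100))
  y <- rnorm(200, mean = c(10, 12)[as.integer(et)])
  res <- enterotype_trait_assoc(data.frame(y = y), et, NULL)
  fit <- lm(y ~ et)
  expect_equal(sum(coef(fit)), mean(y[et == 2]), tolerance = 1e-10)
  expect_equal(res$estimate, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("chi-square covariate tests: printed table, null rate, degenerate rows", {
  # unique/shared network-edge contingency table from the studied cohort
  et <- rep(c("E1", "E2"), times = c(579 + 864, 488 + 864))
  kind <- c(rep(c("unique", "shared"), times = c(579, 864)),
            rep(c("unique", "shared"), times = c(488, 864)))
  res <- covariate_chi_square(kind, et)
  expect_equal(res$chi2, 4.8033, tolerance = 1e-3)
  expect_equal(res$df, 1)
  expect_equal(round(res$p, 2), 0.03)

  # proportional rows: chi2 = 0, p = 1
  tab0 <- covariate_chi_square(rep(c("a", "b"), times = c(60, 30)),
                               rep(c("x", "y"), 45))
  expect_equal(tab0$chi2, 0, tolerance = 1e-12)
  expect_equal(tab0$p, 1)

  # independence null: rejection rate near 0.05
  set.seed(17)
  rej <- vapply(1:600, function(i) {
    a <- sample(c("x", "y"), 200, TRUE)
    b <- sample(c("u", "v"), 200, TRUE)
    covariate_chi_square(a, b)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)

  # pairwise tests appear for > 2 levels and carry BH q
  set.seed(18)
  pw <- covariate_chi_square(sample(c("E1", "E2"), 300, TRUE),
                             sample(c("a", "b", "c"), 300, TRUE))
  expect_equal(nrow(pw$pairwise), 3)
  expect_true(all(pw$pairwise$q >= pw$pairwise$p - 1e-12))
})

test_that("logistic covariate models recover planted odds ratios", {
  set.seed(19)
  n <- 1000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(log(3) * x))
  res <- covariate_logistic(y, x)
  est <- res$estimate[res$term == "covariate"]
  se <- res$se[res$term == "covariate"]
  expect_lt(abs(est - log(3)), 2 * se)
  expect_true(all(res$converged))

  # balanced intercept-only: intercept near 0
  y2 <- rep(0:1, 200)
  res2 <- covariate_logistic(y2, rep(1, 400))
  expect_lt(abs(res2$estimate[1]), 0.2)

  # perfect separation is flagged
  res3 <- covariate_logistic(c(rep(0, 20), rep(1, 20)),
                             c(rep(0, 20), rep(1, 20)))
  expect_false(all(res3$converged))
})

test_that("collinearity report flags duplicated covariates", {
  set.seed(20)
  a <- factor(sample(letters[1:4], 120, TRUE))
  b <- factor(sample(letters[1:3], 120, TRUE))
  cc <- covariate_collinearity(data.frame(a = a, b = b, a2 = a))
  expect_equal(cc$spearman["a", "a2"], 1)
  expect_gt(cc$condition_index["all"], 30)
  expect_equal(cc$annotation[["all"]], "severe")
  expect_true(all(cc$condition_index >= 1))
})
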