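test_that("mean with t-based confidence interval matches the textbook formula", {
  s <- meanCI(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$ci_high - s$mean, qt(0.975, 2) * 1 / sqrt(3),
               tolerance = 1e-9)                     # 4.303 / sqrt(3)
  # constant vector collapses the interval onto the mean
  s0 <- meanCI(rep(7, 5))
  expect_equal(c(s0$ci_low, s0$ci_high), c(7, 7))
  # a 90% CI nests inside the 95% CI on the same data
  set.seed(2); x <- rnorm(20)
  s90 <- meanCI(x, level = 0.90); s95 <- meanCI(x, level = 0.95)
  expect_gt(s90$ci_low, s95$ci_low)
  expect_lt(s90$ci_high, s95$ci_high)
  expect_error(meanCI(1), "at least 2")
})

test_that("Student's t test matches the pooled-variance formula", {
  a <- c(3.1, 4.7, 2.2, 5.8, 4.4); b <- c(6.3, 7.1, 5.5, 8.2)
  res <- studentsTTest(a, b)
  # independently coded pooled-variance formula
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pref <- 2 * pt(-abs(tref), length(a) + length(b) - 2)
  expect_equal(res$t, tref, tolerance = 1e-10)
  expect_equal(res$p, pref, tolerance = 1e-10)
  # identical groups, antisymmetry, degenerate convention
  same <- studentsTTest(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  swapped <- studentsTTest(b, a)
  expect_equal(swapped$t, -res$t); expect_equal(swapped$p, res$p)
  deg <- studentsTTest(c(2, 2), c(2, 2))
  expect_equal(deg$t, 0); expect_equal(deg$p, 1)
})

test_that("Pearson correlation behaves as the product-moment estimator", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  set.seed(4); y <- rnorm(5)
  expect_equal(pearsonCorrelation(x, y)$r, pearsonCorrelation(y, x)$r)
  expect_error(pearsonCorrelation(x, rep(1, 5)), "zero variance")
  # latent-factor simulation reaches the analytic correlation target
  set.seed(6)
  z <- rnorm(10000); w <- 0.85 * z + sqrt(1 - 0.85^2) * rnorm(10000)
  expect_lt(abs(pearsonCorrelation(z, w)$r - 0.85), 0.05)
})

test_that("empirical AUC equals the exhaustive pair-count oracle", {
  expect_equal(rocCurve(c(10, 20, 30), c(1, 2, 3))$auc, 1.0)
  x <- c(4, 7, 9)
  expect_equal(rocCurve(x, x)$auc, 0.5)
  set.seed(8)
  for (i in 1:200) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    cases <- sample(0:10, n1, replace = TRUE)     # integers force ties
    controls <- sample(0:10, n2, replace = TRUE)
    roc <- rocCurve(cases, controls)
    expect_equal(roc$auc, oracle_auc(cases, controls), tolerance = 1e-12)
    # trapezoidal area under the coordinates is a second, independent route
    trapz <- sum(diff(roc$coordinates$fpr) *
                   (head(roc$coordinates$tpr, -1) +
                      tail(roc$coordinates$tpr, -1)) / 2)
    expect_equal(trapz, roc$auc, tolerance = 1e-12)
  }
})

test_that("ROC coordinates sweep monotonically from (0,0) to (1,1)", {
  set.seed(10)
  for (i in 1:20) {
    roc <- rocCurve(rnorm(7, 1), rnorm(5))
    co <- roc$coordinates
    expect_equal(c(co$tpr[1], co$fpr[1]), c(0, 0))
    expect_equal(c(co$tpr[nrow(co)], co$fpr[nrow(co)]), c(1, 1))
    expect_true(all(diff(co$tpr) >= 0))
    expect_true(all(diff(co$fpr) >= 0))
  }
})

test_that("Hanley-McNeil SE matches its closed form and symmetries", {
  # direct evaluation at auc = 0.5: q1 = 1/3, q2 = 1/3
  n <- 10
  vref <- (0.25 + (n - 1) * (1 / 3 - 0.25) * 2) / (n * n)
  expect_equal(aucSE(0.5, n, n), sqrt(vref), tolerance = 1e-12)
  # se shrinks with n and is symmetric in auc about one half
  expect_lt(aucSE(0.8, 50, 50), aucSE(0.8, 10, 10))
  # reversing the marker direction swaps the case/control roles
  expect_equal(aucSE(0.3, 8, 12), aucSE(0.7, 12, 8), tolerance = 1e-12)
  expect_equal(aucSE(0.3, 10, 10), aucSE(0.7, 10, 10), tolerance = 1e-12)
  expect_equal(aucSE(1, 5, 5), 0)
})

test_that("the Youden cutoff matches an exhaustive threshold scan", {
  res <- optimalCutoff(rocCurve(c(10, 20, 30), c(1, 2, 3))$coordinates)
  expect_equal(res$sensitivityPct, 100)
  expect_equal(res$specificityPct, 100)
  expect_gt(res$cutoff, 3); expect_lt(res$cutoff, 10)
  # 16 of 17 cases above and 9 of 10 controls below the chosen cutoff
  cases <- c(150, seq(600, 2100, length.out = 16))
  controls <- c(seq(100, 420, length.out = 9), 10000)
  opt <- optimalCutoff(rocCurve(cases, controls)$coordinates)
  expect_equal(opt$sensitivityPct, 100 * 16 / 17, tolerance = 1e-9)  # 94.1
  expect_equal(opt$specificityPct, 90)
  expect_gt(opt$cutoff, 420); expect_lt(opt$cutoff, 600)
  set.seed(12)
  for (i in 1:100) {
    cs <- sample(0:20, sample(2:8, 1), replace = TRUE)
    ct <- sample(0:20, sample(2:8, 1), replace = TRUE)
    roc <- rocCurve(cs, ct)
    opt <- optimalCutoff(roc$coordinates)
    expect_equal(opt$j, opt$sensitivityPct / 100 +
                   opt$specificityPct / 100 - 1, tolerance = 1e-9)
    expect_equal(opt$sensitivityPct / 100 + opt$specificityPct / 100 - 1,
                 oracle_best_youden(cs, ct), tolerance = 1e-9)
  }
})

test_that("biomarker evaluation composes the ROC machinery consistently", {
  groups <- c(rep("control", 10), rep("survivor", 9), rep("non_survivor", 8))
  set.seed(14)
  values <- c(rnorm(10, 0), rnorm(9, 3), rnorm(8, 6))
  res <- evaluateBiomarker(values, groups, "diagnosis", histone = "H3")
  direct <- rocCurve(values[groups != "control"], values[groups == "control"])
  expect_equal(rocAUC(res), direct$auc)
  expect_equal(res@nCases, 17L); expect_equal(res@nControls, 10L)
  expect_true(res@ciLow <= rocAUC(res) && rocAUC(res) <= res@ciHigh)
  prog <- evaluateBiomarker(values, groups, "prognosis")
  expect_equal(prog@nCases, 8L); expect_equal(prog@nControls, 9L)
  # perfectly separated synthetic groups give AUC 1
  sep <- evaluateBiomarker(c(1:10, 101:117),
                           c(rep("control", 10), rep("survivor", 9),
                             rep("non_survivor", 8)), "diagnosis")
  expect_equal(rocAUC(sep), 1.0)
  expect_error(evaluateBiomarker(1:5, rep("control", 5), "diagnosis"),
               "empty group")
  # permuted labels give chance-level AUC on average
  set.seed(16)
  aucs <- replicate(100, {
    rocAUC(evaluateBiomarker(values, sample(groups), "diagnosis"))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUC and its sweep agree with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (i in 1:10) {
    cases <- rlnorm(9, 7, 1); controls <- rlnorm(10, 5.5, 1)
    mine <- rocCurve(cases, controls)
    ref <- pROC::roc(response = c(rep(1, 9), rep(0, 10)),
                     predictor = c(cases, controls), quiet = TRUE,
                     direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})
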