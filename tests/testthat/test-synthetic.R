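test_that("the default cohort spec matches the study design", {
  spec <- sepsisCohortSpec()
  g <- spec@groups
  expect_equal(g$n[g$group == "control"], 10L)
  expect_equal(g$n[g$group == "survivor"], 9L)
  expect_equal(g$n[g$group == "non_survivor"], 8L)
  expect_equal(g$h2b_mean, c(720.15, 1351.65, 10106.89))
  expect_equal(g$h3_mean, c(179.77, 2094.31, 19988.56))
  # SD back-solved from a t-based 95% CI: mean +/- t * sd / sqrt(n)
  # recovered to the printed precision (the reported mean is 0.005 off the
  # exact CI centre)
  half <- qt(0.975, 9) * g$h2b_sd[1] / sqrt(10)
  expect_equal(c(720.15 - half, 720.15 + half), c(451.23, 989.06),
               tolerance = 1e-4)
})

test_that("concentration draws are deterministic and hit the group means", {
  spec <- sepsisCohortSpec()
  a <- sampleTrueConcentrations(spec, seed = 5)
  b <- sampleTrueConcentrations(spec, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 27L)
  expect_true(all(a$h2b_ng_per_ml > 0 & a$h3_ng_per_ml > 0))
  # law of large numbers at the stated log-normal parameters
  big <- sampleTrueConcentrations(spec, seed = 9,
                                  sizes = c(control = 10000, survivor = 1,
                                            non_survivor = 1))
  ctl <- big[big$group == "control", ]
  expect_equal(mean(ctl$h2b_ng_per_ml), 720.15, tolerance = 0.02)
  expect_equal(mean(ctl$h3_ng_per_ml), 179.77, tolerance = 0.02)
})

test_that("the latent factor calibration delivers the Pearson target", {
  spec <- sepsisCohortSpec()
  big <- sampleTrueConcentrations(spec, seed = 21,
                                  sizes = c(control = 10000, survivor = 1,
                                            non_survivor = 1))
  ctl <- big[big$group == "control", ]
  r <- cor(ctl$h2b_ng_per_ml, ctl$h3_ng_per_ml)
  expect_lt(abs(r - 0.85), 0.05)
})

test_that("unattainable correlation targets are rejected with an explanation", {
  groups <- data.frame(group = "g", n = 5L, h2b_mean = 1, h2b_sd = 0.01,
                       h3_mean = 1, h3_sd = 3)
  spec <- CohortSpec(groups, correlationTarget = 0.85)
  expect_error(sampleTrueConcentrations(spec, seed = 1), "unattainable")
})

test_that("expected ratio inverts the quantification algebra", {
  cfg <- AssayConfig(areaCV = 0)
  # hand algebra: 1540.4 ng/mL at 1000 ug/mL plasma protein and Mr 15404
  # is 100 fmol/ug, i.e. 100 fmol on a 1 ug load against 300 fmol heavy
  expect_equal(concentrationToExpectedRatio(1540.4, 1000, 15404, cfg),
               100 / 300, tolerance = 1e-12)
  # monotone in concentration
  x <- concentrationToExpectedRatio(c(1, 10, 100), 70000, 13906, cfg)
  expect_true(all(diff(x) > 0))
  expect_error(concentrationToExpectedRatio(-1, 70000, 13906, cfg), "> 0")
})

test_that("peak-area noise is multiplicative, positive and unbiased", {
  cfg0 <- AssayConfig(areaCV = 0)
  areas <- simulatePeakAreas(0.5, 12, cfg0, seed = 1)
  expect_equal(areas$light_area / areas$heavy_area, rep(0.5, 12),
               tolerance = 1e-12)
  cfg <- AssayConfig(areaCV = 0.1)
  big <- simulatePeakAreas(2, 10000, cfg, seed = 2)
  expect_true(all(big$light_area > 0 & big$heavy_area > 0))
  expect_equal(mean(big$light_area / big$heavy_area), 2, tolerance = 0.01)
})

test_that("simulated chromatograms integrate to their nominal area", {
  tr <- simulateChromatogram(area = 100, retentionTime = 10, sigma = 0.1,
                             samplingInterval = 0.005)
  expect_equal(integratePeak(tr, c(10 - 0.5, 10 + 0.5)), 100,
               tolerance = 0.005)
  # zero area leaves a flat baseline
  flat <- simulateChromatogram(0, 10, 0.1, 0.005, baseline = 50)
  expect_true(all(flat$intensity == 50))
  # area linearity
  tr2 <- simulateChromatogram(200, 10, 0.1, 0.005)
  expect_equal(integratePeak(tr2, c(9.5, 10.5)),
               2 * integratePeak(tr, c(9.5, 10.5)), tolerance = 1e-9)
})

test_that("calibration series carry the true response slope", {
  cfg0 <- AssayConfig(areaCV = 0)
  cal <- simulateCalibrationSeries(c(0, 1, 5, 10), 2, cfg0, seed = 3)
  curves <- fitCalibrationCurves(cal)
  for (cu in curves) {
    expect_equal(curveSlope(cu), 1 / 300, tolerance = 1e-10)
    expect_equal(curveIntercept(cu), 0, tolerance = 1e-12)
  }
  # blanks carry an expected ratio of zero
  blank <- cal[cal$level_fmol == 0, ]
  expect_equal(blank$light_area, rep(0, nrow(blank)))
  # noisy series still recovers the slope to 5%
  cfg <- AssayConfig(areaCV = 0.1)
  calN <- simulateCalibrationSeries(replicates = 3, config = cfg, seed = 4)
  for (cu in fitCalibrationCurves(calN))
    expect_equal(curveSlope(cu), 1 / 300, tolerance = 0.05)
  expect_error(simulateCalibrationSeries(c(1, 5), 3, cfg, 1), "3 distinct")
  expect_error(simulateCalibrationSeries(c(-1, 5, 10), 3, cfg, 1),
               "non-negative")
})

test_that("cohort simulation is deterministic and properly shaped", {
  cfg <- AssayConfig(areaCV = 0.1)
  s1 <- simulateCohort(sepsisCohortSpec(), cfg, seed = 8)
  s2 <- simulateCohort(sepsisCohortSpec(), cfg, seed = 8)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1$areas$sample_id)), 27L)
  # 12 transitions for the H2B peptide, 9 for the H3 peptide, per sample
  counts <- table(s1$areas$peptide)
  expect_equal(unname(counts[["LLLPGELAK"]]), 27L * 12L)
  expect_equal(unname(counts[["STELLIR"]]), 27L * 9L)
  expect_true(all(s1$areas$light_area > 0 & s1$areas$heavy_area > 0))
})
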