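test_that("ratio computation and aggregation follow the averaging rule", {
  expect_equal(computeLHRatio(3000, 1000), 3.0)
  expect_equal(computeLHRatio(1234, 1234), 1.0)
  expect_error(computeLHRatio(100, 0), "must be > 0")
  agg <- aggregateTransitions(c(2000, 4000), c(1000, 1000))
  expect_equal(agg$meanRatio, 3.0)
  expect_equal(agg$ratioCV, sd(c(2, 4)) / 3, tolerance = 1e-12)  # ~0.471
  expect_equal(agg$nUsed, 2L)
  # single transition and all-equal ratios give CV 0
  expect_equal(aggregateTransitions(500, 100)$ratioCV, 0)
  expect_equal(aggregateTransitions(c(2, 2, 2), c(1, 1, 1))$ratioCV, 0)
  # aggregation mean lies within the per-transition ratio range
  set.seed(3)
  for (i in 1:20) {
    l <- runif(8, 10, 1000); h <- runif(8, 10, 1000)
    a <- aggregateTransitions(l, h)
    expect_gte(a$meanRatio, min(a$ratios))
    expect_lte(a$meanRatio, max(a$ratios))
  }
  # unusable transitions are excluded and counted
  a <- aggregateTransitions(c(10, 20), c(0, 10))
  expect_equal(a$nUsed, 1L); expect_equal(a$nExcluded, 1L)
  expect_equal(a$meanRatio, 2)
})

test_that("standard-curve fitting recovers exact and noisy lines", {
  x <- c(1, 10, 50, 100, 300)
  cu <- fitStandardCurve(x, 0.01 * x)
  expect_equal(curveSlope(cu), 0.01, tolerance = 1e-12)
  expect_equal(curveIntercept(cu), 0, tolerance = 1e-12)
  expect_equal(curveRSquared(cu), 1, tolerance = 1e-12)
  expect_equal(curveRange(cu), c(1, 300))
  # 1/x weighting cannot change a perfect fit
  cuw <- fitStandardCurve(x, 0.01 * x, weighting = "1/x")
  expect_equal(curveSlope(cuw), curveSlope(cu), tolerance = 1e-10)
  expect_equal(curveIntercept(cuw), curveIntercept(cu), tolerance = 1e-10)
  expect_error(fitStandardCurve(c(1, 1, 1), c(1, 2, 3)), "3 distinct")
})

test_that("interpolation inverts the calibration line and flags the range", {
  cu <- fitStandardCurve(c(10, 100, 300), 0.01 * c(10, 100, 300))
  res <- interpolateAmount(cu, 3)
  expect_equal(res$amount_fmol, 300, tolerance = 1e-9)
  expect_false(res$below_range); expect_false(res$above_range)
  expect_equal(interpolateAmount(cu, curveIntercept(cu))$amount_fmol, 0,
               tolerance = 1e-9)
  expect_true(interpolateAmount(cu, 0.001)$below_range)
  expect_true(interpolateAmount(cu, 100)$above_range)
  # round trip on generated lines: interpolate(fit(line), predict(x)) = x
  set.seed(5)
  for (i in 1:10) {
    slope <- runif(1, 1e-4, 1); icpt <- runif(1, 0, 0.5)
    xs <- sort(runif(5, 1, 500))
    cu2 <- fitStandardCurve(xs, slope * xs + icpt)
    expect_equal(interpolateAmount(cu2, slope * 42 + icpt)$amount_fmol, 42,
                 tolerance = 1e-6)
  }
  bad <- new("StandardCurve", peptide = "X", slope = -1, intercept = 0,
             rSquared = 1, residualSE = 0, rangeFmol = c(1, 10),
             weighting = "none")
  expect_error(interpolateAmount(bad, 1), "slope")
})

test_that("unit conversion to ng/mL follows the Mr-based formula", {
  expect_equal(toConcentration(100, 1, 1000, 15404), 1540.4, tolerance = 1e-12)
  expect_equal(toConcentration(0, 1, 1000, 15404), 0)
  # doubling plasma protein doubles the concentration
  expect_equal(toConcentration(10, 1, 2000, 13906),
               2 * toConcentration(10, 1, 1000, 13906), tolerance = 1e-12)
  expect_error(toConcentration(10, 0, 1000, 13906), "> 0")
})

test_that("noiseless simulated cohorts are recovered exactly", {
  cfg <- AssayConfig(areaCV = 0)
  sim <- simulateCohort(sepsisCohortSpec(), cfg, seed = 17)
  curves <- fitCalibrationCurves(simulateCalibrationSeries(config = cfg,
                                                           seed = 18))
  q <- quantifySamples(sim$areas, curves, sim$metadata, cfg)
  truth <- sim$truth
  tru <- ifelse(q$histone == "H2B",
                truth$h2b_ng_per_ml[match(q$sample_id, truth$sample_id)],
                truth$h3_ng_per_ml[match(q$sample_id, truth$sample_id)])
  expect_equal(nrow(q), 54L)
  expect_lt(max(abs(q$ng_per_ml / tru - 1)), 1e-6)
  expect_true(all(q$flags %in% c("", "below_range", "above_range")))
})

test_that("scaling all light areas scales concentrations proportionally", {
  cfg <- AssayConfig(areaCV = 0)
  sim <- simulateCohort(sepsisCohortSpec(), cfg, seed = 23)
  cal <- simulateCalibrationSeries(c(0, 1, 5, 20, 50), 1, cfg, seed = 24)
  curves <- fitCalibrationCurves(cal)      # intercept 0 in the noiseless limit
  q1 <- quantifySamples(sim$areas, curves, sim$metadata, cfg)
  scaled <- sim$areas; scaled$light_area <- 3 * scaled$light_area
  q3 <- quantifySamples(scaled, curves, sim$metadata, cfg)
  expect_equal(q3$ng_per_ml, 3 * q1$ng_per_ml, tolerance = 1e-9)
})

test_that("degenerate inputs yield flagged records, not failures", {
  cfg <- AssayConfig(areaCV = 0)
  sim <- simulateCohort(sepsisCohortSpec(), cfg, seed = 29)
  curves <- fitCalibrationCurves(simulateCalibrationSeries(config = cfg,
                                                           seed = 30))
  # empty measurement table
  expect_equal(nrow(quantifySamples(sim$areas[0, ], curves, sim$metadata, cfg)),
               0L)
  # all heavy areas zero for one sample -> unquantifiable, run continues
  areas <- sim$areas
  sid <- areas$sample_id[1]
  areas$heavy_area[areas$sample_id == sid] <- 0
  q <- quantifySamples(areas, curves, sim$metadata, cfg)
  expect_equal(unique(q$flags[q$sample_id == sid]), "unquantifiable")
  expect_true(all(is.na(q$ng_per_ml[q$sample_id == sid])))
  expect_false(any(is.na(q$ng_per_ml[q$sample_id != sid])))
})

test_that("peak integration handles windows and baselines", {
  tr <- simulateChromatogram(50, 5, 0.05, 0.002, baseline = 10)
  expect_equal(integratePeak(tr, c(4.75, 5.25)), 50, tolerance = 0.005)
  # baseline-only trace integrates to zero
  flat <- simulateChromatogram(0, 5, 0.05, 0.002, baseline = 10)
  expect_equal(integratePeak(flat, c(4.8, 5.2)), 0)
  # zero-width window
  expect_equal(integratePeak(tr, c(5, 5)), 0)
})
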