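# Synthetic calibration series and cohort generator.
#
# Concentrations are log-normal within each group (positive, right-skewed,
# consistent with wide asymmetric confidence intervals around the reported
# means). The two histones share a latent Gaussian factor whose correlation
# is calibrated analytically so the *observed* Pearson correlation of the
# log-normal concentrations hits the requested target.

# back-solve an SD from a t-based 95% CI of the mean at sample size n
.sdFromCI <- function(ci_low, ci_high, n, level = 0.95) {
  half <- (ci_high - ci_low) / 2
  half * sqrt(n) / stats::qt(1 - (1 - level) / 2, df = n - 1)
}

# log-normal (meanlog, sdlog) from arithmetic mean m and SD s
.lnormPars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# latent Gaussian correlation giving Pearson r between two log-normals
.latentRho <- function(r, sdlog1, sdlog2) {
  arg <- 1 + r * sqrt(expm1(sdlog1^2) * expm1(sdlog2^2))
  if (arg <= 0)
    stop("correlation target unattainable: implied latent covariance <= 0")
  rho <- log(arg) / (sdlog1 * sdlog2)
  if (abs(rho) > 1)
    stop(sprintf(
      "correlation target unattainable at these dispersions (latent rho = %.3f)",
      rho))
  rho
}

#' Cohort specification matching the published septic-shock study
#'
#' Builds the default [CohortSpec-class]: 10 healthy controls, 9 surviving
#' and 8 non-surviving septic-shock patients, with per-group log-normal
#' concentration distributions whose arithmetic means equal the reported
#' group means (H2B: 720.15 / 1,351.65 / 10,106.89 ng/mL; H3: 179.77 /
#' 2,094.31 / 19,988.56 ng/mL) and whose SDs are back-solved from the
#' reported t-based 95% confidence intervals at the reported group sizes.
#' The inter-histone correlation target defaults to 0.85, between the
#' reported subgroup Pearson coefficients (0.856 controls, 0.824 patients).
#'
#' @return A [CohortSpec-class] object.
#'
#' @examples
#' sepsisCohortSpec()
#' @export
sepsisCohortSpec <- function() {
  groups <- data.frame(
    group = c("control", "survivor", "non_survivor"),
    n = c(10L, 9L, 8L),
    h2b_mean = c(720.15, 1351.65, 10106.89),
    h2b_sd = c(
      .sdFromCI(451.23, 989.06, 10),
      .sdFromCI(688.01, 2015.28, 9),
      .sdFromCI(2076.16, 18137.62, 8)
    ),
    h3_mean = c(179.77, 2094.31, 19988.56),
    h3_sd = c(
      .sdFromCI(7.64, 351.89, 10),
      .sdFromCI(660.44, 3528.17, 9),
      .sdFromCI(5743.14, 34233.97, 8)
    ),
    stringsAsFactors = FALSE
  )
  CohortSpec(groups)
}

#' Draw true per-sample histone concentrations
#'
#' Within each group, (H2B, H3) concentrations are bivariate log-normal:
#' a shared standard-normal latent factor with analytically calibrated
#' correlation drives both log-concentrations, so the observed Pearson
#' correlation matches the spec's target at large n. Plasma total protein
#' is drawn log-normally around the spec's mean. Deterministic under a
#' fixed seed.
#'
#' @param spec A [CohortSpec-class].
#' @param seed Integer RNG seed.
#' @param sizes Optional named integer vector overriding group sizes
#'   (e.g. for Monte-Carlo checks at large n).
#'
#' @return data.frame with columns `sample_id`, `group`, `h2b_ng_per_ml`,
#'   `h3_ng_per_ml`, `plasma_protein_ug_per_ml`.
#'
#' @examples
#' head(sampleTrueConcentrations(sepsisCohortSpec(), seed = 1))
#' @export
sampleTrueConcentrations <- function(spec, seed, sizes = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(spec@groups)), function(i) {
    g <- spec@groups[i, ]
    n <- if (!is.null(sizes)) as.integer(sizes[[g$group]]) else g$n
    p1 <- .lnormPars(g$h2b_mean, g$h2b_sd)
    p2 <- .lnormPars(g$h3_mean, g$h3_sd)
    rho <- .latentRho(spec@correlationTarget, p1[["sdlog"]], p2[["sdlog"]])
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(
      sample_id = sprintf("%s_%02d", g$group, seq_len(n)),
      group = g$group,
      h2b_ng_per_ml = exp(p1[["meanlog"]] + p1[["sdlog"]] * z1),
      h3_ng_per_ml = exp(p2[["meanlog"]] + p2[["sdlog"]] * z2),
      plasma_protein_ug_per_ml = stats::rlnorm(
        n,
        meanlog = log(spec@plasmaProteinMean) -
          log(1 + spec@plasmaProteinCV^2) / 2,
        sdlog = sqrt(log(1 + spec@plasmaProteinCV^2))
      ),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected L/H ratio for a given plasma concentration
#'
#' Exact algebraic inverse of the quantification chain: ng/mL is converted
#' back to fmol light peptide in the digest (via plasma total protein,
#' protein load and Mr), and the fmol amount to an L/H ratio through the
#' true detector response line (slope `1/spikeAmountFmol`, intercept 0).
#' Composing with [toConcentration()] and a noiseless fitted curve is the
#' identity.
#'
#' @param concNgPerMl True plasma concentration, ng/mL.
#' @param plasmaProteinUgPerMl Plasma total protein, ug/mL.
#' @param mrDa Average molecular mass of the intact protein, Da.
#' @param config An [AssayConfig-class].
#'
#' @return Expected light/heavy area ratio (dimensionless).
#' @export
concentrationToExpectedRatio <- function(concNgPerMl, plasmaProteinUgPerMl,
                                         mrDa, config = AssayConfig()) {
  if (any(concNgPerMl <= 0) || any(plasmaProteinUgPerMl <= 0) || any(mrDa <= 0))
    stop("all arguments must be > 0")
  fmolPerUg <- concNgPerMl * 1e6 / (mrDa * plasmaProteinUgPerMl)
  fmol <- fmolPerUg * config@proteinLoadUg
  fmol / config@spikeAmountFmol
}

# log-normal multiplicative noise factors with mean exactly 1 and CV = cv
.noiseFactors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-transition light/heavy peak areas
#'
#' Heavy areas are `heavyBaseArea` times independent log-normal noise of
#' mean 1 and CV `areaCV`; light areas are the expected ratio times the
#' heavy area times an independent noise factor. Per-transition ratios
#' therefore scatter multiplicatively around the expected ratio with mean
#' exactly equal to it. `areaCV = 0` reproduces the expected ratio on every
#' transition.
#'
#' @param expectedRatio Expected L/H ratio (0 allowed for blanks).
#' @param nTransitions Number of transitions to simulate.
#' @param config An [AssayConfig-class].
#' @param seed Optional integer seed (omit when called inside a larger
#'   seeded simulation).
#'
#' @return data.frame with columns `fragment` (t1..tn), `light_area`,
#'   `heavy_area`.
#' @export
simulatePeakAreas <- function(expectedRatio, nTransitions,
                              config = AssayConfig(), seed = NULL) {
  if (expectedRatio < 0) stop("'expectedRatio' must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  heavy <- config@heavyBaseArea * .noiseFactors(nTransitions, config@areaCV)
  light <- expectedRatio * heavy * .noiseFactors(nTransitions, config@areaCV)
  data.frame(
    fragment = sprintf("t%02d", seq_len(nTransitions)),
    light_area = light,
    heavy_area = heavy,
    stringsAsFactors = FALSE
  )
}

#' Simulate a single MRM chromatographic peak
#'
#' A Gaussian elution profile of the stated area on a flat baseline,
#' sampled on a regular time grid spanning +/- 6 sigma around the retention
#' time, with optional additive Gaussian noise (clamped at zero intensity).
#'
#' @param area Peak area (intensity x min).
#' @param retentionTime Apex time, min.
#' @param sigma Peak width (Gaussian SD), min.
#' @param samplingInterval Grid spacing, min.
#' @param baseline Flat baseline intensity, default 0.
#' @param noiseSd Additive noise SD, default 0.
#' @param seed Optional integer seed.
#'
#' @return A list of class `ChromatogramTrace`: `time`, `intensity`,
#'   `retentionTime`, `sigma`, `baseline`.
#' @export
simulateChromatogram <- function(area, retentionTime, sigma, samplingInterval,
                                 baseline = 0, noiseSd = 0, seed = NULL) {
  if (area < 0) stop("'area' must be >= 0")
  if (sigma <= 0 || samplingInterval <= 0)
    stop("'sigma' and 'samplingInterval' must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  time <- seq(retentionTime - 6 * sigma, retentionTime + 6 * sigma,
              by = samplingInterval)
  intensity <- baseline + area * stats::dnorm(time, retentionTime, sigma)
  if (noiseSd > 0) intensity <- intensity + stats::rnorm(length(time), 0, noiseSd)
  intensity <- pmax(intensity, 0)
  structure(
    list(time = time, intensity = intensity, retentionTime = retentionTime,
         sigma = sigma, baseline = baseline),
    class = "ChromatogramTrace"
  )
}

#' Simulate a spike-in calibration series
#'
#' For each calibration level (fmol of light peptide in the digest) and
#' replicate, per-transition light/heavy areas are simulated with expected
#' ratio `level / spikeAmountFmol` for every configured peptide.
#'
#' @param levelsFmol Numeric vector of calibration levels (>= 3 distinct,
#'   non-negative; 0 is a blank).
#' @param replicates Replicates per level.
#' @param config An [AssayConfig-class].
#' @param seed Integer seed.
#'
#' @return data.frame with columns `level_fmol`, `replicate`, `peptide`,
#'   `fragment`, `light_area`, `heavy_area`.
#'
#' @examples
#' head(simulateCalibrationSeries(c(1, 5, 10), 2, AssayConfig(areaCV = 0), 1))
#' @export
simulateCalibrationSeries <- function(levelsFmol = c(0.1, 0.5, 1, 5, 10, 20, 40),
                                      replicates = 3L,
                                      config = AssayConfig(), seed = 1L) {
  if (any(levelsFmol < 0)) stop("calibration levels must be non-negative")
  if (length(unique(levelsFmol)) < 3L)
    stop("at least 3 distinct calibration levels are required")
  set.seed(as.integer(seed))
  grid <- expand.grid(
    replicate = seq_len(replicates),
    level_fmol = levelsFmol,
    peptide = names(config@transitionsPerPeptide),
    stringsAsFactors = FALSE
  )
  out <- lapply(seq_len(nrow(grid)), function(i) {
    pep <- grid$peptide[i]
    areas <- simulatePeakAreas(
      expectedRatio = grid$level_fmol[i] / config@spikeAmountFmol,
      nTransitions = config@transitionsPerPeptide[[pep]],
      config = config
    )
    cbind(
      level_fmol = grid$level_fmol[i], replicate = grid$replicate[i],
      peptide = pep, areas, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("level_fmol", "replicate", "peptide", "fragment",
          "light_area", "heavy_area")]
}

#' Simulate a full cohort of per-transition peak areas
#'
#' Draws true concentrations via [sampleTrueConcentrations()], converts them
#' to expected L/H ratios per histone peptide, and simulates per-transition
#' areas for every sample.
#'
#' @param spec A [CohortSpec-class].
#' @param config An [AssayConfig-class].
#' @param seed Integer seed.
#'
#' @return A list with elements `areas` (long data.frame: `sample_id`,
#'   `peptide`, `fragment`, `light_area`, `heavy_area`), `metadata`
#'   (`sample_id`, `group`, `plasma_protein_ug_per_ml`) and `truth` (the
#'   [sampleTrueConcentrations()] output).
#'
#' @examples
#' sim <- simulateCohort(sepsisCohortSpec(), AssayConfig(areaCV = 0), seed = 1)
#' head(sim$areas)
#' @export
simulateCohort <- function(spec = sepsisCohortSpec(), config = AssayConfig(),
                           seed = 1L) {
  truth <- sampleTrueConcentrations(spec, seed = seed)
  pepinfo <- histoneForPeptide(names(config@transitionsPerPeptide))
  areas <- lapply(seq_len(nrow(truth)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(pepinfo)), function(j) {
      conc <- if (pepinfo$histone[j] == "H2B") truth$h2b_ng_per_ml[i]
              else truth$h3_ng_per_ml[i]
      ratio <- concentrationToExpectedRatio(
        conc, truth$plasma_protein_ug_per_ml[i], pepinfo$mr_da[j], config)
      cbind(
        sample_id = truth$sample_id[i], peptide = pepinfo$peptide[j],
        simulatePeakAreas(ratio, config@transitionsPerPeptide[[pepinfo$peptide[j]]],
                          config),
        stringsAsFactors = FALSE
      )
    }))
  })
  areas <- do.call(rbind, areas)
  rownames(areas) <- NULL
  list(
    areas = areas[, c("sample_id", "peptide", "fragment",
                      "light_area", "heavy_area")],
    metadata = truth[, c("sample_id", "group", "plasma_protein_ug_per_ml")],
    truth = truth
  )
}
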