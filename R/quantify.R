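#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the baseline-subtracted intensity over a time
#' window, clamped at zero (a noisy baseline cannot yield a negative area).
#'
#' @param trace A `ChromatogramTrace` from [simulateChromatogram()].
#' @param window `c(from, to)` in the trace's time units; defaults to the
#'   full trace.
#'
#' @return Peak area (intensity x min), >= 0.
#' @export
integratePeak <- function(trace, window = range(trace$time)) {
  if (!inherits(trace, "ChromatogramTrace")) stop("'trace' must be a ChromatogramTrace")
  if (length(window) != 2L || window[1] > window[2]) stop("invalid window")
  keep <- trace$time >= window[1] & trace$time <= window[2]
  if (sum(keep) < 2L) return(0)
  t <- trace$time[keep]
  y <- trace$intensity[keep] - trace$baseline
  area <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  max(area, 0)
}

#' Light/heavy ratio of one transition measurement
#'
#' @param lightArea,heavyArea Peak areas; `heavyArea` must be > 0 for a
#'   usable record.
#' @return `lightArea / heavyArea`.
#' @export
computeLHRatio <- function(lightArea, heavyArea) {
  if (any(heavyArea <= 0))
    stop("heavy area must be > 0; record should be excluded upstream")
  lightArea / heavyArea
}

#' Aggregate per-transition ratios into a peptide-level ratio
#'
#' The peptide-level readout is the unweighted arithmetic mean of the
#' usable per-transition L/H ratios; its CV (sd/mean) is reported and
#' flagged when above the configured threshold. Transitions with
#' non-positive heavy area are excluded and counted.
#'
#' @param lightAreas,heavyAreas Numeric vectors of per-transition areas.
#' @param cvFlagThreshold Ratio-CV flag threshold, default 0.2.
#'
#' @return A list: `meanRatio`, `ratioCV`, `nUsed`, `nExcluded`,
#'   `highRatioCV` (logical), `ratios`.
#'
#' @examples
#' aggregateTransitions(c(2000, 4000), c(1000, 1000))  # mean 3, cv ~0.471
#' @export
aggregateTransitions <- function(lightAreas, heavyAreas,
                                 cvFlagThreshold = 0.2) {
  stopifnot(length(lightAreas) == length(heavyAreas))
  usable <- is.finite(lightAreas) & is.finite(heavyAreas) &
    heavyAreas > 0 & lightAreas >= 0
  nExcluded <- sum(!usable)
  if (!any(usable))
    return(list(meanRatio = NA_real_, ratioCV = NA_real_, nUsed = 0L,
                nExcluded = nExcluded, highRatioCV = NA, ratios = numeric(0)))
  ratios <- lightAreas[usable] / heavyAreas[usable]
  m <- mean(ratios)
  cv <- if (length(ratios) > 1L && m > 0) stats::sd(ratios) / m else 0
  list(meanRatio = m, ratioCV = cv, nUsed = length(ratios),
       nExcluded = nExcluded, highRatioCV = cv > cvFlagThreshold,
       ratios = ratios)
}

#' Fit a spike-in standard curve
#'
#' Ordinary least squares of the L/H ratio against the spiked light amount
#' (fmol), with a free intercept (matrix blanks may sit above zero) and
#' optional 1/x weighting (equalises relative influence across a wide
#' calibration range; zero-fmol blanks are excluded from a weighted fit
#' since their weight is undefined).
#'
#' @param levelFmol Numeric vector of calibration levels.
#' @param ratio Matching L/H ratios.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @param peptide Optional peptide label stored on the curve.
#'
#' @return A [StandardCurve-class].
#'
#' @examples
#' fitStandardCurve(c(1, 10, 100), c(0.01, 0.1, 1))
#' @export
fitStandardCurve <- function(levelFmol, ratio, weighting = c("none", "1/x"),
                             peptide = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(levelFmol) == length(ratio))
  if (length(unique(levelFmol)) < 3L)
    stop("at least 3 distinct calibration levels are required")
  df <- data.frame(x = levelFmol, y = ratio)
  if (weighting == "1/x") {
    df <- df[df$x > 0, , drop = FALSE]
    if (length(unique(df$x)) < 3L)
      stop("at least 3 distinct positive levels are required for 1/x weighting")
    fit <- stats::lm(y ~ x, data = df, weights = 1 / df$x)
  } else {
    fit <- stats::lm(y ~ x, data = df)
  }
  sm <- suppressWarnings(summary(fit))  # noiseless series fit exactly
  new("StandardCurve",
      peptide = peptide,
      slope = unname(stats::coef(fit)[["x"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      rSquared = sm$r.squared,
      residualSE = sm$sigma,
      rangeFmol = range(df$x),
      weighting = weighting)
}

#' Interpolate a ratio on a standard curve
#'
#' Inverts the calibration line: `fmol = (ratio - intercept) / slope`.
#' Ratios outside the calibrated range still return a value but are
#' flagged, so cohort statistics remain computable.
#'
#' @param curve A [StandardCurve-class] with positive slope.
#' @param ratio Numeric vector of L/H ratios.
#'
#' @return data.frame with columns `amount_fmol`, `below_range`,
#'   `above_range`.
#' @export
interpolateAmount <- function(curve, ratio) {
  stopifnot(is(curve, "StandardCurve"))
  if (curve@slope <= 0)
    stop("standard curve rejected: slope must be > 0")
  amount <- (ratio - curve@intercept) / curve@slope
  data.frame(
    amount_fmol = amount,
    below_range = amount < curve@rangeFmol[1],
    above_range = amount > curve@rangeFmol[2]
  )
}

#' Convert a molar amount to a plasma concentration
#'
#' `ng/mL = (fmol / ug digested protein) * Mr(Da) * 1e-6 * plasma total
#' protein (ug/mL)`; the 1e-6 factor converts fmol x (g/mol) to ng.
#'
#' @param amountFmol Interpolated light-peptide amount, fmol.
#' @param proteinLoadUg Digested protein load, ug.
#' @param plasmaProteinUgPerMl Plasma total protein, ug/mL.
#' @param mrDa Average molecular mass of the intact protein, Da.
#'
#' @return Concentration in ng histone per mL plasma.
#'
#' @examples
#' toConcentration(100, 1, 1000, 15404)  # 1540.4 ng/mL
#' @export
toConcentration <- function(amountFmol, proteinLoadUg, plasmaProteinUgPerMl,
                            mrDa) {
  if (any(proteinLoadUg <= 0) || any(plasmaProteinUgPerMl <= 0) || any(mrDa <= 0))
    stop("'proteinLoadUg', 'plasmaProteinUgPerMl' and 'mrDa' must be > 0")
  (amountFmol / proteinLoadUg) * mrDa * 1e-6 * plasmaProteinUgPerMl
}

#' Quantify a cohort of samples
#'
#' Full quantification chain per sample x peptide: per-transition L/H
#' ratios, arithmetic-mean aggregation with CV QC, standard-curve
#' interpolation to fmol, and conversion to ng/mL plasma via plasma total
#' protein and protein Mr. Samples without metadata or without a curve for
#' their peptide yield an unquantifiable record (NA concentration, flag
#' set); the run continues.
#'
#' @param areas Long data.frame: `sample_id`, `peptide`, `fragment`,
#'   `light_area`, `heavy_area`.
#' @param curves Named list of [StandardCurve-class] objects, one per
#'   peptide.
#' @param metadata data.frame: `sample_id`, `group`,
#'   `plasma_protein_ug_per_ml`.
#' @param config An [AssayConfig-class].
#'
#' @return data.frame with one row per sample x histone: `sample_id`,
#'   `group`, `histone`, `peptide`, `mean_ratio`, `ratio_cv`,
#'   `n_transitions_used`, `amount_fmol_per_ug`, `ng_per_ml`, `flags`
#'   (semicolon-separated subset of below_range/above_range/high_ratio_cv/
#'   unquantifiable, empty when clean).
#'
#' @examples
#' sim <- simulateCohort(sepsisCohortSpec(), AssayConfig(areaCV = 0), seed = 1)
#' cal <- simulateCalibrationSeries(config = AssayConfig(areaCV = 0), seed = 2)
#' curves <- fitCalibrationCurves(cal)
#' head(quantifySamples(sim$areas, curves, sim$metadata, AssayConfig(areaCV = 0)))
#' @export
quantifySamples <- function(areas, curves, metadata, config = AssayConfig()) {
  need <- c("sample_id", "peptide", "light_area", "heavy_area")
  miss <- setdiff(need, names(areas))
  if (length(miss))
    stop(sprintf("areas table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(areas) == 0L) return(.emptyQuantFrame())
  keys <- unique(areas[, c("sample_id", "peptide")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sid <- keys$sample_id[i]; pep <- keys$peptide[i]
    sub <- areas[areas$sample_id == sid & areas$peptide == pep, ]
    agg <- aggregateTransitions(sub$light_area, sub$heavy_area,
                                config@cvFlagThreshold)
    info <- histoneForPeptide(pep)
    meta <- metadata[metadata$sample_id == sid, , drop = FALSE]
    flags <- character(0)
    amount <- NA_real_; conc <- NA_real_
    if (agg$nUsed == 0L || nrow(meta) != 1L || is.null(curves[[pep]]) ||
        is.na(info$histone)) {
      flags <- "unquantifiable"
    } else {
      interp <- interpolateAmount(curves[[pep]], agg$meanRatio)
      amount <- interp$amount_fmol / config@proteinLoadUg
      conc <- toConcentration(interp$amount_fmol, config@proteinLoadUg,
                              meta$plasma_protein_ug_per_ml, info$mr_da)
      if (interp$below_range) flags <- c(flags, "below_range")
      if (interp$above_range) flags <- c(flags, "above_range")
      if (isTRUE(agg$highRatioCV)) flags <- c(flags, "high_ratio_cv")
    }
    data.frame(
      sample_id = sid,
      group = if (nrow(meta) == 1L) meta$group else NA_character_,
      histone = info$histone, peptide = pep,
      mean_ratio = agg$meanRatio, ratio_cv = agg$ratioCV,
      n_transitions_used = agg$nUsed,
      amount_fmol_per_ug = amount, ng_per_ml = conc,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.emptyQuantFrame <- function() {
  data.frame(
    sample_id = character(0), group = character(0), histone = character(0),
    peptide = character(0), mean_ratio = numeric(0), ratio_cv = numeric(0),
    n_transitions_used = integer(0), amount_fmol_per_ug = numeric(0),
    ng_per_ml = numeric(0), flags = character(0), stringsAsFactors = FALSE
  )
}

#' Fit standard curves for every peptide in a calibration table
#'
#' Aggregates per-transition ratios within each level x replicate (the
#' same arithmetic-mean readout used for samples), then fits one
#' [StandardCurve-class] per peptide.
#'
#' @param calibration data.frame from [simulateCalibrationSeries()] (or the
#'   calibration CSV): `level_fmol`, `replicate`, `peptide`, `fragment`,
#'   `light_area`, `heavy_area`.
#' @param weighting `"none"` or `"1/x"`.
#'
#' @return Named list of [StandardCurve-class] objects.
#' @export
fitCalibrationCurves <- function(calibration, weighting = "none") {
  need <- c("level_fmol", "replicate", "peptide", "light_area", "heavy_area")
  miss <- setdiff(need, names(calibration))
  if (length(miss))
    stop(sprintf("calibration table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  out <- lapply(split(calibration, calibration$peptide), function(sub) {
    keys <- unique(sub[, c("level_fmol", "replicate")])
    pts <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      s <- sub[sub$level_fmol == keys$level_fmol[i] &
                 sub$replicate == keys$replicate[i], ]
      agg <- aggregateTransitions(s$light_area, s$heavy_area)
      data.frame(level = keys$level_fmol[i], ratio = agg$meanRatio)
    }))
    fitStandardCurve(pts$level, pts$ratio, weighting = weighting,
                     peptide = sub$peptide[1])
  })
  out
}
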