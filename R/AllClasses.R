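#' @import methods
NULL

#' Assay configuration
#'
#' Holds the acquisition-side constants of the spike-in MRM assay: the heavy
#' peptide amount spiked per digest (fmol), the digested protein load (ug),
#' the number of transitions monitored per peptide, and the multiplicative
#' noise level of simulated peak areas.
#'
#' The detector is modelled as equally responsive to light and heavy
#' species, so the true calibration line has slope
#' `1 / spikeAmountFmol` (L/H ratio per fmol) and intercept 0; fitted
#' standard curves re-estimate both from (possibly noisy) calibration data.
#'
#' @slot spikeAmountFmol Heavy peptide amount per digest, fmol (default 300).
#' @slot proteinLoadUg Digested total protein, ug (default 1).
#' @slot transitionsPerPeptide Named integer vector, transitions monitored
#'   per peptide (defaults: LLLPGELAK 12, STELLIR 9).
#' @slot areaCV Fractional coefficient of variation of simulated areas.
#' @slot heavyBaseArea Mean heavy-channel peak area, arbitrary units.
#' @slot cvFlagThreshold Per-peptide ratio CV above which a measurement is
#'   flagged `high_ratio_cv` (default 0.2).
#' @slot weighting Standard-curve weighting, `"none"` or `"1/x"`.
#'
#' @export
setClass("AssayConfig", representation(
  spikeAmountFmol = "numeric",
  proteinLoadUg = "numeric",
  transitionsPerPeptide = "integer",
  areaCV = "numeric",
  heavyBaseArea = "numeric",
  cvFlagThreshold = "numeric",
  weighting = "character"
))

setValidity("AssayConfig", function(object) {
  msg <- character(0)
  if (object@spikeAmountFmol <= 0) msg <- c(msg, "spikeAmountFmol must be > 0")
  if (object@proteinLoadUg <= 0) msg <- c(msg, "proteinLoadUg must be > 0")
  if (object@areaCV < 0 || object@areaCV >= 1)
    msg <- c(msg, "areaCV must lie in [0, 1)")
  if (object@heavyBaseArea <= 0) msg <- c(msg, "heavyBaseArea must be > 0")
  if (!object@weighting %in% c("none", "1/x"))
    msg <- c(msg, "weighting must be 'none' or '1/x'")
  if (length(object@transitionsPerPeptide) &&
      (is.null(names(object@transitionsPerPeptide)) ||
       any(object@transitionsPerPeptide < 1L)))
    msg <- c(msg, "transitionsPerPeptide must be a named positive integer vector")
  if (length(msg)) msg else TRUE
})

#' @param spikeAmountFmol,proteinLoadUg,transitionsPerPeptide,areaCV,heavyBaseArea,cvFlagThreshold,weighting
#'   See slot documentation.
#' @return An `AssayConfig` object.
#' @rdname AssayConfig-class
#' @examples
#' AssayConfig(areaCV = 0)
#' @export
AssayConfig <- function(spikeAmountFmol = 300, proteinLoadUg = 1,
                        transitionsPerPeptide = .DEFAULT_TRANSITIONS,
                        areaCV = 0.1, heavyBaseArea = 1e5,
                        cvFlagThreshold = 0.2, weighting = "none") {
  new("AssayConfig",
      spikeAmountFmol = spikeAmountFmol, proteinLoadUg = proteinLoadUg,
      transitionsPerPeptide = as.integer(transitionsPerPeptide) |>
        stats::setNames(names(transitionsPerPeptide)),
      areaCV = areaCV, heavyBaseArea = heavyBaseArea,
      cvFlagThreshold = cvFlagThreshold, weighting = weighting)
}

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig:",
      sprintf("%g fmol heavy spike on %g ug protein;", object@spikeAmountFmol,
              object@proteinLoadUg),
      sprintf("area CV %.3g; weighting %s\n", object@areaCV, object@weighting))
  cat("  transitions per peptide:",
      paste(names(object@transitionsPerPeptide),
            object@transitionsPerPeptide, sep = "=", collapse = ", "), "\n")
})

#' Cohort specification for the synthetic septic-shock study
#'
#' Per-group sample sizes and log-normal concentration parameters for both
#' histones, a latent inter-histone correlation target, and the plasma
#' total-protein distribution. [sepsisCohortSpec()] builds the default spec
#' from the published group means and 95% confidence intervals of the emulated septic-shock study.
#'
#' @slot groups data.frame with columns `group`, `n`, `h2b_mean`, `h2b_sd`,
#'   `h3_mean`, `h3_sd` (arithmetic mean / SD of the ng/mL distributions).
#' @slot correlationTarget Target Pearson correlation between the two
#'   histone concentrations within each group.
#' @slot plasmaProteinMean Mean plasma total protein, ug/mL.
#' @slot plasmaProteinCV Fractional CV of plasma total protein.
#'
#' @export
setClass("CohortSpec", representation(
  groups = "data.frame",
  correlationTarget = "numeric",
  plasmaProteinMean = "numeric",
  plasmaProteinCV = "numeric"
))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  need <- c("group", "n", "h2b_mean", "h2b_sd", "h3_mean", "h3_sd")
  if (!all(need %in% names(object@groups)))
    msg <- c(msg, paste("groups must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(object@groups$n <= 0)) msg <- c(msg, "group sizes must be > 0")
    if (any(object@groups[, c("h2b_mean", "h2b_sd", "h3_mean", "h3_sd")] <= 0))
      msg <- c(msg, "means and SDs must be > 0")
  }
  if (abs(object@correlationTarget) >= 1)
    msg <- c(msg, "correlationTarget must lie in (-1, 1)")
  if (object@plasmaProteinMean <= 0 || object@plasmaProteinCV < 0)
    msg <- c(msg, "plasma protein parameters out of range")
  if (length(msg)) msg else TRUE
})

#' @param groups,correlationTarget,plasmaProteinMean,plasmaProteinCV See
#'   slot documentation.
#' @return A `CohortSpec` object.
#' @rdname CohortSpec-class
#' @export
CohortSpec <- function(groups, correlationTarget = 0.85,
                       plasmaProteinMean = 70000, plasmaProteinCV = 0.1) {
  new("CohortSpec", groups = groups, correlationTarget = correlationTarget,
      plasmaProteinMean = plasmaProteinMean, plasmaProteinCV = plasmaProteinCV)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups, %d subjects; latent correlation target %.2f\n",
              nrow(object@groups), sum(object@groups$n),
              object@correlationTarget))
  print(object@groups, row.names = FALSE)
})

#' Fitted spike-in standard curve
#'
#' Linear response of the light/heavy area ratio against the spiked light
#' amount (fmol): `ratio = slope * fmol + intercept`.
#'
#' @slot peptide Peptide sequence the curve belongs to.
#' @slot slope Ratio per fmol; must be > 0 for a usable curve.
#' @slot intercept Ratio at 0 fmol (matrix blank level).
#' @slot rSquared Coefficient of determination of the fit.
#' @slot residualSE Residual standard error.
#' @slot rangeFmol Calibrated range, `c(min, max)` fmol.
#' @slot weighting `"none"` or `"1/x"`.
#'
#' @export
setClass("StandardCurve", representation(
  peptide = "character",
  slope = "numeric",
  intercept = "numeric",
  rSquared = "numeric",
  residualSE = "numeric",
  rangeFmol = "numeric",
  weighting = "character"
))

setValidity("StandardCurve", function(object) {
  msg <- character(0)
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(object@rangeFmol) != 2L || object@rangeFmol[1] >= object@rangeFmol[2])
    msg <- c(msg, "rangeFmol must be c(min, max) with min < max")
  if (!object@weighting %in% c("none", "1/x"))
    msg <- c(msg, "weighting must be 'none' or '1/x'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve [%s]: ratio = %.6g * fmol + %.6g (R2 = %.5f, %s weighting)\n",
    object@peptide, object@slope, object@intercept, object@rSquared,
    object@weighting))
  cat(sprintf("  calibrated range: %.4g - %.4g fmol\n",
              object@rangeFmol[1], object@rangeFmol[2]))
})

#' @rdname StandardCurve-class
#' @param object A `StandardCurve`.
#' @export
curveSlope <- function(object) object@slope

#' @rdname StandardCurve-class
#' @export
curveIntercept <- function(object) object@intercept

#' @rdname StandardCurve-class
#' @export
curveRSquared <- function(object) object@rSquared

#' @rdname StandardCurve-class
#' @export
curveRange <- function(object) object@rangeFmol

#' ROC analysis result for one biomarker and contrast
#'
#' @slot histone Biomarker label (e.g. `"H2B"`).
#' @slot contrast `"diagnosis"` (patients vs controls) or `"prognosis"`
#'   (non-survivors vs survivors).
#' @slot auc Area under the empirical ROC curve.
#' @slot se Hanley-McNeil standard error of the AUC.
#' @slot ciLow,ciHigh 95% confidence limits, truncated to `[0, 1]`.
#' @slot pValue Two-sided normal-approximation p against AUC = 0.5.
#' @slot cutoff Optimal concentration cutoff (ng/mL), Youden criterion,
#'   reported as the midpoint between adjacent observed scores.
#' @slot sensitivityPct,specificityPct Percent sensitivity/specificity at
#'   the optimal cutoff.
#' @slot nCases,nControls Group sizes used.
#' @slot coordinates data.frame of the ROC sweep: `cutoff`, `tpr`, `fpr`.
#'
#' @export
setClass("RocResult", representation(
  histone = "character",
  contrast = "character",
  auc = "numeric",
  se = "numeric",
  ciLow = "numeric",
  ciHigh = "numeric",
  pValue = "numeric",
  cutoff = "numeric",
  sensitivityPct = "numeric",
  specificityPct = "numeric",
  nCases = "integer",
  nControls = "integer",
  coordinates = "data.frame"
))

setValidity("RocResult", function(object) {
  msg <- character(0)
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0, 1]")
  if (!is.na(object@ciLow) &&
      (object@auc < object@ciLow - 1e-9 || object@auc > object@ciHigh + 1e-9))
    msg <- c(msg, "auc must lie within its confidence interval")
  if (object@sensitivityPct < 0 || object@sensitivityPct > 100 ||
      object@specificityPct < 0 || object@specificityPct > 100)
    msg <- c(msg, "sensitivity/specificity must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult [%s, %s]: AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f, p %.3g)\n",
              object@histone, object@contrast, object@auc, object@se,
              object@ciLow, object@ciHigh, object@pValue))
  cat(sprintf("  optimal cutoff %.2f ng/mL: sensitivity %.1f%%, specificity %.1f%% (%d cases / %d controls)\n",
              object@cutoff, object@sensitivityPct, object@specificityPct,
              object@nCases, object@nControls))
})

#' @rdname RocResult-class
#' @param object A `RocResult`.
#' @export
rocAUC <- function(object) object@auc

#' @rdname RocResult-class
#' @export
rocCutoff <- function(object) object@cutoff

#' @rdname RocResult-class
#' @export
rocCoordinates <- function(object) object@coordinates

#' Flatten a RocResult to a one-row data.frame
#'
#' Mirrors the layout of a published ROC summary table: AUC, SE, 95% CI,
#' p value, optimal cutoff (ng/mL), sensitivity and specificity (%).
#'
#' @param object A `RocResult`.
#' @return One-row data.frame.
#' @export
rocAsRow <- function(object) {
  data.frame(
    histone = object@histone, contrast = object@contrast,
    auc = object@auc, se = object@se,
    ci_low = object@ciLow, ci_high = object@ciHigh, p_value = object@pValue,
    cutoff_ng_per_ml = object@cutoff,
    sensitivity_pct = object@sensitivityPct,
    specificity_pct = object@specificityPct,
    n_cases = object@nCases, n_controls = object@nControls,
    stringsAsFactors = FALSE
  )
}
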