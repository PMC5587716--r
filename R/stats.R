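#' Group mean with t-based confidence interval
#'
#' @param values Numeric vector, n >= 2 (n = 1 reports the mean with NA
#'   limits).
#' @param level Confidence level, default 0.95.
#' @param group Optional group label carried into the result.
#'
#' @return data.frame with `group`, `n`, `mean`, `sd`, `ci_low`, `ci_high`.
#'
#' @examples
#' meanCI(c(1, 2, 3))
#' @export
meanCI <- function(values, level = 0.95, group = NA_character_) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("at least 2 finite values are required for a CI")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  data.frame(group = group, n = n, mean = m, sd = s,
             ci_low = m - half, ci_high = m + half,
             stringsAsFactors = FALSE)
}

#' Two-sample Student's t test
#'
#' Pooled-variance Student's t by default (Welch available via
#' `varEqual = FALSE`), two-sided. Two degenerate constant groups with
#' equal means return t = 0, p = 1 by convention.
#'
#' @param groupA,groupB Numeric vectors, each n >= 2.
#' @param varEqual Pooled variance (default TRUE) or Welch.
#'
#' @return A list: `t`, `df`, `p`.
#' @export
studentsTTest <- function(groupA, groupB, varEqual = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf,
                df = length(groupA) + length(groupB) - 2, p = 0))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = varEqual)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length n >= 3 with nonzero variance.
#' @return A list: `r`, `p` (two-sided, t-based), `n`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct threshold (midpoints between adjacent observed
#' scores, plus -Inf/+Inf end points; a sample is called positive when its
#' score >= threshold). The AUC is computed by the Mann-Whitney identity:
#' the fraction of case/control pairs with case > control, ties counted
#' one half.
#'
#' @param caseScores,controlScores Numeric scores; higher = more
#'   case-like.
#'
#' @return A list: `coordinates` (data.frame `cutoff`, `tpr`, `fpr`,
#'   sorted from (0,0) to (1,1)) and `auc`.
#'
#' @examples
#' rocCurve(c(10, 20, 30), c(1, 2, 3))$auc  # 1
#' @export
rocCurve <- function(caseScores, controlScores) {
  if (length(caseScores) == 0L || length(controlScores) == 0L)
    stop("both groups must be non-empty")
  all <- sort(unique(c(caseScores, controlScores)))
  cutoffs <- c(Inf, rev(if (length(all) > 1)
    (utils::head(all, -1) + utils::tail(all, -1)) / 2 else numeric(0)),
    -Inf)
  tpr <- vapply(cutoffs, function(t) mean(caseScores >= t), numeric(1))
  fpr <- vapply(cutoffs, function(t) mean(controlScores >= t), numeric(1))
  auc <- mean(outer(caseScores, controlScores,
                    function(a, b) (a > b) + 0.5 * (a == b)))
  list(coordinates = data.frame(cutoff = cutoffs, tpr = tpr, fpr = fpr),
       auc = auc)
}

#' Hanley-McNeil standard error of an AUC
#'
#' @param auc AUC estimate in (0, 1); 0 or 1 returns SE 0 (degenerate CI).
#' @param nCases,nControls Group sizes.
#' @return Standard error of the AUC.
#' @export
aucSE <- function(auc, nCases, nControls) {
  if (nCases < 1L || nControls < 1L) stop("group sizes must be >= 1")
  if (auc <= 0 || auc >= 1) return(0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (nCases - 1) * (q1 - auc^2) +
          (nControls - 1) * (q2 - auc^2)) / (nCases * nControls)
  sqrt(v)
}

#' Optimal ROC cutoff by the Youden index
#'
#' Maximises J = sensitivity + specificity - 1 over the ROC coordinates;
#' ties are broken toward higher specificity (and then the higher cutoff).
#' Because [rocCurve()] places thresholds at midpoints between adjacent
#' observed scores, the reported cutoff is a midpoint concentration.
#'
#' @param coordinates Coordinate data.frame from [rocCurve()].
#' @return A list: `cutoff`, `sensitivityPct`, `specificityPct`, `j`.
#'
#' @examples
#' optimalCutoff(rocCurve(c(10, 20, 30), c(1, 2, 3))$coordinates)
#' @export
optimalCutoff <- function(coordinates) {
  if (!any(is.finite(coordinates$cutoff)))
    stop("degenerate ROC: all scores identical, no finite threshold")
  # the sweep endpoints (call none / call all positive, J = 0) are legitimate
  # maxima for a worse-than-chance marker; an infinite cutoff then signals
  # that no useful threshold exists
  co <- coordinates
  j <- co$tpr - co$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) {                      # higher specificity = lower fpr
    best <- best[co$fpr[best] == min(co$fpr[best])]
    best <- best[which.max(co$cutoff[best])]
  }
  list(cutoff = co$cutoff[best],
       sensitivityPct = 100 * co$tpr[best],
       specificityPct = 100 * (1 - co$fpr[best]),
       j = j[best])
}

#' Evaluate a histone biomarker by ROC analysis
#'
#' Diagnosis contrasts all patients (survivors + non-survivors) against
#' healthy controls; prognosis contrasts non-survivors against survivors
#' within the patients. Produces the full [RocResult-class]: empirical
#' AUC, Hanley-McNeil SE, 95% CI (truncated to [0, 1]), normal-theory p
#' against AUC = 0.5, and the Youden-optimal cutoff with its sensitivity
#' and specificity.
#'
#' @param values Numeric concentrations (ng/mL).
#' @param groups Character vector of group labels (`control`, `survivor`,
#'   `non_survivor`), parallel to `values`.
#' @param contrast `"diagnosis"` or `"prognosis"`.
#' @param histone Biomarker label stored in the result.
#'
#' @return A [RocResult-class] object.
#' @export
evaluateBiomarker <- function(values, groups,
                              contrast = c("diagnosis", "prognosis"),
                              histone = NA_character_) {
  contrast <- match.arg(contrast)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  if (contrast == "diagnosis") {
    caseIdx <- groups %in% c("survivor", "non_survivor")
    ctrlIdx <- groups == "control"
  } else {
    caseIdx <- groups == "non_survivor"
    ctrlIdx <- groups == "survivor"
  }
  if (!any(caseIdx) || !any(ctrlIdx))
    stop(sprintf("empty group for contrast '%s'", contrast))
  cases <- values[caseIdx]; controls <- values[ctrlIdx]
  roc <- rocCurve(cases, controls)
  se <- aucSE(roc$auc, length(cases), length(controls))
  ci <- if (se > 0) roc$auc + c(-1, 1) * stats::qnorm(0.975) * se
        else c(roc$auc, roc$auc)
  ci <- pmin(pmax(ci, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(roc$auc - 0.5) / se) else 0
  opt <- optimalCutoff(roc$coordinates)
  new("RocResult",
      histone = histone, contrast = contrast,
      auc = roc$auc, se = se, ciLow = ci[1], ciHigh = ci[2], pValue = p,
      cutoff = opt$cutoff,
      sensitivityPct = opt$sensitivityPct,
      specificityPct = opt$specificityPct,
      nCases = length(cases), nControls = length(controls),
      coordinates = roc$coordinates)
}
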