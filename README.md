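# histoneMRM

Absolute quantification of circulating histones H2B and H3 in plasma by
targeted mass spectrometry, with ROC-based biomarker evaluation.

Circulating histones are released into the bloodstream during NETosis and
cell death and are cytotoxic drivers of septic-shock pathology, which makes
their plasma concentration a candidate biomarker for sepsis diagnosis and
early outcome prediction. `histoneMRM` implements a multiple-reaction-
monitoring (MRM) workflow that quantifies histones H2B and H3 absolutely
using stable-isotope-labelled (SIL) spike-in peptides, and evaluates the
resulting concentrations as diagnostic and prognostic biomarkers. It is
aimed at targeted-proteomics and clinical-biomarker researchers who want a
reproducible, vendor-neutral implementation of this assay design and its
statistics.

## The method

**Assay design.** Each histone is represented by one quantotypic tryptic
peptide: `LLLPGELAK` (H2B) and `STELLIR` (H3). The package digests the
target chains in silico (trypsin: cleavage after K/R, suppressed before P),
filters for proteotypic candidates (fully tryptic, length 6–25, no Met/Cys,
unique among the targets), and computes light and heavy precursor and b/y
fragment m/z. Spike-in standards carry a C-terminal heavy residue
(Arg +10.008 Da from ¹³C₆¹⁵N₄; Lys +8.014 Da from ¹³C₆¹⁵N₂), so heavy y
ions shift while b ions stay at light m/z.

**Quantification.** For each sample the per-transition light/heavy (L/H)
peak-area ratios are averaged into a peptide-level ratio *R*. A spike-in
standard curve *R = a·x + b* (x in fmol, fitted by OLS with free intercept,
optional 1/x weighting) converts ratios into molar amounts, and amounts into
mass concentrations via

    ng/mL = (fmol / µg protein digested) × Mr(Da) × 10⁻⁶ × total plasma protein (µg/mL)

with Mr the average intact-chain mass (13,906 Da for H2B, 15,404 Da for
H3). Defaults follow the assay design: 300 fmol heavy spike per 1 µg of
digested plasma protein, 12 transitions for `LLLPGELAK`, 9 for `STELLIR`.

**Biomarker statistics.** Group summaries (mean, SD, t-based 95% CI),
pooled-variance Student's *t* comparisons, Pearson correlation between the
two histones, and empirical ROC analysis: AUC by the Mann–Whitney
pair-count identity, Hanley–McNeil standard errors and 95% CIs, and
Youden-index optimal cutoffs (reported as midpoints between adjacent
observed concentrations). *Diagnosis* contrasts all patients against
healthy controls; *prognosis* contrasts non-survivors against survivors.

**Synthetic cohort.** Because no patient-level measurements are publicly
available, the package ships a generator that emulates the study design:
10 controls, 9 survivors, 8 non-survivors, per-group log-normal
concentrations parameterised by the published group means and 95% CIs, a
latent Gaussian factor calibrated to the published inter-histone
correlation (~0.85), and multiplicative log-normal noise on peak areas.

## Worked example

```r
library(histoneMRM)

## assay design: paired light/heavy transitions for the histone peptides
tl <- designTransitions(histoneTargets())
head(tl[tl$peptide == "STELLIR",
        c("protein", "peptide", "label_state", "precursor_mz", "fragment",
          "product_mz")], 4)
#>  protein peptide label_state precursor_mz fragment product_mz
#>       H3 STELLIR       light     416.2504       y6   744.4614
#>       H3 STELLIR       light     416.2504       y5   643.4137
#>       H3 STELLIR       light     416.2504       y4   514.3711
#>       H3 STELLIR       light     416.2504       y3   401.2871

## simulate a study-sized cohort and a calibration series (10% area CV)
cfg <- AssayConfig(areaCV = 0.1)
sim <- simulateCohort(sepsisCohortSpec(), cfg, seed = 42)
curves <- fitCalibrationCurves(simulateCalibrationSeries(config = cfg, seed = 43))
curves[["STELLIR"]]
#> StandardCurve [STELLIR]: ratio = 0.00332583 * fmol + -0.000331019 (R2 = 0.99823, none weighting)
#>   calibrated range: 0.1 - 40 fmol

## quantify: mean L/H ratio -> fmol -> ng/mL plasma
q <- quantifySamples(sim$areas, curves, sim$metadata, cfg)
head(q[, c("sample_id", "histone", "mean_ratio", "ng_per_ml", "flags")], 2)
#>   sample_id histone mean_ratio ng_per_ml flags
#>  control_01     H2B  0.0044456    1257.3
#>  control_01      H3  0.0019309     707.7

## biomarker evaluation
ev <- evaluateCohort(q)
ev$roc_results[, c("histone", "contrast", "auc", "se", "cutoff_ng_per_ml",
                   "sensitivity_pct", "specificity_pct")]
#>  histone  contrast    auc      se cutoff_ng_per_ml sensitivity_pct specificity_pct
#>      H2B diagnosis 0.7294 0.09759           1429.1           64.71              90
#>      H2B prognosis 0.9028 0.08125           3101.9           87.50             100
#>       H3 diagnosis 0.9765 0.02803            733.4           88.24             100
#>       H3 prognosis 0.9722 0.04388           7431.5           87.50             100
```

The fitted slope (0.00333 ≈ 1/300) is the reciprocal of the 300-fmol heavy
spike, as expected when light and heavy species respond equally. At
study-cohort size the H3 diagnostic AUC exceeds the H2B AUC in essentially
every simulated replicate, and non-survivors run roughly ten-fold above
survivors — the effect directions the assay was designed to detect.

The same pipeline is scriptable from a shell via
`inst/scripts/mrm-histones.R` with subcommands `design`, `simulate`,
`quantify` and `evaluate`.

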