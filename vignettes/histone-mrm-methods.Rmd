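---
title: "Quantifying circulating histones by spike-in MRM: models and design choices"
author: "histoneMRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circulating histones by spike-in MRM: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneMRM)
```

## The measurement model

Multiple reaction monitoring (MRM) quantifies a peptide by monitoring fixed
precursor→fragment m/z pairs (transitions) on a triple quadrupole. Absolute
quantification works by spiking a known amount of a stable-isotope-labelled
(SIL) analogue of the analyte peptide into every digest: the SIL peptide
co-elutes and co-fragments with the endogenous ("light") peptide, so the
light/heavy (L/H) peak-area ratio is a relative abundance readout that is
robust to injection and ionisation variability.

The chain from raw areas to a plasma concentration is:

1. per transition, ratio $r_i = A^{light}_i / A^{heavy}_i$;
2. per peptide, the unweighted arithmetic mean $R = \frac{1}{k}\sum r_i$
   over the $k$ usable transitions, with a CV flag;
3. a standard curve $R = a\,x + b$ ($x$ = spiked light amount, fmol) fitted
   on a calibration series in plasma matrix, inverted to
   $\hat x = (R - b)/a$;
4. unit conversion
   $\mathrm{ng/mL} = \dfrac{\hat x}{m_{prot}} \cdot M_r \cdot 10^{-6}
   \cdot c_{plasma}$,
   where $m_{prot}$ is the digested protein load (µg), $M_r$ the average
   intact-chain mass (Da) and $c_{plasma}$ the sample's total plasma
   protein (µg/mL); $10^{-6}$ converts fmol·(g/mol) to ng.

The model assumes equal detector response for light and heavy species (the
only difference being the isotope label), linear response over the
calibrated range, and that the quantotypic peptide is released
stoichiometrically by trypsin from its parent histone.

### Mass arithmetic

All m/z values use monoisotopic residue masses derived internally from
elemental compositions (C/H/N/O/S counts times isotope masses), a proton
mass of 1.007276 Da, and the standard b/y conventions: b ions are
N-terminal residue sums plus proton(s); y ions add one water. The SIL label
sits on the C-terminal Lys/Arg, so heavy precursors and y ions shift by the
label delta (computed from $6(m_{^{13}C}-m_{^{12}C})$ plus
$4$ or $2\,(m_{^{15}N}-m_{^{14}N})$: +10.008 Da for Arg, +8.014 Da for
Lys) while b ions are label-blind — a structural invariant the tests
exercise. Average (isotope-abundance-weighted) masses are used only for the
intact-chain $M_r$ entering the unit conversion, because a protein
quantified in mass units is a population across its isotopologues. The
bundled canonical chains — H2B type 1 (126 aa) and H3.1 (136 aa), initiator
Met included — have average masses that round to 13,906 and 15,404 Da; H2B
type 1 family members share this mass, so the choice of family member does
not affect quantification.

### Digestion and peptide selection

Trypsin is modelled by the classic Keil rule — cleavage after K or R except
before P — which is the reproducible textbook convention. Peptide
coordinates are 1-based inclusive. Proteotypic selection keeps fully
tryptic, zero-missed-cleavage peptides of length 6–25 without Met or Cys
(oxidation and alkylation variability make those residues poor
quantification anchors) that are unique among the supplied targets.
Uniqueness is deliberately checked only within the target set, not against
the whole proteome: the package designs assays for the proteins it is
given, and `LLLPGELAK`/`STELLIR` are established quantotypic peptides for
H2B/H3. Transition lists rank y ions before b ions, by descending fragment
index — y ions dominate CID spectra of tryptic peptides and longer
fragments are more specific; the assay defaults monitor 12 transitions for
`LLLPGELAK` and 9 for `STELLIR`, per label state, at precursor charge 2+
and fragment charge 1+ (2+ is the typical charge state for tryptic peptides
of this length; the monitored charge states are a design default, not a
measured property).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `spikeAmountFmol` | 300 | fmol | heavy spike per digest |
| `proteinLoadUg` | 1 | µg | digested plasma protein per injection |
| `transitionsPerPeptide` | 12 / 9 | — | `LLLPGELAK` / `STELLIR` |
| `areaCV` | 0.1 | fraction | multiplicative area noise in simulation |
| `cvFlagThreshold` | 0.2 | fraction | flags unstable transition ratios |
| `weighting` | `"none"` | — | standard-curve weighting (`"1/x"` optional) |

The true simulated response slope is `1/spikeAmountFmol` (ratio per fmol):
if light and heavy respond equally, $R = x/300$ at a 300-fmol spike. The
calibration series defaults to 7 levels (0.1–40 fmol) × 3 replicates,
spanning the fmol range the cohort concentrations imply at physiological
plasma protein (~70 mg/mL).

### Standard-curve choices

The curve is ordinary least squares with a *free intercept*: plasma is a
complex matrix and blanks can show a nonzero apparent ratio, so forcing the
origin would fold matrix background into the slope. `1/x` weighting is
exposed because unweighted OLS lets the highest calibration levels dominate
the intercept estimate, which matters for samples near or below the lowest
level (zero-fmol blanks are excluded from a weighted fit, where their
weight is undefined). Ratios outside the calibrated range are interpolated
anyway and *flagged* (`below_range`/`above_range`) rather than censored, so
cohort statistics stay computable; transitions with non-positive heavy area
are excluded and counted rather than failing the run.

## What the synthetic cohort emulates

`sepsisCohortSpec()` encodes the study conditions: groups of 10 healthy
controls, 9 surviving and 8 non-surviving septic-shock patients; per-group
arithmetic means of 720.15 / 1,351.65 / 10,106.89 ng/mL (H2B) and 179.77 /
2,094.31 / 19,988.56 ng/mL (H3); SDs back-solved from the published
t-based 95% CIs at the published n (half-width $= t_{0.975,n-1}\,s/\sqrt n$).
Concentrations are log-normal within groups — strictly positive,
right-skewed, consistent with CIs that are wide relative to the means — and
the two histones share a latent Gaussian factor whose correlation is
calibrated analytically so the *observed* Pearson correlation of the
log-normal pair hits the 0.85 target (between the published subgroup values
0.856 and 0.824). An unattainable target at the given dispersions is
rejected with an explanation. Pooling groups with different means inflates
the observed r above the within-group target; the reported patient-group
correlation therefore reflects both the latent factor and the
survivor/non-survivor separation, as it would in real data. Plasma total
protein is log-normal around 70,000 µg/mL (CV 0.1), a physiological
default, since per-sample values are not published.

Peak-area noise is multiplicative log-normal with mean exactly 1 and CV
`areaCV`, independent across transitions and channels; heavy areas scatter
around `heavyBaseArea`, light areas around `expected ratio × heavy`. The
zero-noise limit reproduces expected ratios exactly, which gives the
pipeline its sharpest correctness check: simulate with `areaCV = 0`,
quantify, and recover the generating truth to relative 1e-6 (in practice
~1e-14).

What the generator does **not** emulate: chromatographic interferences,
retention-time drift, detector saturation, between-day batch effects,
clinical covariates, or any deviation from log-normality. Passing tests
therefore certify the *arithmetic and statistical machinery*, not the
assay's real-world selectivity or matrix behaviour.

## Statistical evaluation

Group summaries use t-based 95% CIs (the reporting convention the group
parameters were back-solved from). Group comparison is a two-sided
pooled-variance Student's *t* (Welch exposed as an option); two degenerate
constant groups with equal means return $t=0, p=1$ by convention. The ROC
curve is empirical: thresholds are midpoints between adjacent distinct
observed concentrations plus the two sweep endpoints, a sample is called
positive at score ≥ threshold, and the AUC is the Mann–Whitney pair-count
(ties 0.5) — the tests verify the identity exhaustively against brute-force
enumeration. The AUC standard error is Hanley–McNeil (documented so users
can compare with software using DeLong or other estimators), the 95% CI is
the normal approximation truncated to [0, 1], and the p-value tests
AUC = 0.5. The optimal cutoff maximises the Youden index; ties break toward
higher specificity and then the higher cutoff (a conservative diagnostic
convention: fewer false positives), and the reported cutoff is a midpoint
concentration, so it never coincides with an observed sample. For a
worse-than-chance marker the sweep endpoints (J = 0) can win, in which case
the cutoff is reported as infinite — a signal that no useful threshold
exists — and an all-tied marker is rejected as degenerate. No
multiple-testing correction is applied, matching the evaluation design this
package reproduces.

## Problem sizes and numerical tolerances

The test suite runs the noiseless round trip on the full 27-sample cohort
(relative tolerance 1e-6), the unbiasedness check at 10% area CV over 200
replicates (the Monte-Carlo SE is computed over replicate means because
samples within a replicate share one fitted curve), direction checks over
200 study-sized replicates, the AUC/pair-count identity over 500 random
small instances, and mass-oracle agreement to 1e-6 Da on 100 random
peptides against an independently coded elemental-composition oracle.
Large-n calibration checks of the generator use 10,000 draws per group. The
acceptance script reports group means at 5,000 draws per group and mean
diagnostic AUCs over 200 replicates.

## Known limitations

- Quantification is single-peptide per histone; a multi-peptide design
  (with agreement diagnostics) is out of scope.
- No LOD/LOQ estimation, carry-over correction, or retention-time
  alignment; peak areas are taken as given (or simulated).
- Published cohort-level results (AUCs, cutoffs, group means) are
  distributional inputs to the simulator, not reproducible targets:
  patient-level data were never published, so study-sized replicates
  scatter around — and can only be compared in distribution with — the
  published values.
- The Hanley–McNeil SE differs from whatever estimator produced any
  particular published table; exact SE agreement is not expected.
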