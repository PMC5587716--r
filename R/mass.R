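#' Neutral peptide mass
#'
#' Sum of residue masses plus one water. Monoisotopic masses feed all m/z
#' arithmetic; average masses are appropriate for intact-chain Mr.
#'
#' @param sequence Character vector of one-letter amino-acid sequences
#'   (20 standard residues). The empty string returns the mass of water.
#' @param kind `"monoisotopic"` (default) or `"average"`.
#'
#' @return Numeric vector of neutral masses in Da.
#'
#' @examples
#' peptideMass("STELLIR")
#' peptideMass("LLLPGELAK")
#' peptideMass("STELLIR", kind = "average")
#' @export
peptideMass <- function(sequence, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  table <- if (kind == "monoisotopic") .AA_MONO else .AA_AVG
  water <- if (kind == "monoisotopic") .WATER_MONO else .WATER_AVG
  vapply(as.character(sequence), function(s) {
    .checkSequence(s, allow_empty = TRUE)
    if (!nzchar(s)) return(water)
    sum(table[strsplit(s, "")[[1L]]]) + water
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Average molecular mass of an intact protein chain
#'
#' Isotope-abundance-weighted (average) mass of the full amino-acid chain,
#' the Mr used to convert molar histone amounts to mass concentrations.
#' Rounding to the nearest Da is left to reporting code.
#'
#' @param x An [Biostrings::AAStringSet], [Biostrings::AAString], or character
#'   vector of sequences.
#'
#' @return Numeric vector of average masses in Da, named after `x` when it
#'   carries names.
#'
#' @examples
#' proteinAverageMass(histoneTargets())
#' @export
proteinAverageMass <- function(x) {
  if (methods::is(x, "AAStringSet") || methods::is(x, "AAString"))
    x <- as.character(x)
  out <- peptideMass(unname(x), kind = "average")
  names(out) <- names(x)
  out
}

#' Heavy-isotope label mass shift for spike-in peptides
#'
#' The spike-in internal standards carry a C-terminal heavy residue:
#' Arg with 13C6,15N4 or Lys with 13C6,15N2. The shift is computed from
#' isotope masses (6 x (13C - 12C), plus 4 or 2 x (15N - 14N)), not
#' hard-coded.
#'
#' @param residue `"K"` or `"R"`.
#'
#' @return A list with elements `residue`, `massShiftDa` (monoisotopic delta
#'   in Da) and `name` (isotope label, e.g. `"13C6,15N4"`).
#'
#' @examples
#' heavyMassShift("R")$massShiftDa  # ~10.008
#' heavyMassShift("K")$massShiftDa  # ~8.014
#' @export
heavyMassShift <- function(residue) {
  if (length(residue) != 1L || !residue %in% c("K", "R"))
    stop("heavy labelling is defined only for C-terminal K or R")
  nN <- if (residue == "R") 4L else 2L
  shift <- 6 * (.C13_DA - .ELEMENT_MONO[["C"]]) +
    nN * (.N15_DA - .ELEMENT_MONO[["N"]])
  list(
    residue = residue,
    massShiftDa = shift,
    name = sprintf("13C6,15N%d", nN)
  )
}

.labelShiftForPeptide <- function(sequence) {
  last <- substr(sequence, nchar(sequence), nchar(sequence))
  if (!last %in% c("K", "R"))
    stop(sprintf(
      "heavy label requested for peptide '%s' not ending in K or R", sequence))
  heavyMassShift(last)$massShiftDa
}

#' Precursor m/z of a light or heavy peptide
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param charge Positive integer precursor charge.
#' @param labelState `"light"` or `"heavy"`; heavy adds the C-terminal
#'   K/R isotope label mass.
#'
#' @return Precursor m/z in Th.
#'
#' @examples
#' precursorMz("STELLIR", 2)            # 416.25
#' precursorMz("STELLIR", 2, "heavy")   # +5.004
#' @export
precursorMz <- function(sequence, charge, labelState = c("light", "heavy")) {
  labelState <- match.arg(labelState)
  .checkSequence(sequence)
  if (length(charge) != 1L || charge < 1 || charge != round(charge))
    stop("'charge' must be a positive integer")
  mass <- peptideMass(sequence)
  if (labelState == "heavy") mass <- mass + .labelShiftForPeptide(sequence)
  (mass + charge * .PROTON_DA) / charge
}

#' Fragment-ion m/z (b and y series)
#'
#' b ions are N-terminal prefixes (residue sum plus proton(s)); y ions are
#' C-terminal suffixes (residue sum plus water plus proton(s)). Because the
#' isotope label sits on the C-terminal residue, heavy peptides shift their
#' y ions but leave b ions at the light m/z.
#'
#' @param sequence Peptide sequence.
#' @param type `"b"` or `"y"`.
#' @param index Fragment index, 1 to `nchar(sequence) - 1`.
#' @param charge Positive integer fragment charge.
#' @param labelState `"light"` or `"heavy"`.
#'
#' @return Fragment m/z in Th.
#'
#' @examples
#' fragmentMz("STELLIR", "y", 1, 1)             # y1 = R immonium-series 175.119
#' fragmentMz("STELLIR", "y", 1, 1, "heavy")    # +10.008
#' fragmentMz("STELLIR", "b", 2, 1, "heavy")    # identical to light b2
#' @export
fragmentMz <- function(sequence, type = c("b", "y"), index, charge = 1L,
                       labelState = c("light", "heavy")) {
  type <- match.arg(type)
  labelState <- match.arg(labelState)
  .checkSequence(sequence)
  n <- nchar(sequence)
  if (length(index) != 1L || index < 1L || index > n - 1L)
    stop(sprintf("fragment index %s out of range 1..%d for '%s'",
                 format(index), n - 1L, sequence))
  if (length(charge) != 1L || charge < 1 || charge != round(charge))
    stop("'charge' must be a positive integer")
  chars <- strsplit(sequence, "")[[1L]]
  neutral <- if (type == "b") {
    sum(.AA_MONO[chars[seq_len(index)]])
  } else {
    sum(.AA_MONO[chars[seq.int(n - index + 1L, n)]]) + .WATER_MONO
  }
  if (labelState == "heavy" && type == "y")
    neutral <- neutral + .labelShiftForPeptide(sequence)
  (neutral + charge * .PROTON_DA) / charge
}
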