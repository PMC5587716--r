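# Physical constants and residue mass tables.
#
# Monoisotopic residue masses are used for all m/z arithmetic (precursors,
# fragments, label shifts); average (isotope-abundance-weighted) masses are
# used only for intact-protein Mr, which is what converts molar amounts into
# mass concentrations.

# mass of a proton (Da); charge carrier for positive-mode m/z
.PROTON_DA <- 1.007276466879

# element monoisotopic masses (Da)
.ELEMENT_MONO <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# heavy-isotope masses used for the spike-in label deltas
.C13_DA <- 13.0033548378
.N15_DA <- 15.0001088982

# residue elemental compositions (amino acid minus water): C, H, N, O, S
.AA_FORMULA <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

# monoisotopic residue masses, Da, from the elemental compositions
.AA_MONO <- drop(.AA_FORMULA %*% .ELEMENT_MONO[c("C", "H", "N", "O", "S")])

# average residue masses, Da (IUPAC atomic weights)
.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 2 * .ELEMENT_MONO[["H"]] + .ELEMENT_MONO[["O"]]
.WATER_AVG <- 18.01528

.AA_ALPHABET <- names(.AA_MONO)

# validate a one-letter amino-acid sequence; error names the first bad position
.checkSequence <- function(sequence, allow_empty = FALSE) {
  if (length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single non-NA character string")
  if (!nzchar(sequence)) {
    if (allow_empty) return(invisible(sequence))
    stop("'sequence' must be non-empty")
  }
  chars <- strsplit(sequence, "")[[1L]]
  bad <- which(!chars %in% .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1L]], bad[1L]))
  invisible(sequence)
}
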