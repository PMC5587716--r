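# Independent oracles, coded from atomic compositions rather than residue
# mass tables, so they share no data with the implementation under test.

# atoms per residue (amino acid minus water): C, H, N, O, S
.oracle_formulas <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
.oracle_mono <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069)

# monoisotopic peptide mass from elemental composition
oracle_peptide_mass <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  atoms <- Reduce(`+`, .oracle_formulas[chars]) + c(0, 2, 0, 1, 0)  # + H2O
  sum(atoms * .oracle_mono)
}

random_peptide <- function(min_len = 4, max_len = 25) {
  n <- sample(min_len:max_len, 1)
  paste(sample(names(.oracle_formulas), n, replace = TRUE), collapse = "")
}

# AUC by explicit pair enumeration (ties count one half)
oracle_auc <- function(cases, controls) {
  total <- 0
  for (a in cases) for (b in controls) {
    if (a > b) total <- total + 1
    else if (a == b) total <- total + 0.5
  }
  total / (length(cases) * length(controls))
}

# exhaustive Youden scan over every candidate threshold (all scores +/- eps)
oracle_best_youden <- function(cases, controls) {
  grid <- sort(unique(c(cases, controls)))
  cand <- sort(unique(c(grid - 1e-9, grid, grid + 1e-9)))
  max(vapply(cand, function(t)
    mean(cases >= t) + mean(controls < t) - 1, numeric(1)))
}
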