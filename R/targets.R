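# Canonical target chains. H2B type 1 (126 aa) and H3.1 (136 aa), initiator
# Met included: their average masses round to the Mr values used for the
# fmol -> ng/mL conversion (13,906 and 15,404 Da).
.H2B_SEQ <- paste0(
  "MPEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSVYVYKVLKQVHPDTGISSKAMGIMNSFVNDIF",
  "ERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYTSSK")
.H3_SEQ <- paste0(
  "MARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQRL",
  "VREIAQDFKTDLRFQSSAVMALQEACEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA")

# quantotypic peptide per histone and its transition count in the assay
.HISTONE_PEPTIDES <- c(H2B = "LLLPGELAK", H3 = "STELLIR")
.DEFAULT_TRANSITIONS <- c(LLLPGELAK = 12L, STELLIR = 9L)

#' Canonical histone H2B and H3 target sequences
#'
#' Full-length canonical human histone H2B type 1 (126 residues) and H3.1
#' (136 residues) chains, the recombinant standards the assay quantifies.
#'
#' @return A named [Biostrings::AAStringSet] with records `H2B` and `H3`.
#'
#' @examples
#' round(proteinAverageMass(histoneTargets()))
#' @export
histoneTargets <- function() {
  Biostrings::AAStringSet(c(H2B = .H2B_SEQ, H3 = .H3_SEQ))
}

#' Map a quantotypic peptide to its histone and Mr
#'
#' @param peptide Character vector of peptide sequences.
#' @return data.frame with `peptide`, `histone` and `mr_da` (average mass of
#'   the intact chain); unknown peptides get NA.
#' @export
histoneForPeptide <- function(peptide) {
  mr <- proteinAverageMass(histoneTargets())
  idx <- match(peptide, .HISTONE_PEPTIDES)
  data.frame(
    peptide = peptide,
    histone = names(.HISTONE_PEPTIDES)[idx],
    mr_da = unname(mr[names(.HISTONE_PEPTIDES)[idx]]),
    stringsAsFactors = FALSE
  )
}

#' Read target proteins from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that validates the
#' alphabet record by record so malformed input is reported by name.
#'
#' @param path Path to a (multi-record) amino-acid FASTA file.
#' @return Named [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {                     # ignored codes = malformed input
      stop(sprintf("malformed FASTA file %s: %s", path, conditionMessage(w)))
    })
  if (length(set) == 0L) stop(sprintf("no records in FASTA file: %s", path))
  # keep only the accession token of each header
  names(set) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    ok <- tryCatch({ .checkSequence(seqs[[i]]); TRUE }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("malformed FASTA record '%s': %s",
                   names(set)[i], conditionMessage(ok)))
  }
  set
}
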