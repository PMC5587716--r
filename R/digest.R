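#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (Keil rule).
#' Returns every peptide with at most `maxMissedCleavages` internal missed
#' cleavage sites; the zero-missed-cleavage peptides tile the input exactly.
#'
#' @param sequence Protein sequence (one-letter codes), or an
#'   [Biostrings::AAString].
#' @param maxMissedCleavages Non-negative integer, default 0.
#'
#' @return A data.frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive) and `missed_cleavages`.
#'
#' @examples
#' trypticDigest("AKPR")        # K-P suppresses cleavage: one peptide
#' fa <- histoneTargets()
#' trypticDigest(fa[["H2B"]])   # contains LLLPGELAK
#' @export
trypticDigest <- function(sequence, maxMissedCleavages = 0L) {
  if (methods::is(sequence, "AAString")) sequence <- as.character(sequence)
  .checkSequence(sequence)
  if (length(maxMissedCleavages) != 1L || maxMissedCleavages < 0 ||
      maxMissedCleavages != round(maxMissedCleavages))
    stop("'maxMissedCleavages' must be a non-negative integer")
  chars <- strsplit(sequence, "")[[1L]]
  n <- length(chars)
  # cut points: position i such that cleavage occurs between i and i+1
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n]                       # terminal K/R ends the chain anyway
  cuts <- cuts[chars[cuts + 1L] != "P"]        # proline suppression
  bounds <- c(0L, cuts, n)                     # fragment i spans (bounds[i], bounds[i+1]]
  nfrag <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (mc in 0:min(maxMissedCleavages, nfrag - 1L)) {
    from <- seq_len(nfrag - mc)
    to <- from + mc
    out[[length(out) + 1L]] <- data.frame(
      peptide = vapply(seq_along(from), function(i)
        substr(sequence, bounds[from[i]] + 1L, bounds[to[i] + 1L]), character(1L)),
      start = bounds[from] + 1L,
      end = bounds[to + 1L],
      missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Digest a set of target proteins
#'
#' Convenience wrapper running [trypticDigest()] over every record of an
#' `AAStringSet` (or named character vector), tagging peptides with their
#' parent accession.
#'
#' @param targets Named [Biostrings::AAStringSet] or named character vector.
#' @param maxMissedCleavages Passed to [trypticDigest()].
#'
#' @return A data.frame with the [trypticDigest()] columns plus `accession`.
#' @export
digestTargets <- function(targets, maxMissedCleavages = 0L) {
  if (methods::is(targets, "AAStringSet")) targets <- as.character(targets)
  if (length(targets) == 0L) stop("empty target set")
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("targets must be named by accession")
  do.call(rbind, lapply(names(targets), function(acc) {
    d <- trypticDigest(targets[[acc]], maxMissedCleavages)
    cbind(accession = acc, d, stringsAsFactors = FALSE)
  }))
}

#' Select proteotypic candidate peptides
#'
#' Filters a digest down to MRM-suitable peptides: fully tryptic with zero
#' missed cleavages, length within bounds, free of Met and Cys (oxidation /
#' alkylation variability), and unique to a single target protein among the
#' supplied digests.
#'
#' @param peptides Digest data.frame from [digestTargets()] (must carry an
#'   `accession` column).
#' @param minLength,maxLength Length bounds, defaults 6 and 25.
#'
#' @return The filtered data.frame.
#'
#' @examples
#' selectProteotypic(digestTargets(histoneTargets()))
#' @export
selectProteotypic <- function(peptides, minLength = 6L, maxLength = 25L) {
  if (is.null(peptides) || nrow(peptides) == 0L) stop("empty target set")
  if (!"accession" %in% names(peptides))
    stop("'peptides' must carry an 'accession' column (see digestTargets)")
  keep <- peptides$missed_cleavages == 0L &
    nchar(peptides$peptide) >= minLength &
    nchar(peptides$peptide) <= maxLength &
    !grepl("[MC]", peptides$peptide)
  cand <- peptides[keep, , drop = FALSE]
  # unique among the target digests: a sequence seen under >1 accession is out
  acc_per_seq <- tapply(peptides$accession, peptides$peptide,
                        function(a) length(unique(a)))
  cand <- cand[acc_per_seq[cand$peptide] == 1L, , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
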