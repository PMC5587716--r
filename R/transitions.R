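#' Build a paired light/heavy MRM transition list for one peptide
#'
#' Candidate fragments are ranked y ions first, then b ions, each by
#' descending fragment index (longer fragments carry more sequence
#' information and usually more signal). The top `nTransitions` candidates
#' are emitted twice: once at light m/z and once with the heavy C-terminal
#' label applied (precursor and y ions shift; b ions do not).
#'
#' @param peptide Peptide sequence ending in K or R.
#' @param precursorCharge Precursor charge state, default 2.
#' @param fragmentCharge Fragment charge state, default 1.
#' @param nTransitions Number of transitions per label state.
#' @param protein Optional accession recorded in the output.
#' @param collisionEnergy Optional collision energy (V), metadata only.
#'
#' @return data.frame with columns `protein`, `peptide`, `label_state`,
#'   `precursor_mz`, `precursor_charge`, `fragment`, `fragment_type`,
#'   `fragment_index`, `fragment_charge`, `product_mz`, `collision_energy`.
#'
#' @examples
#' buildTransitionList("STELLIR", nTransitions = 9)
#' @export
buildTransitionList <- function(peptide, precursorCharge = 2L,
                                fragmentCharge = 1L, nTransitions,
                                protein = NA_character_,
                                collisionEnergy = NA_real_) {
  .checkSequence(peptide)
  n <- nchar(peptide)
  if (nTransitions < 0) stop("'nTransitions' must be non-negative")
  if (nTransitions == 0) {
    return(.emptyTransitionFrame())
  }
  idx <- seq.int(n - 1L, 1L)
  candidates <- rbind(
    data.frame(fragment_type = "y", fragment_index = idx),
    data.frame(fragment_type = "b", fragment_index = idx)
  )
  if (nTransitions > nrow(candidates))
    stop(sprintf("requested %d transitions but only %d b/y fragments exist",
                 nTransitions, nrow(candidates)))
  candidates <- candidates[seq_len(nTransitions), , drop = FALSE]
  rows <- lapply(c("light", "heavy"), function(state) {
    pre <- precursorMz(peptide, precursorCharge, state)
    data.frame(
      protein = protein,
      peptide = peptide,
      label_state = state,
      precursor_mz = pre,
      precursor_charge = precursorCharge,
      fragment = paste0(candidates$fragment_type, candidates$fragment_index),
      fragment_type = candidates$fragment_type,
      fragment_index = candidates$fragment_index,
      fragment_charge = fragmentCharge,
      product_mz = mapply(function(ty, ix)
        fragmentMz(peptide, ty, ix, fragmentCharge, state),
        candidates$fragment_type, candidates$fragment_index),
      collision_energy = collisionEnergy,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyTransitionFrame <- function() {
  data.frame(
    protein = character(0), peptide = character(0), label_state = character(0),
    precursor_mz = numeric(0), precursor_charge = integer(0),
    fragment = character(0), fragment_type = character(0),
    fragment_index = integer(0), fragment_charge = integer(0),
    product_mz = numeric(0), collision_energy = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Design transition lists for a set of target proteins
#'
#' Digests the targets, selects proteotypic peptides and builds paired
#' light/heavy transition lists. With the bundled histone targets and
#' default settings this yields the assay's 12 transitions for LLLPGELAK
#' (H2B) and 9 for STELLIR (H3), each in light and heavy form.
#'
#' @param targets Named [Biostrings::AAStringSet] or named character vector.
#' @param nTransitions Named integer vector (names = peptide sequences) or a
#'   single number applied to all peptides; peptides without an entry get
#'   the smaller of 9 and the number of available fragments.
#' @param precursorCharge,fragmentCharge Charge states, defaults 2 and 1.
#'
#' @return Combined transition data.frame (see [buildTransitionList()]).
#' @export
designTransitions <- function(targets, nTransitions = .DEFAULT_TRANSITIONS,
                              precursorCharge = 2L, fragmentCharge = 1L) {
  peptides <- selectProteotypic(digestTargets(targets))
  if (nrow(peptides) == 0L) stop("no proteotypic peptides survive filtering")
  out <- lapply(seq_len(nrow(peptides)), function(i) {
    pep <- peptides$peptide[i]
    nt <- if (!is.null(names(nTransitions)) && pep %in% names(nTransitions)) {
      nTransitions[[pep]]
    } else if (is.null(names(nTransitions)) && length(nTransitions) == 1L) {
      nTransitions
    } else {
      min(9L, 2L * (nchar(pep) - 1L))
    }
    buildTransitionList(pep, precursorCharge, fragmentCharge, nt,
                        protein = peptides$accession[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a vendor-neutral transition list CSV
#'
#' Columns follow a Skyline-importable layout: protein, peptide,
#' label_state, precursor_mz, precursor_charge, fragment, fragment_charge,
#' product_mz, collision_energy. m/z values are written with 4 decimals.
#'
#' @param transitions data.frame from [buildTransitionList()] /
#'   [designTransitions()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the data.frame (reader).
#' @export
writeTransitionList <- function(transitions, path) {
  out <- transitions[, c("protein", "peptide", "label_state", "precursor_mz",
                         "precursor_charge", "fragment", "fragment_charge",
                         "product_mz", "collision_energy")]
  out$precursor_mz <- sprintf("%.4f", out$precursor_mz)
  out$product_mz <- sprintf("%.4f", out$product_mz)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeTransitionList
#' @export
readTransitionList <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
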