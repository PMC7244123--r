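## Projection of reference residue positions into alignment columns, and
## sub-alignment slicing.

#' Map reference residue positions to alignment columns
#'
#' Column `c` is returned for position `p` iff the reference record's p-th
#' non-gap codon sits at protein column `c` of the alignment. Order (and
#' strict monotonicity) of the positions is preserved.
#'
#' @param aln A [CodonAlignment-class].
#' @param positions A [PocketDefinition-class] or an integer vector of 1-based
#'   residue positions in the ungapped reference protein.
#' @return A [ColumnSet-class].
#' @export
mapPositionsToColumns <- function(aln, positions) {
  if (methods::is(positions, "PocketDefinition"))
    positions <- pocketPositions(positions)
  positions <- as.integer(positions)
  ref <- alignmentSeqs(aln)[[referenceId(aln)]]
  cm <- .codonMatrix(ref)[1, ]
  nonGap <- which(cm != "---")
  if (length(positions) && max(positions) > length(nonGap))
    stop(sprintf("position %d beyond reference length %d",
                 max(positions), length(nonGap)))
  ColumnSet(nonGap[positions])
}

#' Restrict a codon alignment to a set of codon columns
#'
#' @param aln A [CodonAlignment-class].
#' @param cols A [ColumnSet-class].
#' @return A [CodonAlignment-class] over the selected codon columns, species
#'   order and reference designation preserved. An empty column set yields
#'   zero-length records over the same species.
#' @export
sliceAlignment <- function(aln, cols) {
  stopifnot(methods::is(cols, "ColumnSet"))
  p <- proteinColumns(cols)
  if (length(p) && max(p) > codonColumns(aln))
    stop("column set exceeds alignment width")
  seqs <- alignmentSeqs(aln)
  if (!length(p)) {
    out <- stats::setNames(rep("", length(seqs)), names(seqs))
  } else {
    cm <- .codonMatrix(seqs)
    out <- apply(cm[, p, drop = FALSE], 1, paste, collapse = "")
  }
  CodonAlignment(out, reference = referenceId(aln))
}

#' Read an aligned coding FASTA as a CodonAlignment
#'
#' @param file Path to an aligned nucleotide FASTA.
#' @param reference Name of the reference record.
#' @return A [CodonAlignment-class]. Frame violations (width not a multiple of
#'   3, mid-codon gaps) are hard errors.
#' @export
readCodonAlignment <- function(file, reference) {
  seqs <- Biostrings::readDNAStringSet(file)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  CodonAlignment(seqs, reference = reference)
}

#' Write a CodonAlignment as FASTA
#' @param aln A [CodonAlignment-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeCodonAlignment <- function(aln, file) {
  Biostrings::writeXStringSet(aln@seqs, file)
  invisible(file)
}
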