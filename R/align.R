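# Pairwise global alignment of an accession sequence to the reference.
# Biostrings does the dynamic programming; this module fixes the scoring
# scheme and returns plain aligned strings for the variant caller.

#' Globally align a query sequence to the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used to
#' extract variants from per-accession gene-region sequences. A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @param ref,query Nucleotide strings over `A,C,G,T,N` (same orientation).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults:
#'   match +1, mismatch -2, gap open -6, gap extend -1 (penalties given as
#'   positive costs).
#' @return A `grf_alignment`: list with aligned `ref` and `query` strings
#'   (with `-` gaps) and the alignment `score`.
#' @export
align_to_reference <- function(ref, query, match = 1, mismatch = -2,
                               gap_open = 6, gap_extend = 1) {
  ref <- .check_sequence(ref, "ref")
  query <- .check_sequence(query, "query")
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5L, 5L, dimnames = list(letters5, letters5))
  diag(mat) <- match
  mat["N", ] <- mismatch; mat[, "N"] <- mismatch  # N never counts as a match
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  structure(
    list(
      ref = as.character(Biostrings::alignedPattern(pa)),
      query = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa)
    ),
    class = "grf_alignment"
  )
}

#' @export
print.grf_alignment <- function(x, ...) {
  cat(sprintf("<grf_alignment> %d columns, score %.1f\n", nchar(x$ref), x$score))
  invisible(x)
}
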