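# Pairwise global alignment used by the variant caller.

#' Global pairwise alignment
#'
#' Needleman-Wunsch (Gotoh) global alignment with match/mismatch scoring and
#' an affine gap penalty: a gap run of length L costs `gap_open + gap * L`.
#' The run-opening cost makes a contiguous indel strictly better than any
#' equal-length split, so a planted multi-base indel is always recovered as a
#' single event even when chance matches in the flanks would let a linear
#' penalty tie.  The traceback is deterministic: the aligned state is
#' preferred, then the move consuming a query base (gap in the reference),
#' then the move consuming a reference base.
#'
#' @param query,ref non-empty nucleotide strings (character or
#'   [Biostrings::DNAString])
#' @param match,mismatch per-column scores
#' @param gap_open penalty added once per gap run
#' @param gap penalty per gap column
#' @return list of class `"deaf_alignment"` with `aligned_query`,
#'   `aligned_ref` (equal-length gapped strings) and `score`
#' @examples
#' globalAlign("ACGT", "ACT")
#' @export
globalAlign <- function(query, ref, match = 1, mismatch = -1, gap_open = -2,
                        gap = -2) {
  query <- as.character(query)
  ref <- as.character(ref)
  if (!nzchar(query) || !nzchar(ref)) stop("sequences must be non-empty")
  out <- nw_align_cpp(query, ref, match, mismatch, gap_open, gap)
  structure(out, class = "deaf_alignment")
}

#' @export
print.deaf_alignment <- function(x, ...) {
  cat(sprintf("global alignment, score %g\n", x$score))
  n <- nchar(x$aligned_query)
  if (n <= 70L) {
    cat(" query:", x$aligned_query, "\n   ref:", x$aligned_ref, "\n")
  } else {
    cat(sprintf(" %d columns\n", n))
  }
  invisible(x)
}
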