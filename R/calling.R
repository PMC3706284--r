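# Variant extraction from alignments, left-normalization, legacy naming, and
# the end-to-end caller.

.empty_calls <- function() {
  data.frame(locus = character(), kind = character(), position = integer(),
             ref_allele = character(), alt_allele = character(),
             name = character(), stringsAsFactors = FALSE)
}

#' Construct a variant call record
#'
#' A named sequence change at a locus.  `position` is the 1-based locus
#' coordinate (`c.` for GJB2, `m.` for the mitochondrial locus) of the first
#' affected base; insertions carry the coordinate their first inserted base
#' assumes, with an empty `ref_allele`; deletions have an empty `alt_allele`;
#' a delins has both sides non-empty and of different content/length.
#'
#' @param locus one of `"GJB2"`, `"GJB2_EX1"`, `"MT12S"`
#' @param kind `"substitution"`, `"mnv_substitution"`, `"deletion"`,
#'   `"insertion"` or `"delins"`
#' @param position 1-based locus coordinate
#' @param ref_allele,alt_allele allele strings (empty on exactly one side for
#'   pure indels)
#' @param name optional legacy name; regenerated with [nameVariant()] if
#'   missing
#' @return one-row data.frame call record
#' @examples
#' variantCall("GJB2", "deletion", 235, "C", "")
#' @export
variantCall <- function(locus, kind, position, ref_allele, alt_allele,
                        name = NULL) {
  locus <- match.arg(locus, .LOCI)
  kind <- match.arg(kind, c("substitution", "mnv_substitution", "deletion",
                            "insertion", "delins"))
  stopifnot(position >= 1L)
  if (kind == "deletion" && (nzchar(alt_allele) || !nzchar(ref_allele))) {
    stop("deletion must have empty alt_allele and non-empty ref_allele")
  }
  if (kind == "insertion" && (nzchar(ref_allele) || !nzchar(alt_allele))) {
    stop("insertion must have empty ref_allele and non-empty alt_allele")
  }
  call <- data.frame(locus = locus, kind = kind, position = as.integer(position),
                     ref_allele = ref_allele, alt_allele = alt_allele,
                     name = NA_character_, stringsAsFactors = FALSE)
  call$name <- if (is.null(name)) nameVariant(call) else name
  call
}

#' Extract variant calls from a global alignment
#'
#' Walks the alignment columns and turns every maximal run of non-matching
#' columns into one event: gap-only runs become a deletion or insertion,
#' equal-length mismatch runs a substitution (length 1) or multi-nucleotide
#' substitution, and mixed runs a delins.  Positions are reported in locus
#' coordinates (`position = reference index + coordinate_offset`).  Events
#' whose query segment contains `N` are ambiguous and are dropped with a
#' warning.
#'
#' @param alignment result of [globalAlign()]
#' @param locus locus label for the emitted calls
#' @param coordinate_offset added to reference string indices to obtain locus
#'   coordinates (0 for the GJB2 CDS, `mtOffset(refs) - 1` for the 12S locus)
#' @return data.frame of unnormalized, unnamed calls (name column `NA`)
#' @examples
#' aln <- globalAlign("ACGAA", "ACGTA")
#' extractVariants(aln, "GJB2")
#' @export
extractVariants <- function(alignment, locus, coordinate_offset = 0L) {
  aq <- strsplit(alignment$aligned_query, "")[[1]]
  ar <- strsplit(alignment$aligned_ref, "")[[1]]
  stopifnot(length(aq) == length(ar))
  altered <- aq != ar
  calls <- .empty_calls()
  refpos <- 0L
  i <- 1L
  ncol <- length(aq)
  while (i <= ncol) {
    if (!altered[i]) {
      refpos <- refpos + 1L
      i <- i + 1L
      next
    }
    j <- i
    while (j < ncol && altered[j + 1L]) j <- j + 1L
    ref_seg <- paste(ar[i:j][ar[i:j] != "-"], collapse = "")
    alt_seg <- paste(aq[i:j][aq[i:j] != "-"], collapse = "")
    pos <- refpos + 1L + as.integer(coordinate_offset)
    if (grepl("N", alt_seg, fixed = TRUE)) {
      warning(sprintf(
        "ambiguous base (N) in query at %s position %d: call excluded",
        locus, pos))
    } else {
      kind <- if (!nzchar(ref_seg)) "insertion"
        else if (!nzchar(alt_seg)) "deletion"
        else if (nchar(ref_seg) == nchar(alt_seg)) {
          if (nchar(ref_seg) == 1L) "substitution" else "mnv_substitution"
        } else "delins"
      calls <- rbind(calls, data.frame(
        locus = locus, kind = kind, position = pos, ref_allele = ref_seg,
        alt_allele = alt_seg, name = NA_character_, stringsAsFactors = FALSE))
    }
    refpos <- refpos + sum(ar[i:j] != "-")
    i <- j + 1L
  }
  calls
}

#' Left-normalize a variant call
#'
#' Shifts deletions and insertions in repeat context to their left-most
#' equivalent position (the convention under which the legacy names of this
#' screen were assigned, e.g. `c.235delC`).  Substitutions are returned
#' unchanged; the operation is idempotent.
#'
#' @param call one-row call data.frame (or several rows)
#' @param ref reference sequence (character or DNAString) of the call's locus
#' @param coordinate_offset as in [extractVariants()]
#' @return the call(s) with position and alleles left-shifted
#' @examples
#' call <- variantCall("GJB2", "deletion", 4, "C", "")  # ACCCG: del third C
#' normalizeVariant(call, "ACCCG")$position             # 2 (first C)
#' @export
normalizeVariant <- function(call, ref, coordinate_offset = 0L) {
  ref <- as.character(ref)
  off <- as.integer(coordinate_offset)
  for (r in seq_len(nrow(call))) {
    kind <- call$kind[r]
    p <- call$position[r] - off
    if (kind == "deletion") {
      L <- nchar(call$ref_allele[r])
      while (p > 1L && substr(ref, p - 1L, p - 1L) ==
             substr(ref, p + L - 1L, p + L - 1L)) {
        p <- p - 1L
      }
      call$position[r] <- p + off
      call$ref_allele[r] <- substr(ref, p, p + L - 1L)
    } else if (kind == "insertion") {
      s <- call$alt_allele[r]
      L <- nchar(s)
      while (p > 1L && substr(ref, p - 1L, p - 1L) == substr(s, L, L)) {
        s <- paste0(substr(ref, p - 1L, p - 1L), substr(s, 1L, L - 1L))
        p <- p - 1L
      }
      call$position[r] <- p + off
      call$alt_allele[r] <- s
    }
  }
  call
}

.is_homopolymer <- function(s) {
  nchar(s) > 0L && length(unique(strsplit(s, "")[[1]])) == 1L
}

#' Generate the legacy name of a call
#'
#' Naming policy (chosen to reproduce every catalogued printed name):
#' \describe{
#'   \item{substitution / MNV}{`{prefix}{pos}{ref}>{alt}` (`c.79G>A`,
#'     `c.608TC>AA`)}
#'   \item{deletion}{bases listed when 1-2 bases long (`c.235delC`,
#'     `c.299delAT`), length otherwise (`c.176del16`)}
#'   \item{insertion}{bases listed when at most 4 long (`c.504insAAGG`),
#'     length otherwise (`c.605ins46`)}
#'   \item{delins}{deletion part + `+` + insertion part; a homopolymer
#'     insertion prints its base once, the field convention for the
#'     variable-length C run at m.961 (`m.961delT+insC`)}
#' }
#' The prefix is `c.` for nuclear loci and `m.` for the mitochondrial locus.
#'
#' @param call one-row (or multi-row) call data.frame, already normalized
#' @return character vector of legacy names
#' @examples
#' nameVariant(variantCall("MT12S", "substitution", 1555, "A", "G"))
#' @export
nameVariant <- function(call) {
  del_part <- function(ref) {
    if (nchar(ref) <= 2L) paste0("del", ref) else paste0("del", nchar(ref))
  }
  ins_part <- function(alt, homopoly_collapse = FALSE) {
    if (homopoly_collapse && .is_homopolymer(alt)) {
      paste0("ins", substr(alt, 1L, 1L))
    } else if (nchar(alt) <= 4L) {
      paste0("ins", alt)
    } else {
      paste0("ins", nchar(alt))
    }
  }
  vapply(seq_len(nrow(call)), function(r) {
    prefix <- .locus_prefix(call$locus[r])
    pos <- call$position[r]
    payload <- switch(call$kind[r],
      substitution = ,
      mnv_substitution = paste0(call$ref_allele[r], ">", call$alt_allele[r]),
      deletion = del_part(call$ref_allele[r]),
      insertion = ins_part(call$alt_allele[r]),
      delins = paste0(del_part(call$ref_allele[r]), "+",
                      ins_part(call$alt_allele[r], homopoly_collapse = TRUE)),
      stop("unknown call kind: ", call$kind[r]))
    paste0(prefix, pos, payload)
  }, character(1))
}

#' Call variants in a subject sequence
#'
#' End-to-end caller: global alignment against the locus reference, event
#' extraction, left-normalization and legacy naming.  A query identical to
#' the reference short-circuits to an empty call set.
#'
#' @param query subject sequence (character or DNAString)
#' @param refs a [ReferenceSet-class]
#' @param locus `"GJB2"`, `"GJB2_EX1"` or `"MT12S"`
#' @param match,mismatch,gap_open,gap alignment scoring (see [globalAlign()])
#' @return data.frame of named calls (zero rows for a wild-type query)
#' @examples
#' cat <- loadCatalogue()
#' refs <- referenceSetOf(cat)
#' def <- variantDefinitions(cat)
#' mut <- plantVariant(gjb2Cds(refs), def[def$name == "c.235delC", ])
#' callVariants(mut, refs, "GJB2")$name  # "c.235delC"
#' @export
callVariants <- function(query, refs, locus = c("GJB2", "GJB2_EX1", "MT12S"),
                         match = 1, mismatch = -1, gap_open = -2, gap = -2) {
  locus <- match.arg(locus)
  lr <- .locus_ref(refs, locus)
  query <- as.character(query)
  if (identical(query, lr$seq)) return(.empty_calls())
  aln <- globalAlign(query, lr$seq, match = match, mismatch = mismatch,
                     gap_open = gap_open, gap = gap)
  calls <- extractVariants(aln, locus, coordinate_offset = lr$offset)
  if (nrow(calls) == 0L) return(calls)
  calls <- normalizeVariant(calls, lr$seq, coordinate_offset = lr$offset)
  calls$name <- nameVariant(calls)
  calls
}
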