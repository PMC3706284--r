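#' Reference sequences for the screened loci
#'
#' Holds the GJB2 coding sequence (1-based `c.` coordinates starting at CDS
#' position 1), the mitochondrial 12S rRNA region together with the `m.`
#' coordinate of its first base, and the GJB2 promoter/exon-1 amplicon (a
#' screened region in which no variants are expected).  The shipped references
#' are synthetic stand-ins of realistic length with the catalogue's wild-type
#' base planted at every catalogued position; they are not the GenBank
#' accessions the original screen compared against.
#'
#' @slot gjb2_cds [Biostrings::DNAString] coding sequence, index i == c.i
#' @slot mt12s [Biostrings::DNAString] 12S region, index i == m.(mt_offset+i-1)
#' @slot promoter_exon1 [Biostrings::DNAString] promoter/exon-1 amplicon
#' @slot mt_offset integer(1), `m.` coordinate of `mt12s[1]`
#'
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    gjb2_cds = "DNAString",
    mt12s = "DNAString",
    promoter_exon1 = "DNAString",
    mt_offset = "integer"
  )
)

setValidity("ReferenceSet", function(object) {
  msgs <- character()
  for (nm in c("gjb2_cds", "mt12s", "promoter_exon1")) {
    s <- as.character(slot(object, nm))
    if (nchar(s) == 0L) msgs <- c(msgs, sprintf("%s is empty", nm))
    if (grepl("[^ACGT]", s)) {
      msgs <- c(msgs, sprintf("%s contains characters outside {A,C,G,T}", nm))
    }
  }
  if (length(object@mt_offset) != 1L || is.na(object@mt_offset) ||
      object@mt_offset < 1L) {
    msgs <- c(msgs, "mt_offset must be a single positive integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceSet
#'
#' @param gjb2_cds,mt12s,promoter_exon1 character or DNAString sequences
#' @param mt_offset `m.` coordinate of the first base of `mt12s`
#' @return A [ReferenceSet-class] object.
#' @examples
#' refs <- referenceSet("ACGTACGTAC", "ACGT", "ACGT", mt_offset = 600L)
#' gjb2Cds(refs)
#' @export
referenceSet <- function(gjb2_cds, mt12s, promoter_exon1, mt_offset = 600L) {
  new("ReferenceSet",
      gjb2_cds = Biostrings::DNAString(as.character(gjb2_cds)),
      mt12s = Biostrings::DNAString(as.character(mt12s)),
      promoter_exon1 = Biostrings::DNAString(as.character(promoter_exon1)),
      mt_offset = as.integer(mt_offset))
}

#' @describeIn referenceSet accessor for the GJB2 coding sequence
#' @param x a `ReferenceSet`
#' @export
gjb2Cds <- function(x) x@gjb2_cds

#' @describeIn referenceSet accessor for the mitochondrial 12S sequence
#' @export
mt12sSeq <- function(x) x@mt12s

#' @describeIn referenceSet accessor for the promoter/exon-1 amplicon
#' @export
promoterExon1 <- function(x) x@promoter_exon1

#' @describeIn referenceSet `m.` coordinate of the first base of the 12S slot
#' @export
mtOffset <- function(x) x@mt_offset

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet\n")
  cat(sprintf("  GJB2 CDS          : %d nt (c.1-c.%d)\n",
              length(object@gjb2_cds), length(object@gjb2_cds)))
  cat(sprintf("  MT 12S region     : %d nt (m.%d-m.%d)\n",
              length(object@mt12s), object@mt_offset,
              object@mt_offset + length(object@mt12s) - 1L))
  cat(sprintf("  promoter/exon 1   : %d nt\n", length(object@promoter_exon1)))
})

# sequence (as character) and coordinate offset for a locus; positions in
# locus coordinates map to string index via  index = position - offset
.locus_ref <- function(refs, locus) {
  switch(locus,
    GJB2 = list(seq = as.character(refs@gjb2_cds), offset = 0L),
    GJB2_EX1 = list(seq = as.character(refs@promoter_exon1), offset = 0L),
    MT12S = list(seq = as.character(refs@mt12s), offset = refs@mt_offset - 1L),
    stop("unknown locus: ", locus)
  )
}

#' Predicted RNA secondary structure
#'
#' A nested (pseudoknot-free) secondary structure over an RNA sequence, as
#' produced by [foldRna()]: Watson-Crick or G·U pairs, no base in two pairs,
#' and every hairpin loop at least `min_loop` unpaired bases.
#'
#' @slot sequence character(1), RNA sequence (A/C/G/U)
#' @slot pairs two-column integer matrix of base pairs (i < j, 1-based)
#' @slot dot_bracket character(1) dot-bracket rendering
#' @slot min_loop integer(1) minimum hairpin loop length used
#'
#' @exportClass RnaStructure
setClass("RnaStructure",
  representation(
    sequence = "character",
    pairs = "matrix",
    dot_bracket = "character",
    min_loop = "integer"
  )
)

setValidity("RnaStructure", function(object) {
  msgs <- character()
  s <- object@sequence
  n <- nchar(s)
  if (grepl("[^ACGU]", s)) msgs <- c(msgs, "sequence must be over {A,C,G,U}")
  p <- object@pairs
  if (ncol(p) != 2L) msgs <- c(msgs, "pairs must have two columns")
  if (nrow(p)) {
    if (any(p[, 1] >= p[, 2])) msgs <- c(msgs, "pairs must satisfy i < j")
    if (any(p < 1L) || any(p > n)) msgs <- c(msgs, "pair indices out of range")
    if (anyDuplicated(c(p[, 1], p[, 2]))) {
      msgs <- c(msgs, "a base participates in more than one pair")
    }
    if (any(p[, 2] - p[, 1] <= object@min_loop)) {
      msgs <- c(msgs, sprintf("hairpin loop shorter than min_loop = %d",
                              object@min_loop))
    }
    bases <- strsplit(s, "")[[1]]
    ok <- paste0(bases[p[, 1]], bases[p[, 2]]) %in%
      c("AU", "UA", "GC", "CG", "GU", "UG")
    if (!all(ok)) msgs <- c(msgs, "non-canonical (non-WC/GU) pair present")
    # crossing check: sort by i, ensure proper nesting
    o <- order(p[, 1])
    pi <- p[o, 1]; pj <- p[o, 2]
    if (nrow(p) > 1L) {
      for (a in seq_len(nrow(p) - 1L)) {
        b <- which(pi > pi[a] & pi < pj[a] & pj > pj[a])
        if (length(b)) {
          msgs <- c(msgs, "crossing pairs (pseudoknot) present")
          break
        }
      }
    }
  }
  if (nchar(object@dot_bracket) != n) {
    msgs <- c(msgs, "dot_bracket length differs from sequence length")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn foldRna base-pair matrix accessor (two columns, i < j)
#' @param x an `RnaStructure`
#' @export
basePairs <- function(x) x@pairs

#' @describeIn foldRna dot-bracket string accessor
#' @export
dotBracket <- function(x) x@dot_bracket

#' @describeIn foldRna number of base pairs in the structure
#' @export
nPairs <- function(x) nrow(x@pairs)

setMethod("show", "RnaStructure", function(object) {
  cat(sprintf("RnaStructure: %d nt, %d pairs (min_loop = %d)\n",
              nchar(object@sequence), nrow(object@pairs), object@min_loop))
  if (nchar(object@sequence) <= 60L) {
    cat(" ", object@sequence, "\n ", object@dot_bracket, "\n")
  }
})

#' Embedded screening catalogue
#'
#' Container returned by [loadCatalogue()]: per-variant annotations, concrete
#' ref/alt definitions of every catalogued variant on the synthetic
#' references, the [ReferenceSet-class], and the machine-readable study count
#' tables (per-variant carriers, genotype strata, genotype-phenotype
#' cross-tabulation, mitochondrial variants).
#'
#' @slot annotations data.frame of variant annotations
#' @slot definitions data.frame of concrete ref/alt variant definitions
#' @slot references a [ReferenceSet-class]
#' @slot tables named list of the four fixture tables
#'
#' @exportClass ScreenCatalogue
setClass("ScreenCatalogue",
  representation(
    annotations = "data.frame",
    definitions = "data.frame",
    references = "ReferenceSet",
    tables = "list"
  )
)

#' @describeIn loadCatalogue variant annotation table accessor
#' @param x a `ScreenCatalogue`
#' @export
variantAnnotations <- function(x) x@annotations

#' @describeIn loadCatalogue concrete variant definition table accessor
#' @export
variantDefinitions <- function(x) x@definitions

#' @describeIn loadCatalogue reference sequence accessor
#' @export
referenceSetOf <- function(x) x@references

#' @describeIn loadCatalogue fixture table accessor; `which` one of
#'   `"gjb2_variants"`, `"genotypes"`, `"phenotypes"`, `"mt_variants"`
#' @param which table name (omit for the full list)
#' @export
fixtureTables <- function(x, which = NULL) {
  if (is.null(which)) x@tables else x@tables[[match.arg(which, names(x@tables))]]
}

setMethod("show", "ScreenCatalogue", function(object) {
  ann <- object@annotations
  cat("ScreenCatalogue\n")
  cat(sprintf("  GJB2 variants : %d (%d pathogenic)\n",
              sum(ann$locus == "GJB2"),
              sum(ann$locus == "GJB2" & ann$category == "pathogenic")))
  cat(sprintf("  MT12S variants: %d (%d known pathogenic)\n",
              sum(ann$locus == "MT12S"),
              sum(ann$locus == "MT12S" & ann$category == "pathogenic")))
  cat(sprintf("  tables        : %s\n", paste(names(object@tables), collapse = ", ")))
})
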